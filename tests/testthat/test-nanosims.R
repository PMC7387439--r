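test_that("single-scan alignment is the identity", {
  sim <- sim_single_cell(seed = 1)
  al <- align_scans(sim$stack)
  expect_equal(nrow(al$shifts), 1)
  expect_equal(c(al$shifts$d_row, al$shifts$d_col), c(0L, 0L))
  expect_true(all(al$valid_mask))
  expect_equal(al$counts[["13C"]],
               matrix(sim$stack$counts[1, "13C", , ], 48, 48) + 0)
})

test_that("two identical scans align at zero shift and double the counts", {
  sim <- sim_single_cell(seed = 2)
  one <- sim$stack$counts[1, , , , drop = FALSE]
  two <- array(0L, dim = c(2, dim(one)[2:4]),
               dimnames = dimnames(one))
  two[1, , , ] <- one[1, , , ]
  two[2, , , ] <- one[1, , , ]
  al <- align_scans(ion_count_stack(two, species = sim$stack$species))
  expect_equal(al$shifts$d_row, c(0L, 0L))
  expect_equal(sum(al$counts[["12C14N"]]), 2 * sum(one[1, "12C14N", , ]))
})

test_that("known integer drift is recovered exactly", {
  cells <- cell_grid(4, field_size = 96, lambda_C = 100, lambda_CN = 100)
  sim <- sim_image_stack(cells, field_size = 96, n_scans = 5,
                         drift = c(2, 1), seed = 3)
  al <- align_scans(sim$stack)
  expect_equal(al$shifts$d_row, c(0L, 2L, 4L, 6L, 8L))
  expect_equal(al$shifts$d_col, c(0L, 1L, 2L, 3L, 4L))
})

test_that("count conservation holds under alignment within the valid mask", {
  cells <- cell_grid(2, field_size = 64, lambda_C = 60, lambda_CN = 60)
  sim <- sim_image_stack(cells, field_size = 64, n_scans = 3,
                         drift = c(1, 2), seed = 4)
  al <- align_scans(sim$stack)
  # recompute the accumulation by hand from the recovered shifts
  for (sp in c("12C", "12C15N")) {
    manual <- matrix(0, 64, 64)
    for (s in 1:3) {
      dr <- al$shifts$d_row[s]; dc <- al$shifts$d_col[s]
      img <- matrix(sim$stack$counts[s, sp, , ], 64, 64)
      dst_r <- max(1, 1 - dr):min(64, 64 - dr)
      dst_c <- max(1, 1 - dc):min(64, 64 - dc)
      manual[dst_r, dst_c] <- manual[dst_r, dst_c] + img[dst_r + dr, dst_c + dc]
    }
    expect_equal(al$counts[[sp]][al$valid_mask], manual[al$valid_mask])
  }
})

test_that("an all-zero reference channel falls back to identity with warning", {
  sim <- sim_single_cell(seed = 5)
  z <- sim$stack$counts
  z[, "12C14N", , ] <- 0L
  stack <- ion_count_stack(z, species = sim$stack$species)
  expect_warning(al <- align_scans(stack), "identity")
  expect_equal(al$status, "degenerate_reference")
  expect_equal(al$shifts$d_row, 0L)
})

test_that("ROI ratios use summed counts and map to atom fractions exactly", {
  img <- structure(
    list(counts = list("12C" = matrix(50, 4, 4), "13C" = matrix(50, 4, 4),
                       "12C14N" = matrix(80, 4, 4), "12C15N" = matrix(0, 4, 4)),
         valid_mask = matrix(TRUE, 4, 4),
         species = c("12C", "13C", "12C14N", "12C15N"),
         shifts = tibble::tibble(scan = 0L, d_row = 0L, d_col = 0L),
         status = "ok"),
    class = "aligned_image"
  )
  mask <- matrix(0L, 4, 4); mask[1:2, 1:2] <- 1L
  m <- measure_rois(img, mask)
  expect_equal(m$R13, 1)
  expect_equal(m$F_C, 0.5)   # equal heavy and light sums
  expect_equal(m$R15, 0)
  expect_equal(m$F_N, 0)     # zero heavy counts is a defined zero
  expect_true(m$defined_N)
})

test_that("zero denominator counts flag the isotope as undefined", {
  img <- structure(
    list(counts = list("12C" = matrix(0, 3, 3), "13C" = matrix(5, 3, 3),
                       "12C14N" = matrix(10, 3, 3), "12C15N" = matrix(1, 3, 3)),
         valid_mask = matrix(TRUE, 3, 3),
         species = c("12C", "13C", "12C14N", "12C15N"),
         shifts = tibble::tibble(scan = 0L, d_row = 0L, d_col = 0L),
         status = "ok"),
    class = "aligned_image"
  )
  mask <- matrix(1L, 3, 3)
  m <- measure_rois(img, mask)
  expect_false(m$defined_C)
  expect_true(is.na(m$F_C))
  expect_true(m$defined_N)
})

test_that("ratio-of-sums is invariant to splitting an ROI and pooling", {
  sim <- sim_single_cell(F_C = 0.3, lambda = 200, seed = 6)
  al <- align_scans(sim$stack)
  whole <- measure_rois(al, sim$roi_mask)
  split_mask <- sim$roi_mask
  px <- which(split_mask == 1)
  split_mask[px[seq(1, length(px), 2)]] <- 2L
  parts <- measure_rois(al, split_mask)
  pooled_R <- sum(parts$c13) / sum(parts$c12)
  expect_equal(pooled_R, whole$R13)
})

test_that("measured F converges to truth as total counts grow", {
  errs <- vapply(c(10, 100, 1000), function(lambda) {
    sim <- sim_single_cell(F_C = 0.25, lambda = lambda, seed = lambda)
    m <- measure_rois(align_scans(sim$stack), sim$roi_mask)
    abs(m$F_C - 0.25)
  }, numeric(1))
  # each error within its own 4-sigma binomial band; bands shrink 10x
  ns <- c(10, 100, 1000) * 49
  expect_true(all(errs < 4 * sqrt(0.25 * 0.75 / ns)))
})

test_that("IMF calibration recovers identity and two-point lines", {
  std <- tibble::tibble(inst = c(0.01, 0.1, 0.4), ref = c(0.01, 0.1, 0.4))
  ident <- fit_imf_calibration(std, inst, ref, "C")
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  two <- fit_imf_calibration(
    tibble::tibble(inst = c(0.01, 0.5), ref = c(0.012, 0.6)), inst, ref, "C")
  expect_equal(two$slope, 1.2, tolerance = 1e-12)
  expect_equal(two$intercept, 0, tolerance = 1e-12)
  expect_equal(apply_calibration(two, 0.25), 0.3)

  expect_error(fit_imf_calibration(std[1, ], inst, ref), "2 standards")
  expect_error(fit_imf_calibration(
    tibble::tibble(inst = c(0.1, 0.1), ref = c(0.1, 0.2)), inst, ref),
    "variance")
})

test_that("calibration round-trips a known line under noise", {
  set.seed(8)
  inst <- seq(0.01, 0.6, length.out = 12)
  ref <- 1.15 * inst + 0.002 + rnorm(12, 0, 0.003)
  fit <- fit_imf_calibration(tibble::tibble(inst, ref), inst, ref, "N")
  co <- tidy(fit)
  expect_lt(abs(co$estimate[co$term == "slope"] - 1.15),
            3 * co$std.error[co$term == "slope"])
  expect_lt(abs(co$estimate[co$term == "(Intercept)"] - 0.002),
            3 * co$std.error[co$term == "(Intercept)"])
  expect_equal(glance(fit)$n_standards, 12)
})

test_that("labeling strength is the concentration-weighted atom fraction", {
  expect_equal(labeling_strength(15, 0.99, 0, 0.0111), 0.99)
  expect_equal(labeling_strength(15, 0.99, 2400, 0.0111),
               (15 * 0.99 + 2400 * 0.0111) / 2415)
  expect_equal(labeling_strength(15, 0.99, 2400, 0.0111), 0.01718,
               tolerance = 1e-4)
  expect_equal(labeling_strength(5, 0.99, 5, 0.0111), 0.50055)
  expect_error(labeling_strength(0, 0.99, 0, 0.0111), "positive")
  expect_error(labeling_strength(-1, 0.99, 1, 0.0111), "non-negative")
})
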
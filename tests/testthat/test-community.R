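test_that("relative abundances are per-sample proportions", {
  counts <- matrix(c(1, 3, 10, 30), 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tb <- otu_table(counts, c("experiment", "experiment"))
  rel <- relative_abundance(tb)
  expect_equal(unname(colSums(rel)), c(1, 1))
  expect_equal(unname(rel[, "s1"]), c(0.25, 0.75))
  expect_equal(rel[, "s1"], rel[, "s2"])  # scale invariance

  zero <- otu_table(matrix(c(1, 0, 0, 0), 2), c("experiment", "experiment"))
  expect_error(relative_abundance(zero), "all-zero")
})

test_that("Bray-Curtis matches the hand formula and its invariants", {
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  bc <- bray_curtis(cbind(s1 = x, s2 = y))
  expect_equal(bc["s1", "s2"], 1 / 3)
  expect_equal(bray_curtis(cbind(a = x, b = x))["a", "b"], 0)
  expect_equal(bray_curtis(cbind(a = c(5, 0), b = c(0, 7)))["a", "b"], 1)
  expect_equal(bray_curtis(cbind(a = x, b = 10 * x))["a", "b"], 0)

  sim <- sim_otu_table(n_otus = 30, seed = 12)
  d <- bray_curtis(sim$table)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, ncol(d)))
  expect_true(all(d >= 0 & d <= 1))
  # cross-check against the explicit double sum on two samples
  rel <- relative_abundance(sim$table)
  manual <- sum(abs(rel[, 1] - rel[, 2])) / sum(rel[, 1] + rel[, 2])
  expect_equal(unname(d[1, 2]), manual)
})

test_that("contaminant flagging is directional and matches aov p-values", {
  sim <- sim_otu_table(n_otus = 40, contaminant_otus = 3, effect_size = 10,
                       seed = 13)
  res <- flag_contaminants(sim$table, "extraction_blank")
  expect_true(all(sim$contaminants %in% res$otu[res$flagged]))

  # p-values equal classical one-way ANOVA (aov) on relative abundances
  rel <- relative_abundance(sim$table)
  keep <- sim$table$groups %in% c("extraction_blank", "experiment")
  grp <- factor(sim$table$groups[keep])
  for (otu in c(sim$contaminants[1], setdiff(res$otu, sim$contaminants)[1])) {
    p_aov <- summary(stats::aov(rel[otu, keep] ~ grp))[[1]]$`Pr(>F)`[1]
    expect_equal(res$p_value[res$otu == otu], p_aov, tolerance = 1e-12)
  }

  # and agree with a permutation oracle on a contaminated OTU
  v <- rel[sim$contaminants[1], keep]
  p_perm <- perm_anova_p(v, grp)
  expect_lt(abs(res$p_value[res$otu == sim$contaminants[1]] - p_perm), 0.05)

  # an OTU enriched in EXPERIMENT samples is never flagged
  counts <- sim$table$counts
  counts["OTU_001", sim$table$groups == "experiment"] <-
    counts["OTU_001", sim$table$groups == "experiment"] + 5000L
  res2 <- flag_contaminants(otu_table(counts, sim$table$groups),
                            "extraction_blank")
  row <- dplyr::filter(res2, otu == "OTU_001")
  expect_gt(row$mean_experiment, row$mean_control)
  expect_false(row$flagged)
})

test_that("a constant-abundance OTU is never flagged", {
  counts <- matrix(100L, 3, 6,
                   dimnames = list(paste0("o", 1:3), paste0("s", 1:6)))
  tb <- otu_table(counts, rep(c("experiment", "extraction_blank"), each = 3))
  res <- flag_contaminants(tb, "extraction_blank")
  expect_false(any(res$flagged))
})

test_that("insufficient replication is an error, not a silent pass", {
  counts <- matrix(10L, 3, 3)
  tb <- otu_table(counts, c("experiment", "experiment", "extraction_blank"))
  expect_error(flag_contaminants(tb, "extraction_blank"), "2 samples")
})

test_that("decontamination removes seeded contaminants sequentially", {
  sim <- sim_otu_table(n_samples = 12, n_blanks = 8, n_ntc = 6,
                       n_otus = 50, contaminant_otus = 5, effect_size = 10,
                       seed = 14)
  out <- decontaminate(sim$table)
  expect_true(all(sim$contaminants %in% out$removed))
  expect_false(any(out$removed %in% rownames(out$table$counts)))
  expect_true(all(out$table$groups == "experiment"))
  expect_true(all(c("pass", "p_value", "flagged") %in% names(out$log)))
})

test_that("decontamination without controls warns and returns unchanged", {
  counts <- matrix(rpois(40, 20), 10, 4,
                   dimnames = list(paste0("o", 1:10), paste0("s", 1:4)))
  tb <- otu_table(counts, rep("experiment", 4))
  expect_warning(out <- decontaminate(tb), "unchanged")
  expect_equal(out$table$counts, counts)
  expect_length(out$removed, 0)
})

test_that("decontamination is idempotent", {
  sim <- sim_otu_table(n_otus = 40, contaminant_otus = 4, seed = 15)
  once <- decontaminate(sim$table)
  expect_warning(twice <- decontaminate(once$table), "unchanged")
  expect_identical(twice$table$counts, once$table$counts)
  expect_length(twice$removed, 0)
})

test_that("sequential filtering differs from simultaneous when masking occurs", {
  tb <- otu_sequential_fixture()
  rel <- relative_abundance(tb)
  ctl <- tb$groups != "experiment"
  # raw table: B is LESS abundant in controls than in experiment samples
  expect_lt(mean(rel["B", ctl]), mean(rel["B", !ctl]))

  # simultaneous (both tests on the raw table) removes only A
  f_blank <- flag_contaminants(tb, "extraction_blank")
  f_ntc <- flag_contaminants(tb, "pcr_ntc")
  simultaneous <- union(f_blank$otu[f_blank$flagged], f_ntc$otu[f_ntc$flagged])
  expect_equal(simultaneous, "A")

  # sequential: after removing A, control columns renormalize and expose B
  seq_out <- decontaminate(tb)
  expect_setequal(seq_out$removed, c("A", "B"))
})
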
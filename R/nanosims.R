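#' Construct an ion-count stack
#'
#' Container for raw multi-scan, multi-species NanoSIMS pixel counts from
#' one imaged field.
#'
#' @param counts Non-negative integer array indexed `(scan, species, row,
#'   column)` with species names on the second dimension.
#' @param species Ordered species names; a subset of `"12C"`, `"13C"`,
#'   `"12C14N"`, `"12C15N"`, `"32S"`. The four ratio species are
#'   required; `"32S"` is optional.
#' @param pixel_size Pixel edge length in micrometres.
#' @param dwell_time Counting time per pixel in milliseconds.
#'
#' @return An object of class `ion_count_stack`.
#' @export
ion_count_stack <- function(counts, species = dimnames(counts)[[2]],
                            pixel_size = 25 / 256, dwell_time = 5) {
  if (length(dim(counts)) != 4) {
    abort("`counts` must be a 4-d array (scan, species, row, column)")
  }
  known <- c("12C", "13C", "12C14N", "12C15N", "32S")
  if (is.null(species) || !all(species %in% known)) {
    abort(paste("species must be drawn from:", paste(known, collapse = ", ")))
  }
  needed <- c("12C", "13C", "12C14N", "12C15N")
  if (!all(needed %in% species)) {
    abort("the four ratio species (12C, 13C, 12C14N, 12C15N) are required")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  dimnames(counts)[[2]] <- species
  structure(
    list(counts = counts, species = species,
         pixel_size = pixel_size, dwell_time = dwell_time),
    class = "ion_count_stack"
  )
}

#' @export
print.ion_count_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<ion_count_stack: %d scan(s), %d species, %d x %d px>\n",
              d[1], d[2], d[3], d[4]))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

# Cross-correlation score for shift (dr, dc), computed over the
# overlapping region only. A scan whose content drifted by +(dr, dc)
# relative to the reference scores highest at that offset: scan pixel
# (r + dr, c + dc) shows the content the reference holds at (r, c).
.xcorr_at <- function(ref, img, dr, dc) {
  n <- nrow(ref); m <- ncol(ref)
  r_ref <- max(1, 1 - dr):min(n, n - dr)
  c_ref <- max(1, 1 - dc):min(m, m - dc)
  sum(ref[r_ref, c_ref] * img[r_ref + dr, c_ref + dc])
}

#' Align scans of an ion-count stack and accumulate counts
#'
#' Corrects inter-scan image drift by integer-pixel cross-correlation of
#' each scan's reference-species image against scan 0, then sums the
#' shifted scans. For each scan the shift maximizing the cross-correlation
#' over a `(2 * window + 1)^2` offset grid is chosen; ties are broken
#' toward the smallest offset magnitude, then row-major order. The
#' accumulated image is only valid where every shifted scan contributed,
#' recorded in `valid_mask`.
#'
#' @param stack An [ion_count_stack()].
#' @param reference_species Species used for registration (default
#'   `"12C14N"`, the cyanide channel on which cells are recognized).
#' @param window Maximum absolute shift searched, in pixels.
#'
#' @return An object of class `aligned_image`: list with `counts` (named
#'   list of per-species accumulated matrices), `shifts` (tibble: `scan`,
#'   `d_row`, `d_col`), `valid_mask` (logical matrix) and `status`
#'   (`"ok"` or `"degenerate_reference"`).
#' @export
#' @examples
#' sim <- sim_image_stack(cell_grid(1), n_scans = 3, drift = c(2, 1), seed = 1)
#' align_scans(sim$stack)$shifts
align_scans <- function(stack, reference_species = "12C14N", window = 10) {
  stopifnot(inherits(stack, "ion_count_stack"))
  d <- dim(stack$counts)
  n_scans <- d[1]
  if (n_scans < 1) abort("stack has no scans")
  if (!reference_species %in% stack$species) {
    abort(sprintf("reference species '%s' not in stack", reference_species))
  }

  ref <- stack$counts[1, reference_species, , , drop = TRUE]
  if (n_scans == 1) ref <- matrix(ref, d[3], d[4])
  status <- "ok"
  shifts <- matrix(0L, n_scans, 2)

  if (all(ref == 0)) {
    warn("reference channel is all zero; alignment undefined, using identity shifts")
    status <- "degenerate_reference"
  } else if (n_scans > 1) {
    offs <- expand.grid(d_row = -window:window, d_col = -window:window)
    offs <- offs[order(offs$d_row^2 + offs$d_col^2, offs$d_row, offs$d_col), ]
    for (s in 2:n_scans) {
      img <- stack$counts[s, reference_species, , , drop = TRUE]
      score <- mapply(function(dr, dc) .xcorr_at(ref, img, dr, dc),
                      offs$d_row, offs$d_col)
      best <- which.max(score)  # first max = smallest magnitude on ties
      shifts[s, ] <- c(offs$d_row[best], offs$d_col[best])
    }
  }

  # Accumulate: scan s content at pixel (r, c) maps back to reference
  # coordinates (r - d_row, c - d_col).
  acc <- lapply(stack$species, function(sp) matrix(0, d[3], d[4]))
  names(acc) <- stack$species
  valid <- matrix(TRUE, d[3], d[4])
  for (s in seq_len(n_scans)) {
    dr <- shifts[s, 1]; dc <- shifts[s, 2]
    r_dst <- max(1, 1 - dr):min(d[3], d[3] - dr)
    c_dst <- max(1, 1 - dc):min(d[4], d[4] - dc)
    covered <- matrix(FALSE, d[3], d[4])
    covered[r_dst, c_dst] <- TRUE
    valid <- valid & covered
    for (sp in stack$species) {
      img <- matrix(stack$counts[s, sp, , , drop = TRUE], d[3], d[4])
      acc[[sp]][r_dst, c_dst] <- acc[[sp]][r_dst, c_dst] +
        img[r_dst + dr, c_dst + dc]
    }
  }

  structure(
    list(counts = acc,
         shifts = tibble::tibble(scan = seq_len(n_scans) - 1L,
                                 d_row = shifts[, 1], d_col = shifts[, 2]),
         valid_mask = valid,
         species = stack$species,
         status = status),
    class = "aligned_image"
  )
}

#' @export
print.aligned_image <- function(x, ...) {
  cat(sprintf("<aligned_image: %d species, %d x %d px, %d scan(s), status: %s>\n",
              length(x$counts), nrow(x$valid_mask), ncol(x$valid_mask),
              nrow(x$shifts), x$status))
  invisible(x)
}

#' Measure isotope ratios and atom fractions over cell ROIs
#'
#' Sums the accumulated counts of each species over every labeled region
#' of interest and computes the isotope ratios `R13 = 13C / 12C` and
#' `R15 = 12C15N / 12C14N` as ratios of summed counts (never means of
#' per-pixel ratios), then atom fractions `F = R / (1 + R)`. Background
#' pixels outside every ROI are excluded. A zero denominator sum flags the
#' measurement as undefined for that isotope rather than returning zero.
#'
#' @param image An [align_scans()] result.
#' @param roi_mask Integer label matrix (0 = background) in reference-scan
#'   coordinates; labeled pixels must lie within `image$valid_mask`.
#' @param calibration_C,calibration_N Optional [fit_imf_calibration()]
#'   curves applied to the raw ratios before conversion to atom
#'   fractions.
#'
#' @return A tibble with one row per ROI: `roi_id`, `n_pixels`, summed
#'   counts (`c12`, `c13`, `cn14`, `cn15`, `s32`), ratios (`R13`, `R15`),
#'   atom fractions (`F_C`, `F_N`) and definedness flags (`defined_C`,
#'   `defined_N`).
#' @export
#' @examples
#' sim <- sim_image_stack(cell_grid(2, F_C = 0.5), seed = 1)
#' measure_rois(align_scans(sim$stack), sim$roi_mask)
measure_rois <- function(image, roi_mask,
                         calibration_C = NULL, calibration_N = NULL) {
  stopifnot(inherits(image, "aligned_image"))
  if (!all(dim(roi_mask) == dim(image$valid_mask))) {
    abort("`roi_mask` dimensions do not match the image")
  }
  ids <- sort(unique(roi_mask[roi_mask > 0]))
  if (length(ids) == 0) abort("`roi_mask` contains no labeled pixels")
  if (any(roi_mask > 0 & !image$valid_mask)) {
    abort("ROI pixels fall outside the valid (all-scan) region")
  }

  sum_sp <- function(sp, px) {
    if (sp %in% names(image$counts)) sum(image$counts[[sp]][px]) else NA_real_
  }
  rows <- purrr::map_dfr(ids, function(id) {
    px <- roi_mask == id
    tibble::tibble(
      roi_id = id,
      n_pixels = sum(px),
      c12 = sum_sp("12C", px), c13 = sum_sp("13C", px),
      cn14 = sum_sp("12C14N", px), cn15 = sum_sp("12C15N", px),
      s32 = sum_sp("32S", px)
    )
  })

  ratio_block <- function(heavy, light, curve) {
    defined <- light > 0
    R <- ifelse(defined, heavy / light, NA_real_)
    if (!is.null(curve)) R <- apply_calibration(curve, R)
    list(R = R, F = R / (1 + R), defined = defined)
  }
  cb <- ratio_block(rows$c13, rows$c12, calibration_C)
  nb <- ratio_block(rows$cn15, rows$cn14, calibration_N)
  dplyr::mutate(rows,
                R13 = cb$R, R15 = nb$R,
                F_C = cb$F, F_N = nb$F,
                defined_C = cb$defined, defined_N = nb$defined)
}

#' Fit an instrumental mass fractionation (IMF) calibration
#'
#' Ordinary least squares of reference (bulk) isotope ratios on
#' single-cell instrument ratios, as obtained from standards of varying
#' enrichment measured both on the ion probe and in bulk. The fitted line
#' maps raw instrument ratios onto the true ratio scale.
#'
#' @param data Data frame holding the standards.
#' @param instrument,reference Column names (unquoted) of the instrument
#'   and reference ratios.
#' @param isotope `"C"` or `"N"` (metadata).
#'
#' @return An object of class `imf_calibration` with `slope`,
#'   `intercept`, `isotope`, `n_standards`, `sigma` (residual spread) and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' std <- tibble::tibble(measured = c(0.01, 0.5), bulk = c(0.012, 0.6))
#' fit_imf_calibration(std, measured, bulk, isotope = "C")
fit_imf_calibration <- function(data, instrument, reference, isotope = c("C", "N")) {
  isotope <- match.arg(isotope)
  x <- dplyr::pull(data, {{ instrument }})
  y <- dplyr::pull(data, {{ reference }})
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) abort("at least 2 standards are required")
  if (sd(x) == 0) abort("instrument ratios have zero variance")
  fit <- lm(y ~ x)
  if (coef(fit)[["x"]] <= 0) {
    warn("fitted calibration slope is non-positive; check standards")
  }
  structure(
    list(slope = unname(coef(fit)[["x"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         isotope = isotope,
         n_standards = length(x),
         # exact standards make lm warn about a perfect fit; sigma = 0 is fine
         sigma = suppressWarnings(summary(fit)$sigma),
         fit = fit,
         data = tibble::tibble(instrument = x, reference = y)),
    class = "imf_calibration"
  )
}

#' Identity calibration (pass-through)
#'
#' Used when no standards are available; raw instrument ratios are taken
#' as true ratios and a warning is logged.
#'
#' @param isotope `"C"` or `"N"`.
#' @param quiet Suppress the warning.
#' @return An `imf_calibration` with slope 1 and intercept 0.
#' @export
identity_calibration <- function(isotope = c("C", "N"), quiet = FALSE) {
  isotope <- match.arg(isotope)
  if (!quiet) warn("no standards supplied; using identity IMF calibration")
  structure(
    list(slope = 1, intercept = 0, isotope = isotope,
         n_standards = 0L, sigma = NA_real_, fit = NULL, data = NULL),
    class = "imf_calibration"
  )
}

#' Apply an IMF calibration to instrument ratios
#'
#' @param curve An [fit_imf_calibration()] object.
#' @param R Numeric vector of raw instrument ratios.
#' @return Calibrated ratios, clipped at 0.
#' @export
apply_calibration <- function(curve, R) {
  stopifnot(inherits(curve, "imf_calibration"))
  pmax(0, curve$slope * R + curve$intercept)
}

#' @export
print.imf_calibration <- function(x, ...) {
  cat(sprintf("<imf_calibration (%s): true = %.6g * instrument + %.6g, n = %d>\n",
              x$isotope, x$slope, x$intercept, x$n_standards))
  invisible(x)
}

#' @rdname fit_imf_calibration
#' @param x An `imf_calibration` object.
#' @param ... Unused.
#' @export
tidy.imf_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("(Intercept)", "slope"),
                          estimate = c(x$intercept, x$slope),
                          std.error = NA_real_))
  }
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"])
}

#' @rdname fit_imf_calibration
#' @export
glance.imf_calibration <- function(x, ...) {
  tibble::tibble(isotope = x$isotope, slope = x$slope,
                 intercept = x$intercept, n_standards = x$n_standards,
                 sigma = x$sigma)
}

#' Labeling strength after dilution into the ambient pool
#'
#' The effective heavy-isotope atom fraction of a substrate pool after an
#' isotopically enriched dose is mixed into the ambient (e.g. dissolved
#' inorganic carbon) pool: the concentration-weighted mean of the two
#' atom fractions.
#'
#' @param added_conc,ambient_conc Concentrations (same units, e.g. µM).
#' @param added_F,ambient_F Atom fractions of the added dose and the
#'   ambient pool.
#' @return The mixed atom fraction `F_label`.
#' @export
#' @examples
#' labeling_strength(15, 0.99, 2400, 0.0111)  # 13C-bicarbonate into DIC
labeling_strength <- function(added_conc, added_F, ambient_conc, ambient_F) {
  if (any(added_conc < 0) || any(ambient_conc < 0)) {
    abort("concentrations must be non-negative")
  }
  total <- added_conc + ambient_conc
  if (any(total == 0)) abort("total concentration must be positive")
  frs <- c(added_F, ambient_F)
  if (any(frs < 0 | frs > 1)) abort("atom fractions must lie in [0, 1]")
  (added_conc * added_F + ambient_conc * ambient_F) / total
}
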
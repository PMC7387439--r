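#' Describe an incubation: label strengths, duration, thresholds
#'
#' Bundles everything needed to interpret single-cell atom fractions from
#' one incubation: the incubation duration, the labeling strengths and
#' natural abundances per isotope, and the activity thresholds derived
#' from the membrane background (99.7% confidence bound; defaults 1.24
#' atom % for 13C and 0.446 atom % for 15N).
#'
#' @param sample_id,substrate Identifiers.
#' @param t Incubation duration in days (> 0).
#' @param F_label_C,F_label_N Labeling strengths (atom fractions).
#' @param F_nat_C,F_nat_N Natural-abundance atom fractions.
#' @param threshold_C,threshold_N Activity thresholds (atom fractions);
#'   must lie strictly between the natural abundance and the labeling
#'   strength of their isotope.
#'
#' @return An object of class `incubation_setup`.
#' @export
incubation_setup <- function(sample_id, substrate, t,
                             F_label_C = 0.99, F_label_N = 0.99,
                             F_nat_C = F_NAT_C_DEFAULT,
                             F_nat_N = F_NAT_N_DEFAULT,
                             threshold_C = THRESHOLD_C_DEFAULT,
                             threshold_N = THRESHOLD_N_DEFAULT) {
  if (t <= 0) abort("incubation duration `t` must be positive")
  if (!(F_nat_C < threshold_C && threshold_C < F_label_C)) {
    abort("need F_nat_C < threshold_C < F_label_C")
  }
  if (!(F_nat_N < threshold_N && threshold_N < F_label_N)) {
    abort("need F_nat_N < threshold_N < F_label_N")
  }
  structure(
    list(sample_id = sample_id, substrate = substrate, t = t,
         F_label_C = F_label_C, F_label_N = F_label_N,
         F_nat_C = F_nat_C, F_nat_N = F_nat_N,
         threshold_C = threshold_C, threshold_N = threshold_N),
    class = "incubation_setup"
  )
}

#' Activity threshold from membrane-background measurements
#'
#' The threshold above which a cell's atom fraction is called enrichment
#' rather than background: the mean plus three sample standard deviations
#' of background atom fractions measured on cell-free membrane (the
#' one-sided 99.7% exceedance bound). A fixed override reproduces the
#' published constants independent of the supplied values.
#'
#' @param background_F Numeric vector of background atom fractions (at
#'   least 3 values).
#' @param fixed Optional fixed threshold returned as-is.
#' @return The threshold as an atom fraction.
#' @export
#' @examples
#' background_threshold(c(0.010, 0.011, 0.012))  # 0.011 + 3 * 0.001
background_threshold <- function(background_F, fixed = NULL) {
  if (!is.null(fixed)) return(fixed)
  if (length(background_F) < 3) {
    abort("at least 3 background measurements are required")
  }
  mean(background_F) + 3 * sd(background_F)
}

#' Classify ROIs as active by isotope enrichment
#'
#' A cell is active for an isotope when its atom fraction strictly
#' exceeds that isotope's background threshold; it is active overall when
#' active for either isotope. Measurements flagged undefined (zero
#' denominator counts) are inactive for that isotope.
#'
#' @param meas Tibble of ROI measurements with columns `F_C`, `F_N` and
#'   (optionally) `defined_C`, `defined_N`, as from [measure_rois()] or
#'   [read_roi_table()].
#' @param setup An [incubation_setup()].
#' @return `meas` with logical columns `active_C`, `active_N`, `active`
#'   appended.
#' @export
classify_active <- function(meas, setup) {
  stopifnot(inherits(setup, "incubation_setup"))
  def_C <- if ("defined_C" %in% names(meas)) meas$defined_C else !is.na(meas$F_C)
  def_N <- if ("defined_N" %in% names(meas)) meas$defined_N else !is.na(meas$F_N)
  dplyr::mutate(
    tibble::as_tibble(meas),
    active_C = def_C & !is.na(.data$F_C) & .data$F_C > setup$threshold_C,
    active_N = def_N & !is.na(.data$F_N) & .data$F_N > setup$threshold_N,
    active = .data$active_C | .data$active_N
  )
}

#' Biomass-based specific growth rate
#'
#' `mu_B = (ln X_t - ln X_0) / t` from a cell-count time series. A decline
#' in abundance yields a negative rate, returned as-is.
#'
#' @param series Data frame with columns `day` and `cells_per_cm3`; must
#'   contain day 0.
#' @param day The incubation day `t` at which to evaluate (must be
#'   present and positive).
#' @return `mu_B` in per day.
#' @export
#' @examples
#' ts <- tibble::tibble(day = c(0, 21), cells_per_cm3 = c(1e3, 1e3 * exp(0.284 * 21)))
#' biomass_growth_rate(ts, 21)
biomass_growth_rate <- function(series, day) {
  if (!0 %in% series$day) abort("the series must contain a day-0 observation")
  if (day <= 0) abort("`day` must be positive")
  if (!day %in% series$day) abort(sprintf("no observation at day %s", day))
  x0 <- series$cells_per_cm3[match(0, series$day)]
  xt <- series$cells_per_cm3[match(day, series$day)]
  if (x0 <= 0 || xt <= 0) abort("cell counts must be positive")
  (log(xt) - log(x0)) / day
}

#' Biomass-based doubling time
#'
#' `T_d = ln 2 / mu_B`; not determinable (`NA`) for non-positive growth
#' rates.
#'
#' @param mu_B Specific growth rate(s), per day.
#' @return Doubling time(s) in days.
#' @export
doubling_time <- function(mu_B) {
  ifelse(mu_B > 0, log(2) / mu_B, NA_real_)
}

#' Substrate-incorporation-based biomass generation rate
#'
#' Inverts the single-cell labeling kinetics: a cell generating biomass
#' at rate `mu_S` from a substrate pool of labeling strength `F_label`
#' reaches atom fraction `F_t` after `t` days, so
#' `mu_S = -ln(1 - (F_t - F_nat) / (F_label - F_nat)) / t`. The rate
#' covers maintenance turnover as well as division. Atom fractions below
#' natural abundance clamp the incorporated fraction at 0 (`mu_S = 0`,
#' measurement noise, not excretion); `F_t >= F_label` is saturated and
#' not determinable (`NA`).
#'
#' @param F_t Measured atom fraction(s) of the cell.
#' @param F_nat Natural-abundance atom fraction.
#' @param F_label Labeling strength of the substrate pool.
#' @param t Incubation duration in days.
#' @return `mu_S` in per day (vectorized over `F_t`).
#' @export
#' @examples
#' substrate_rate(0.4896, F_nat = 0.011, F_label = 0.99, t = 21)
substrate_rate <- function(F_t, F_nat, F_label, t) {
  if (any(F_label <= F_nat)) abort("`F_label` must exceed `F_nat`")
  if (any(t <= 0)) abort("`t` must be positive")
  frac <- pmax(0, (F_t - F_nat) / (F_label - F_nat))
  ifelse(is.na(F_t), NA_real_,
         ifelse(frac >= 1, NA_real_, -log(1 - frac) / t))
}

#' Originally active fraction of the community
#'
#' Back-calculates the fraction `f_0` of cells that were active in the
#' original sample from the observed active ROI fraction `f_t` and the
#' biomass increase factor `A = X_t / X_0`, assuming inactive cells
#' neither grew nor died: `f_0 = 1 - A * (1 - f_t)`. The estimate is only
#' determinable when `f_t < 1`, the implied original inactive pool does
#' not exceed the original population (`A * (1 - f_t) <= 1`), and enough
#' ROIs were analyzed to give sampling depth.
#'
#' @param A Biomass increase factor (`X_t / X_0`, > 0).
#' @param f_t Observed active ROI fraction in `[0, 1]`.
#' @param n_rois Number of ROIs behind `f_t`.
#' @param min_rois Minimum ROIs required for determinability.
#' @return A one-row tibble: `A`, `f_t`, `n_rois`, `f_0` (`NA` when not
#'   determinable) and `reason` (`"ok"`, `"all_active_no_depth"`,
#'   `"inactive_exceeds_original"`, or `"insufficient_rois"`).
#' @export
#' @examples
#' original_active_fraction(A = 10, f_t = 0.95, n_rois = 100)
original_active_fraction <- function(A, f_t, n_rois, min_rois = 10) {
  if (A <= 0) abort("`A` must be positive")
  if (f_t < 0 || f_t > 1) abort("`f_t` must lie in [0, 1]")
  f0 <- 1 - A * (1 - f_t)
  reason <- "ok"
  if (n_rois < min_rois) {
    f0 <- NA_real_
    reason <- "insufficient_rois"
  } else if (f_t >= 1) {
    # every sampled ROI active: f_0 = 1 only in the edge case A = 1
    if (A == 1) {
      f0 <- 1
    } else {
      f0 <- NA_real_
      reason <- "all_active_no_depth"
    }
  } else if (A * (1 - f_t) > 1) {
    f0 <- NA_real_
    reason <- "inactive_exceeds_original"
  }
  tibble::tibble(A = A, f_t = f_t, n_rois = n_rois, f_0 = f0, reason = reason)
}

#' Analyze one incubation end-to-end
#'
#' Combines classified ROI measurements with the cell-count series for
#' one incubation: biomass growth rate and doubling time, per-ROI biomass
#' generation rates (conservatively restricted to ROIs active for the
#' respective isotope), the observed active fraction and the originally
#' active fraction.
#'
#' @param meas ROI measurement tibble (columns `F_C`, `F_N`, ...).
#' @param series Cell-count time series (columns `day`, `cells_per_cm3`).
#' @param setup An [incubation_setup()].
#' @param min_rois Minimum ROI count for `f_0` determinability.
#' @return An object of class `incubation_result`; see
#'   [tidy.incubation_result()] and [glance.incubation_result()].
#' @export
analyze_incubation <- function(meas, series, setup, min_rois = 10) {
  stopifnot(inherits(setup, "incubation_setup"))
  cls <- classify_active(meas, setup)
  mu_B <- biomass_growth_rate(series, setup$t)
  rates <- dplyr::mutate(
    cls,
    mu_S_C = ifelse(.data$active_C,
                    substrate_rate(.data$F_C, setup$F_nat_C, setup$F_label_C, setup$t),
                    NA_real_),
    mu_S_N = ifelse(.data$active_N,
                    substrate_rate(.data$F_N, setup$F_nat_N, setup$F_label_N, setup$t),
                    NA_real_)
  )
  A <- exp(mu_B * setup$t)
  f_t <- mean(rates$active)
  frac <- original_active_fraction(A, f_t, nrow(rates), min_rois)
  structure(
    list(setup = setup, rois = rates, series = series,
         mu_B = mu_B, T_d = doubling_time(mu_B),
         A = A, f_t = f_t, f_0 = frac$f_0, f0_reason = frac$reason,
         n_rois = nrow(rates)),
    class = "incubation_result"
  )
}

#' @export
print.incubation_result <- function(x, ...) {
  cat(sprintf("<incubation_result: %s / %s, t = %g d>\n",
              x$setup$sample_id, x$setup$substrate, x$setup$t))
  cat(sprintf("  mu_B = %.3f /d, T_d = %s d, f_t = %.3f, f_0 = %s (%d ROIs)\n",
              x$mu_B,
              ifelse(is.na(x$T_d), "nm", sprintf("%.1f", x$T_d)),
              x$f_t,
              ifelse(is.na(x$f_0), "N.A.", sprintf("%.1f%%", 100 * x$f_0)),
              x$n_rois))
  invisible(x)
}

#' Tidy per-ROI rates of an incubation result
#'
#' @param x An [analyze_incubation()] result.
#' @param ... Unused.
#' @return The per-ROI tibble with activity flags and `mu_S_C`, `mu_S_N`.
#' @export
tidy.incubation_result <- function(x, ...) {
  dplyr::mutate(x$rois,
                sample_id = x$setup$sample_id,
                substrate = x$setup$substrate,
                .before = 1)
}

#' One-row summary of an incubation result
#'
#' @param x An [analyze_incubation()] result.
#' @param ... Unused.
#' @return A one-row tibble shaped like a growth-characteristics table
#'   row: `sample_id`, `substrate`, `t_days`, `mu_B`, `T_d`, `mu_S_C`,
#'   `mu_S_N` (means over active ROIs; `NA` when no ROI was active for
#'   that isotope), `f_t`, `f_0`, `f0_reason`, `n_rois`.
#' @export
glance.incubation_result <- function(x, ...) {
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  tibble::tibble(
    sample_id = x$setup$sample_id,
    substrate = x$setup$substrate,
    t_days = x$setup$t,
    mu_B = x$mu_B,
    T_d = x$T_d,
    mu_S_C = mean_or_na(x$rois$mu_S_C),
    mu_S_N = mean_or_na(x$rois$mu_S_N),
    f_t = x$f_t,
    f_0 = x$f_0,
    f0_reason = x$f0_reason,
    n_rois = x$n_rois
  )
}

#' Summarize a set of incubations
#'
#' Builds a growth-characteristics table (one row per incubation) from
#' [analyze_incubation()] results, or accepts such a table directly, and
#' computes the study-level aggregates: mean/min/max doubling time, the
#' mean determinable originally-active fraction, and the
#' nitrogen-to-carbon ratio of biomass generation rates computed as the
#' ratio of grand means (mean of all nitrogen rates over mean of all
#' determinable carbon rates). Non-determinable entries are excluded from
#' the aggregate they cannot contribute to.
#'
#' @param results A list of `incubation_result` objects, or a data frame
#'   with columns `mu_B`, `T_d`, `mu_S_C`, `mu_S_N`, `f_0` (fractions in
#'   `[0, 1]`; `NA` marks "nm"/"N.A." entries).
#' @return A list with `table` (per-incubation tibble) and `aggregates`
#'   (one-row tibble: `n_incubations`, `mean_T_d`, `min_T_d`, `max_T_d`,
#'   `mean_f0`, `n_f0`, `ratio_N_to_C`).
#' @export
summarize_incubations <- function(results) {
  if (is.data.frame(results)) {
    tbl <- tibble::as_tibble(results)
  } else {
    if (length(results) == 0) abort("no incubation results supplied")
    tbl <- purrr::map_dfr(results, glance)
  }
  if (nrow(tbl) == 0) abort("no incubation results supplied")
  td <- tbl$T_d[!is.na(tbl$T_d)]
  f0 <- tbl$f_0[!is.na(tbl$f_0)]
  muC <- tbl$mu_S_C[!is.na(tbl$mu_S_C)]
  muN <- tbl$mu_S_N[!is.na(tbl$mu_S_N)]
  aggregates <- tibble::tibble(
    n_incubations = nrow(tbl),
    mean_T_d = if (length(td)) mean(td) else NA_real_,
    min_T_d = if (length(td)) min(td) else NA_real_,
    max_T_d = if (length(td)) max(td) else NA_real_,
    mean_f0 = if (length(f0)) mean(f0) else NA_real_,
    n_f0 = length(f0),
    ratio_N_to_C = if (length(muC) && length(muN) && mean(muC) > 0) {
      mean(muN) / mean(muC)
    } else {
      NA_real_
    }
  )
  list(table = tbl, aggregates = aggregates)
}

#' Internal consistency of printed growth-rate and doubling-time columns
#'
#' Recomputes doubling times as `ln 2 / mu_B` from a published table's
#' growth-rate column and compares them with the printed doubling times.
#' Because both columns are independently rounded, two notions of
#' agreement are reported per row: `exact` (the recomputed value rounds
#' to the printed one at its printed precision) and `consistent` (some
#' unrounded growth rate exists that rounds to the printed rate and whose
#' doubling time rounds to the printed doubling time, i.e. the two
#' rounding intervals overlap).
#'
#' @param table Data frame with columns `mu_B` and `T_d`.
#' @param digits_mu,digits_td Printed decimal places of the two columns.
#' @return `table` with columns `T_d_recomputed`, `exact`, `consistent`
#'   appended.
#' @export
#' @examples
#' check_doubling_consistency(table1_growth())
check_doubling_consistency <- function(table, digits_mu = 3, digits_td = 1) {
  tbl <- tibble::as_tibble(table)
  stopifnot(all(c("mu_B", "T_d") %in% names(tbl)))
  half_mu <- 0.5 * 10^-digits_mu
  half_td <- 0.5 * 10^-digits_td
  rec <- doubling_time(tbl$mu_B)
  # interval of T_d values implied by the printed (rounded) mu_B
  lo <- doubling_time(tbl$mu_B + half_mu)
  hi <- doubling_time(pmax(tbl$mu_B - half_mu, .Machine$double.eps))
  dplyr::mutate(
    tbl,
    T_d_recomputed = rec,
    exact = !is.na(rec) & round(rec, digits_td) == .data$T_d,
    consistent = !is.na(rec) &
      lo <= .data$T_d + half_td & hi >= .data$T_d - half_td
  )
}
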
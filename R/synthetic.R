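#' Lay out synthetic cells on a regular grid
#'
#' Convenience constructor for the cell table consumed by
#' [sim_image_stack()]. Cells are placed on a regular grid with enough
#' margin that integer scan drift keeps every cell inside the field.
#'
#' @param n Number of cells.
#' @param field_size Field edge length in pixels (square field).
#' @param F_C,F_N True heavy-isotope atom fractions (13C, 15N) of each
#'   cell, recycled to length `n`.
#' @param lambda_C Expected total carbon counts (12C- + 13C-) per pixel.
#' @param lambda_CN Expected total cyanide counts (12C14N- + 12C15N-) per
#'   pixel.
#' @param radius Ellipse semi-axes in pixels (recycled; a single value
#'   gives circular cells).
#' @param margin Pixels kept clear of the field edge (cover worst-case
#'   drift).
#'
#' @return A tibble with one row per cell and columns `cell_id`, `row`,
#'   `col`, `radius_row`, `radius_col`, `F_C`, `F_N`, `lambda_C`,
#'   `lambda_CN`.
#' @export
#' @examples
#' cell_grid(4, field_size = 64, F_C = c(0.0111, 0.5))
cell_grid <- function(n, field_size = 64, F_C = 0.0111, F_N = 0.00366,
                      lambda_C = 50, lambda_CN = 50, radius = 3,
                      margin = 12) {
  stopifnot(n >= 1, field_size > 2 * margin)
  per_side <- ceiling(sqrt(n))
  usable <- field_size - 2 * margin
  step <- usable / per_side
  if (step < 2 * max(radius) + 1) {
    abort("field too small for the requested number and size of cells")
  }
  idx <- seq_len(n) - 1L
  centers <- margin + step / 2 + step * (0:(per_side - 1))
  tibble::tibble(
    cell_id = seq_len(n),
    row = round(centers[idx %/% per_side + 1L]),
    col = round(centers[idx %% per_side + 1L]),
    radius_row = rep_len(radius, n),
    radius_col = rep_len(radius, n),
    F_C = rep_len(F_C, n),
    F_N = rep_len(F_N, n),
    lambda_C = rep_len(lambda_C, n),
    lambda_CN = rep_len(lambda_CN, n)
  )
}

# Poisson total split binomially between heavy and light isotopologue.
# Equivalent to independent Poisson draws with means F*lambda and
# (1 - F)*lambda, but keeps the binomial sampling oracle exact.
.split_counts <- function(lambda_map, f_map) {
  total <- rpois(length(lambda_map), lambda_map)
  heavy <- rbinom(length(total), total, as.vector(f_map))
  list(
    light = matrix(total - heavy, nrow = nrow(lambda_map)),
    heavy = matrix(heavy, nrow = nrow(lambda_map))
  )
}

#' Simulate a multi-scan NanoSIMS ion-count image stack
#'
#' Generates Poisson-distributed per-pixel counts for the five collected
#' secondary ion species (12C-, 13C-, 12C14N-, 12C15N-, 32S-) over
#' elliptical cells on a membrane background, with optional integer-pixel
#' drift between scans. Per pixel the heavy/light pair is a Poisson total
#' thinned binomially at that pixel's true atom fraction, so the expected
#' 13C- count is `F * lambda` and the expected 12C- count `(1 - F) * lambda`.
#'
#' @param cells Tibble of cell specifications as produced by [cell_grid()].
#' @param field_size Field edge length in pixels.
#' @param n_scans Number of scans.
#' @param drift Integer pixel offset `(rows, cols)` added per scan; scan
#'   `s` (0-based) is translated by `s * drift`.
#' @param background_F_C,background_F_N Membrane background atom
#'   fractions.
#' @param background_level Expected total counts per background pixel
#'   (same level used for the C and CN pairs).
#' @param s_fraction Expected 32S- counts as a fraction of `lambda_CN`
#'   over cells.
#' @param pixel_size Pixel edge in micrometres (metadata only).
#' @param dwell_time Counting time per pixel in milliseconds (metadata
#'   only).
#' @param seed Optional integer seed.
#'
#' @return A list with elements `stack` (an [ion_count_stack()]),
#'   `roi_mask` (integer label matrix in scan-0 coordinates, 0 =
#'   background), `cells` (the ground-truth cell table) and `drift`.
#' @export
#' @examples
#' sim <- sim_image_stack(cell_grid(1, F_C = 0.5), n_scans = 2, seed = 1)
#' dim(sim$stack$counts)
sim_image_stack <- function(cells, field_size = 64, n_scans = 1,
                            drift = c(0, 0),
                            background_F_C = 0.0111,
                            background_F_N = 0.00366,
                            background_level = 2,
                            s_fraction = 0.2,
                            pixel_size = 25 / 256,
                            dwell_time = 5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  if (field_size <= 0) abort("`field_size` must be positive")
  fr <- c(cells$F_C, cells$F_N, background_F_C, background_F_N)
  if (any(fr < 0 | fr > 1)) abort("atom fractions must lie in [0, 1]")
  if (any(cells$radius_row < 1 | cells$radius_col < 1)) {
    abort("cell radii must be at least 1 pixel")
  }
  if (any(c(cells$lambda_C, cells$lambda_CN) <= 0) || background_level <= 0) {
    abort("expected count levels must be positive")
  }
  drift <- as.integer(round(drift))
  max_shift <- (n_scans - 1L) * abs(drift)
  lim_row <- cells$row + cells$radius_row + max_shift[1]
  lim_col <- cells$col + cells$radius_col + max_shift[2]
  if (any(cells$row - cells$radius_row < 1) || any(cells$col - cells$radius_col < 1) ||
      any(lim_row > field_size) || any(lim_col > field_size)) {
    abort("cells (after drift) must stay inside the field")
  }

  rows <- matrix(seq_len(field_size), field_size, field_size)
  cols <- matrix(seq_len(field_size), field_size, field_size, byrow = TRUE)

  roi_mask <- matrix(0L, field_size, field_size)
  lamC <- matrix(background_level, field_size, field_size)
  lamCN <- matrix(background_level, field_size, field_size)
  fC <- matrix(background_F_C, field_size, field_size)
  fN <- matrix(background_F_N, field_size, field_size)
  for (i in seq_len(nrow(cells))) {
    inside <- ((rows - cells$row[i]) / cells$radius_row[i])^2 +
      ((cols - cells$col[i]) / cells$radius_col[i])^2 <= 1
    roi_mask[inside] <- cells$cell_id[i]
    lamC[inside] <- cells$lambda_C[i]
    lamCN[inside] <- cells$lambda_CN[i]
    fC[inside] <- cells$F_C[i]
    fN[inside] <- cells$F_N[i]
  }
  lamS <- matrix(0.02 * background_level, field_size, field_size)
  lamS[roi_mask > 0] <- s_fraction * lamCN[roi_mask > 0]

  species <- c("12C", "13C", "12C14N", "12C15N", "32S")
  counts <- array(0L, dim = c(n_scans, length(species), field_size, field_size),
                  dimnames = list(NULL, species, NULL, NULL))
  shift_map <- function(m, sh, fill) {
    out <- matrix(fill, field_size, field_size)
    src_r <- seq_len(field_size) - sh[1]
    src_c <- seq_len(field_size) - sh[2]
    ok_r <- src_r >= 1 & src_r <= field_size
    ok_c <- src_c >= 1 & src_c <= field_size
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  for (s in seq_len(n_scans)) {
    sh <- (s - 1L) * drift
    lC <- shift_map(lamC, sh, background_level)
    lN <- shift_map(lamCN, sh, background_level)
    lS <- shift_map(lamS, sh, 0.02 * background_level)
    fCs <- shift_map(fC, sh, background_F_C)
    fNs <- shift_map(fN, sh, background_F_N)
    cpair <- .split_counts(lC, fCs)
    npair <- .split_counts(lN, fNs)
    counts[s, "12C", , ] <- cpair$light
    counts[s, "13C", , ] <- cpair$heavy
    counts[s, "12C14N", , ] <- npair$light
    counts[s, "12C15N", , ] <- npair$heavy
    counts[s, "32S", , ] <- matrix(rpois(length(lS), lS), field_size)
  }

  list(
    stack = ion_count_stack(counts, species = species,
                            pixel_size = pixel_size, dwell_time = dwell_time),
    roi_mask = roi_mask,
    cells = cells,
    drift = drift
  )
}

#' Define a synthetic incubation scenario
#'
#' Bundles the ground-truth parameters of a stable-isotope-probing
#' incubation: an originally active fraction `f_0` of cells grows
#' exponentially at rate `mu_B` while incorporating labeled substrate at
#' per-cell biomass generation rates `mu_S`; inactive cells neither grow
#' nor incorporate label.
#'
#' @param n_cells Number of cells sampled (imaged) at each timepoint.
#' @param active_fraction Originally active fraction `f_0` in `[0, 1]`.
#' @param mu_B Specific growth rate of the active subpopulation (per
#'   day).
#' @param mu_S_C,mu_S_N Biomass generation rates (per day) of active
#'   cells; a scalar or a vector sampled from (with replacement) per cell.
#' @param X0 Initial cell abundance (cells per cubic centimetre).
#' @param timepoints Sampling days; must start at 0 and increase.
#' @param F_label_C,F_label_N Labeling strengths (atom fractions).
#' @param F_nat_C,F_nat_N Natural-abundance atom fractions.
#' @param noise_sd Standard deviation (log scale) of multiplicative
#'   lognormal observation noise on cell counts; 0 disables noise.
#' @param seed Optional integer seed stored with the scenario.
#'
#' @return An object of class `sip_scenario` (a validated list).
#' @export
incubation_scenario <- function(n_cells = 100,
                                active_fraction = 0.8,
                                mu_B = 0.2,
                                mu_S_C = 0.03,
                                mu_S_N = 0.05,
                                X0 = 1e3,
                                timepoints = c(0, 21, 68, 557),
                                F_label_C = 0.99, F_label_N = 0.99,
                                F_nat_C = F_NAT_C_DEFAULT,
                                F_nat_N = F_NAT_N_DEFAULT,
                                noise_sd = 0,
                                seed = NULL) {
  if (active_fraction < 0 || active_fraction > 1) {
    abort("`active_fraction` must lie in [0, 1]")
  }
  if (any(c(mu_B, mu_S_C, mu_S_N) < 0)) abort("rates must be non-negative")
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0) || any(timepoints < 0)) {
    abort("`timepoints` must be non-negative, strictly increasing, starting at 0")
  }
  frs <- c(F_label_C, F_label_N, F_nat_C, F_nat_N)
  if (any(frs < 0 | frs > 1)) abort("atom fractions must lie in [0, 1]")
  if (F_label_C <= F_nat_C || F_label_N <= F_nat_N) {
    abort("labeling strength must exceed natural abundance")
  }
  structure(
    list(n_cells = n_cells, active_fraction = active_fraction, mu_B = mu_B,
         mu_S_C = mu_S_C, mu_S_N = mu_S_N, X0 = X0, timepoints = timepoints,
         F_label_C = F_label_C, F_label_N = F_label_N,
         F_nat_C = F_nat_C, F_nat_N = F_nat_N,
         noise_sd = noise_sd, seed = seed),
    class = "sip_scenario"
  )
}

# Active-cell label fraction after t days at biomass generation rate mu_S.
.forward_label <- function(mu_S, t, F_label, F_nat) {
  F_label - (F_label - F_nat) * exp(-mu_S * t)
}

#' Simulate an incubation: cell counts and per-cell enrichment
#'
#' Forward model of the incubation. Total abundance follows
#' `X_t = X0 * ((1 - f0) + f0 * exp(mu_B * t))`; active cells approach the
#' labeling strength as `F_t = F_label - (F_label - F_nat) * exp(-mu_S *
#' t)` per isotope while inactive cells remain at natural abundance. Cells
#' sampled at each timepoint are drawn from the current active:inactive
#' composition.
#'
#' @param scenario A [incubation_scenario()].
#'
#' @return A list with `counts` (tibble: `day`, `cells_per_cm3`), `cells`
#'   (tibble: `day`, `cell_id`, `active`, `mu_S_C`, `mu_S_N`, `F_t_C`,
#'   `F_t_N`) and the `scenario`.
#' @export
#' @examples
#' sim <- sim_incubation(incubation_scenario(n_cells = 20, seed = 1))
#' head(sim$cells)
sim_incubation <- function(scenario) {
  stopifnot(inherits(scenario, "sip_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  f0 <- scenario$active_fraction
  tp <- scenario$timepoints

  growth <- (1 - f0) + f0 * exp(scenario$mu_B * tp)
  x <- scenario$X0 * growth
  if (scenario$noise_sd > 0) {
    x <- x * rlnorm(length(x), 0, scenario$noise_sd)
  }
  counts <- tibble::tibble(day = tp, cells_per_cm3 = x)

  f_t <- f0 * exp(scenario$mu_B * tp) / growth
  cells <- purrr::map2_dfr(tp, f_t, function(day, ft) {
    n_active <- rbinom(1, scenario$n_cells, ft)
    active <- c(rep(TRUE, n_active), rep(FALSE, scenario$n_cells - n_active))
    muC <- ifelse(active, sample(rep_len(scenario$mu_S_C, scenario$n_cells),
                                 scenario$n_cells, replace = TRUE), 0)
    muN <- ifelse(active, sample(rep_len(scenario$mu_S_N, scenario$n_cells),
                                 scenario$n_cells, replace = TRUE), 0)
    tibble::tibble(
      day = day,
      cell_id = seq_len(scenario$n_cells),
      active = active,
      mu_S_C = muC,
      mu_S_N = muN,
      F_t_C = ifelse(active,
                     .forward_label(muC, day, scenario$F_label_C, scenario$F_nat_C),
                     scenario$F_nat_C),
      F_t_N = ifelse(active,
                     .forward_label(muN, day, scenario$F_label_N, scenario$F_nat_N),
                     scenario$F_nat_N)
    )
  })
  list(counts = counts, cells = cells, scenario = scenario)
}

#' Simulate an OTU count table with seeded contaminants
#'
#' Generates a negative-binomial OTU table over experiment samples,
#' extraction blanks and PCR no-template controls (NTCs). Contaminant
#' OTUs receive a systematically higher expected relative abundance in
#' both control groups, emulating reagent-borne taxa in low-biomass
#' sequencing.
#'
#' @param n_samples Number of experiment samples.
#' @param n_blanks Number of extraction blanks (default 8).
#' @param n_ntc Number of PCR no-template controls (default 6).
#' @param n_otus Total number of OTUs.
#' @param contaminant_otus Number of seeded contaminant OTUs.
#' @param effect_size Fold enrichment of contaminant OTUs in control
#'   columns.
#' @param library_size Expected total counts per sample.
#' @param nb_size Negative-binomial dispersion parameter (`size` of
#'   [stats::rnbinom()]).
#' @param seed Optional integer seed.
#'
#' @return A list with `table` (an [otu_table()]) and `contaminants`
#'   (character vector of ground-truth contaminant OTU ids).
#' @export
#' @examples
#' sim <- sim_otu_table(n_samples = 12, contaminant_otus = 3, seed = 1)
#' sim$contaminants
sim_otu_table <- function(n_samples = 12, n_blanks = 8, n_ntc = 6,
                          n_otus = 100, contaminant_otus = 5,
                          effect_size = 10, library_size = 5000,
                          nb_size = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (contaminant_otus > n_otus) {
    abort("`contaminant_otus` cannot exceed `n_otus`")
  }
  if (min(n_samples, n_blanks, n_ntc) < 2) {
    abort("each sample group needs at least 2 replicates")
  }
  groups <- c(rep("experiment", n_samples),
              rep("extraction_blank", n_blanks),
              rep("pcr_ntc", n_ntc))
  samples <- paste0(c(paste0("S", seq_len(n_samples)),
                      paste0("B", seq_len(n_blanks)),
                      paste0("N", seq_len(n_ntc))))
  otus <- sprintf("OTU_%03d", seq_len(n_otus))
  contam <- if (contaminant_otus > 0) {
    sort(sample(otus, contaminant_otus))
  } else {
    character(0)
  }

  base <- stats::rgamma(n_otus, shape = 0.8, rate = 1) + 0.05
  mu <- matrix(base, n_otus, length(groups))
  mu[otus %in% contam, groups != "experiment"] <-
    mu[otus %in% contam, groups != "experiment"] * effect_size
  mu <- sweep(mu, 2, colSums(mu), "/") * library_size

  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = nb_size),
                   n_otus, length(groups),
                   dimnames = list(otus, samples))
  # guard against a degenerate all-zero sample at tiny library sizes
  empty <- colSums(counts) == 0
  if (any(empty)) counts[1, empty] <- 1L

  list(table = otu_table(counts, setNames(groups, samples)),
       contaminants = contam)
}
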
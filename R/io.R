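# File-format layer. Atom fractions are fractions everywhere in memory;
# the serializers convert to/from atom percent at the file boundary.

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
}

#' Write / read a per-ROI isotope measurement table (TSV)
#'
#' Columns: `roi_id`, `n_pixels`, `c12`, `c13`, `cn14`, `cn15`, `s32`,
#' `R13`, `R15`, `F_C_atompct`, `F_N_atompct`. Atom fractions are stored
#' as atom percent in the file and converted back to fractions (`F_C`,
#' `F_N`) on read; undefined measurements (`NA`) survive the round trip.
#'
#' @param meas ROI measurement tibble from [measure_rois()].
#' @param path File path.
#' @return `write_roi_table()` returns `path` invisibly;
#'   `read_roi_table()` returns the measurement tibble.
#' @export
write_roi_table <- function(meas, path) {
  out <- tibble::tibble(
    roi_id = meas$roi_id,
    n_pixels = meas$n_pixels,
    c12 = meas$c12, c13 = meas$c13,
    cn14 = meas$cn14, cn15 = meas$cn15, s32 = meas$s32,
    R13 = meas$R13, R15 = meas$R15,
    F_C_atompct = 100 * meas$F_C,
    F_N_atompct = 100 * meas$F_N
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  .require_columns(df, c("roi_id", "n_pixels", "c12", "c13", "cn14", "cn15",
                         "s32", "R13", "R15", "F_C_atompct", "F_N_atompct"),
                   path)
  counts <- c("c12", "c13", "cn14", "cn15")
  bad <- which(apply(df[counts], 1, function(v) any(!is.na(v) & v < 0)))
  if (length(bad)) {
    abort(sprintf("%s: negative counts at data line(s) %s", path,
                  paste(bad, collapse = ", ")))
  }
  dplyr::mutate(df,
                F_C = .data$F_C_atompct / 100,
                F_N = .data$F_N_atompct / 100,
                defined_C = !is.na(.data$F_C),
                defined_N = !is.na(.data$F_N))
}

#' Write / read a cell-count time series (CSV)
#'
#' Columns `day`, `cells_per_cm3`. Reading validates the schema: a day-0
#' observation must be present and counts must be positive.
#'
#' @param series Tibble with `day` and `cells_per_cm3`.
#' @param path File path.
#' @return `write_cell_counts()` returns `path` invisibly;
#'   `read_cell_counts()` returns the series tibble.
#' @export
write_cell_counts <- function(series, path) {
  readr::write_csv(series[c("day", "cells_per_cm3")], path)
  invisible(path)
}

#' @rdname write_cell_counts
#' @export
read_cell_counts <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_columns(df, c("day", "cells_per_cm3"), path)
  if (!0 %in% df$day) {
    abort(sprintf("%s: schema requires a day-0 row (initial abundance X_0)", path))
  }
  if (any(df$cells_per_cm3 <= 0)) {
    abort(sprintf("%s: cell counts must be positive", path))
  }
  tibble::as_tibble(df)
}

#' Write / read an OTU table with group labels (TSV)
#'
#' Layout: a comment line `#group` carrying each sample's group label,
#' then a header row with sample names and one row per OTU. Rows are
#' OTUs, columns are samples.
#'
#' @param table An [otu_table()].
#' @param path File path.
#' @return `write_otu_table()` returns `path` invisibly;
#'   `read_otu_table()` returns an [otu_table()].
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  header <- paste(c("otu", colnames(table$counts)), collapse = "\t")
  groups <- paste(c("#group", unname(table$groups)), collapse = "\t")
  body <- apply(cbind(rownames(table$counts), table$counts), 1,
                paste, collapse = "\t")
  writeLines(c(groups, header, body), path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#group")) {
    abort(sprintf("%s: line 1 must be the '#group' label row", path))
  }
  groups <- strsplit(lines[1], "\t")[[1]][-1]
  df <- readr::read_tsv(path, skip = 1, show_col_types = FALSE)
  if (names(df)[1] != "otu") {
    abort(sprintf("%s: line 2 must be a header starting with 'otu'", path))
  }
  counts <- as.matrix(df[-1])
  rownames(counts) <- df$otu
  if (any(is.na(counts)) || any(counts < 0)) {
    abort(sprintf("%s: counts must be non-negative integers", path))
  }
  otu_table(counts, setNames(groups, colnames(counts)))
}

#' Write / read an ion-count image stack (multi-page TIFF + YAML sidecar)
#'
#' The TIFF holds one 16-bit page per (species, scan), ordered
#' species-major (all scans of species 1, then species 2, ...). The YAML
#' sidecar records the species order, scan count, pixel size, dwell time,
#' and optionally the ground-truth drift and seed of a simulation. ROI
#' label masks ride along as a second (label-image) TIFF.
#'
#' @param stack An [ion_count_stack()].
#' @param prefix Path prefix; writes `<prefix>.tiff` and `<prefix>.yml`
#'   (and `<prefix>_roi.tiff` when `roi_mask` is given).
#' @param roi_mask Optional integer label matrix.
#' @param truth Optional list of ground-truth metadata (drift, seed)
#'   stored in the sidecar.
#' @return `write_ion_stack()` returns `prefix` invisibly;
#'   `read_ion_stack()` returns a list with `stack`, `roi_mask` (or
#'   `NULL`) and `meta`.
#' @export
write_ion_stack <- function(stack, prefix, roi_mask = NULL, truth = NULL) {
  stopifnot(inherits(stack, "ion_count_stack"))
  d <- dim(stack$counts)
  if (max(stack$counts) > 65535) {
    abort("counts exceed the 16-bit TIFF range")
  }
  pages <- list()
  for (sp in stack$species) {
    for (s in seq_len(d[1])) {
      pages[[length(pages) + 1L]] <-
        matrix(stack$counts[s, sp, , , drop = TRUE], d[3], d[4]) / 65535
    }
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tiff"), bits.per.sample = 16L,
                  compression = "none")
  meta <- list(species = as.list(stack$species), n_scans = d[1],
               n_rows = d[3], n_cols = d[4],
               pixel_size_um = stack$pixel_size,
               dwell_time_ms = stack$dwell_time)
  if (!is.null(truth)) meta$truth <- truth
  yaml::write_yaml(meta, paste0(prefix, ".yml"))
  if (!is.null(roi_mask)) {
    if (max(roi_mask) > 65535) abort("ROI labels exceed the 16-bit range")
    tiff::writeTIFF(roi_mask / 65535, paste0(prefix, "_roi.tiff"),
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(prefix)
}

#' @rdname write_ion_stack
#' @export
read_ion_stack <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  species <- unlist(meta$species)
  pages <- tiff::readTIFF(paste0(prefix, ".tiff"), all = TRUE, as.is = TRUE)
  if (length(pages) != length(species) * meta$n_scans) {
    abort(sprintf("%s.tiff: expected %d pages, found %d", prefix,
                  length(species) * meta$n_scans, length(pages)))
  }
  counts <- array(0L, dim = c(meta$n_scans, length(species),
                              meta$n_rows, meta$n_cols),
                  dimnames = list(NULL, species, NULL, NULL))
  k <- 1L
  for (sp in species) {
    for (s in seq_len(meta$n_scans)) {
      counts[s, sp, , ] <- pages[[k]]
      k <- k + 1L
    }
  }
  roi_path <- paste0(prefix, "_roi.tiff")
  roi_mask <- if (file.exists(roi_path)) {
    m <- tiff::readTIFF(roi_path, as.is = TRUE)
    matrix(as.integer(m), nrow(m), ncol(m))
  }
  list(stack = ion_count_stack(counts, species = species,
                               pixel_size = meta$pixel_size_um,
                               dwell_time = meta$dwell_time_ms),
       roi_mask = roi_mask, meta = meta)
}

#' Write / read a growth-characteristics table (TSV)
#'
#' Table of per-incubation growth summaries in the shape of the study's
#' published table: `sample_id`, `substrate`, `t_days`, `mu_B`, `T_d`,
#' `mu_S_C`, `mu_S_N`, `f0_pct`. Non-determinable rates carry the marker
#' `nm` and non-determinable active fractions `N.A.`; both become `NA` on
#' read. `f_0` is stored as percent in the file and also returned as a
#' fraction column `f_0`.
#'
#' @param tbl Tibble with the columns above (`f_0` as a fraction is
#'   accepted in place of `f0_pct`).
#' @param path File path.
#' @return `write_growth_table()` returns `path` invisibly;
#'   `read_growth_table()` returns the tibble.
#' @export
write_growth_table <- function(tbl, path) {
  if (!"f0_pct" %in% names(tbl) && "f_0" %in% names(tbl)) {
    tbl$f0_pct <- 100 * tbl$f_0
  }
  fmt <- function(v, marker) {
    ifelse(is.na(v), marker, format(v, trim = TRUE, digits = 15))
  }
  out <- tibble::tibble(
    sample_id = tbl$sample_id,
    substrate = tbl$substrate,
    t_days = tbl$t_days,
    mu_B = fmt(tbl$mu_B, "nm"),
    T_d = fmt(tbl$T_d, "nm"),
    mu_S_C = fmt(tbl$mu_S_C, "nm"),
    mu_S_N = fmt(tbl$mu_S_N, "nm"),
    f0_pct = fmt(tbl$f0_pct, "N.A.")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_growth_table
#' @export
read_growth_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        na = c("nm", "N.A.", "NA"),
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          substrate = readr::col_character(),
                          .default = readr::col_double()
                        ))
  .require_columns(df, c("sample_id", "substrate", "t_days", "mu_B", "T_d",
                         "mu_S_C", "mu_S_N", "f0_pct"), path)
  dplyr::mutate(tibble::as_tibble(df), f_0 = .data$f0_pct / 100)
}

#' Published growth-characteristics table (bundled fixture)
#'
#' The 24 incubation rows (4 sediment samples x 6 substrates, all at
#' t = 21 days) of the study's growth-characteristics table: biomass-based
#' specific growth rate, doubling time, carbon and nitrogen
#' substrate-incorporation-based biomass generation rates, and the
#' estimated originally active fraction. `nm` / `N.A.` entries are `NA`.
#'
#' @return A tibble with columns `sample_id`, `substrate`, `t_days`,
#'   `mu_B`, `T_d`, `mu_S_C`, `mu_S_N`, `f0_pct`, `f_0`.
#' @export
#' @examples
#' summarize_incubations(table1_growth())$aggregates
table1_growth <- function() {
  path <- system.file("extdata", "table1_growth.tsv", package = "nanosip",
                      mustWork = TRUE)
  read_growth_table(path)
}
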
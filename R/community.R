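#' Construct an OTU count table with sample groups
#'
#' Container for an operational-taxonomic-unit count matrix (rows = OTUs,
#' columns = samples) where every sample is labeled as an experiment
#' sample, an extraction blank, or a PCR no-template control (NTC).
#'
#' @param counts Non-negative integer matrix with OTU row names and
#'   sample column names.
#' @param groups Character vector (named by sample, or in column order)
#'   with values in `"experiment"`, `"extraction_blank"`, `"pcr_ntc"`.
#' @param taxonomy Optional character vector of taxonomy strings, one per
#'   OTU.
#'
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, groups, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU_%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  valid <- c("experiment", "extraction_blank", "pcr_ntc")
  if (length(groups) != ncol(counts)) {
    abort("`groups` must label every sample")
  }
  if (!all(groups %in% valid)) {
    abort(paste("sample groups must be one of:", paste(valid, collapse = ", ")))
  }
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(counts))) {
      abort("names of `groups` do not match the sample columns")
    }
    groups <- groups[colnames(counts)]
  } else {
    names(groups) <- colnames(counts)
  }
  if (!"experiment" %in% groups) abort("at least one experiment sample is required")
  if (!is.null(taxonomy) && length(taxonomy) != nrow(counts)) {
    abort("`taxonomy` must have one entry per OTU")
  }
  structure(
    list(counts = counts, groups = groups, taxonomy = taxonomy),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table: %d OTUs x %d samples (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' Converts OTU counts to within-sample proportions; every sample column
#' sums to 1.
#'
#' @param table An [otu_table()].
#' @return A numeric matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    abort(paste("all-zero sample(s):",
                paste(colnames(table$counts)[totals == 0], collapse = ", ")))
  }
  sweep(table$counts, 2, totals, "/")
}

#' Flag OTUs enriched in negative controls
#'
#' Per OTU, a one-way ANOVA compares relative abundances between one
#' control group and the experiment samples; the OTU is flagged as a
#' contaminant when the test is significant (`p < alpha`) AND its mean
#' relative abundance is higher in the controls (directionality: only
#' control-enriched OTUs are contaminants). With two groups the ANOVA is
#' the classical equal-variance F-test, identical to a two-sided pooled
#' t-test.
#'
#' @param table An [otu_table()].
#' @param control_group `"extraction_blank"` or `"pcr_ntc"`.
#' @param alpha Per-OTU significance level (default 0.05).
#' @param adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; `"none"` by default (per-OTU testing).
#' @return A tibble with one row per OTU: `otu`, `p_value`,
#'   `mean_control`, `mean_experiment`, `flagged`.
#' @export
#' @examples
#' sim <- sim_otu_table(contaminant_otus = 2, effect_size = 20, seed = 1)
#' dplyr::filter(flag_contaminants(sim$table, "extraction_blank"), flagged)
flag_contaminants <- function(table,
                              control_group = c("extraction_blank", "pcr_ntc"),
                              alpha = 0.05, adjust = "none") {
  stopifnot(inherits(table, "otu_table"))
  control_group <- match.arg(control_group)
  in_ctrl <- table$groups == control_group
  in_exp <- table$groups == "experiment"
  if (sum(in_ctrl) < 2 || sum(in_exp) < 2) {
    abort("at least 2 samples per compared group are required")
  }
  rel <- relative_abundance(table)
  grp <- factor(ifelse(in_ctrl, "control", "experiment"))[in_ctrl | in_exp]
  sub <- rel[, in_ctrl | in_exp, drop = FALSE]

  p <- apply(sub, 1, function(v) {
    if (sd(v) == 0) return(1)  # constant across samples: no evidence
    oneway.test(v ~ grp, var.equal = TRUE)$p.value
  })
  p <- p.adjust(p, method = adjust)
  mean_ctrl <- rowMeans(rel[, in_ctrl, drop = FALSE])
  mean_exp <- rowMeans(rel[, in_exp, drop = FALSE])
  tibble::tibble(
    otu = rownames(rel),
    p_value = unname(p),
    mean_control = unname(mean_ctrl),
    mean_experiment = unname(mean_exp),
    flagged = .data$p_value < alpha & .data$mean_control > .data$mean_experiment
  )
}

#' Sequential negative-control decontamination
#'
#' Removes contaminant OTUs in two sequential passes: first OTUs
#' significantly enriched in the extraction blanks, then — on the
#' remaining OTUs — those enriched in the PCR no-template controls. The
#' sequential order is authoritative: relative abundances are recomputed
#' after the first pass, so an OTU can become (or stop being)
#' control-enriched between passes. Control columns are dropped from the
#' returned table.
#'
#' @param table An [otu_table()].
#' @param alpha Per-OTU significance level.
#' @param adjust Multiple-testing adjustment (default `"none"`).
#' @return A list with `table` (filtered `otu_table`, experiment samples
#'   only), `removed` (character vector) and `log` (tibble of per-OTU
#'   test results with a `pass` column).
#' @export
decontaminate <- function(table, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(table, "otu_table"))
  passes <- c(extraction_blank = "extraction_blank", pcr_ntc = "pcr_ntc")
  present <- vapply(passes, function(g) sum(table$groups == g) >= 2, logical(1))
  if (!any(present)) {
    warn("no negative-control samples present; table returned unchanged")
  }
  current <- table
  logs <- list()
  removed <- character(0)
  for (g in passes[present]) {
    res <- flag_contaminants(current, g, alpha = alpha, adjust = adjust)
    logs[[g]] <- dplyr::mutate(res, pass = g, .before = 1)
    drop <- res$otu[res$flagged]
    removed <- c(removed, drop)
    if (length(drop)) {
      keep <- !rownames(current$counts) %in% drop
      current <- otu_table(current$counts[keep, , drop = FALSE],
                           current$groups,
                           current$taxonomy[keep])
    }
  }
  keep_samples <- current$groups == "experiment"
  filtered <- otu_table(current$counts[, keep_samples, drop = FALSE],
                        current$groups[keep_samples],
                        current$taxonomy)
  list(table = filtered, removed = removed,
       log = if (length(logs)) dplyr::bind_rows(logs) else tibble::tibble())
}

#' Bray-Curtis dissimilarity between samples
#'
#' Pairwise Bray-Curtis dissimilarities `D(i, j) = sum |x_i - x_j| /
#' sum (x_i + x_j)` computed on within-sample relative abundances, as
#' consumed by downstream ordination.
#'
#' @param table An [otu_table()] (or a plain counts matrix, rows = OTUs).
#' @return A symmetric numeric matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
#' @examples
#' sim <- sim_otu_table(seed = 1)
#' bc <- bray_curtis(sim$table)
#' range(bc)
bray_curtis <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  totals <- colSums(counts)
  if (any(totals == 0)) abort("all-zero sample(s) in the table")
  rel <- sweep(counts, 2, totals, "/")
  d <- vegan::vegdist(t(rel), method = "bray")
  as.matrix(d)
}
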
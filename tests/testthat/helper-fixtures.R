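# Shared fixture builders; everything is generated in code at test time.

# Single high-count cell for binomial-oracle checks on the ratio estimator.
sim_single_cell <- function(F_C = 0.5, lambda = 400, n_scans = 1, seed = 1) {
  cells <- cell_grid(1, field_size = 48, F_C = F_C,
                     lambda_C = lambda, lambda_CN = lambda, radius = 4)
  sim_image_stack(cells, field_size = 48, n_scans = n_scans, seed = seed)
}

# OTU table where OTU "B" is control-enriched only after OTU "A" (dominant
# in every control) is removed: raw control relative abundance of B is
# BELOW the experiment level, renormalized (post-removal) abundance above.
otu_sequential_fixture <- function() {
  ab <- function(b) c(A = 10L, B = b, C = 1000L - 10L - b)
  ctl <- function(b) c(A = 800L, B = b, C = 1000L - 800L - b)
  counts <- cbind(
    sapply(c(117L, 117L, 91L, 113L), ab),    # experiment
    sapply(c(36L, 31L, 39L, 15L), ctl),      # extraction blanks
    sapply(c(36L, 38L, 28L, 39L), ctl)       # PCR NTCs
  )
  colnames(counts) <- c(paste0("S", 1:4), paste0("B", 1:4), paste0("N", 1:4))
  otu_table(counts, setNames(rep(c("experiment", "extraction_blank", "pcr_ntc"),
                                 each = 4), colnames(counts)))
}

# Permutation oracle for the two-group equal-variance one-way ANOVA:
# p-value as the permutation-null exceedance probability of the F statistic.
perm_anova_p <- function(values, groups, n_perm = 4000, seed = 99) {
  set.seed(seed)
  fstat <- function(g) {
    m <- tapply(values, g, mean)
    n <- tapply(values, g, length)
    gm <- mean(values)
    ssb <- sum(n * (m - gm)^2)
    ssw <- sum((values - m[g])^2)
    (ssb / (length(n) - 1)) / (ssw / (length(values) - length(n)))
  }
  obs <- fstat(groups)
  exceed <- replicate(n_perm, fstat(sample(groups)) >= obs)
  mean(exceed)
}
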
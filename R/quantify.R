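# Closed-form quantifications: cytometric AC size, qPCR copy number,
# Fisher's exact segregation comparison, segregation rate with exact CI,
# transmission frequency.

#' Cytometric estimate of artificial chromosome size
#'
#' In diakinesis oocytes the AC is a univalent (2C) while the six endogenous
#' bivalents together hold the replicated diploid genome (4C, ~400 Mb). The
#' AC/endo ratio of DAPI integrated densities therefore converts directly:
#' `AC(2C) = ratio x 400 Mb`, `AC(1C) = ratio x 200 Mb`.
#'
#' @param ac_intden Integrated density (summed voxel values) of the AC
#'   object; non-negative.
#' @param endo_intden Integrated density of the six endogenous bivalents;
#'   positive.
#' @param genome_4c_mb Size of the replicated diploid genome in Mb
#'   (default 400).
#' @return List with `ratio`, `size_2c_mb`, `size_1c_mb`.
#' @examples
#' ac_size(0.065, 1)  # 1C estimate of 13 Mb
#' @export
ac_size <- function(ac_intden, endo_intden, genome_4c_mb = 400) {
  if (endo_intden <= 0) stop("endo_intden must be positive")
  if (ac_intden < 0) stop("ac_intden must be non-negative")
  ratio <- ac_intden / endo_intden
  list(ratio = ratio, size_2c_mb = ratio * genome_4c_mb,
       size_1c_mb = ratio * genome_4c_mb / 2)
}

#' qPCR copy-number deduction
#'
#' Copies per 2C genome from the fold change of the target against a unique
#' reference locus present at `ref_copies_per_2c` copies (2 for a
#' single-copy locus in a diploid).
#'
#' @param fold_change Target/reference qPCR fold change (>= 0).
#' @param ref_copies_per_2c Copies of the reference locus per 2C genome
#'   (default 2).
#' @return Estimated copies per 2C genome.
#' @examples
#' copy_number(21)   # 42  (mCherry)
#' copy_number(151)  # 302 (yeast rDNA)
#' @export
copy_number <- function(fold_change, ref_copies_per_2c = 2) {
  if (any(fold_change < 0)) stop("fold_change must be >= 0")
  ref_copies_per_2c * fold_change
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under fixed margins: the sum of hypergeometric
#' probabilities of all tables at most as probable as the observed one
#' (within relative tolerance 1e-7 on the probability comparison, absorbing
#' floating-point ties). Used to compare AC segregation rates between
#' conditions.
#'
#' @param a,b,c,d Non-negative integer counts, rows = condition, columns =
#'   segregating / non-segregating. Alternatively pass a 2x2 matrix as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(2, 0, 0, 2)  # 1/3
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) < 1) stop("empty table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Segregation rate with exact binomial confidence interval
#'
#' Rate of dividing cells containing segregating ACs among all dividing
#' cells containing ACs, with a Clopper-Pearson 95% interval.
#'
#' @param n_segregating Count of segregating divisions.
#' @param n_total Total divisions with ACs (>= 1).
#' @return List with `rate`, `ci95` (2-vector), `n`.
#' @export
segregation_rate <- function(n_segregating, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_segregating < 0 || n_segregating > n_total)
    stop("need 0 <= n_segregating <= n_total")
  ci <- stats::binom.test(n_segregating, n_total)$conf.int
  attributes(ci) <- NULL
  list(rate = n_segregating / n_total, ci95 = ci, n = n_total)
}

#' Cross-generation transmission frequency
#'
#' Per-line fraction of progeny carrying the AC and the unweighted mean
#' across lines (the headline value is ~60% across three sublines).
#'
#' @param per_line_counts List (or data frame with columns `n_carrier`,
#'   `n_total`) of per-line counts; every `n_total >= 1`.
#' @return List with `per_line` (rates) and `mean_rate`.
#' @examples
#' transmission_frequency(list(c(6, 10), c(6, 10), c(6, 10)))  # mean 0.6
#' @export
transmission_frequency <- function(per_line_counts) {
  if (is.data.frame(per_line_counts))
    per_line_counts <- Map(c, per_line_counts$n_carrier,
                           per_line_counts$n_total)
  if (!length(per_line_counts)) stop("empty list of lines")
  rates <- vapply(per_line_counts, function(x) {
    if (x[2L] < 1) stop("every n_total must be >= 1")
    if (x[1L] < 0 || x[1L] > x[2L]) stop("need 0 <= n_carrier <= n_total")
    x[1L] / x[2L]
  }, 0)
  list(per_line = rates, mean_rate = mean(rates))
}
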
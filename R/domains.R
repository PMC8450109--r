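# CENP-A (HCP-3) domain characterization: widths, AT%, occupancy,
# width-AT correlation, inter-domain gap ECDF, profile clustering,
# marker-averaged enrichment, AT-ceiling check. Includes a minimal run-based
# domain caller for synthetic tracks; real-data peak calling stays external
# and is consumed as BED.

#' Construct a binned signal track
#'
#' Per-sequence binned log2(ChIP/Input) values. Missing bins are NA.
#'
#' @param values Named list, one numeric vector per sequence; each vector
#'   must have `ceiling(seq_length / bin_size)` entries.
#' @param bin_size Bin width in bp.
#' @param seq_lengths Named vector of sequence lengths in bp.
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(values, bin_size, seq_lengths) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  seq_lengths <- unlist(seq_lengths)
  if (!setequal(names(values), names(seq_lengths)))
    stop("values and seq_lengths must name the same sequences")
  for (sid in names(values)) {
    expect <- ceiling(seq_lengths[[sid]] / bin_size)
    if (length(values[[sid]]) != expect)
      stop("wrong number of bins for ", sid, ": expected ", expect)
  }
  structure(list(values = values[names(seq_lengths)],
                 bin_size = as.integer(bin_size),
                 seq_lengths = seq_lengths),
            class = "signal_track")
}

#' Construct a domain set
#'
#' @param x Interval data frame (optionally with a `mean_signal` column).
#' @param source Provenance: `"external_caller"`, `"internal_caller"` or
#'   `"truth"`.
#' @return The interval data frame with class `"domain_set"`.
#' @export
domain_set <- function(x, source = c("external_caller", "internal_caller",
                                     "truth")) {
  source <- match.arg(source)
  validate_intervals(x)
  if (!"mean_signal" %in% names(x)) x$mean_signal <- NA_real_
  structure(x, class = c("domain_set", "data.frame"), source = source)
}

#' Minimal threshold-run domain caller for synthetic tracks
#'
#' Calls maximal runs of bins at or above `threshold`; runs separated by at
#' most `merge_gap` bp are merged; merged runs narrower than `min_width` bp
#' are dropped. Missing bins count as below threshold. This caller exists so
#' synthetic pipelines run end to end; real data should use a dedicated
#' broad-peak caller and enter via [read_bed()].
#'
#' @param track A [signal_track()].
#' @param threshold Signal threshold (log2 units).
#' @param merge_gap Merge runs separated by at most this many bp (default 0).
#' @param min_width Minimum domain width in bp (must be positive).
#' @return A [domain_set()] with per-domain mean signal.
#' @export
call_domains <- function(track, threshold, merge_gap = 0, min_width = 1) {
  stopifnot(inherits(track, "signal_track"))
  if (min_width <= 0) stop("min_width must be positive")
  bs <- track$bin_size
  out <- list()
  for (sid in names(track$values)) {
    v <- track$values[[sid]]
    hi <- !is.na(v) & v >= threshold
    if (!any(hi)) next
    r <- rle(hi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    iv <- intervals(rep(sid, nrow(runs)), (runs[, 1L] - 1L) * bs,
                    pmin(runs[, 2L] * bs, track$seq_lengths[[sid]]))
    if (merge_gap > 0 && nrow(iv) > 1L) {
      # chain-merge consecutive runs separated by <= merge_gap bp
      grp <- cumsum(c(0L, (iv$start[-1L] - iv$end[-nrow(iv)]) > merge_gap))
      iv <- do.call(rbind, lapply(split(iv, grp), function(g)
        intervals(sid, min(g$start), max(g$end))))
    }
    iv <- iv[iv$end - iv$start >= min_width, , drop = FALSE]
    if (!nrow(iv)) next
    iv$mean_signal <- vapply(seq_len(nrow(iv)), function(i) {
      b0 <- iv$start[i] %/% bs + 1L
      b1 <- ceiling(iv$end[i] / bs)
      mean(v[b0:b1], na.rm = TRUE)
    }, 0)
    out[[sid]] <- iv
  }
  res <- if (length(out)) do.call(rbind, out)
         else {
           z <- intervals(character(0), integer(0), integer(0))
           z$mean_signal <- numeric(0)
           z
         }
  rownames(res) <- NULL
  domain_set(res, source = "internal_caller")
}

#' Per-domain statistics and genome occupancy
#'
#' Widths, AT% of each domain's sequence, and occupancy: merged domain bases
#' over the analyzed genome length. With `exclude_zero_domain_seqs = TRUE`
#' (the default, matching how AC contigs that fail to call any domain are
#' excluded), sequences carrying no domain do not count toward the
#' denominator.
#'
#' @param domains A [domain_set()].
#' @param genome Named character vector of sequences.
#' @param exclude_zero_domain_seqs Drop domain-free sequences from the
#'   occupancy denominator (default TRUE).
#' @return List of class `"domain_stats"`: `widths`, `at_per_domain`,
#'   `occupancy` (fraction), `occupancy_pct` (2 decimals), `analyzed_length`,
#'   `covered_bases`, `n_domains`, and the per-domain table `per_domain`.
#' @export
domain_stats <- function(domains, genome, exclude_zero_domain_seqs = TRUE) {
  stopifnot(inherits(domains, "domain_set"))
  seq_lengths <- stats::setNames(nchar(genome), names(genome))
  validate_intervals(domains, seq_lengths)
  widths <- domains$end - domains$start
  at <- vapply(seq_len(nrow(domains)), function(i)
    at_content(substring(genome[[domains$seq_id[i]]],
                         domains$start[i] + 1L, domains$end[i])), 0)
  analyzed <- if (exclude_zero_domain_seqs)
    sum(seq_lengths[names(seq_lengths) %in% unique(domains$seq_id)])
  else sum(seq_lengths)
  covered <- .covered_bases(domains)
  occ <- covered / analyzed
  structure(list(widths = widths, at_per_domain = at,
                 occupancy = occ, occupancy_pct = round(100 * occ, 2),
                 analyzed_length = unname(analyzed),
                 covered_bases = covered, n_domains = nrow(domains),
                 per_domain = data.frame(seq_id = domains$seq_id,
                                         start = domains$start,
                                         end = domains$end,
                                         width = widths, at = at,
                                         stringsAsFactors = FALSE)),
            class = "domain_stats")
}

#' @export
print.domain_stats <- function(x, ...) {
  cat(sprintf("Domain stats: %d domains, mean width %.0f bp\n",
              x$n_domains, mean(x$widths)))
  cat(sprintf("  occupancy %.2f%% of %.0f analyzed bp; AT%% range %.1f-%.1f\n",
              x$occupancy_pct, x$analyzed_length,
              100 * min(x$at_per_domain), 100 * max(x$at_per_domain)))
  invisible(x)
}

#' Correlation of domain width with AT-content
#'
#' Pearson correlation between per-domain width and AT%, with the ordinary
#' least-squares line (width on AT) and its 95% confidence bounds on slope
#' and intercept.
#'
#' @param stats A [domain_stats()] result (needs >= 3 domains with
#'   non-constant AT%).
#' @return List with `pearson_r`, `p_value`, `slope`, `intercept`, `ci95`
#'   (2x2 matrix of slope/intercept bounds), `n`.
#' @export
width_at_correlation <- function(stats) {
  w <- stats$widths
  a <- stats$at_per_domain
  if (length(w) < 3L) stop("need at least 3 domains")
  if (length(unique(a)) == 1L) stop("AT%% constant across domains; ",
                                    "correlation undefined")
  ct <- stats::cor.test(a, w, method = "pearson")
  fit <- stats::lm(w ~ a)
  ci <- stats::confint(fit, level = 0.95)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       ci95 = ci, n = length(w))
}

#' ECDF of inter-domain gap distances
#'
#' Pools [interval_gaps()] across sequences (gaps never span sequences) and
#' reports the empirical CDF plus the fraction of gaps strictly greater
#' than `cutoff` (headline cutoff: 20 kb).
#'
#' @param domains A [domain_set()]; must be disjoint per sequence (merge
#'   first if needed).
#' @param cutoff Gap cutoff in bp (default 20000).
#' @return List with `gaps` (bp), `ecdf` (a function, or NULL when no
#'   sequence has two domains — flagged via `defined = FALSE`),
#'   `fraction_gt_cutoff`, `fraction_gt_cutoff_pct` (2 decimals), `defined`.
#' @export
gap_ecdf <- function(domains, cutoff = 20000) {
  gaps <- interval_gaps(domains)
  if (!length(gaps))
    return(list(gaps = integer(0), ecdf = NULL, fraction_gt_cutoff = NA_real_,
                fraction_gt_cutoff_pct = NA_real_, defined = FALSE))
  frac <- mean(gaps > cutoff)
  list(gaps = gaps, ecdf = stats::ecdf(gaps), fraction_gt_cutoff = frac,
       fraction_gt_cutoff_pct = round(100 * frac, 2), defined = TRUE)
}

#' Signal profile matrix around domain midpoints
#'
#' One row per domain: signal re-binned over `[midpoint - flank,
#' midpoint + flank)`. Profile bins falling outside the sequence are NA.
#'
#' @param track A [signal_track()].
#' @param domains A [domain_set()].
#' @param flank Flank on each side of the midpoint in bp (default 2000,
#'   the main-figure choice; 4000 reproduces the wider variant).
#' @param bin Profile bin width in bp; must divide `2 * flank`.
#' @return Matrix of dimension `n_domains x (2*flank/bin)` with class
#'   `"profile_matrix"`; attributes `flank` and `bin`.
#' @export
profile_matrix <- function(track, domains, flank = 2000, bin = 50) {
  stopifnot(inherits(track, "signal_track"), flank > 0, bin > 0)
  if ((2 * flank) %% bin != 0) stop("bin must divide 2*flank")
  ncols <- as.integer(2 * flank / bin)
  bs <- track$bin_size
  mat <- matrix(NA_real_, nrow = nrow(domains), ncol = ncols)
  for (i in seq_len(nrow(domains))) {
    sid <- domains$seq_id[i]
    v <- track$values[[sid]]
    L <- track$seq_lengths[[sid]]
    mid <- (domains$start[i] + domains$end[i]) %/% 2L
    for (j in seq_len(ncols)) {
      p0 <- mid - flank + (j - 1L) * bin
      p1 <- p0 + bin
      if (p1 <= 0 || p0 >= L) next
      b0 <- max(p0, 0) %/% bs + 1L
      b1 <- ceiling(min(p1, L) / bs)
      mat[i, j] <- mean(v[b0:b1], na.rm = FALSE)
    }
  }
  structure(mat, class = c("profile_matrix", "matrix", "array"),
            flank = flank, bin = bin)
}

#' k-means clustering of domain signal profiles
#'
#' Euclidean k-means on the profile rows with missing bins imputed as 0,
#' `nstart` restarts, and a fixed seed; clusters are relabeled in order of
#' descending peak height of their mean profile so cluster 1 is always the
#' strongest. When fewer than `k` distinct rows exist, all rows go to
#' cluster 1 (ties broken by index) and the result is flagged degenerate.
#'
#' @param matrix A [profile_matrix()] (rows >= k).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed (required for reproducible assignment).
#' @param nstart Random restarts (default 10).
#' @return List with `assignment` (integer per row), `cluster_means`
#'   (k x ncol matrix, NA rows for unpopulated clusters), `sizes`,
#'   `degenerate`.
#' @export
cluster_profiles <- function(matrix, k = 4, seed, nstart = 10) {
  if (nrow(matrix) < k) stop("fewer rows than clusters")
  if (missing(seed)) stop("a seed is required")
  m <- unclass(matrix)
  m[is.na(m)] <- 0
  if (nrow(unique(m)) < k) {
    means <- matrix(NA_real_, nrow = k, ncol = ncol(m))
    means[1L, ] <- colMeans(m)
    return(list(assignment = rep(1L, nrow(m)), cluster_means = means,
                sizes = c(nrow(m), rep(0L, k - 1L)), degenerate = TRUE))
  }
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart)
  ord <- order(apply(km$centers, 1L, max), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  list(assignment = relabel[km$cluster],
       cluster_means = km$centers[ord, , drop = FALSE],
       sizes = as.integer(km$size[ord]), degenerate = FALSE)
}

#' Average ChIP enrichment across marker gene copies
#'
#' Projects each copy of a marker onto a common gene coordinate system
#' (reverse-strand copies are flipped so position 1 is always the gene
#' start), averages the per-base signal across copies, and excludes masked
#' positions (e.g. promoter/3'UTR windows whose reads cannot be assigned
#' uniquely). Positions masked or absent in every copy are reported NA.
#'
#' @param track A [signal_track()].
#' @param copies Interval data frame of the marker's copies (`seq_id`,
#'   `start`, `end`, `strand`); all copies must have equal width.
#' @param mask Optional interval data frame of masked regions in genome
#'   coordinates.
#' @return List with `profile` (numeric, one value per gene position),
#'   `n_copies`, and `coverage` (copies contributing per position).
#' @export
marker_enrichment <- function(track, copies, mask = NULL) {
  stopifnot(inherits(track, "signal_track"))
  validate_intervals(copies)
  if (nrow(copies) == 0L) stop("at least one copy required")
  widths <- copies$end - copies$start
  if (length(unique(widths)) != 1L)
    stop("all copies must have equal width")
  W <- widths[1L]
  bs <- track$bin_size
  acc <- numeric(W)
  cov <- integer(W)
  for (i in seq_len(nrow(copies))) {
    sid <- copies$seq_id[i]
    v <- track$values[[sid]]
    pos <- copies$start[i]:(copies$end[i] - 1L)          # genome bp
    val <- v[pos %/% bs + 1L]                            # bin value per bp
    if (!is.null(mask) && nrow(mask)) {
      ms <- mask[mask$seq_id == sid, , drop = FALSE]
      for (j in seq_len(nrow(ms)))
        val[pos >= ms$start[j] & pos < ms$end[j]] <- NA_real_
    }
    if (identical(copies$strand[i], "-")) val <- rev(val)
    ok <- !is.na(val)
    acc[ok] <- acc[ok] + val[ok]
    cov <- cov + ok
  }
  profile <- ifelse(cov > 0L, acc / cov, NA_real_)
  list(profile = profile, n_copies = nrow(copies), coverage = cov)
}

#' Maximum per-domain AT fraction
#'
#' The AT ceiling check: no CENP-A domain on either the AC or endogenous
#' chromosomes exceeds 80% AT.
#'
#' @param stats A [domain_stats()] result with at least one domain.
#' @return The maximum AT fraction across domains.
#' @export
max_domain_at <- function(stats) {
  if (!length(stats$at_per_domain)) stop("empty domain set")
  max(stats$at_per_domain)
}
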
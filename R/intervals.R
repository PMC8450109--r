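# Interval algebra over BED-convention coordinates.
#
# All coordinates are 0-based, half-open ([start, end)) everywhere inside the
# package; 1-based coordinates appear only where an external format requires
# them, and are labeled there.

#' Construct an interval table
#'
#' The package-wide representation of genomic intervals: a plain data frame
#' with columns `seq_id`, `start`, `end`, `strand`, using 0-based half-open
#' coordinates (BED convention).
#'
#' @param seq_id Character vector of sequence names.
#' @param start,end Integer vectors; `0 <= start < end` per row.
#' @param strand Strand per row: `"+"`, `"-"` or `"."` (default).
#' @return A data frame with columns `seq_id`, `start`, `end`, `strand`.
#' @export
intervals <- function(seq_id, start, end, strand = rep(".", length(start))) {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' @rdname intervals
#' @param x An interval data frame to validate.
#' @param seq_lengths Optional named vector of sequence lengths; when given,
#'   every interval must lie within `[0, length]` of its sequence.
#' @export
validate_intervals <- function(x, seq_lengths = NULL) {
  stopifnot(is.data.frame(x),
            all(c("seq_id", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)) ||
      any(x$start < 0) || any(x$start >= x$end))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(seq_lengths)) {
    unknown <- setdiff(x$seq_id, names(seq_lengths))
    if (length(unknown))
      stop("interval seq_id not in genome: ", paste(unknown, collapse = ", "))
    if (any(x$end > seq_lengths[x$seq_id]))
      stop("interval extends beyond its sequence")
  }
  invisible(x)
}

.as_iranges <- function(x) {
  # 0-based half-open -> 1-based closed
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Merge intervals into a minimal disjoint set
#'
#' Returns the minimal set of disjoint intervals covering exactly the same
#' bases, per sequence. Book-ended intervals (one ends where the next starts)
#' are merged; intervals on different sequences never merge. Strand is
#' ignored and reported as `"."`.
#'
#' @param x Interval data frame (see [intervals()]).
#' @return A merged interval data frame sorted by `seq_id`, then `start`.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(intervals(character(0), integer(0), integer(0)))
  pieces <- lapply(split(x, x$seq_id), function(xs) {
    r <- IRanges::reduce(.as_iranges(xs))  # merges overlapping and adjacent
    intervals(rep(xs$seq_id[1L], length(r)),
              BiocGenerics::start(r) - 1L, BiocGenerics::end(r))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Gap lengths between consecutive intervals
#'
#' For each sequence, the distances between consecutive sorted intervals
#' (`next start - previous end`). Terminal flanks are not gaps, and gaps
#' never span different sequences. Input must already be disjoint per
#' sequence (run [merge_intervals()] first); overlapping input is an error
#' rather than silently mis-measured.
#'
#' @param x Disjoint interval data frame.
#' @return Integer vector of gap lengths in bp, pooled across sequences.
#' @examples
#' iv <- intervals(rep("chr", 3), c(0, 20, 100), c(10, 30, 110))
#' interval_gaps(iv)  # 10 70
#' @export
interval_gaps <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(integer(0))
  gaps <- lapply(split(x, x$seq_id), function(xs) {
    xs <- xs[order(xs$start), , drop = FALSE]
    if (nrow(xs) > 1L && any(xs$start[-1L] < xs$end[-nrow(xs)]))
      stop("overlapping intervals; merge_intervals() first")
    if (nrow(xs) < 2L) return(integer(0))
    xs$start[-1L] - xs$end[-nrow(xs)]
  })
  unlist(gaps, use.names = FALSE)
}

# total bases covered by a (possibly overlapping) interval set
.covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start)
}

# TRUE for rows of x overlapping any interval of y (same seq_id)
.overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (sid in unique(x$seq_id)) {
    xi <- which(x$seq_id == sid)
    ys <- y[y$seq_id == sid, , drop = FALSE]
    if (nrow(ys) == 0L) next
    ov <- IRanges::overlapsAny(.as_iranges(x[xi, , drop = FALSE]),
                               .as_iranges(ys))
    out[xi] <- ov
  }
  out
}
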
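# File I/O: FASTA (via Biostrings), BED6 and bedGraph (plain-text readers
# and writers that round-trip records this package wrote itself).

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on load (soft-masking is not preserved). By
#' default any letter outside A, C, G, T, N is an error; with
#' `invalid = "N"` such letters are mapped to N instead.
#'
#' @param path FASTA file.
#' @param invalid `"error"` (default) or `"N"`.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, invalid = c("error", "N")) {
  invalid <- match.arg(invalid)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (invalid == "error")
      stop("non-ACGTN letters in record(s): ",
           paste(names(seqs)[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  if (any(names(seqs) == "")) stop("empty FASTA record id")
  if (any(nchar(seqs) == 0L)) stop("empty FASTA sequence")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file; lines wrapped at `width` columns.
#' @param width Line width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED files are 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged. `read_bed` accepts
#' 3 to 6 columns; `write_bed` emits BED6 (name ".", score 0 where absent).
#'
#' @param path BED file.
#' @return `read_bed`: an interval data frame with a `name` column.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("BED needs at least 3 columns")
  df <- intervals(raw[[1L]], as.integer(raw[[2L]]), as.integer(raw[[3L]]),
                  strand = if (ncol(raw) >= 6L) raw[[6L]]
                           else rep(".", nrow(raw)))
  df$name <- if (ncol(raw) >= 4L) raw[[4L]] else rep(".", nrow(raw))
  df
}

#' @rdname read_bed
#' @param x Interval data frame (optionally with `name`/`score` columns).
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- data.frame(x$seq_id, x$start, x$end,
                    name = if ("name" %in% names(x)) x$name
                           else rep(".", nrow(x)),
                    score = if ("score" %in% names(x)) x$score
                            else rep(0L, nrow(x)),
                    strand = if ("strand" %in% names(x)) x$strand
                             else rep(".", nrow(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph signal
#'
#' Handles both the fixed-bin dialect (all spans equal) and variable spans.
#' `read_bedgraph` returns the raw 4-column table; [bedgraph_to_track()]
#' converts it to a binned [signal_track()].
#'
#' @param path bedGraph file.
#' @return `read_bedgraph`: data frame `seq_id`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 4L) stop("bedGraph needs 4 columns")
  df <- data.frame(seq_id = as.character(raw[[1L]]),
                   start = as.integer(raw[[2L]]), end = as.integer(raw[[3L]]),
                   value = as.numeric(raw[[4L]]), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' @rdname read_bedgraph
#' @param x Data frame `seq_id`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("seq_id", "start", "end", "value") %in% names(x)))
  utils::write.table(x[, c("seq_id", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between a signal track and bedGraph rows
#'
#' `track_to_bedgraph` emits one row per non-missing bin (fixed-bin dialect;
#' the last bin of a sequence is truncated to the sequence end).
#' `bedgraph_to_track` rebuilds a track from rows whose spans align to the
#' bin grid; bins not covered by any row are missing (NA).
#'
#' @param track A [signal_track()].
#' @param x bedGraph data frame from [read_bedgraph()].
#' @param bin_size,seq_lengths Bin width and named sequence lengths for the
#'   rebuilt track.
#' @export
track_to_bedgraph <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  rows <- lapply(names(track$values), function(sid) {
    v <- track$values[[sid]]
    keep <- which(!is.na(v))
    if (!length(keep)) return(NULL)
    start <- (keep - 1L) * track$bin_size
    data.frame(seq_id = sid, start = start,
               end = pmin(start + track$bin_size, track$seq_lengths[[sid]]),
               value = v[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname track_to_bedgraph
#' @export
bedgraph_to_track <- function(x, bin_size, seq_lengths) {
  track <- signal_track(lapply(seq_lengths, function(L)
    rep(NA_real_, ceiling(L / bin_size))), bin_size, seq_lengths)
  for (i in seq_len(nrow(x))) {
    sid <- x$seq_id[i]
    if (!sid %in% names(seq_lengths)) stop("unknown sequence: ", sid)
    if (x$start[i] %% bin_size != 0L)
      stop("bedGraph span not aligned to bin grid")
    b0 <- x$start[i] %/% bin_size + 1L
    b1 <- ceiling(x$end[i] / bin_size)
    track$values[[sid]][b0:b1] <- x$value[i]
  }
  track
}
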
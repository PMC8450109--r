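# Sequence primitives: AT-content, reverse complement, IUPAC consensus
# scanning, N50.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

.check_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L) stop(what, " is empty")
  s <- toupper(seq)
  if (grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), s))
    stop(what, " contains non-IUPAC letters")
  s
}

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L) stop(what, " is empty")
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) stop(what, " contains letters outside {A,C,G,T,N}")
  s
}

#' AT-content of a nucleotide sequence
#'
#' Fraction of A and T bases among the unambiguous bases (A, C, G, T) of a
#' sequence. N bases are excluded from both the numerator and the denominator,
#' so gap-padded assemblies do not have their AT% inflated.
#'
#' @param seq A single string over the alphabet A, C, G, T, N (case
#'   insensitive).
#' @return A fraction in `[0, 1]`.
#' @examples
#' at_content("ATAT")                 # 1
#' at_content("AATTGTGAGCGCTCACAA")   # the 18-bp LacO site, 10/18
#' @export
at_content <- function(seq) {
  s <- .check_dna(seq)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence is all-N; AT-content undefined")
  unname((counts[["A"]] + counts[["T"]]) / denom)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes are complemented per the IUPAC complement table
#' (R <-> Y, S <-> S, W <-> W, K <-> M, B <-> V, D <-> H, N <-> N), so
#' `revcomp(revcomp(s))` is always `s`.
#'
#' @param seq A single IUPAC nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  s <- .check_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a sequence for matches to a degenerate IUPAC consensus
#'
#' Finds every position (overlapping matches included) whose subsequence
#' matches the consensus letter by letter under IUPAC degeneracy: consensus R
#' matches A or G, D matches A/G/T, and so on. An N in the scanned sequence
#' matches only a consensus N. With `strands = "both"`, reverse-strand
#' matches are matches of `revcomp(consensus)` on the forward sequence and
#' are reported in forward coordinates with strand `"-"`.
#'
#' Sites that match on both strands at identical coordinates (palindromic
#' consensus) are reported once when `dedup_palindromes = TRUE`, which avoids
#' double-counting strand-symmetric site tallies.
#'
#' @param consensus IUPAC consensus string, e.g. the 29-bp A-rich
#'   holocentromere consensus `"AAAARRAARARAADVAAAAAAARARRAAA"`.
#' @param seq Sequence to scan (string over A,C,G,T,N).
#' @param seq_id Name used in the `seq_id` column of the result.
#' @param strands `"both"` (default) or `"forward"`.
#' @param dedup_palindromes Collapse identical-coordinate two-strand matches
#'   to one row (default `TRUE`).
#' @return An interval data frame (`seq_id`, `start`, `end`, `strand`),
#'   0-based half-open, sorted by start. A consensus longer than the sequence
#'   yields zero rows.
#' @export
scan_consensus <- function(consensus, seq, seq_id = "seq",
                           strands = c("both", "forward"),
                           dedup_palindromes = TRUE) {
  strands <- match.arg(strands)
  pat <- .check_iupac(consensus, "consensus")
  s <- .check_dna(seq)
  if (nchar(pat) > nchar(s))
    return(intervals(character(0), integer(0), integer(0)))
  subject <- Biostrings::DNAString(s)
  hit_starts <- function(p) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), subject,
                                  fixed = "subject")
    BiocGenerics::start(m) - 1L  # to 0-based
  }
  fwd <- hit_starts(pat)
  res <- intervals(rep(seq_id, length(fwd)), fwd, fwd + nchar(pat),
                   strand = rep("+", length(fwd)))
  if (strands == "both") {
    rev <- hit_starts(revcomp(pat))
    if (dedup_palindromes) rev <- setdiff(rev, fwd)
    res <- rbind(res, intervals(rep(seq_id, length(rev)), rev,
                                rev + nchar(pat),
                                strand = rep("-", length(rev))))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

#' N50 of a set of lengths
#'
#' The largest length L such that pieces of length >= L together contain at
#' least half of the total length.
#'
#' @param lengths Non-empty vector of positive integer lengths.
#' @return The N50, an integer-valued scalar.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("lengths must be positive")
  l <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(l))
  l[which(cum >= sum(as.numeric(l)) / 2)[1L]]
}
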
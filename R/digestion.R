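# In-silico restriction digestion producing a provenance-tracked fragment
# catalogue.

#' Define a blunt-cutting restriction enzyme
#'
#' The duplex is severed `cut_offset` bases after the start of each
#' occurrence of the recognition site, on both strands (blunt ends only).
#' Degenerate IUPAC recognitions are allowed; non-palindromic recognitions
#' are handled by scanning both strands and mapping reverse-strand hits to
#' forward cut coordinates.
#'
#' @param name Enzyme name.
#' @param recognition Recognition site (IUPAC string, length >= 4).
#' @param cut_offset Cut position within the site, `0 <= cut_offset <=
#'   nchar(recognition)`.
#' @return An object of class `"enzyme"`.
#' @examples
#' enzyme("AfaI", "GTAC", 2)     # GT|AC
#' enzyme("PvuII", "CAGCTG", 3)  # CAG|CTG
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- .check_iupac(recognition, "recognition")
  if (nchar(recognition) < 4L) stop("recognition site must be >= 4 bp")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must be within the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "enzyme")
}

#' The two blunt cutters used to fragment the yeast donor genome
#'
#' AfaI (GT|AC) and PvuII (CAG|CTG).
#' @return List of two [enzyme()] objects.
#' @export
ac_donor_enzymes <- function() {
  list(enzyme("AfaI", "GTAC", 2L), enzyme("PvuII", "CAGCTG", 3L))
}

#' Find all cut positions of a set of enzymes on a sequence
#'
#' Returns forward-strand offsets at which the duplex is severed. Both
#' strands are scanned (for palindromic recognitions this is redundant and
#' duplicates are collapsed); overlapping recognition occurrences each
#' contribute a cut, matching digestion to completion. Cuts at the very ends
#' of a linear sequence (offset 0 or the sequence length) sever nothing and
#' are dropped.
#'
#' @param seq Sequence string (A,C,G,T,N).
#' @param enzymes List of [enzyme()] objects.
#' @return Sorted integer vector of cut offsets (0-based: a cut at `p`
#'   separates `[0, p)` from `[p, len)`).
#' @examples
#' find_cut_sites("GGTACC", list(enzyme("AfaI", "GTAC", 2)))          # 3
#' find_cut_sites("AAGTACAACAGCTGAA", ac_donor_enzymes())             # 4 11
#' @export
find_cut_sites <- function(seq, enzymes) {
  s <- .check_dna(seq)
  cuts <- integer(0)
  for (e in enzymes) {
    stopifnot(inherits(e, "enzyme"))
    fwd <- scan_consensus(e$recognition, s, strands = "forward")
    cuts <- c(cuts, fwd$start + e$cut_offset)
    if (e$recognition != revcomp(e$recognition)) {
      # site on the minus strand at forward window [p, p+k): the minus-strand
      # cut at cut_offset from the site start maps to forward p + k - offset
      rev <- scan_consensus(revcomp(e$recognition), s, strands = "forward")
      cuts <- c(cuts, rev$start + nchar(e$recognition) - e$cut_offset)
    }
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(s)]
}

#' Digest a genome into a fragment catalogue
#'
#' Linear records are split at every cut position; concatenating a linear
#' record's fragments in order reconstructs the record exactly. Circular
#' records are linearized at their lowest cut position, the final fragment
#' wrapping across the origin; a circular record with no cut site yields one
#' whole fragment flagged circular.
#'
#' @param genome Named character vector of sequences.
#' @param enzymes List of [enzyme()] objects (non-empty).
#' @param circular Character vector of record names to treat as circular
#'   (e.g. a mitochondrial genome); default none.
#' @param donor_id Label stored with the catalogue.
#' @return A `fragment_catalogue`: a data frame with columns `fragment_id`,
#'   `source_seq`, `start`, `end`, `length`, `circular`, `sequence`
#'   (0-based half-open donor coordinates; for a fragment wrapping a
#'   circular origin, `end = start of wrap + length` exceeds the record
#'   length). Enzymes and donor id are attached as attributes.
#' @export
digest <- function(genome, enzymes, circular = character(0),
                   donor_id = "donor") {
  if (length(genome) == 0L) stop("empty genome")
  if (length(enzymes) == 0L) stop("no enzymes")
  stopifnot(!is.null(names(genome)))
  rows <- list()
  for (sid in names(genome)) {
    s <- .check_dna(genome[[sid]], paste0("record ", sid))
    L <- nchar(s)
    cuts <- find_cut_sites(s, enzymes)
    is_circ <- sid %in% circular
    if (!is_circ) {
      bounds <- c(0L, cuts, L)
      st <- bounds[-length(bounds)]
      en <- bounds[-1L]
      frag_seq <- substring(s, st + 1L, en)
      rows[[sid]] <- data.frame(source_seq = sid, start = st, end = en,
                                length = en - st, circular = FALSE,
                                sequence = frag_seq, stringsAsFactors = FALSE)
    } else if (length(cuts) == 0L) {
      rows[[sid]] <- data.frame(source_seq = sid, start = 0L, end = L,
                                length = L, circular = TRUE,
                                sequence = s, stringsAsFactors = FALSE)
    } else {
      st <- cuts
      en <- c(cuts[-1L], cuts[1L] + L)  # last fragment wraps the origin
      frag_seq <- ifelse(en <= L,
                         substring(s, st + 1L, en),
                         paste0(substring(s, st + 1L, L),
                                substring(s, 1L, en - L)))
      rows[[sid]] <- data.frame(source_seq = sid, start = st, end = en,
                                length = en - st, circular = FALSE,
                                sequence = frag_seq, stringsAsFactors = FALSE)
    }
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  cat <- cbind(fragment_id = sprintf("frag%06d", seq_len(nrow(cat))), cat,
               stringsAsFactors = FALSE)
  structure(cat, class = c("fragment_catalogue", "data.frame"),
            enzymes = enzymes, donor_id = donor_id)
}

#' @export
print.fragment_catalogue <- function(x, ...) {
  enz <- paste(vapply(attr(x, "enzymes"), `[[`, "", "name"), collapse = " + ")
  cat(sprintf("Fragment catalogue: %d fragments from '%s' (%s)\n",
              nrow(x), attr(x, "donor_id"), enz))
  cat(sprintf("  total %.0f bp, mean length %.1f bp, range %d-%d bp\n",
              sum(as.numeric(x$length)), mean(x$length),
              min(x$length), max(x$length)))
  invisible(x)
}

#' Summary statistics of fragment lengths
#'
#' @param catalogue A [digest()] catalogue.
#' @param subset Optional character vector of `fragment_id`s to restrict to.
#' @param bin_width Histogram bin width in bp (default 100).
#' @return List with `n`, `mean`, `median`, `min`, `max`, `total`, and a
#'   `histogram` data frame (`mid`, `count`, `density`); the density
#'   integrates to 1.
#' @export
fragment_length_stats <- function(catalogue, subset = NULL, bin_width = 100) {
  lens <- catalogue$length
  if (!is.null(subset)) lens <- lens[catalogue$fragment_id %in% subset]
  if (length(lens) == 0L) stop("no fragments after subsetting")
  breaks <- seq(0, max(lens) + bin_width, by = bin_width)
  h <- graphics::hist(lens, breaks = breaks, plot = FALSE)
  list(n = length(lens), mean = mean(lens), median = stats::median(lens),
       min = min(lens), max = max(lens), total = sum(as.numeric(lens)),
       histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density))
}

#' Write / read a fragment catalogue as TSV
#'
#' Columns: fragment_id, source_seq, start, end, length, circular and
#' (optionally) sequence.
#'
#' @param catalogue A `fragment_catalogue`.
#' @param path TSV path.
#' @param sequences Include the sequence column (default TRUE).
#' @export
write_catalogue <- function(catalogue, path, sequences = TRUE) {
  cols <- c("fragment_id", "source_seq", "start", "end", "length", "circular")
  if (sequences) cols <- c(cols, "sequence")
  utils::write.table(as.data.frame(catalogue)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @param genome Donor genome; required to restore sequences when the TSV
#'   has no sequence column.
#' @export
read_catalogue <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df)) {
    if (is.null(genome)) stop("TSV has no sequences; supply the donor genome")
    df$sequence <- substring(genome[df$source_seq], df$start + 1L, df$end)
  }
  structure(df, class = c("fragment_catalogue", "data.frame"),
            enzymes = list(), donor_id = "file")
}
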
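# Independent brute-force oracles and small-fixture builders used across the
# suite. These deliberately avoid the code paths they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

rand_dna_fixed <- function(n, seed = 1, at = 0.5) {
  set.seed(seed)
  rand_dna(n, at)
}

rand_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# window-by-window IUPAC matching; subject N matches only consensus N
brute_iupac_starts <- function(consensus, seq) {
  k <- nchar(consensus)
  n <- nchar(seq)
  if (k > n) return(integer(0))
  cl <- strsplit(consensus, "")[[1]]
  sl <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (p in 0:(n - k)) {
    ok <- TRUE
    for (j in 1:k) {
      sb <- sl[p + j]
      cb <- cl[j]
      match_j <- if (sb == "N") cb == "N" else sb %in% IUPAC_SETS[[cb]]
      if (!match_j) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

brute_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# per-base coverage of an interval data frame, as a named list of logical
brute_coverage <- function(x, seq_lengths) {
  cov <- lapply(seq_lengths, function(L) logical(L))
  for (i in seq_len(nrow(x))) {
    sid <- x$seq_id[i]
    cov[[sid]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  cov
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact-mode classification labels by base-R fixed-string search
brute_incorporated <- function(frag_seqs, ac_seqs) {
  vapply(frag_seqs, function(f) {
    rc <- brute_revcomp(f)
    any(vapply(ac_seqs, function(s)
      grepl(f, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE))
  }, TRUE, USE.NAMES = FALSE)
}

# all 0-based match starts of a plain string (both strands, dedup identical
# coordinates), window by window
brute_loci_count <- function(frag, ac) {
  k <- nchar(frag)
  rc <- brute_revcomp(frag)
  n <- 0L
  for (p in 0:(nchar(ac) - k)) {
    w <- substring(ac, p + 1, p + k)
    if (w == frag || w == rc) n <- n + 1L
  }
  n
}

# a tiny two-species pool: a catalogue built from one linear record plus an
# optional marker cassette
toy_pool <- function(record, mass = c(1), marker = NULL, marker_mass = 1) {
  ct <- digest(c(donor = record), ac_donor_enzymes())
  if (is.null(marker)) pool_spec(ct, mass_fractions = mass)
  else pool_spec(ct, marker, mass_fractions = c(mass, marker_mass))
}
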
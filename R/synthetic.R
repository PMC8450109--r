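# Synthetic-data generator: donor genomes with controlled AT composition and
# high-AT islands, marker cassettes, ChIP-like log2-ratio tracks with
# AT-dependent and transcription-excluded domain placement, and end-to-end
# fixtures. Everything is deterministic given its seed.

#' Generate a donor genome with controlled AT composition
#'
#' Bases are drawn independently per region with `P(A) = P(T) = AT/2` and
#' `P(C) = P(G) = (1-AT)/2` (an order-0 model, like the random-sequence
#' generators used for synthetic injection pools); an optional order-1 mode
#' adds base-class autocorrelation at the same stationary AT. High-AT
#' islands (emulating yeast CEN-like and mitochondrial sequences at >= 83%
#' AT) and marker cassettes overwrite the background at their positions.
#'
#' @param chromosomes Data frame with columns `length` (bp) and `at`
#'   (target AT fraction), optionally `name` (default chr1..chrN).
#' @param islands Optional data frame `chrom` (name), `start`, `length`,
#'   `at` (each >= 0.83).
#' @param cassettes Optional list of entries `list(cassette =
#'   marker_cassette, chrom = name, pos = insertion offset)`; insertions
#'   (and islands) must not overlap one another.
#' @param seed Integer seed.
#' @param order 0 (default, i.i.d. bases) or 1 (autocorrelated classes).
#' @param rho Class persistence probability for `order = 1` (default 0.3).
#' @return List with `genome` (named character vector) and `features`, an
#'   interval data frame with columns `type` (`island`/`cassette`/`gene`),
#'   `label` and `expression` (for genes: `ubiquitous`, `somatic` or
#'   `germline`; NA otherwise).
#' @export
synth_genome <- function(chromosomes, islands = NULL, cassettes = NULL,
                         seed = 1L, order = 0, rho = 0.3) {
  stopifnot(all(c("length", "at") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (any(chromosomes$at <= 0 | chromosomes$at >= 1))
    stop("AT targets must be in (0,1)")
  if (!is.null(islands) && any(islands$at < 0.83))
    stop("island AT must be >= 0.83")
  nm <- if ("name" %in% names(chromosomes)) chromosomes$name
        else paste0("chr", seq_len(nrow(chromosomes)))
  set.seed(seed)
  draw <- function(L, at) {
    probs <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
    if (order == 0)
      return(sample(names(probs), L, replace = TRUE, prob = probs))
    cls <- integer(L)                       # 1 = A/T class, 0 = C/G class
    cls_iid <- stats::rbinom(L, 1L, at)
    keep <- stats::runif(L) < rho
    cls[1L] <- cls_iid[1L]
    for (i in 2:L) cls[i] <- if (keep[i]) cls[i - 1L] else cls_iid[i]
    within <- sample(c(0L, 1L), L, replace = TRUE)
    c("C", "G", "A", "T")[1L + within + 2L * cls]
  }
  genome <- character(nrow(chromosomes))
  names(genome) <- nm
  for (i in seq_len(nrow(chromosomes)))
    genome[i] <- paste(draw(chromosomes$length[i], chromosomes$at[i]),
                       collapse = "")
  feats <- list()
  occupied <- intervals(character(0), integer(0), integer(0))
  claim <- function(sid, start, end, what) {
    iv <- intervals(sid, start, end)
    if (any(.overlaps_any(iv, occupied)))
      stop("overlapping insertions: ", what)
    occupied <<- rbind(occupied, iv)
    iv
  }
  if (!is.null(islands)) {
    for (i in seq_len(nrow(islands))) {
      sid <- islands$chrom[i]
      st <- islands$start[i]
      en <- st + islands$length[i]
      if (en > nchar(genome[[sid]])) stop("island beyond chromosome end")
      claim(sid, st, en, "island")
      substr(genome[[sid]], st + 1L, en) <-
        paste(draw(islands$length[i], islands$at[i]), collapse = "")
      feats[[length(feats) + 1L]] <-
        data.frame(seq_id = sid, start = st, end = en, strand = ".",
                   type = "island",
                   label = sprintf("island_%d", i),
                   expression = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cassettes)) {
    for (cs in cassettes) {
      cat_ <- cs$cassette
      stopifnot(inherits(cat_, "marker_cassette"))
      sid <- cs$chrom
      st <- cs$pos
      en <- st + cat_$length
      if (en > nchar(genome[[sid]])) stop("cassette beyond chromosome end")
      claim(sid, st, en, cat_$name)
      substr(genome[[sid]], st + 1L, en) <- cat_$sequence
      feats[[length(feats) + 1L]] <-
        data.frame(seq_id = sid, start = st, end = en, strand = "+",
                   type = "cassette", label = cat_$name,
                   expression = NA_character_, stringsAsFactors = FALSE)
      if (!is.null(cat_$subfeatures)) {
        sf <- cat_$subfeatures
        feats[[length(feats) + 1L]] <-
          data.frame(seq_id = sid, start = st + sf$start,
                     end = st + sf$end, strand = "+", type = "gene",
                     label = sf$label,
                     expression = if ("expression" %in% names(sf))
                       sf$expression else NA_character_,
                     stringsAsFactors = FALSE)
      }
    }
  }
  features <- if (length(feats)) do.call(rbind, feats)
              else data.frame(seq_id = character(0), start = integer(0),
                              end = integer(0), strand = character(0),
                              type = character(0), label = character(0),
                              expression = character(0))
  rownames(features) <- NULL
  list(genome = genome, features = features)
}

#' A synthetic three-gene co-injection marker cassette
#'
#' A deterministic stand-in for the NeoR / gfp::h2b / mCherry ("NGM")
#' co-injection marker: three synthetic gene bodies with the corresponding
#' expression classes (`ubiquitous`, `germline`, `somatic`) separated by
#' short spacers. The sequence is random (seeded), not the real cassette.
#'
#' @param gene_length Length of each synthetic gene body in bp (default
#'   1500).
#' @param spacer Spacer between genes in bp (default 200).
#' @param at AT fraction of the cassette sequence (default 0.55).
#' @param seed Integer seed (default 421).
#' @return A [marker_cassette()] named `"NGM"`.
#' @export
ngm_cassette <- function(gene_length = 1500L, spacer = 200L, at = 0.55,
                         seed = 421L) {
  set.seed(seed)
  L <- 3L * gene_length + 2L * spacer
  probs <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  seq <- paste(sample(names(probs), L, replace = TRUE, prob = probs),
               collapse = "")
  step <- gene_length + spacer
  marker_cassette("NGM", seq, subfeatures = data.frame(
    label = c("NeoR", "gfp_h2b", "mCherry"),
    start = c(0L, step, 2L * step),
    end = c(gene_length, step + gene_length, 2L * step + gene_length),
    expression = c("ubiquitous", "germline", "somatic"),
    stringsAsFactors = FALSE))
}

# AT fraction in a window of `window` bp centered on each bin midpoint;
# returns one value per bin (N-free synthetic sequences assumed)
.window_at <- function(seq, bin_size, window) {
  L <- nchar(seq)
  is_at <- as.integer(strsplit(seq, "", fixed = TRUE)[[1L]] %in% c("A", "T"))
  cum <- c(0L, cumsum(is_at))
  nbins <- ceiling(L / bin_size)
  mids <- pmin((seq_len(nbins) - 1L) * bin_size + bin_size %/% 2L, L - 1L)
  lo <- pmax(mids - window %/% 2L, 0L)
  hi <- pmin(mids + window %/% 2L, L)
  (cum[hi + 1L] - cum[lo + 1L]) / (hi - lo)
}

#' Simulate a ChIP-like log2-ratio track with planted domains
#'
#' Plants CENP-A-like enrichment domains with placement density
#' proportional to `g(AT) = AT` of the local 1-kb window, zero where the
#' window AT exceeds `at_cap` (the empirical ceiling: no observed domain
#' exceeds 80% AT) or overlaps a feature of an excluded expression class
#' (`ubiquitous` or `germline` genes — transcribed or germline-active
#' regions are refractory). Domain widths are log-normal, optionally
#' coupled to local AT so AT-richer placements come out wider (emulating
#' the weak positive width-AT correlation). The track is `amplitude` over
#' domains plus Gaussian noise per bin.
#'
#' Planted domains are aligned to the bin grid and separated by at least
#' two empty bins, so at `noise_sd = 0` the internal caller
#' ([call_domains()] at `threshold = amplitude/2`) recovers the truth
#' bit-exactly.
#'
#' @param genome Named character vector of sequences.
#' @param features Feature table from [synth_genome()] (or any interval
#'   data frame with an `expression` column); used for exclusion zones.
#' @param occupancy Target fraction of the genome covered by planted
#'   domains (default 0.20).
#' @param at_cap Maximum window AT for placement (default 0.80).
#' @param amplitude Domain signal in log2 units (default 2).
#' @param noise_sd Gaussian noise SD per bin (default 0.3).
#' @param bin_size Track bin width in bp (default 50).
#' @param width_meanlog,width_sdlog Log-normal width parameters (defaults
#'   `log(1000)` and 0.4).
#' @param width_at_coupling Added to the log-width per unit of (window AT
#'   minus its genome mean); 0 decouples width from AT (default 1.5, a weak
#'   positive coupling).
#' @param window AT window in bp (default 1000).
#' @param exclude_classes Expression classes that forbid placement
#'   (default `c("ubiquitous", "germline")`).
#' @param seed Integer seed.
#' @return List with `track` (a [signal_track()]) and `truth` (a
#'   [domain_set()] with source `"truth"`).
#' @export
synth_chip_signal <- function(genome, features = NULL, occupancy = 0.20,
                              at_cap = 0.80, amplitude = 2, noise_sd = 0.3,
                              bin_size = 50L,
                              width_meanlog = log(1000), width_sdlog = 0.4,
                              width_at_coupling = 1.5, window = 1000L,
                              exclude_classes = c("ubiquitous", "germline"),
                              seed = 1L) {
  if (at_cap <= 0.5 || at_cap >= 1) stop("at_cap must be in (0.5, 1)")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  seq_lengths <- stats::setNames(nchar(genome), names(genome))
  excl <- if (!is.null(features) && "expression" %in% names(features))
    features[!is.na(features$expression) &
             features$expression %in% exclude_classes, , drop = FALSE]
  else intervals(character(0), integer(0), integer(0))
  bs <- as.integer(bin_size)
  set.seed(seed)
  win_at <- lapply(names(genome), function(sid)
    .window_at(genome[[sid]], bs, window))
  names(win_at) <- names(genome)
  at_mean <- mean(unlist(win_at))
  # per-bin placement weight
  weights <- lapply(names(genome), function(sid) {
    w <- win_at[[sid]]
    g <- ifelse(w > at_cap, 0, w)
    L <- seq_lengths[[sid]]
    nb <- length(g)
    # windows overlapping an exclusion feature are forbidden
    ex <- excl[excl$seq_id == sid, , drop = FALSE]
    if (nrow(ex)) {
      mids <- pmin((seq_len(nb) - 1L) * bs + bs %/% 2L, L - 1L)
      lo <- pmax(mids - window %/% 2L, 0L)
      hi <- pmin(mids + window %/% 2L, L)
      for (j in seq_len(nrow(ex)))
        g[hi > ex$start[j] & lo < ex$end[j]] <- 0
    }
    g[c(1L, nb)] <- 0   # keep a margin bin at each end
    g
  })
  names(weights) <- names(genome)
  if (all(unlist(weights) == 0))
    stop("no placeable region: all windows above at_cap or excluded")
  total_len <- sum(as.numeric(seq_lengths))
  target <- occupancy * total_len
  placed <- lapply(names(genome), function(sid) logical(length(weights[[sid]])))
  names(placed) <- names(genome)
  rows <- list()
  covered <- 0
  flat_sid <- rep(names(genome), vapply(weights, length, 0L))
  flat_bin <- unlist(lapply(weights, seq_along), use.names = FALSE)
  flat_w <- unlist(weights, use.names = FALSE)
  attempts <- 0L
  max_attempts <- 1000L + 50L * ceiling(target / exp(width_meanlog))
  while (covered < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(length(flat_w), 1L, prob = flat_w)
    sid <- flat_sid[pick]
    cbin <- flat_bin[pick]
    at_here <- win_at[[sid]][cbin]
    wlog <- width_meanlog + width_at_coupling * (at_here - at_mean)
    width <- stats::rlnorm(1L, wlog, width_sdlog)
    nb_w <- max(3L, as.integer(round(width / bs)))
    nb <- length(weights[[sid]])
    b0 <- cbin - nb_w %/% 2L
    b1 <- b0 + nb_w - 1L
    if (b0 < 2L || b1 > nb - 1L) next           # keep margin bins free
    # require the domain plus one flanking bin on each side to be free
    if (any(placed[[sid]][(b0 - 1L):(b1 + 1L)])) next
    iv <- intervals(sid, (b0 - 1L) * bs, b1 * bs)
    if (nrow(excl) && any(.overlaps_any(iv, excl))) next
    # the realized span must respect the AT ceiling too (a window can pass
    # while the span hangs over a high-AT island edge)
    if (at_content(substring(genome[[sid]], iv$start + 1L, iv$end)) >
        at_cap) next
    placed[[sid]][b0:b1] <- TRUE
    rows[[length(rows) + 1L]] <- iv
    covered <- covered + nb_w * bs
  }
  if (!length(rows)) stop("no domain could be placed")
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  truth$mean_signal <- amplitude
  truth <- domain_set(truth, source = "truth")
  values <- lapply(names(genome), function(sid) {
    v <- ifelse(placed[[sid]], amplitude, 0)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    v
  })
  names(values) <- names(genome)
  list(track = signal_track(values, bs, seq_lengths), truth = truth)
}

#' Project marker subfeatures from truth-table segments to AC coordinates
#'
#' For each marker segment of a simulation truth table, maps the cassette's
#' annotated genes into AC coordinates (respecting partial segments and
#' orientation), yielding the exclusion features that ChIP-signal synthesis
#' on the AC needs.
#'
#' @param truth Truth table from [simulate_ac()].
#' @param pool The [pool_spec()] used.
#' @param ac_id AC sequence name (default "AC").
#' @return Interval data frame with `type = "gene"`, `label`, `expression`.
#' @export
project_marker_features <- function(truth, pool, ac_id = "AC") {
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), label = character(0),
                      expression = character(0))
  sel <- which(truth$source == "marker")
  if (!length(sel)) return(empty)
  cass <- Filter(function(s) inherits(s, "marker_cassette"), pool$species)
  names(cass) <- vapply(cass, `[[`, "", "name")
  rows <- list()
  for (i in sel) {
    cs <- cass[[truth$segment_id[i]]]
    if (is.null(cs$subfeatures)) next
    sf <- cs$subfeatures
    s0 <- truth$src_start[i]; s1 <- truth$src_end[i]
    ov_lo <- pmax(sf$start, s0); ov_hi <- pmin(sf$end, s1)
    keep <- which(ov_lo < ov_hi)
    for (j in keep) {
      if (truth$orientation[i] == "+") {
        a <- truth$ac_start[i] + (ov_lo[j] - s0)
        b <- truth$ac_start[i] + (ov_hi[j] - s0)
      } else {
        a <- truth$ac_start[i] + (s1 - ov_hi[j])
        b <- truth$ac_start[i] + (s1 - ov_lo[j])
      }
      rows[[length(rows) + 1L]] <-
        data.frame(seq_id = ac_id, start = a, end = b,
                   strand = truth$orientation[i], type = "gene",
                   label = sf$label[j],
                   expression = if ("expression" %in% names(sf))
                     sf$expression[j] else NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a complete end-to-end synthetic fixture
#'
#' Chains the full pipeline: synthetic donor genome (with high-AT islands)
#' -> restriction digestion -> AC formation by simulated end-joining with a
#' co-injected marker cassette at a 300:1 mass ratio -> ChIP-like signal
#' with planted domains on the AC. All stage seeds derive from one master
#' seed and are recorded in the manifest, so the same seed rebuilds the
#' fixture byte-identically.
#'
#' The pool is restricted to fragments of at least `min_fragment_length` bp
#' with distinct sequences, which makes exact-match classification
#' identifiable (a fragment is in the AC iff the simulator placed it).
#'
#' @param donor_chromosomes Data frame passed to [synth_genome()]; default
#'   four chromosomes totaling 2 Mb at 62% AT (yeast-like).
#' @param island_at AT of two planted high-AT islands (default 0.85).
#' @param L0,s,p_hr,target_length Join-model parameters (defaults 500, 150,
#'   0, 5e5).
#' @param mass_ratio Digest : marker mass ratio (default `c(300, 1)`).
#' @param occupancy,noise_sd ChIP-signal parameters on the AC (defaults
#'   0.20 and 0.3).
#' @param min_fragment_length Pool length floor in bp (default 30).
#' @param seed Master seed.
#' @param dir Optional directory; when given, writes donor FASTA, catalogue
#'   TSV, AC FASTA, truth TSV, signal bedGraph, truth-domain BED and a JSON
#'   manifest there.
#' @return List with `donor` (genome + features), `catalogue` (full),
#'   `pool_catalogue` (filtered), `cassette`, `pool`, `sim` (AC + truth),
#'   `chip` (track + truth domains), `manifest`.
#' @export
build_fixture <- function(donor_chromosomes = data.frame(
                            length = c(8e5, 6e5, 4e5, 2e5), at = 0.62),
                          island_at = 0.85, L0 = 500, s = 150, p_hr = 0,
                          target_length = 5e5, mass_ratio = c(300, 1),
                          occupancy = 0.20, noise_sd = 0.3,
                          min_fragment_length = 30L, seed = 1L,
                          dir = NULL) {
  seeds <- list(genome = seed, sim = seed + 1000L, chip = seed + 2000L)
  nm <- paste0("chr", seq_len(nrow(donor_chromosomes)))
  # one high-AT island on each of the first (up to) two chromosomes, sized
  # to the chromosome
  n_isl <- min(2L, nrow(donor_chromosomes))
  isl_len <- pmin(c(20e3L, 15e3L)[seq_len(n_isl)],
                  floor(donor_chromosomes$length[seq_len(n_isl)] * 0.1))
  islands <- data.frame(chrom = nm[seq_len(n_isl)],
                        start = floor(donor_chromosomes$length[
                          seq_len(n_isl)] * 0.05),
                        length = isl_len, at = island_at)
  donor <- synth_genome(cbind(donor_chromosomes, name = nm),
                        islands = islands, seed = seeds$genome)
  catalogue <- digest(donor$genome, ac_donor_enzymes(),
                      donor_id = "synthetic_donor")
  keep <- catalogue$length >= min_fragment_length &
    !duplicated(catalogue$sequence)
  pool_catalogue <- catalogue[keep, , drop = FALSE]
  class(pool_catalogue) <- class(catalogue)
  attributes(pool_catalogue)[c("enzymes", "donor_id")] <-
    attributes(catalogue)[c("enzymes", "donor_id")]
  cassette <- ngm_cassette()
  pool <- pool_spec(pool_catalogue, cassette, mass_fractions = mass_ratio)
  model <- join_model(L0 = L0, s = s, p_hr = p_hr,
                      target_length = target_length, seed = seeds$sim)
  sim <- simulate_ac(pool, model)
  ac_feats <- project_marker_features(sim$truth, pool)
  chip <- synth_chip_signal(sim$ac, ac_feats, occupancy = occupancy,
                            noise_sd = noise_sd, seed = seeds$chip)
  manifest <- list(seed = seed, seeds = seeds,
                   donor_chromosomes = donor_chromosomes,
                   island_at = island_at,
                   model = list(L0 = L0, s = s, p_hr = p_hr,
                                target_length = target_length),
                   mass_ratio = mass_ratio, occupancy = occupancy,
                   noise_sd = noise_sd,
                   min_fragment_length = min_fragment_length)
  fx <- list(donor = donor, catalogue = catalogue,
             pool_catalogue = pool_catalogue, cassette = cassette,
             pool = pool, sim = sim, chip = chip, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(donor$genome, file.path(dir, "donor.fasta"))
    write_catalogue(catalogue, file.path(dir, "catalogue.tsv"))
    write_fasta(sim$ac, file.path(dir, "ac.fasta"))
    write_truth(sim$truth, file.path(dir, "ac_truth.tsv"))
    write_bedgraph(track_to_bedgraph(chip$track),
                   file.path(dir, "chip_signal.bedgraph"))
    write_bed(chip$truth, file.path(dir, "domains_truth.bed"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}
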
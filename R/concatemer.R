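# Concatemer (artificial chromosome) formation simulator: random end-joining
# of digest fragments and spiked marker cassettes with length-biased
# incorporation, emitting the AC sequence and a complete truth table.

#' Define a marker cassette
#'
#' A co-injection marker molecule (e.g. the NeoR / gfp::h2b / mCherry "NGM"
#' cassette), optionally annotated with subfeatures and their expression
#' class (used downstream when placing ChIP-like signal: `ubiquitous` and
#' `germline` features are exclusion zones).
#'
#' @param name Cassette name.
#' @param sequence Cassette sequence (A,C,G,T,N).
#' @param subfeatures Optional data frame `label`, `start`, `end`,
#'   `expression` (0-based half-open, within the cassette).
#' @return An object of class `"marker_cassette"`.
#' @export
marker_cassette <- function(name, sequence, subfeatures = NULL) {
  sequence <- .check_dna(sequence, "cassette sequence")
  if (!is.null(subfeatures)) {
    stopifnot(all(c("label", "start", "end") %in% names(subfeatures)))
    if (any(subfeatures$start < 0) ||
        any(subfeatures$end > nchar(sequence)) ||
        any(subfeatures$start >= subfeatures$end))
      stop("subfeature intervals must lie within the cassette")
  }
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), subfeatures = subfeatures),
            class = "marker_cassette")
}

#' Specify the injected molecule pool
#'
#' Each species is a fragment catalogue or a marker cassette together with
#' its relative mass in the injection mix. The headline mix is digested
#' yeast genomic DNA and the NGM marker at a mass ratio of 300:1.
#'
#' Per-molecule draw weights follow the molar model: a species' mass is
#' spread over its total length, so each distinct molecule of species `s`
#' carries weight `mass_fraction[s] / total_length[s]` — for a
#' single-molecule species this is mass/length, and molecules of equal mass
#' draw inversely to their length.
#'
#' @param ... Species, each a `fragment_catalogue` or `marker_cassette`.
#' @param mass_fractions Numeric vector of relative masses, one per species
#'   (e.g. `c(300, 1)`).
#' @param break_prob Per-species probability that a drawn marker molecule is
#'   pre-fragmented by a uniform random double cut before joining (models
#'   the incomplete marker fragments observed on real ACs). Ignored for
#'   catalogues. Default 0.
#' @return An object of class `"pool_spec"` with a flattened molecule table.
#' @export
pool_spec <- function(..., mass_fractions, break_prob = 0) {
  species <- list(...)
  if (length(species) == 0L) stop("at least one species required")
  if (length(mass_fractions) != length(species))
    stop("one mass fraction per species required")
  if (any(mass_fractions <= 0)) stop("mass fractions must be positive")
  break_prob <- rep_len(break_prob, length(species))
  mols <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    if (inherits(sp, "fragment_catalogue")) {
      if (any(sp$length == 0L)) stop("zero-length molecule in pool")
      mols[[i]] <- data.frame(id = sp$fragment_id, source = "fragment",
                              sequence = sp$sequence, length = sp$length,
                              species = i, breakable = FALSE,
                              stringsAsFactors = FALSE)
    } else if (inherits(sp, "marker_cassette")) {
      mols[[i]] <- data.frame(id = sp$name, source = "marker",
                              sequence = sp$sequence, length = sp$length,
                              species = i, breakable = break_prob[i] > 0,
                              stringsAsFactors = FALSE)
    } else stop("species must be fragment_catalogue or marker_cassette")
  }
  structure(list(molecules = do.call(rbind, mols),
                 mass_fractions = as.numeric(mass_fractions),
                 break_prob = break_prob, species = species),
            class = "pool_spec")
}

#' Per-molecule sampling weights of a pool
#'
#' Converts the mix's mass ratios into per-molecule draw probabilities:
#' `weight(molecule in species s) = mass_fraction[s] / total_length[s]`,
#' normalized over the pool.
#'
#' @param pool A [pool_spec()].
#' @return Numeric vector of probabilities, one per molecule, summing to 1.
#' @export
molar_weights <- function(pool) {
  stopifnot(inherits(pool, "pool_spec"))
  m <- pool$molecules
  if (any(m$length <= 0L)) stop("zero-length molecule")
  tot_len <- tapply(as.numeric(m$length), m$species, sum)
  w <- pool$mass_fractions[m$species] / tot_len[as.character(m$species)]
  unname(w / sum(w))
}

#' Length-bias model for end-joining incorporation
#'
#' Incorporation of a candidate molecule is accepted with logistic
#' probability `w(L) = 1 / (1 + exp(-(L - L0)/s))`: molecules much shorter
#' than the midpoint `L0` are rarely incorporated, long ones almost always.
#' `s = 0` is the hard-step limit (0 below `L0`, 1 at or above). Defaults
#' follow the observation that fragments under ~500 bp rarely end up in the
#' AC.
#'
#' @param L0 Logistic midpoint in bp (default 500).
#' @param s Logistic scale in bp (default 150); 0 means a hard step.
#' @param p_hr Probability that a join with sufficient terminal homology is
#'   resolved by homology-mediated overlap merge instead of blunt ligation
#'   (default 0: pure NHEJ).
#' @param h_min Minimum exact terminal homology in bp for an HR join
#'   (default 20).
#' @param target_length Stop once the concatemer reaches this length (bp).
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return An object of class `"join_model"`.
#' @export
join_model <- function(L0 = 500, s = 150, p_hr = 0, h_min = 20,
                       target_length = 5e5, seed = 1L) {
  if (L0 <= 0) stop("L0 must be positive")
  if (s < 0) stop("s must be >= 0")
  if (p_hr < 0 || p_hr > 1) stop("p_hr must be in [0,1]")
  if (target_length <= 0) stop("target_length must be positive")
  structure(list(L0 = L0, s = s, p_hr = p_hr, h_min = as.integer(h_min),
                 target_length = as.numeric(target_length),
                 seed = as.integer(seed)),
            class = "join_model")
}

#' Probability that a molecule of a given length is incorporated
#'
#' @param length Molecule length(s) in bp.
#' @param model A [join_model()].
#' @return Probability in `[0, 1]` (vectorized over `length`).
#' @examples
#' incorporation_prob(500, join_model(L0 = 500, s = 100))  # 0.5
#' @export
incorporation_prob <- function(length, model) {
  stopifnot(inherits(model, "join_model"), all(length >= 1))
  if (model$s == 0) return(as.numeric(length >= model$L0))
  1 / (1 + exp(-(length - model$L0) / model$s))
}

# longest exact overlap (>= h_min, <= cap) between the end of `left` and the
# start of `right`; 0 if none
.terminal_homology <- function(left, right, h_min, cap = 200L) {
  # at least one novel base must remain after an overlap merge
  hmax <- min(cap, nchar(left), nchar(right) - 1L)
  if (hmax < h_min) return(0L)
  tail_s <- substring(left, nchar(left) - hmax + 1L, nchar(left))
  for (h in hmax:h_min) {
    if (substring(tail_s, hmax - h + 1L, hmax) == substring(right, 1L, h))
      return(h)
  }
  0L
}

#' Simulate artificial chromosome formation by random end-joining
#'
#' Repeats until the concatemer reaches the model's target length: draw a
#' molecule from the pool by [molar_weights()] (with replacement — re-use of
#' the same fragment is allowed), accept it with [incorporation_prob()],
#' pick its orientation uniformly at random, and append it to the growing
#' array. If `p_hr > 0` and the incoming terminus shares at least `h_min`
#' exact bases with the current AC end, the join is resolved with
#' probability `p_hr` by overlap merge (the homologous bases counted once)
#' and labeled `HR`; otherwise the join is a blunt `NHEJ` ligation.
#'
#' @param pool A [pool_spec()].
#' @param model A [join_model()].
#' @param ac_id Name of the produced AC record.
#' @param orientation `"random"` (default, uniform +/-) or `"forward"`
#'   (every segment kept in + orientation; useful for worked examples).
#' @return List of class `"ac_simulation"` with elements `ac` (named
#'   character vector of length 1) and `truth`, a data frame tiling the AC:
#'   `segment_id`, `source` (fragment/marker), `src_start`, `src_end`
#'   (coordinates used of the source molecule), `orientation`, `ac_start`,
#'   `ac_end`, `join_type` (`origin` for the first segment, then
#'   `NHEJ`/`HR`). The seed is recorded as an attribute of the truth table.
#' @export
simulate_ac <- function(pool, model, ac_id = "AC",
                        orientation = c("random", "forward")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(pool, "pool_spec"), inherits(model, "join_model"))
  w <- molar_weights(pool)
  m <- pool$molecules
  if (all(incorporation_prob(m$length, model) == 0))
    stop("no molecule in the pool can be incorporated under this model")
  set.seed(model$seed)
  pieces <- character(0)
  rows <- list()
  total <- 0
  k <- 0L
  while (total < model$target_length) {
    i <- sample.int(nrow(m), 1L, prob = w)
    seq_i <- m$sequence[i]
    src <- c(0L, m$length[i])
    # optional pre-fragmentation of breakable (marker) molecules
    if (m$breakable[i] &&
        stats::runif(1) < pool$break_prob[m$species[i]]) {
      cuts <- sort(sample.int(m$length[i] - 1L, 2L, replace = TRUE))
      if (cuts[1L] < cuts[2L]) {
        src <- cuts
        seq_i <- substring(seq_i, cuts[1L] + 1L, cuts[2L])
      }
    }
    len_i <- nchar(seq_i)
    if (stats::runif(1) >= incorporation_prob(len_i, model)) next
    orient <- if (orientation == "forward") "+"
              else if (stats::runif(1) < 0.5) "+" else "-"
    if (orient == "-") seq_i <- revcomp(seq_i)
    join <- if (k == 0L) "origin" else "NHEJ"
    if (k > 0L && model$p_hr > 0) {
      h <- .terminal_homology(pieces[k], seq_i, model$h_min)
      if (h > 0L && stats::runif(1) < model$p_hr) {
        seq_i <- substring(seq_i, h + 1L)  # homology counted once
        join <- "HR"
        if (nchar(seq_i) == 0L) next       # fully absorbed; skip
      }
    }
    k <- k + 1L
    pieces[k] <- seq_i
    rows[[k]] <- data.frame(segment_id = m$id[i], source = m$source[i],
                            src_start = src[1L], src_end = src[2L],
                            orientation = orient,
                            ac_start = total, ac_end = total + nchar(seq_i),
                            join_type = join, stringsAsFactors = FALSE)
    total <- total + nchar(seq_i)
  }
  truth <- do.call(rbind, rows)
  attr(truth, "seed") <- model$seed
  ac <- stats::setNames(paste(pieces, collapse = ""), ac_id)
  structure(list(ac = ac, truth = truth, model = model),
            class = "ac_simulation")
}

#' @export
print.ac_simulation <- function(x, ...) {
  cat(sprintf("AC simulation: %s, %d bp, %d segments (seed %d)\n",
              names(x$ac), nchar(x$ac), nrow(x$truth),
              attr(x$truth, "seed")))
  cat("  joins:", paste(sprintf("%s=%d", names(table(x$truth$join_type)),
                                table(x$truth$join_type)), collapse = " "),
      "\n")
  invisible(x)
}

#' Rebuild the AC sequence from a truth table
#'
#' Independent reconstruction used to verify that the truth table tiles the
#' AC exactly: re-extracts each segment from its source molecule, reverse
#' complements `-` segments, and concatenates.
#'
#' @param truth Truth table from [simulate_ac()].
#' @param pool The [pool_spec()] the simulation drew from.
#' @return The reconstructed AC sequence (unnamed string).
#' @export
reconstruct_ac <- function(truth, pool) {
  m <- pool$molecules
  idx <- match(truth$segment_id, m$id)
  if (any(is.na(idx))) stop("truth references unknown molecules")
  pieces <- substring(m$sequence[idx], truth$src_start + 1L, truth$src_end)
  flip <- truth$orientation == "-"
  pieces[flip] <- vapply(pieces[flip], revcomp, "", USE.NAMES = FALSE)
  # HR joins absorbed the homologous prefix into the previous segment
  hr <- which(truth$join_type == "HR")
  if (length(hr)) {
    seg_len <- truth$ac_end[hr] - truth$ac_start[hr]
    pieces[hr] <- substring(pieces[hr],
                            nchar(pieces[hr]) - seg_len + 1L)
  }
  paste(pieces, collapse = "")
}

#' Marker placement report
#'
#' Lists every marker segment of a truth table with its AC interval,
#' orientation, and completeness (segment length as a fraction of the full
#' cassette length).
#'
#' @param truth Truth table from [simulate_ac()].
#' @param pool The [pool_spec()] used (provides cassette lengths).
#' @param ac_id Name reported in the `seq_id` column.
#' @return Data frame `marker`, `seq_id`, `ac_start`, `ac_end`, `strand`,
#'   `completeness`; zero rows when no marker was incorporated.
#' @export
spike_markers <- function(truth, pool, ac_id = "AC") {
  m <- pool$molecules
  sel <- truth$source == "marker"
  if (!any(sel))
    return(data.frame(marker = character(0), seq_id = character(0),
                      ac_start = integer(0), ac_end = integer(0),
                      strand = character(0), completeness = numeric(0)))
  t2 <- truth[sel, , drop = FALSE]
  full <- m$length[match(t2$segment_id, m$id)]
  data.frame(marker = t2$segment_id, seq_id = ac_id,
             ac_start = t2$ac_start, ac_end = t2$ac_end,
             strand = t2$orientation,
             completeness = (t2$ac_end - t2$ac_start) / full,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a simulation truth table as TSV
#' @param truth Truth table.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(truth, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          stringsAsFactors = FALSE)
  if (skip == 1L)
    attr(df, "seed") <- as.integer(sub("# seed=", "", first, fixed = TRUE))
  df
}
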
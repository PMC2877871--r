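#' Specify a null model for site counts
#'
#' Three null models are supported:
#' \describe{
#'   \item{uniform}{equal, independent base frequencies (1/4 each); the
#'     model behind the back-of-envelope rate 2 x (1/4)^6, one chance site
#'     about every 2 kb for the default motif.}
#'   \item{markov0}{independent bases with user base frequencies.}
#'   \item{shuffle}{empirical null by shuffling an observed sequence while
#'     preserving its mono- or dinucleotide composition; used only by
#'     [montecarlo_expected_count()].}
#' }
#'
#' @param kind One of `"uniform"`, `"markov0"`, `"shuffle"`.
#' @param base_probabilities Named probabilities for A, C, G, T (markov0
#'   only); must sum to 1 within 1e-12.
#' @param shuffle_preserve `"mono"` or `"di"` (shuffle only).
#' @param replicates Number of shuffle replicates (shuffle only; >= 1).
#' @param seed RNG seed for the shuffle null.
#' @return An object of class `null_model`.
#' @export
null_model <- function(kind = c("uniform", "markov0", "shuffle"),
                       base_probabilities = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                       shuffle_preserve = c("mono", "di"),
                       replicates = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  shuffle_preserve <- match.arg(shuffle_preserve)
  if (kind == "markov0") {
    if (!all(c("A", "C", "G", "T") %in% names(base_probabilities))) {
      stop("base_probabilities must be named with A, C, G, T", call. = FALSE)
    }
    base_probabilities <- base_probabilities[c("A", "C", "G", "T")]
    if (any(base_probabilities < 0) ||
        abs(sum(base_probabilities) - 1) > 1e-12) {
      stop("base_probabilities must be non-negative and sum to 1 (within 1e-12)",
           call. = FALSE)
    }
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(
    list(kind = kind, base_probabilities = base_probabilities,
         shuffle_preserve = shuffle_preserve,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "null_model"
  )
}

#' Per-position probability of a motif occurrence under an analytic null
#'
#' Under the uniform null the probability that a given position starts a
#' site of any allowed spacer class is
#' `n_classes x (1/4)^(fixed bases)` — `2 x (1/4)^6 = 1/2048` for the
#' default motif, i.e. one chance site about every 2 kb. Under a markov0
#' null each spacer class contributes the product of the flank base
#' probabilities (spacer positions contribute a factor of 1).
#'
#' @param motif A `motif_spec`.
#' @param null A `null_model` of kind `"uniform"` or `"markov0"`.
#' @return The per-position probability (a single number).
#' @examples
#' per_position_probability(compile_motif(), null_model("uniform"))  # 1/2048
#' @export
per_position_probability <- function(motif, null = null_model("uniform")) {
  stopifnot(inherits(motif, "motif_spec"), inherits(null, "null_model"))
  if (null$kind == "shuffle") {
    stop("per_position_probability: the shuffle null has no analytic ",
         "per-position probability; use montecarlo_expected_count()",
         call. = FALSE)
  }
  n_classes <- length(motif$spacer_lengths)
  flanks <- strsplit(paste0(motif$left_flank, motif$right_flank), "",
                     fixed = TRUE)[[1]]
  if (null$kind == "uniform") {
    n_classes * 0.25^length(flanks)
  } else {
    n_classes * prod(null$base_probabilities[flanks])
  }
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Expected number of sites in a region
#'
#' `mode = "approx"` is the back-of-envelope rule `length x p`, with no
#' edge correction — the arithmetic that yields the expected 70 sites in
#' 144 kb and 34 sites in 70 kb for the default motif under the uniform
#' null. `mode = "exact_positions"` counts, per spacer class, only the
#' positions where a full site fits:
#' `sum_s max(0, L - sitelen(s) + 1) x p_single`.
#' The rounded value rounds half away from zero.
#'
#' @param region_length Region length in bp (>= 0).
#' @param p Per-position probability; computed from `motif` and `null` when
#'   `NULL`.
#' @param mode `"approx"` or `"exact_positions"`.
#' @param motif A `motif_spec` (default motif if missing).
#' @param null A `null_model` (uniform if missing).
#' @return A list with `expected` (real) and `expected_rounded` (integer).
#' @examples
#' expected_count(144000)  # expected 70.3125, rounded 70
#' expected_count(70000)   # expected ~34.18, rounded 34
#' @export
expected_count <- function(region_length, p = NULL,
                           mode = c("approx", "exact_positions"),
                           motif = compile_motif(),
                           null = null_model("uniform")) {
  mode <- match.arg(mode)
  if (region_length < 0) stop("region_length must be >= 0", call. = FALSE)
  if (is.null(p)) p <- per_position_probability(motif, null)
  if (mode == "approx") {
    expected <- region_length * p
  } else {
    p_single <- p / length(motif$spacer_lengths)
    n_pos <- pmax(0, region_length - site_length(motif, motif$spacer_lengths) + 1)
    expected <- sum(n_pos * p_single)
  }
  list(expected = expected, expected_rounded = round_half_away(expected))
}

#' Observed-vs-expected site enrichment for one region
#'
#' Computes the expected count under the analytic null, the excess
#' (observed minus rounded expected) and an upper Poisson tail probability
#' `P(X >= observed)` at the unrounded expectation. The Poisson tail treats
#' potential site positions as independent, which ignores overlap
#' dependence between nearby positions; in the rare-site regime this is a
#' good approximation, and [montecarlo_expected_count()] provides an
#' assumption-free alternative.
#'
#' @param observed Observed site count (integer >= 0).
#' @param region_length Region length in bp.
#' @param motif A `motif_spec`.
#' @param null A `null_model` of kind `"uniform"` or `"markov0"`.
#' @param mode Expected-count mode, see [expected_count()].
#' @return An object of class `enrichment_result`: a list with
#'   `region_length`, `observed`, `p_per_position`, `expected`,
#'   `expected_rounded`, `excess`, `poisson_tail`, `null_model`, `mode`.
#' @examples
#' excess_and_test(85, 144000)  # excess 15
#' excess_and_test(53, 70000)   # excess 19
#' @export
excess_and_test <- function(observed, region_length,
                            motif = compile_motif(),
                            null = null_model("uniform"),
                            mode = c("approx", "exact_positions")) {
  mode <- match.arg(mode)
  if (is.na(observed) || observed < 0 || observed != floor(observed)) {
    stop("observed must be a non-negative integer", call. = FALSE)
  }
  observed <- as.integer(observed)
  p <- per_position_probability(motif, null)
  ec <- expected_count(region_length, p = p, mode = mode, motif = motif)
  structure(
    list(region_length = as.integer(region_length),
         observed = observed,
         p_per_position = p,
         expected = ec$expected,
         expected_rounded = ec$expected_rounded,
         excess = observed - ec$expected_rounded,
         poisson_tail = stats::ppois(observed - 1L, lambda = ec$expected,
                                     lower.tail = FALSE),
         null_model = null,
         mode = mode),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (", x$null_model$kind, " null, ", x$mode, "):\n",
      "  region length : ", x$region_length, " bp\n",
      "  p/position    : ", format(x$p_per_position), "\n",
      "  observed      : ", x$observed, "\n",
      "  expected      : ", format(x$expected), " (rounded ",
      x$expected_rounded, ")\n",
      "  excess        : ", x$excess, "\n",
      "  Poisson tail  : P(X >= obs) = ", format(x$poisson_tail), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(region_length = x$region_length, observed = x$observed,
             p_per_position = x$p_per_position, expected = x$expected,
             expected_rounded = x$expected_rounded, excess = x$excess,
             poisson_tail = x$poisson_tail, null_kind = x$null_model$kind,
             mode = x$mode, stringsAsFactors = FALSE)
}

#' Empirical expected count by composition-preserving shuffling
#'
#' Shuffles the observed sequence (preserving exact mono- or dinucleotide
#' composition per replicate), rescans each shuffle and returns the
#' replicate count statistics. Deterministic for a fixed `null$seed`.
#'
#' @param record A `seq_record` or bare DNA string.
#' @param motif A `motif_spec`.
#' @param null A `null_model` of kind `"shuffle"`.
#' @return A list with `mean`, `sd` and `counts` (one count per replicate).
#' @export
montecarlo_expected_count <- function(record, motif,
                                      null = null_model("shuffle")) {
  if (is.character(record)) record <- seq_record("seq", record)
  stopifnot(inherits(null, "null_model"))
  if (null$kind != "shuffle") {
    stop("montecarlo_expected_count requires a shuffle null", call. = FALSE)
  }
  min_len <- min(site_length(motif, motif$spacer_lengths))
  if (nchar(record$sequence) < min_len) {
    warning("sequence shorter than the minimal site length (", min_len,
            " bp); expected count is 0")
    counts <- rep(0L, null$replicates)
    return(list(mean = 0, sd = 0, counts = counts))
  }
  set.seed(null$seed)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  counts <- vapply(seq_len(null$replicates), function(i) {
    shuf <- shuffle_chars(chars, preserve = null$shuffle_preserve)
    rec <- seq_record(record$seq_id, paste(shuf, collapse = ""))
    nrow(scan_sequence(rec, motif))
  }, integer(1))
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
}
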
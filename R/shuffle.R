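#' Shuffle a DNA sequence preserving composition
#'
#' `preserve = "mono"` permutes the characters uniformly (exact base counts
#' kept). `preserve = "di"` draws a uniform random sequence with exactly the
#' same dinucleotide count multiset (and hence the same first and last
#' character) using the Altschul-Erickson Eulerian-path construction:
#' the sequence is a walk on the graph whose edges are its dinucleotides;
#' a random arborescence toward the final character fixes each vertex's last
#' exit, the remaining exits are permuted, and the walk is replayed.
#'
#' @param sequence DNA string.
#' @param preserve `"mono"` or `"di"`.
#' @return The shuffled string.
#' @export
shuffle_sequence <- function(sequence, preserve = c("mono", "di")) {
  preserve <- match.arg(preserve)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  paste(shuffle_chars(chars, preserve), collapse = "")
}

shuffle_chars <- function(chars, preserve = "mono") {
  if (preserve == "mono") return(sample(chars))
  dinucleotide_shuffle_chars(chars)
}

# Altschul & Erickson doublet-preserving shuffle on a character vector
dinucleotide_shuffle_chars <- function(chars) {
  n <- length(chars)
  if (n <= 3L) return(chars)
  from <- chars[-n]
  to <- chars[-1]
  last <- chars[n]
  adj <- split(to, from)            # out-edge target multisets
  sources <- names(adj)
  inner <- setdiff(sources, last)   # vertices needing a designated last exit

  if (length(inner) == 0L) {
    # every edge leaves `last`: any permutation of its exits works
    adj[[last]] <- sample(adj[[last]])
  } else {
    for (attempt in seq_len(10000L)) {
      last_edge <- vapply(inner, function(v) {
        tv <- adj[[v]]
        tv[sample.int(length(tv), 1L)]
      }, character(1))
      # the designated exits must form an arborescence into `last`
      ok <- all(vapply(inner, function(v) {
        for (step in seq_len(length(sources) + 1L)) {
          v <- if (v == last) return(TRUE) else last_edge[[v]]
          if (is.null(v)) return(FALSE)
          if (v == last) return(TRUE)
        }
        FALSE
      }, logical(1)))
      if (ok) break
      if (attempt == 10000L) stop("dinucleotide shuffle: no arborescence found")
    }
    for (v in sources) {
      tv <- adj[[v]]
      if (v %in% inner) {
        # remove one copy of the designated last edge, permute, re-append
        idx <- match(last_edge[[v]], tv)
        rest <- tv[-idx]
        adj[[v]] <- c(if (length(rest)) sample(rest) else character(0),
                      last_edge[[v]])
      } else {
        adj[[v]] <- sample(tv)
      }
    }
  }

  # replay the Eulerian walk
  out <- character(n)
  out[1] <- chars[1]
  ptr <- stats::setNames(rep(1L, length(sources)), sources)
  v <- chars[1]
  for (i in 2:n) {
    nxt <- adj[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  out
}
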
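# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check: the scan oracle tests every (position,
# spacer) pair by direct substring comparison, the cluster oracle merges by
# repeated transitive closure, and the Poisson-tail oracle sums the mass
# function term by term.

random_dna <- function(n, alphabet = c("A", "C", "G", "T"), probs = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

oracle_scan <- function(seq, motif, allow_n_spacer = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  lf <- strsplit(motif$left_flank, "", fixed = TRUE)[[1]]
  rf <- strsplit(motif$right_flank, "", fixed = TRUE)[[1]]
  spacer_ok <- if (allow_n_spacer) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  rows <- list()
  for (s in motif$spacer_lengths) {
    len <- length(lf) + s + length(rf)
    if (L < len) next
    for (i in 0:(L - len)) {
      win <- chars[(i + 1):(i + len)]
      if (all(win[seq_along(lf)] == lf) &&
          all(win[length(lf) + s + seq_along(rf)] == rf) &&
          (s == 0 || all(win[length(lf) + seq_len(s)] %in% spacer_ok))) {
        rows[[length(rows) + 1L]] <- data.frame(start = i, end = i + len,
                                                spacer_length = s)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      spacer_length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$spacer_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^2) transitive-closure merge: returns an integer partition label per
# input site (labels renumbered in order of first appearance by start)
oracle_closure_clusters <- function(start, end, max_gap) {
  n <- length(start)
  if (n == 0L) return(integer(0))
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (labels[i] != labels[j]) {
          gap <- max(start[i], start[j]) - min(end[i], end[j])
          if (gap <= max_gap) {
            new_lab <- min(labels[i], labels[j])
            labels[labels == labels[i] | labels == labels[j]] <- new_lab
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  o <- order(start, end)
  first_seen <- unique(labels[o])
  match(labels, first_seen)
}

oracle_poisson_tail <- function(observed, lambda, tol = 1e-16) {
  if (observed <= 0) return(1)
  # P(X >= obs) = 1 - sum_{k < obs} term_k, terms by recurrence
  term <- exp(-lambda)
  cum <- term
  k <- 0
  while (k < observed - 1) {
    k <- k + 1
    term <- term * lambda / k
    cum <- cum + term
  }
  max(0, 1 - cum)
}

# gapless coordinate of aligned column j (0-based) by direct recount
oracle_gapless_coord <- function(aligned_seq, column) {
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  sum(chars[seq_len(column)] != "-")
}

# Monte-Carlo survival oracle for a decoy site: probability that, after
# i.i.d. substitution of a root window at rate r (uniform over the three
# alternatives), the window still contains a hit overlapping the decoy's
# root-frame span. `win` is the root window string, decoy span given in
# window coordinates (0-based half-open).
oracle_decoy_survival <- function(win, decoy_start, decoy_end, motif, rate,
                                  n_sim = 2000L) {
  chars <- strsplit(win, "", fixed = TRUE)[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  alt <- lapply(stats::setNames(bases, bases), function(b) setdiff(bases, b))
  hits_overlap <- function(cs) {
    for (s in motif$spacer_lengths) {
      len <- nchar(motif$left_flank) + s + nchar(motif$right_flank)
      if (L < len) next
      for (i in 0:(L - len)) {
        if (i >= decoy_end || i + len <= decoy_start) next
        txt <- paste(cs[(i + 1):(i + len)], collapse = "")
        pat <- paste0("^", motif$left_flank, "[ACGT]{", s, "}",
                      motif$right_flank, "$")
        if (grepl(pat, txt)) return(TRUE)
      }
    }
    FALSE
  }
  hits <- 0L
  for (k in seq_len(n_sim)) {
    cs <- chars
    mut <- which(runif(L) < rate)
    for (m in mut) cs[m] <- sample(alt[[cs[m]]], 1L)
    if (hits_overlap(cs)) hits <- hits + 1L
  }
  hits / n_sim
}
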
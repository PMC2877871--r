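#' Compile a degenerate STAT-site motif model
#'
#' A STAT binding site is modelled as two fixed half-sites (flanks) separated
#' by a spacer of arbitrary bases. The default is the palindromic STAT92E
#' consensus `TTC...GAA` with spacers of 3 or 4 bases (the "3n" and "4n" site
#' classes). The spacer positions are fully degenerate: any of A, C, G, T is
#' accepted there.
#'
#' @param left_flank DNA string over A/C/G/T (default `"TTC"`). Ambiguity
#'   codes are rejected; the model is an exact degenerate consensus, not a
#'   weight matrix.
#' @param right_flank DNA string over A/C/G/T (default `"GAA"`).
#' @param spacer_lengths Integer vector of allowed spacer lengths, all >= 0
#'   (default `c(3, 4)`). Duplicates are removed; the set is stored sorted.
#' @param name Label used in output track names (default `"STAT92E"`).
#' @return An object of class `motif_spec`.
#' @examples
#' compile_motif()                       # TTCnnnGAA / TTCnnnnGAA
#' compile_motif("TTC", "GAA", 0)        # exactly TTCGAA
#' @export
compile_motif <- function(left_flank = "TTC", right_flank = "GAA",
                          spacer_lengths = c(3L, 4L), name = "STAT92E") {
  left_flank <- toupper(as.character(left_flank))
  right_flank <- toupper(as.character(right_flank))
  check_flank(left_flank, "left_flank")
  check_flank(right_flank, "right_flank")
  if (length(spacer_lengths) == 0L) {
    stop("spacer_lengths: must contain at least one spacer length", call. = FALSE)
  }
  if (any(is.na(spacer_lengths)) || any(spacer_lengths != floor(spacer_lengths))) {
    stop("spacer_lengths: must be non-negative integers", call. = FALSE)
  }
  if (any(spacer_lengths < 0)) {
    stop("spacer_lengths: negative spacer length not allowed", call. = FALSE)
  }
  spacer_lengths <- sort(unique(as.integer(spacer_lengths)))
  structure(
    list(left_flank = left_flank, right_flank = right_flank,
         spacer_lengths = spacer_lengths, name = name),
    class = "motif_spec"
  )
}

check_flank <- function(x, field) {
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(field, ": flank must be a non-empty DNA string", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    stop(field, ": flank may only contain A, C, G, T (got '", x, "')",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("motif_spec '", x$name, "': ", x$left_flank, "(",
      paste0("N{", x$spacer_lengths, "}", collapse = "|"),
      ")", x$right_flank,
      if (is_revcomp_closed(x)) "  [reverse-complement closed]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of fixed (non-spacer) bases in a motif
#' @param motif A `motif_spec`.
#' @return Integer count of flank bases (6 for the default motif).
#' @export
fixed_base_count <- function(motif) {
  nchar(motif$left_flank) + nchar(motif$right_flank)
}

#' Site length for a given spacer class
#' @param motif A `motif_spec`.
#' @param spacer_length Spacer length(s).
#' @return Integer site length(s) in bp.
#' @export
site_length <- function(motif, spacer_length) {
  fixed_base_count(motif) + as.integer(spacer_length)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement over the A/C/G/T/N alphabet; N maps to N.
#'
#' @param sequence Character vector of DNA strings (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' reverse_complement("TTCAAAGAA")  # "TTCTTTGAA"
#' @export
reverse_complement <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("reverse_complement: illegal character in sequence (allowed: A,C,G,T,N)",
         call. = FALSE)
  }
  vapply(sequence, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a motif closed under reverse complementation?
#'
#' The default STAT consensus is palindromic as a pattern class: the reverse
#' complement of any `TTC<spacer>GAA` instance is again a `TTC<spacer>GAA`
#' instance. This holds exactly when `reverse_complement(right_flank)` equals
#' `left_flank`, and it is why a single forward-strand scan counts every site
#' once.
#'
#' @param motif A `motif_spec`.
#' @return `TRUE` or `FALSE`.
#' @export
is_revcomp_closed <- function(motif) {
  identical(reverse_complement(motif$right_flank), motif$left_flank)
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             spacer_length = integer(0), matched_text = character(0),
             strand = character(0), species = character(0),
             stringsAsFactors = FALSE)
}

#' Find all motif occurrences in one sequence
#'
#' Reports every position at which the sequence carries the left flank, an
#' allowed number of spacer bases, then the right flank. Coordinates are
#' 0-based half-open relative to the record. For a reverse-complement-closed
#' motif (the default) only the forward strand is scanned and strand is
#' recorded as `"."`; for a non-closed motif both strands are scanned and
#' strand is `"+"` or `"-"` (minus-strand hits are reported in forward
#' coordinates). Overlapping hits of different spacer classes are all
#' reported; exact duplicate intervals are reported once.
#'
#' By default an N never matches, neither in the flanks nor in the spacer,
#' so a hit never overlaps an N. Set `allow_n_spacer = TRUE` to let N count
#' as a spacer base (flank positions still require the exact base).
#'
#' @param record A `seq_record` (see [seq_record()]) or a bare DNA string,
#'   which is wrapped as a record with `seq_id = "seq"`.
#' @param motif A `motif_spec`.
#' @param allow_n_spacer Should N match at spacer positions? Default `FALSE`.
#' @return A data frame of hits with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `spacer_length`, `matched_text`, `strand`,
#'   `species`, sorted by `(start, spacer_length)`.
#' @examples
#' scan_sequence("TTCAAAGAA", compile_motif())
#' @export
scan_sequence <- function(record, motif, allow_n_spacer = FALSE) {
  if (is.character(record)) record <- seq_record("seq", record)
  stopifnot(inherits(record, "seq_record"), inherits(motif, "motif_spec"))
  seq <- record$sequence
  L <- nchar(seq)
  closed <- is_revcomp_closed(motif)

  fwd <- scan_one_strand(seq, motif, allow_n_spacer)
  if (closed) {
    hits <- fwd
    hits$strand <- rep(".", nrow(hits))
  } else {
    fwd$strand <- rep("+", nrow(fwd))
    rc <- scan_one_strand(reverse_complement(seq), motif, allow_n_spacer)
    if (nrow(rc)) {
      rev_hits <- data.frame(
        start = L - rc$end, end = L - rc$start,
        spacer_length = rc$spacer_length, strand = "-",
        stringsAsFactors = FALSE)
    } else {
      rev_hits <- fwd[0, c("start", "end", "spacer_length", "strand")]
    }
    hits <- rbind(fwd[c("start", "end", "spacer_length", "strand")], rev_hits)
  }
  if (nrow(hits) == 0L) return(empty_hits())
  # "+" (or ".") wins over "-" for identical intervals
  hits <- hits[order(hits$start, hits$spacer_length, hits$strand), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("start", "end")]), , drop = FALSE]
  data.frame(
    seq_id = record$seq_id,
    start = as.integer(hits$start),
    end = as.integer(hits$end),
    spacer_length = as.integer(hits$spacer_length),
    matched_text = substring(seq, hits$start + 1L, hits$end),
    strand = hits$strand,
    species = if (is.null(record$species)) NA_character_ else record$species,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# forward-strand scan of a bare string; returns start/end/spacer_length
scan_one_strand <- function(seq, motif, allow_n_spacer) {
  spacer_class <- if (allow_n_spacer) "[ACGTN]" else "[ACGT]"
  out <- lapply(motif$spacer_lengths, function(s) {
    pat <- paste0("(?=", motif$left_flank, spacer_class, "{", s, "}",
                  motif$right_flank, ")")
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start <- as.integer(m) - 1L
    data.frame(start = start, end = start + site_length(motif, s),
               spacer_length = s, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      spacer_length = integer(0)))
  }
  do.call(rbind, out)
}

#' Scan several sequence records
#'
#' @param records A list of `seq_record` objects (e.g. from [read_fasta()]).
#' @inheritParams scan_sequence
#' @return One data frame of hits (the row-bound per-record scans).
#' @export
scan_records <- function(records, motif, allow_n_spacer = FALSE) {
  if (inherits(records, "seq_record")) records <- list(records)
  out <- lapply(records, scan_sequence, motif = motif,
                allow_n_spacer = allow_n_spacer)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
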
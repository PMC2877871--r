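#' Construct a sequence record
#'
#' A minimal container for one DNA sequence: an identifier, the sequence
#' (uppercased, restricted to A/C/G/T/N), an optional species label and an
#' `origin_offset` giving the coordinate of base 0 in a parent reference,
#' so sub-region scans can be lifted back to reference coordinates.
#'
#' @param seq_id Non-empty identifier string.
#' @param sequence DNA string over A/C/G/T/N (any case; uppercased).
#' @param species Optional species label.
#' @param origin_offset Non-negative integer offset (default 0).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(seq_id, sequence, species = NA_character_,
                       origin_offset = 0L) {
  if (!is.character(seq_id) || length(seq_id) != 1L || is.na(seq_id) ||
      nchar(seq_id) == 0L) {
    stop("seq_id: must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence: must be a single string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence: illegal character (allowed: A,C,G,T,N) in record '",
         seq_id, "'", call. = FALSE)
  }
  if (origin_offset < 0) stop("origin_offset: must be >= 0", call. = FALSE)
  structure(
    list(seq_id = seq_id, sequence = sequence,
         species = if (is.na(species)) NA_character_ else as.character(species),
         origin_offset = as.integer(origin_offset)),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat("seq_record '", x$seq_id, "' (", nchar(x$sequence), " bp",
      if (!is.na(x$species)) paste0(", species=", x$species) else "",
      if (x$origin_offset > 0) paste0(", offset=", x$origin_offset) else "",
      ")\n", sep = "")
  invisible(x)
}

# parse "id key=value key=value" FASTA description lines
parse_fasta_header <- function(header) {
  tokens <- strsplit(trimws(header), "\\s+")[[1]]
  id <- tokens[1]
  species <- NA_character_
  offset <- 0L
  for (tok in tokens[-1]) {
    if (grepl("^species=", tok)) species <- sub("^species=", "", tok)
    if (grepl("^offset=", tok)) offset <- as.integer(sub("^offset=", "", tok))
  }
  list(seq_id = id, species = species, origin_offset = offset)
}

#' Read a FASTA file into sequence records
#'
#' Multi-record FASTA; description lines may carry `species=<label>` and
#' `offset=<int>` key-value pairs after the identifier. Lowercase
#' (soft-masked) input is uppercased. CRLF line endings and trailing
#' whitespace are tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `seq_record` objects (names = seq_ids).
#' @export
read_fasta <- function(path) {
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("read_fasta: cannot parse '", path,
                                      "': ", conditionMessage(e),
                                      call. = FALSE)),
    warning = function(w) stop("read_fasta: illegal sequence content in '",
                               path, "': ", conditionMessage(w),
                               call. = FALSE))
  if (length(set) == 0L) stop("read_fasta: no records in '", path, "'",
                              call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  meta <- lapply(headers, parse_fasta_header)
  ids <- vapply(meta, `[[`, character(1), "seq_id")
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate seq_id '", ids[duplicated(ids)][1], "' in '",
         path, "'", call. = FALSE)
  }
  recs <- Map(function(m, s) seq_record(m$seq_id, s, m$species, m$origin_offset),
              meta, seqs)
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records A list of `seq_record` objects or one record.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, `[[`, character(1), "sequence")
  headers <- vapply(records, function(r) {
    h <- r$seq_id
    if (!is.na(r$species)) h <- paste0(h, " species=", r$species)
    if (r$origin_offset > 0) h <- paste0(h, " offset=", r$origin_offset)
    h
  }, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
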
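#' Construct an aligned ortholog set
#'
#' Holds one multiple alignment of orthologous regions from several species,
#' one of which is the focal species whose sites are being classified.
#' Gaps are `-`. All members must have the same aligned length; per-member
#' maps between gapless and alignment-column coordinates are derived on
#' construction.
#'
#' @param aligned Named character vector of aligned sequences
#'   (names = species labels; characters A/C/G/T/N/-).
#' @param focal_species Label of the focal species; must occur exactly once.
#' @return An object of class `ortholog_set` with elements `species`,
#'   `aligned`, `focal_species`, `column_count`, and `records` (gapless
#'   `seq_record`s, one per species).
#' @export
ortholog_set <- function(aligned, focal_species) {
  if (is.null(names(aligned)) || any(names(aligned) == "")) {
    stop("ortholog_set: aligned sequences must be named by species",
         call. = FALSE)
  }
  aligned <- toupper(aligned)
  bad <- grepl("[^ACGTN-]", aligned)
  if (any(bad)) {
    stop("ortholog_set: illegal character in member '",
         names(aligned)[bad][1], "' (allowed: A,C,G,T,N,-)", call. = FALSE)
  }
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("ortholog_set: ragged alignment (member lengths ",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  n_focal <- sum(names(aligned) == focal_species)
  if (n_focal == 0L) {
    stop("ortholog_set: focal species '", focal_species,
         "' not found among members (", paste(names(aligned), collapse = ", "),
         ")", call. = FALSE)
  }
  if (n_focal > 1L) {
    stop("ortholog_set: focal species '", focal_species,
         "' occurs more than once", call. = FALSE)
  }
  records <- Map(function(sp, s) {
    seq_record(sp, gsub("-", "", s, fixed = TRUE), species = sp)
  }, names(aligned), aligned)
  structure(
    list(species = names(aligned), aligned = aligned,
         focal_species = focal_species,
         column_count = unname(widths[1]), records = records),
    class = "ortholog_set"
  )
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("ortholog_set: ", length(x$species), " species, ", x$column_count,
      " alignment columns, focal = '", x$focal_species, "'\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as an ortholog set
#'
#' @param path Path to an aligned FASTA file (`-` gaps). The species label of
#'   each member is the `species=` key in its description line if present,
#'   otherwise its identifier.
#' @param focal_species Label of the focal species.
#' @return An `ortholog_set`.
#' @export
read_alignment <- function(path, focal_species) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("read_alignment: cannot parse '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("read_alignment: no records in '", path, "'",
                              call. = FALSE)
  meta <- lapply(names(set), parse_fasta_header)
  labels <- vapply(meta, function(m) {
    if (!is.na(m$species)) m$species else m$seq_id
  }, character(1))
  aligned <- toupper(as.character(set))
  names(aligned) <- labels
  ortholog_set(aligned, focal_species)
}

# 0-based alignment column of each gapless base (integer vector, one entry
# per gapless position)
gapless_to_column <- function(aligned_seq) {
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  which(chars != "-") - 1L
}

# number of non-gap characters strictly before each 0-based column
column_to_gapless <- function(aligned_seq) {
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  c(0L, cumsum(chars != "-"))[seq_along(chars)]
}

#' Scan every species and map hits to alignment columns
#'
#' Each member's gapless sequence is scanned with [scan_sequence()]; every
#' hit is annotated with the half-open alignment-column span of its first
#' and last base.
#'
#' @param ortho An `ortholog_set`.
#' @param motif A `motif_spec`.
#' @param allow_n_spacer Passed to [scan_sequence()].
#' @return A named list (per species) of hit data frames with extra columns
#'   `col_start`, `col_end` (0-based half-open alignment columns).
#' @export
map_hits_to_alignment <- function(ortho, motif, allow_n_spacer = FALSE) {
  stopifnot(inherits(ortho, "ortholog_set"))
  out <- lapply(ortho$species, function(sp) {
    hits <- scan_sequence(ortho$records[[sp]], motif,
                          allow_n_spacer = allow_n_spacer)
    cols <- gapless_to_column(ortho$aligned[[sp]])
    if (nrow(hits)) {
      hits$col_start <- cols[hits$start + 1L]
      hits$col_end <- cols[hits$end] + 1L
    } else {
      hits$col_start <- integer(0)
      hits$col_end <- integer(0)
    }
    hits
  })
  names(out) <- ortho$species
  out
}

#' Classify conservation of each focal-species site
#'
#' For every motif hit in the focal species, each other species is marked
#' *present* if it carries a hit of any allowed spacer class whose
#' alignment-column span, widened by `tolerance_columns` on each side,
#' overlaps the focal span by at least `overlap_min_columns` columns. A site
#' is *conserved* when it is present in at least `min_species_required`
#' species (the focal species always counts). The default requires presence
#' in all members, the criterion used to asterisk sites conserved in all ten
#' drosophilids.
#'
#' @param ortho An `ortholog_set`.
#' @param motif A `motif_spec`.
#' @param min_species_required Minimum number of species (including focal) in
#'   which the site must be present; default: all members.
#' @param overlap_min_columns Minimum column overlap (default 1: a single
#'   shared column suffices).
#' @param tolerance_columns Widening applied to the other species' span
#'   before the overlap test (default 0).
#' @param allow_n_spacer Passed to [scan_sequence()].
#' @return A data frame of class `conservation_calls`: the focal hits plus
#'   `col_start`, `col_end`, one logical `present_<species>` column per
#'   member, `n_species_present` and `conserved`, sorted by focal `start`.
#'   The parameters are attached as attributes `min_species_required`,
#'   `overlap_min_columns` and `tolerance_columns`.
#' @export
classify_conservation <- function(ortho, motif,
                                  min_species_required = NULL,
                                  overlap_min_columns = 1L,
                                  tolerance_columns = 0L,
                                  allow_n_spacer = FALSE) {
  stopifnot(inherits(ortho, "ortholog_set"))
  n_members <- length(ortho$species)
  if (is.null(min_species_required)) min_species_required <- n_members
  if (min_species_required > n_members) {
    stop("min_species_required (", min_species_required,
         ") exceeds the number of members (", n_members, ")", call. = FALSE)
  }
  if (overlap_min_columns < 0 || tolerance_columns < 0 ||
      min_species_required < 0) {
    stop("conservation parameters must be >= 0", call. = FALSE)
  }
  per_species <- map_hits_to_alignment(ortho, motif,
                                       allow_n_spacer = allow_n_spacer)
  focal <- per_species[[ortho$focal_species]]
  others <- setdiff(ortho$species, ortho$focal_species)

  presence <- matrix(FALSE, nrow = nrow(focal), ncol = n_members,
                     dimnames = list(NULL, ortho$species))
  if (nrow(focal)) presence[, ortho$focal_species] <- TRUE
  for (sp in others) {
    sp_hits <- per_species[[sp]]
    if (nrow(sp_hits) == 0L || nrow(focal) == 0L) next
    for (i in seq_len(nrow(focal))) {
      ov <- pmin(focal$col_end[i], sp_hits$col_end + tolerance_columns) -
        pmax(focal$col_start[i], sp_hits$col_start - tolerance_columns)
      presence[i, sp] <- any(ov >= overlap_min_columns)
    }
  }
  n_present <- as.integer(rowSums(presence))
  calls <- focal
  for (sp in ortho$species) calls[[paste0("present_", sp)]] <- presence[, sp]
  calls$n_species_present <- n_present
  calls$conserved <- n_present >= min_species_required
  calls <- calls[order(calls$start, calls$spacer_length), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "min_species_required") <- as.integer(min_species_required)
  attr(calls, "overlap_min_columns") <- as.integer(overlap_min_columns)
  attr(calls, "tolerance_columns") <- as.integer(tolerance_columns)
  class(calls) <- c("conservation_calls", "data.frame")
  calls
}

#' Write conservation calls as a TSV table
#'
#' One row per focal site: coordinates, alignment-column span, one 0/1
#' presence column per species and the conserved flag.
#'
#' @param calls A `conservation_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(calls, path) {
  out <- as.data.frame(calls)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
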
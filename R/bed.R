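hits_granges <- function(hits, motif_name = "STAT92E", mark_conserved = FALSE,
                         score = NULL) {
  nm <- if (!is.null(hits$name)) hits$name else
    paste0(motif_name, "_", hits$spacer_length, "n")
  if (mark_conserved && "conserved" %in% names(hits)) {
    nm <- ifelse(hits$conserved, paste0(nm, "_cons"), nm)
  }
  strand <- if (!is.null(hits$strand)) {
    ifelse(hits$strand %in% c("+", "-"), hits$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = strand)
  S4Vectors::mcols(gr)$name <- nm
  S4Vectors::mcols(gr)$score <- if (is.null(score)) rep(0L, nrow(hits)) else
    as.integer(score)
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr),
           S4Vectors::mcols(gr)$name)]
}

#' Write motif hits or regions as BED6
#'
#' Hit names are `<motif>_<spacer>n` (with suffix `_cons` for conserved
#' sites when `mark_conserved = TRUE` — the machine analogue of marking a
#' conserved site with an asterisk); the score column is 0 for hits.
#' Coordinates are written 0-based half-open (BED native); rows are sorted
#' by `(chrom, start, end, name)`.
#'
#' @param hits Data frame of hits/calls (`seq_id`, `start`, `end`,
#'   `spacer_length`, optional `strand`, `conserved`, `name`).
#' @param path Output path.
#' @param motif_name Motif label used in names.
#' @param mark_conserved Append `_cons` to conserved site names?
#' @param score Optional integer score vector (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path, motif_name = "STAT92E",
                      mark_conserved = FALSE, score = NULL) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- hits_granges(hits, motif_name, mark_conserved, score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write candidate enhancer regions as BED6
#'
#' Names are `candidate_<cluster_id>`; the score column carries the number
#' of conserved sites in the underlying cluster.
#'
#' @param candidates Output of [select_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  if (nrow(candidates) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- candidates
  df$name <- paste0("candidate_", df$cluster_id)
  df$strand <- "*"
  write_bed(df, path, score = df$n_conserved)
}

#' Read a BED file into a hit-style data frame
#'
#' @param path BED path.
#' @return Data frame with `seq_id`, `start` (0-based), `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name))
      S4Vectors::mcols(gr)$name else NA_character_,
    score = if (!is.null(S4Vectors::mcols(gr)$score))
      as.integer(S4Vectors::mcols(gr)$score) else NA_integer_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write motif hits as GFF3
#'
#' Same content as the BED output in 1-based inclusive GFF3 coordinates,
#' feature type `TF_binding_site`.
#'
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hits, path, motif_name = "STAT92E",
                       mark_conserved = FALSE) {
  if (nrow(hits) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- hits_granges(hits, motif_name, mark_conserved)
  S4Vectors::mcols(gr)$type <- "TF_binding_site"
  S4Vectors::mcols(gr)$source <- "statsites"
  S4Vectors::mcols(gr)$Name <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr)$name <- NULL
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
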
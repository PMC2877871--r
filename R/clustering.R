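#' Merge sites into clusters by single-linkage gap distance
#'
#' Two sites belong to the same cluster when the gap between them (start of
#' the later minus the largest end seen so far) is at most `max_gap`;
#' clusters are the transitive closure of this relation. Singleton clusters
#' are allowed. All calls must come from one sequence.
#'
#' @param calls A data frame of hits or conservation calls for a single
#'   `seq_id` (columns `seq_id`, `start`, `end`, optionally `conserved`).
#' @param max_gap Maximum gap in bp between member sites (default 500).
#' @return An object of class `site_clusters`: a list with `clusters` (data
#'   frame `cluster_id`, `seq_id`, `start`, `end`, `n_total`, `n_conserved`)
#'   and `members` (the input rows plus a `cluster_id` column).
#' @export
cluster_hits <- function(calls, max_gap = 500L) {
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L) {
    clusters <- data.frame(cluster_id = integer(0), seq_id = character(0),
                           start = integer(0), end = integer(0),
                           n_total = integer(0), n_conserved = integer(0),
                           stringsAsFactors = FALSE)
    calls$cluster_id <- integer(0)
    return(structure(list(clusters = clusters, members = calls),
                     class = "site_clusters"))
  }
  if (length(unique(calls$seq_id)) > 1L) {
    stop("cluster_hits: mixed seq_ids in one call list (",
         paste(unique(calls$seq_id), collapse = ", "),
         "); cluster each sequence separately", call. = FALSE)
  }
  o <- order(calls$start, calls$end)
  calls <- calls[o, , drop = FALSE]
  n <- nrow(calls)
  run_max_end <- cummax(calls$end)
  new_cluster <- c(TRUE, calls$start[-1] - run_max_end[-n] > max_gap)
  cid <- cumsum(new_cluster)
  calls$cluster_id <- cid
  conserved <- if ("conserved" %in% names(calls)) calls$conserved else
    rep(FALSE, n)
  clusters <- data.frame(
    cluster_id = sort(unique(cid)),
    seq_id = calls$seq_id[1],
    start = as.integer(tapply(calls$start, cid, min)),
    end = as.integer(tapply(calls$end, cid, max)),
    n_total = as.integer(tapply(rep(1L, n), cid, sum)),
    n_conserved = as.integer(tapply(as.integer(conserved), cid, sum)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rownames(calls) <- NULL
  structure(list(clusters = clusters, members = calls),
            class = "site_clusters")
}

#' @export
print.site_clusters <- function(x, ...) {
  cat("site_clusters: ", nrow(x$clusters), " cluster(s), ",
      nrow(x$members), " site(s)\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' Select candidate enhancer regions from site clusters
#'
#' Keeps clusters with at least `min_conserved` conserved and `min_total`
#' total sites, widens each kept cluster by `padding` on both sides, clips
#' to the sequence bounds, and ranks candidates by conserved count, then
#' total count, then leftmost position. The default (`min_conserved = 1`)
#' implements the selection rule "clusters where at least some sites are
#' conserved"; set `min_conserved = 0` to also retain clusters of
#' non-conserved sites (control regions).
#'
#' @param clusters A `site_clusters` object or its `clusters` data frame.
#' @param min_conserved Minimum conserved sites per cluster (default 1).
#' @param min_total Minimum total sites per cluster (default 1).
#' @param padding Widening in bp on each side (default 250).
#' @param sequence_length Length of the scanned sequence (for clipping).
#' @return A data frame of candidate regions: `seq_id`, `start`, `end`
#'   (padded, clipped), `cluster_id`, `cluster_start`, `cluster_end`,
#'   `n_total`, `n_conserved`, sorted by rank.
#' @export
select_candidates <- function(clusters, min_conserved = 1L, min_total = 1L,
                              padding = 250L, sequence_length) {
  if (inherits(clusters, "site_clusters")) clusters <- clusters$clusters
  if (min_conserved < 0 || min_total < 0 || padding < 0) {
    stop("selection parameters must be >= 0", call. = FALSE)
  }
  keep <- clusters$n_conserved >= min_conserved &
    clusters$n_total >= min_total
  sel <- clusters[keep, , drop = FALSE]
  out <- data.frame(
    seq_id = sel$seq_id,
    start = as.integer(pmax(0L, sel$start - as.integer(padding))),
    end = as.integer(pmin(as.integer(sequence_length),
                          sel$end + as.integer(padding))),
    cluster_id = sel$cluster_id,
    cluster_start = sel$start,
    cluster_end = sel$end,
    n_total = sel$n_total,
    n_conserved = sel$n_conserved,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_conserved, -out$n_total, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count sites (and conserved sites) fully inside a region
#'
#' @param calls A data frame of hits or conservation calls.
#' @param region_start,region_end Half-open region (0-based).
#' @return Named integer vector `c(n_total, n_conserved)`.
#' @export
summarize_region <- function(calls, region_start, region_end) {
  if (region_end < region_start) {
    stop("summarize_region: inverted interval [", region_start, ", ",
         region_end, ")", call. = FALSE)
  }
  calls <- as.data.frame(calls)
  inside <- calls$start >= region_start & calls$end <= region_end
  conserved <- if ("conserved" %in% names(calls)) calls$conserved else
    rep(FALSE, nrow(calls))
  c(n_total = sum(inside), n_conserved = sum(inside & conserved))
}
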
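default_pipeline_config <- function() {
  list(
    mode = "auto",                 # auto | enrichment_only
    input_fasta = NULL,            # FASTA path (single-species scan mode)
    input_alignment = NULL,        # aligned FASTA path (conservation mode)
    focal_species = NULL,          # focal species label in the alignment
    simulate = FALSE,              # generate the dataset from `simulation`
    motif = list(left_flank = "TTC", right_flank = "GAA",
                 spacer_lengths = c(3L, 4L), name = "STAT92E"),
    conservation = list(min_species_required = NULL,
                        overlap_min_columns = 1L, tolerance_columns = 0L),
    clustering = list(max_gap = 500L, padding = 250L,
                      min_conserved = 1L, min_total = 1L),
    null = list(kind = "uniform", base_probabilities = NULL,
                shuffle_preserve = "mono", replicates = 1000L),
    enrichment = list(region_length = NULL, observed = NULL,
                      mode = "approx"),
    simulation = list(length = 680L, substitution_rate = 0.1,
                      indel_rate = 0, indel_max_len = 5L, n_species = 10L),
    outdir = NULL,
    seed = 1L,
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Returns the full configuration with every omitted parameter at its
#' documented module default. Unknown keys are rejected.
#'
#' @param ... Named settings overriding the defaults (nested lists for the
#'   `motif`, `conservation`, `clustering`, `null`, `enrichment` and
#'   `simulation` sections).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_pipeline_config(), user)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must end in .yaml, .yml or .json", call. = FALSE)
  }
  do.call(pipeline_config, user)
}

log_msg <- function(level, cfg, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]]) {
    message("[", level, "] ", ...)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full site-to-candidate pipeline
#'
#' Stages: scan -> conserve -> cluster -> select -> enrich. Input is one of:
#' an aligned ortholog FASTA (`input_alignment` + `focal_species`), a plain
#' FASTA (`input_fasta`; no conservation calls, so candidate selection needs
#' `clustering$min_conserved = 0`), a simulated dataset
#' (`simulate = TRUE`), or bare numbers (`mode = "enrichment_only"` with
#' `enrichment$region_length` and `enrichment$observed`). When `outdir` is
#' set, BED/TSV/JSON artifacts and a JSON run report are written and an
#' internal consistency check recomputes the report totals from the emitted
#' files. Fully deterministic given the config (the seed covers every
#' stochastic component).
#'
#' @param config A `pipeline_config` (or a list coerced through
#'   [pipeline_config()]).
#' @return A `run_report`: tool version, resolved config, per-sequence hit
#'   and conserved counts, cluster and candidate tables, enrichment results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  set.seed(config$seed)
  motif <- stage("motif", do.call(compile_motif, config$motif))
  null <- stage("null", {
    args <- config$null
    args$replicates <- as.integer(args$replicates)
    if (is.null(args$base_probabilities)) args$base_probabilities <- NULL
    args$seed <- config$seed
    do.call(null_model, args[!vapply(args, is.null, logical(1))])
  })

  report <- list(
    tool = "statsites",
    version = as.character(utils::packageVersion("statsites")),
    seed = config$seed,
    config = unclass(config)
  )

  if (identical(config$mode, "enrichment_only")) {
    if (is.null(config$enrichment$region_length) ||
        is.null(config$enrichment$observed)) {
      stop("pipeline stage 'enrich' failed: enrichment_only mode needs ",
           "enrichment$region_length and enrichment$observed", call. = FALSE)
    }
    enr <- stage("enrich", excess_and_test(
      config$enrichment$observed, config$enrichment$region_length,
      motif = motif, null = null, mode = config$enrichment$mode))
    report$enrichment <- list(as.data.frame(enr))
    report$sequences <- data.frame()
    report$clusters <- data.frame()
    report$candidates <- data.frame()
    class(report) <- "run_report"
    if (!is.null(config$outdir)) write_run_artifacts(report, config)
    return(report)
  }

  # ---- acquire inputs ------------------------------------------------
  ortho <- NULL
  records <- NULL
  if (isTRUE(config$simulate)) {
    sim_args <- config$simulation
    sim_args$seed <- config$seed
    sim_args$motif <- motif
    simcfg <- stage("simulate", do.call(simulation_config, sim_args))
    ds <- stage("simulate", simulate_dataset(simcfg))
    ortho <- ds$ortho
    report$simulation_truth <- ds$truth
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(ds$root, file.path(config$outdir, "root.fasta"))
      aln_recs <- Map(function(sp, s) list(seq_id = sp, sequence = s),
                      ortho$species, ortho$aligned)
      writeLines(unlist(lapply(aln_recs, function(r) {
        c(paste0(">", r$seq_id), r$sequence)
      })), file.path(config$outdir, "orthologs.aln.fasta"))
      truth <- ds$truth
      truth$seq_id <- "root"
      truth$spacer_length <- truth$spacer_length
      write_bed(truth, file.path(config$outdir, "planted_sites.bed"),
                motif_name = motif$name)
    }
  } else if (!is.null(config$input_alignment)) {
    if (is.null(config$focal_species)) {
      stop("pipeline stage 'conserve' failed: input_alignment needs ",
           "focal_species", call. = FALSE)
    }
    ortho <- stage("conserve",
                   read_alignment(config$input_alignment,
                                  config$focal_species))
  } else if (!is.null(config$input_fasta)) {
    records <- stage("scan", read_fasta(config$input_fasta))
  } else {
    stop("pipeline needs input_fasta, input_alignment, simulate = TRUE, ",
         "or mode = 'enrichment_only'", call. = FALSE)
  }

  # ---- scan / conserve ----------------------------------------------
  if (!is.null(ortho)) {
    calls <- stage("conserve", classify_conservation(
      ortho, motif,
      min_species_required = config$conservation$min_species_required,
      overlap_min_columns = config$conservation$overlap_min_columns,
      tolerance_columns = config$conservation$tolerance_columns))
    log_msg("info", config, "conserve: ", nrow(calls), " focal hits, ",
            sum(calls$conserved), " conserved")
    seq_lengths <- stats::setNames(
      nchar(ortho$records[[ortho$focal_species]]$sequence),
      ortho$focal_species)
    call_list <- split(as.data.frame(calls), calls$seq_id)
  } else {
    hit_list <- lapply(records, scan_sequence, motif = motif)
    calls <- do.call(rbind, c(hit_list, list(make.row.names = FALSE)))
    if (is.null(calls)) calls <- empty_hits()
    calls$conserved <- rep(FALSE, nrow(calls))
    log_msg("info", config, "scan: ", nrow(calls), " hits in ",
            length(records), " sequence(s)")
    seq_lengths <- vapply(records, function(r) nchar(r$sequence), integer(1))
    names(seq_lengths) <- vapply(records, `[[`, character(1), "seq_id")
    call_list <- split(calls, factor(calls$seq_id, names(seq_lengths)))
  }

  # ---- cluster / select / enrich per sequence ------------------------
  clusters_all <- list()
  members_all <- list()
  candidates_all <- list()
  enrichment_all <- list()
  for (sid in names(seq_lengths)) {
    sc <- call_list[[sid]]
    if (is.null(sc)) sc <- calls[0, , drop = FALSE]
    cl <- stage("cluster", cluster_hits(sc, max_gap = config$clustering$max_gap))
    cand <- stage("select", select_candidates(
      cl, min_conserved = config$clustering$min_conserved,
      min_total = config$clustering$min_total,
      padding = config$clustering$padding,
      sequence_length = seq_lengths[[sid]]))
    region_length <- config$enrichment$region_length %||% seq_lengths[[sid]]
    observed <- config$enrichment$observed %||% nrow(sc)
    enr <- stage("enrich", excess_and_test(observed, region_length,
                                           motif = motif, null = null,
                                           mode = config$enrichment$mode))
    clusters_all[[sid]] <- cl$clusters
    members_all[[sid]] <- cl$members
    candidates_all[[sid]] <- cand
    df <- as.data.frame(enr)
    df$seq_id <- sid
    enrichment_all[[sid]] <- df
  }
  report$sequences <- data.frame(
    seq_id = names(seq_lengths),
    length = as.integer(unname(seq_lengths)),
    n_hits = vapply(names(seq_lengths), function(s) {
      x <- call_list[[s]]; if (is.null(x)) 0L else nrow(x)
    }, integer(1)),
    n_conserved = vapply(names(seq_lengths), function(s) {
      x <- call_list[[s]]; if (is.null(x)) 0L else sum(x$conserved)
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  report$calls <- as.data.frame(calls)
  report$clusters <- do.call(rbind, c(clusters_all,
                                      list(make.row.names = FALSE)))
  report$members <- do.call(rbind, c(members_all,
                                     list(make.row.names = FALSE)))
  report$candidates <- do.call(rbind, c(candidates_all,
                                        list(make.row.names = FALSE)))
  report$enrichment <- enrichment_all
  class(report) <- "run_report"
  if (!is.null(config$outdir)) write_run_artifacts(report, config)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("statsites run report (v", x$version, ", seed ", x$seed, ")\n", sep = "")
  if (nrow(x$sequences)) {
    for (i in seq_len(nrow(x$sequences))) {
      cat("  ", x$sequences$seq_id[i], ": ", x$sequences$n_hits[i],
          " sites, ", x$sequences$n_conserved[i], " conserved\n", sep = "")
    }
    cat("  clusters: ", nrow(x$clusters), ", candidates: ",
        nrow(x$candidates), "\n", sep = "")
  }
  for (enr in x$enrichment) {
    cat("  enrichment: observed ", enr$observed, " vs expected ",
        enr$expected_rounded, " in ", enr$region_length,
        " bp (excess ", enr$excess, ")\n", sep = "")
  }
  invisible(x)
}

# write BED/TSV/JSON artifacts + report.json; verify totals against the
# emitted files
write_run_artifacts <- function(report, config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  motif_name <- config$motif$name %||% "STAT92E"

  if (!is.null(report$calls)) {
    write_bed(report$calls, file.path(outdir, "hits.bed"),
              motif_name = motif_name, mark_conserved = TRUE)
    cons <- report$calls[report$calls$conserved %in% TRUE, , drop = FALSE]
    write_bed(cons, file.path(outdir, "conserved.bed"),
              motif_name = motif_name, mark_conserved = TRUE)
    if (inherits(report$calls, "data.frame") &&
        any(grepl("^present_", names(report$calls)))) {
      write_conservation_tsv(report$calls,
                             file.path(outdir, "conservation.tsv"))
    }
    utils::write.table(report$clusters, file.path(outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$members, file.path(outdir, "cluster_members.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_candidates_bed(report$candidates,
                         file.path(outdir, "candidates.bed"))
    # consistency: the emitted BED must round-trip to the report totals
    emitted <- read_bed(file.path(outdir, "hits.bed"))
    if (nrow(emitted) != sum(report$sequences$n_hits)) {
      stop("internal consistency check failed: hits.bed has ", nrow(emitted),
           " rows but the report counts ", sum(report$sequences$n_hits),
           call. = FALSE)
    }
    n_cons_emitted <- sum(grepl("_cons$", emitted$name))
    if (n_cons_emitted != sum(report$sequences$n_conserved)) {
      stop("internal consistency check failed: conserved totals disagree",
           call. = FALSE)
    }
  }
  enr_df <- do.call(rbind, c(unname(report$enrichment),
                             list(make.row.names = FALSE)))
  if (!is.null(enr_df) && nrow(enr_df)) {
    utils::write.table(enr_df, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(enr_df, file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  json_report <- report
  class(json_report) <- NULL
  # keep reports byte-identical across runs: drop machine-specific paths
  json_report$config$outdir <- NULL
  json_report$config$input_fasta <- NULL
  json_report$config$input_alignment <- NULL
  jsonlite::write_json(json_report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(outdir)
}
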
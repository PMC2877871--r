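#' The ten drosophilid species of the default comparison set
#'
#' Species labels used by default in simulated ortholog sets, mirroring a
#' classic ten-species comparison panel; the first is the focal species.
#'
#' @return Character vector of ten species labels.
#' @export
drosophilid_species <- function() {
  c("melanogaster", "simulans", "sechellia", "erecta", "yakuba",
    "ananassae", "grimshawi", "virilis", "mojavensis", "persimilis")
}

#' Configure a sequence-evolution simulation
#'
#' Describes one synthetic dataset: an i.i.d. background of given length and
#' composition, planted motif instances at chosen positions, and an ortholog
#' set derived from that root by independent per-species substitution (and
#' optional indels) with designated intervals protected from mutation.
#'
#' The defaults reproduce the geometry of a well-characterized 680 bp
#' STAT-dependent tracheal enhancer fragment: three planted sites, a 3n site
#' at position 86 and a 4n site at position 219 (both protected, i.e.
#' conserved by construction) and a 3n decoy at position 508 that evolves
#' neutrally. Substitution rate defaults to 0.1 per base per species, a
#' divergence on the scale seen between drosophilid noncoding regions.
#'
#' @param length Root sequence length in bp.
#' @param base_probabilities Named A/C/G/T probabilities (must sum to 1).
#' @param planted_sites Data frame with columns `position`,
#'   `spacer_length` and optionally `spacer_text`.
#' @param n_species Number of species in the ortholog set (>= 1), including
#'   the focal species.
#' @param substitution_rate Per-base substitution probability per species,
#'   in `[0, 1]`; substitutions are uniform over the three alternatives.
#' @param indel_rate Per-base indel initiation probability per species
#'   (default 0); split evenly between insertions and deletions.
#' @param indel_max_len Maximum indel length (lengths uniform on
#'   `1..indel_max_len`).
#' @param protected_intervals List of half-open `c(start, end)` intervals
#'   copied verbatim into every species.
#' @param seed RNG seed; every simulation from this config is deterministic.
#' @param motif The `motif_spec` planted and (for cleaning) destroyed in the
#'   background.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(length = 680L,
                              base_probabilities = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                              planted_sites = data.frame(
                                position = c(86L, 219L, 508L),
                                spacer_length = c(3L, 4L, 3L)),
                              n_species = 10L,
                              substitution_rate = 0.1,
                              indel_rate = 0,
                              indel_max_len = 5L,
                              protected_intervals = list(c(86L, 95L),
                                                         c(219L, 229L)),
                              seed = 1L,
                              motif = compile_motif()) {
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  base_probabilities <- base_probabilities[c("A", "C", "G", "T")]
  if (any(is.na(base_probabilities)) || any(base_probabilities < 0) ||
      abs(sum(base_probabilities) - 1) > 1e-12) {
    stop("base_probabilities must be named A,C,G,T, non-negative, sum to 1",
         call. = FALSE)
  }
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("substitution_rate and indel_rate must lie in [0, 1]", call. = FALSE)
  }
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (nrow(planted_sites)) {
    if (is.null(planted_sites$spacer_text)) {
      planted_sites$spacer_text <- NA_character_
    }
    spans <- cbind(planted_sites$position,
                   planted_sites$position +
                     site_length(motif, planted_sites$spacer_length))
    if (any(spans[, 1] < 0) || any(spans[, 2] > length)) {
      stop("planted site outside [0, length)", call. = FALSE)
    }
    o <- order(spans[, 1])
    if (nrow(spans) > 1 &&
        any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)])) {
      stop("planted sites overlap", call. = FALSE)
    }
  }
  for (iv in protected_intervals) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > length || iv[1] > iv[2]) {
      stop("protected interval out of bounds: [", iv[1], ", ", iv[2], ")",
           call. = FALSE)
    }
  }
  structure(
    list(length = as.integer(length),
         base_probabilities = base_probabilities,
         planted_sites = planted_sites,
         n_species = as.integer(n_species),
         substitution_rate = substitution_rate,
         indel_rate = indel_rate,
         indel_max_len = as.integer(indel_max_len),
         protected_intervals = protected_intervals,
         seed = as.integer(seed),
         motif = motif),
    class = "simulation_config"
  )
}

#' The bundled three-site demo configuration
#'
#' A 680 bp fragment with a protected 3n site at 86, a protected 4n site at
#' 219 and an unprotected 3n decoy at 508 — the package's standard worked
#' example for the conservation filter.
#'
#' @param seed RNG seed.
#' @param substitution_rate Per-base substitution rate (default 0.1).
#' @param ... Further arguments to [simulation_config()].
#' @return A `simulation_config`.
#' @export
vvl_like_config <- function(seed = 1L, substitution_rate = 0.1, ...) {
  simulation_config(seed = seed, substitution_rate = substitution_rate, ...)
}

#' Generate an i.i.d. background sequence
#'
#' Draws `length` independent bases from `base_probabilities`. With
#' `clean_background = TRUE`, accidental motif instances are destroyed by
#' resampling the middle base of each hit's left flank until no hits remain
#' (bounded number of passes), so that subsequently planted sites are the
#' only hits.
#'
#' @param length Sequence length in bp.
#' @param base_probabilities Named A/C/G/T probabilities.
#' @param seed RNG seed.
#' @param motif `motif_spec` used for cleaning.
#' @param clean_background Destroy accidental motif instances? Default
#'   `FALSE`.
#' @param seq_id Identifier of the returned record.
#' @param max_passes Cleaning pass bound before giving up.
#' @return A `seq_record`.
#' @export
generate_background <- function(length,
                                base_probabilities = c(A = 0.25, C = 0.25,
                                                       G = 0.25, T = 0.25),
                                seed = 1L,
                                motif = compile_motif(),
                                clean_background = FALSE,
                                seq_id = "background",
                                max_passes = 100L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  p <- base_probabilities[bases]
  if (length == 0L) return(seq_record(seq_id, ""))
  chars <- sample(bases, length, replace = TRUE, prob = p)
  rec <- seq_record(seq_id, paste(chars, collapse = ""))
  if (!clean_background) return(rec)
  mid <- 1L + (nchar(motif$left_flank) - 1L) %/% 2L  # middle left-flank base
  for (pass in seq_len(max_passes)) {
    hits <- scan_sequence(rec, motif)
    if (nrow(hits) == 0L) return(rec)
    pos <- hits$start + mid  # 1-based position of the middle flank base
    chars[pos] <- sample(bases, length(pos), replace = TRUE, prob = p)
    rec <- seq_record(seq_id, paste(chars, collapse = ""))
  }
  stop("generate_background: could not remove all motif instances in ",
       max_passes, " passes (alphabet too restricted?)", call. = FALSE)
}

#' Write motif instances into a sequence
#'
#' Overwrites the sequence at each planted position with left flank, spacer
#' (given text or random A/C/G/T bases from the current RNG stream) and
#' right flank. After planting, [scan_sequence()] finds a hit at every
#' planted position.
#'
#' @param record A `seq_record`.
#' @param planted_sites Data frame with `position`, `spacer_length`,
#'   optional `spacer_text`.
#' @param motif A `motif_spec`.
#' @return The modified `seq_record`.
#' @export
plant_motifs <- function(record, planted_sites, motif = compile_motif()) {
  stopifnot(inherits(record, "seq_record"))
  if (nrow(planted_sites) == 0L) return(record)
  L <- nchar(record$sequence)
  ends <- planted_sites$position + site_length(motif, planted_sites$spacer_length)
  if (any(planted_sites$position < 0) || any(ends > L)) {
    stop("plant_motifs: planted site outside [0, ", L, ")", call. = FALSE)
  }
  o <- order(planted_sites$position)
  if (nrow(planted_sites) > 1 &&
      any(planted_sites$position[o][-1] < ends[o][-length(ends)])) {
    stop("plant_motifs: planted sites overlap", call. = FALSE)
  }
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(planted_sites))) {
    s <- planted_sites$spacer_length[i]
    spacer <- planted_sites$spacer_text[i]
    if (is.null(spacer) || is.na(spacer)) {
      spacer <- paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                      collapse = "")
    }
    if (nchar(spacer) != s || grepl("[^ACGT]", spacer)) {
      stop("plant_motifs: spacer_text '", spacer,
           "' does not match spacer_length ", s, call. = FALSE)
    }
    text <- paste0(motif$left_flank, spacer, motif$right_flank)
    idx <- planted_sites$position[i] + seq_len(nchar(text))
    chars[idx] <- strsplit(text, "", fixed = TRUE)[[1]]
  }
  seq_record(record$seq_id, paste(chars, collapse = ""),
             species = record$species, origin_offset = record$origin_offset)
}

# logical mask of protected positions
protected_mask <- function(length, intervals) {
  mask <- logical(length)
  for (iv in intervals) {
    if (iv[2] > iv[1]) mask[(iv[1] + 1L):iv[2]] <- TRUE
  }
  mask
}

#' Evolve an aligned ortholog set from a root sequence
#'
#' Each non-focal species is derived independently from the root (star
#' phylogeny): every unprotected position mutates with probability
#' `substitution_rate`, uniformly to one of the three alternative bases;
#' with `indel_rate > 0`, insertions and deletions (lengths uniform on
#' `1..indel_max_len`) are applied outside protected intervals. Protected
#' intervals are copied verbatim. The members are returned pre-aligned in
#' the root coordinate frame: deletions become gaps in the derived species
#' and insertions open gap columns in all other species. Deterministic for
#' a fixed `config$seed`.
#'
#' @param root A `seq_record` (typically a planted background); the focal
#'   species.
#' @param config A `simulation_config`.
#' @param species Species labels; default [drosophilid_species()] truncated
#'   or extended to `config$n_species`, the first label being the focal
#'   species.
#' @return An `ortholog_set`.
#' @export
evolve_orthologs <- function(root, config, species = NULL) {
  stopifnot(inherits(root, "seq_record"), inherits(config, "simulation_config"))
  L <- nchar(root$sequence)
  for (iv in config$protected_intervals) {
    if (iv[2] > L) stop("protected interval beyond root length", call. = FALSE)
  }
  if (is.null(species)) {
    base <- drosophilid_species()
    species <- if (config$n_species <= length(base)) {
      base[seq_len(config$n_species)]
    } else {
      c(base, paste0("species_", seq_len(config$n_species - length(base)) +
                       length(base)))
    }
  }
  stopifnot(length(species) == config$n_species)
  focal <- species[1]
  set.seed(config$seed)
  rootc <- strsplit(root$sequence, "", fixed = TRUE)[[1]]
  prot <- protected_mask(L, config$protected_intervals)
  bases <- c("A", "C", "G", "T")

  # per species: root-frame characters ("-" = deleted) + insertions per slot
  body <- list()
  insertions <- list()
  body[[focal]] <- rootc
  insertions[[focal]] <- list()
  for (sp in species[-1]) {
    chars <- rootc
    mut <- stats::runif(L) < config$substitution_rate & !prot & chars != "N"
    if (any(mut)) {
      chars[mut] <- vapply(chars[mut], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    ins <- list()
    if (config$indel_rate > 0 && L > 0) {
      ev <- which(stats::runif(L) < config$indel_rate & !prot)
      for (pos in ev) {
        len <- sample.int(config$indel_max_len, 1L)
        if (stats::runif(1) < 0.5) {
          # deletion starting at root position pos (1-based); skip protected
          del <- pos:min(L, pos + len - 1L)
          del <- del[!prot[del]]
          chars[del] <- "-"
        } else {
          # insertion in the slot after root position pos (never strictly
          # inside a protected interval: slot `pos` is interior iff
          # prot[pos] && prot[pos + 1])
          interior <- pos < L && prot[pos] && prot[pos + 1L]
          if (!interior) {
            ins[[as.character(pos)]] <- paste(
              sample(bases, len, replace = TRUE,
                     prob = config$base_probabilities[bases]),
              collapse = "")
          }
        }
      }
    }
    body[[sp]] <- chars
    insertions[[sp]] <- ins
  }

  # assemble alignment columns: slot widths = max insertion length per slot
  slot_width <- integer(L + 1L)  # slot j = gap between root pos j and j+1
  for (sp in species) {
    for (slot in names(insertions[[sp]])) {
      j <- as.integer(slot)
      slot_width[j + 1L] <- max(slot_width[j + 1L],
                                nchar(insertions[[sp]][[slot]]))
    }
  }
  aligned <- vapply(species, function(sp) {
    pieces <- character(0)
    ins <- insertions[[sp]]
    for (j in 0:L) {
      w <- slot_width[j + 1L]
      if (w > 0L) {
        txt <- if (!is.null(ins[[as.character(j)]])) ins[[as.character(j)]] else ""
        pieces <- c(pieces, paste0(txt, strrep("-", w - nchar(txt))))
      }
      if (j < L) pieces <- c(pieces, body[[sp]][j + 1L])
    }
    paste(pieces, collapse = "")
  }, character(1))
  names(aligned) <- species
  ortholog_set(aligned, focal_species = focal)
}

#' Build one complete simulated dataset from a configuration
#'
#' Convenience wrapper: clean background, planted sites, evolved ortholog
#' set, plus the ground-truth planted-site table.
#'
#' @param config A `simulation_config`.
#' @return A list with `root` (`seq_record`), `ortho` (`ortholog_set`) and
#'   `truth` (planted-site data frame with `start`, `end`, `protected`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  root <- generate_background(config$length, config$base_probabilities,
                              seed = config$seed, motif = config$motif,
                              clean_background = TRUE, seq_id = "root")
  root <- plant_motifs(root, config$planted_sites, config$motif)
  ortho <- evolve_orthologs(root, config)
  prot <- protected_mask(config$length, config$protected_intervals)
  truth <- data.frame(
    start = config$planted_sites$position,
    end = config$planted_sites$position +
      site_length(config$motif, config$planted_sites$spacer_length),
    spacer_length = config$planted_sites$spacer_length,
    stringsAsFactors = FALSE
  )
  truth$protected <- vapply(seq_len(nrow(truth)), function(i) {
    span <- (truth$start[i] + 1L):truth$end[i]
    all(prot[span])
  }, logical(1))
  list(root = root, ortho = ortho, truth = truth)
}

#' Power experiment for the conservation filter
#'
#' For each substitution rate, simulates `n_replicates` datasets from the
#' configuration, runs [classify_conservation()], and reports the fraction
#' of protected planted sites called conserved (sensitivity) and the
#' fraction of unprotected decoy sites called conserved. Deterministic for
#' a fixed `seed`.
#'
#' @param substitution_rates Numeric vector of rates to test.
#' @param n_replicates Replicates per rate.
#' @param config Base `simulation_config` (its rate and seed are replaced).
#' @param min_species_required Conservation threshold; default all members.
#' @param seed Master seed from which per-replicate seeds are drawn.
#' @return A data frame with one row per rate: `substitution_rate`,
#'   `n_replicates`, `n_protected`, `n_decoy`, `sensitivity`,
#'   `decoy_conserved_rate`.
#' @export
power_experiment <- function(substitution_rates, n_replicates = 50L,
                             config = simulation_config(),
                             min_species_required = NULL, seed = 1L) {
  set.seed(seed)
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max,
               length(substitution_rates) * n_replicates),
    nrow = length(substitution_rates))
  rows <- lapply(seq_along(substitution_rates), function(ri) {
    rate <- substitution_rates[ri]
    prot_hits <- 0L; prot_cons <- 0L
    decoy_hits <- 0L; decoy_cons <- 0L
    for (rep in seq_len(n_replicates)) {
      cfg <- config
      cfg$substitution_rate <- rate
      cfg$seed <- rep_seeds[ri, rep]
      ds <- simulate_dataset(cfg)
      calls <- classify_conservation(ds$ortho, cfg$motif,
                                     min_species_required = min_species_required)
      for (i in seq_len(nrow(ds$truth))) {
        hit <- calls$start == ds$truth$start[i] & calls$end == ds$truth$end[i]
        if (!any(hit)) next  # planted site missing from focal scan (cannot happen)
        cons <- any(calls$conserved[hit])
        if (ds$truth$protected[i]) {
          prot_hits <- prot_hits + 1L
          prot_cons <- prot_cons + cons
        } else {
          decoy_hits <- decoy_hits + 1L
          decoy_cons <- decoy_cons + cons
        }
      }
    }
    data.frame(substitution_rate = rate, n_replicates = n_replicates,
               n_protected = prot_hits, n_decoy = decoy_hits,
               sensitivity = if (prot_hits) prot_cons / prot_hits else NA_real_,
               decoy_conserved_rate = if (decoy_hits) decoy_cons / decoy_hits
                                      else NA_real_)
  })
  do.call(rbind, rows)
}
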
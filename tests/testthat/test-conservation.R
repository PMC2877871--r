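make_ortho <- function(seqs, focal = names(seqs)[1]) ortholog_set(seqs, focal)

ten_identical <- function(seq) {
  sp <- drosophilid_species()
  make_ortho(stats::setNames(rep(seq, 10), sp), focal = "melanogaster")
}

site_seq <- paste0(strrep("C", 30), "TTCAGTGAA", strrep("G", 30))

test_that("ortholog_set validates alignment geometry", {
  o <- ten_identical(site_seq)
  expect_equal(o$column_count, nchar(site_seq))
  expect_length(o$records, 10L)

  expect_error(make_ortho(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(make_ortho(c(a = "ACGT", b = "ACGT"), focal = "c"),
               "not found")
  expect_error(ortholog_set(c(a = "AC-T", a = "ACGT"), "a"),
               "more than once")
  expect_error(make_ortho(c(a = "AC.T", b = "ACGT")), "illegal")
})

test_that("aligned FASTA reading picks species labels and focal member", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">mel species=melanogaster", "AC-GT",
               ">sim species=simulans", "ACTGT"), path)
  o <- read_alignment(path, "melanogaster")
  expect_equal(o$species, c("melanogaster", "simulans"))
  expect_equal(o$records$melanogaster$sequence, "ACGT")
  expect_error(read_alignment(path, "virilis"), "not found")
})

test_that("gap coordinate maps agree with a direct recount", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    chars <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                    prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    aln <- paste(chars, collapse = "")
    cols <- statsites:::gapless_to_column(aln)
    glpos <- statsites:::column_to_gapless(aln)
    for (j in seq_len(n) - 1L) {
      expect_equal(glpos[j + 1L], oracle_gapless_coord(aln, j))
    }
    # each gapless base's column must hold a non-gap character
    if (length(cols)) {
      expect_true(all(chars[cols + 1L] != "-"))
      expect_equal(length(cols), sum(chars != "-"))
    }
  }
})

test_that("hits map to identical columns in ungapped identical members", {
  o <- ten_identical(site_seq)
  mapped <- map_hits_to_alignment(o, compile_motif())
  expect_length(mapped, 10L)
  for (sp in names(mapped)) {
    expect_equal(mapped[[sp]]$col_start, 30L)
    expect_equal(mapped[[sp]]$col_end, 39L)
  }
})

test_that("a gap before the site shifts the column span, not the gapless start", {
  gapped <- paste0("--", site_seq)
  seqs <- stats::setNames(c(paste0("AA", site_seq), gapped),
                          c("melanogaster", "simulans"))
  o <- make_ortho(seqs)
  mapped <- map_hits_to_alignment(o, compile_motif())
  expect_equal(mapped$melanogaster$col_start, 32L)
  expect_equal(mapped$simulans$col_start, 32L)
  expect_equal(mapped$simulans$start, 30L)  # gapless coordinate unshifted
})

test_that("column spans match a brute-force recount on gapped alignments", {
  set.seed(55)
  motif <- compile_motif()
  for (i in 1:20) {
    core <- paste0(random_dna(40), "TTCAAAGAA", random_dna(40))
    # insert random gaps independently per species
    seqs <- vapply(1:4, function(k) {
      chars <- strsplit(core, "", fixed = TRUE)[[1]]
      pos <- sort(sample(seq_along(chars), sample(0:6, 1)))
      for (p in rev(pos)) chars <- append(chars, "-", after = p)
      paste(chars, collapse = "")
    }, character(1))
    # pad to equal width
    w <- max(nchar(seqs))
    seqs <- paste0(seqs, strrep("-", w - nchar(seqs)))
    names(seqs) <- c("melanogaster", "simulans", "erecta", "yakuba")
    o <- make_ortho(seqs)
    mapped <- map_hits_to_alignment(o, motif)
    for (sp in names(mapped)) {
      h <- mapped[[sp]]
      aln <- o$aligned[[sp]]
      for (j in seq_len(nrow(h))) {
        expect_equal(oracle_gapless_coord(aln, h$col_start[j]), h$start[j])
        expect_equal(oracle_gapless_coord(aln, h$col_end[j]), h$end[j])
      }
    }
  }
})

test_that("identical members give a fully conserved call", {
  calls <- classify_conservation(ten_identical(site_seq), compile_motif())
  expect_equal(nrow(calls), 1L)
  expect_true(calls$conserved)
  expect_equal(calls$n_species_present, 10L)
  expect_equal(attr(calls, "min_species_required"), 10L)
})

test_that("a focal-only site is called non-conserved", {
  mutated <- sub("TTCAGTGAA", "TTAAGTGAA", site_seq, fixed = TRUE)
  seqs <- stats::setNames(c(site_seq, rep(mutated, 9)), drosophilid_species())
  calls <- classify_conservation(make_ortho(seqs), compile_motif())
  expect_equal(calls$n_species_present, 1L)
  expect_false(calls$conserved)
})

test_that("any allowed spacer class certifies conservation", {
  # focal 3n site; the other species carries a 4n site at the same place
  focal <- paste0(strrep("C", 20), "TTCAGTGAA-", strrep("G", 10))
  other <- paste0(strrep("C", 20), "TTCAGTTGAA", strrep("G", 10))
  o <- make_ortho(stats::setNames(c(focal, other),
                                  c("melanogaster", "virilis")))
  calls <- classify_conservation(o, compile_motif())
  expect_true(calls$conserved[calls$spacer_length == 3][1])
})

test_that("conservation calls obey monotonicity and permutation invariance", {
  set.seed(17)
  cfg <- vvl_like_config(seed = 99, substitution_rate = 0.15)
  ds <- simulate_dataset(cfg)
  m <- compile_motif()
  base <- classify_conservation(ds$ortho, m, min_species_required = 8)
  # raising the species threshold never creates a conserved call
  stricter <- classify_conservation(ds$ortho, m, min_species_required = 10)
  expect_true(all(stricter$conserved <= base$conserved))
  # raising tolerance never destroys one
  looser <- classify_conservation(ds$ortho, m, min_species_required = 8,
                                  tolerance_columns = 3)
  expect_true(all(looser$conserved >= base$conserved))
  # focal species always present for its own hits
  expect_true(all(base$present_melanogaster))
  # reordering non-focal members changes nothing
  perm <- c("melanogaster", sample(setdiff(ds$ortho$species, "melanogaster")))
  o2 <- ortholog_set(ds$ortho$aligned[perm], "melanogaster")
  calls2 <- classify_conservation(o2, m, min_species_required = 8)
  expect_equal(calls2$conserved, base$conserved)
  expect_equal(calls2$n_species_present, base$n_species_present)

  expect_error(classify_conservation(ds$ortho, m, min_species_required = 11),
               "exceeds")
})

test_that("protected planted sites are recovered under divergence", {
  # substitution rate 0.2 outside protected intervals; the two protected
  # planted sites must be called conserved in (essentially) every replicate
  set.seed(1)
  seeds <- sample.int(.Machine$integer.max, 60)
  recovered <- 0L
  total <- 0L
  for (s in seeds) {
    cfg <- vvl_like_config(seed = s, substitution_rate = 0.2)
    ds <- simulate_dataset(cfg)
    calls <- classify_conservation(ds$ortho, cfg$motif)
    for (i in which(ds$truth$protected)) {
      total <- total + 1L
      hit <- calls$start == ds$truth$start[i] & calls$end == ds$truth$end[i]
      recovered <- recovered + any(calls$conserved[hit])
    }
  }
  expect_gte(recovered / total, 0.95)
})

test_that("conservation TSV output carries per-species 0/1 columns", {
  calls <- classify_conservation(ten_identical(site_seq), compile_motif())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conservation_tsv(calls, path)
  tab <- utils::read.delim(path)
  expect_true(all(paste0("present_", drosophilid_species()) %in% names(tab)))
  expect_true(all(unlist(tab[grepl("^present_", names(tab))]) %in% 0:1))
  expect_equal(tab$conserved, 1L)
})
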
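---
title: "Finding STAT-regulated enhancers by phylogenetically filtered site scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding STAT-regulated enhancers by phylogenetically filtered site scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statsites)
```

## The problem

STAT transcription factors bind a palindromic consensus of the form
`TTC(N)nGAA`. The single *Drosophila* STAT, STAT92E, uses sites with
spacers of 3 or 4 bases (the "3n" and "4n" classes) to regulate its
targets. Because the consensus is short and degenerate, chance occurrences
are abundant: in a large cis-regulatory region tens of spurious matches are
expected, so a raw site map cannot, by itself, locate the enhancers. The
strategy implemented here combines three filters:

1. **scan** for every 3n/4n site in the region of interest;
2. **conserve**: keep sites that are also present, at the orthologous
   position, in the other species of a comparison panel (phylogenetic
   footprinting by presence/absence, not by score);
3. **cluster and select**: propose as candidate enhancers the regions where
   sites cluster and at least some cluster members are conserved.

An analytic null model quantifies how many sites are expected by chance and
whether an observed count is in excess.

## The motif model

A `motif_spec` is an exact degenerate consensus: a fixed left flank, a set
of allowed spacer lengths whose bases are unconstrained, and a fixed right
flank. The default (`compile_motif()`) is `TTC{N3|N4}GAA`. There is no
position weight matrix and no score threshold; a window either matches or
it does not. This mirrors how the site classes are defined experimentally:
both classes are bound in vivo, and 2n sites — bound by some vertebrate
STATs — are deliberately not part of the default (they can be requested via
`spacer_lengths`).

The default consensus is *closed under reverse complementation*: the
reverse complement of any `TTC...GAA` instance is again an instance
(`is_revcomp_closed()`). A forward-strand scan therefore counts each
physical site exactly once, and strand is reported as `"."`. For a
user-supplied motif that is not closed, both strands are scanned and
strand is reported as `+`/`-`, with identical intervals deduplicated.

Two policies needed a decision:

* **N handling.** An ambiguous base could be anything, so counting it as a
  match inflates site totals; by default N matches nowhere (hence a hit
  never overlaps an N). `allow_n_spacer = TRUE` relaxes this for spacer
  positions only.
* **Soft masking.** Lowercase input is uppercased and scanned normally;
  gene-desert DNA of the kind this method targets is repeat-poor and no
  masking-specific behaviour is assumed.

Coordinates are 0-based half-open throughout the package; BED output is
native, GFF3 output converts to 1-based inclusive.

## Conservation calls

The input is a gapped multiple alignment of orthologous regions (aligned
FASTA), with one member designated focal. The package does not align
sequences itself: choosing an aligner is a major analytical decision that
should not happen silently, and simulated ortholog sets come pre-aligned
by construction.

Conservation is operationalized through alignment columns: every member is
scanned independently on its gapless sequence, each hit is lifted to its
alignment-column span, and a focal site counts as *present* in species *s*
if *s* has a hit of **any** allowed spacer class whose span overlaps the
focal span by at least `overlap_min_columns` (default 1) after widening by
`tolerance_columns` (default 0). A site is *conserved* when present in at
least `min_species_required` members — by default **all** of them, the
strictest reading of "conserved in all studied species". The threshold is
exposed because users often have fewer orthologs, and because whether a
9-of-10 site should count is a judgment call, not a fact.

Two deliberate choices: spacer content may differ between species (spacer
bases are degenerate by definition, so demanding identity would be
arbitrary), and a 3n site may certify a 4n focal site (the two classes are
treated jointly throughout). The single-column overlap default exists
because indels inside the spacer shift flank columns; requiring
full-footprint overlap would miss biologically identical sites.

## Clusters and candidate regions

`cluster_hits()` merges sites by single-linkage: consecutive sites join a
cluster when the gap between them is at most `max_gap`. Single linkage was
chosen over fixed windows because its output is invariant to the
coordinate origin. `select_candidates()` keeps clusters with at least
`min_conserved` conserved members (default 1 — "clusters where at least
some sites are conserved"; set 0 to retain non-conserved control
clusters), widens them by `padding` and clips to the sequence.

No cluster geometry is prescribed by the underlying biology, so the
defaults (`max_gap = 500` bp, `padding = 250` bp) were tuned once so that
default candidates have the ~0.7–2 kb scale of enhancer fragments that are
practical to test in reporter assays; both are plain parameters.
Candidates are ranked by conserved count, then total count, then position:
empirically it is the fragments with conserved sites that carry the
regulation, which is the whole point of the filter.

## The null model and enrichment

Under the uniform null (equal, independent base frequencies) a given
position starts a site of one spacer class with probability `(1/4)^6`
(six fixed bases; spacer bases are free), so for the two classes jointly

```{r}
per_position_probability(compile_motif(), null_model("uniform"))
```

which is `2 × (1/4)^6 = 1/2048` — one chance site about every 2 kb. The
default expected count is the back-of-envelope rule `length × p` with no
edge correction, kept as the default precisely so that the headline
arithmetic reproduces exactly:

```{r}
expected_count(144000)$expected_rounded   # 70 expected in the 144 kb region
expected_count(70000)$expected_rounded    # 34 expected in the 70 kb locus
excess_and_test(85, 144000)$excess        # 15 sites in excess
excess_and_test(53, 70000)$excess         # 19 sites in excess
```

`mode = "exact_positions"` refines this by counting, per spacer class, only
positions where a full site fits (`max(0, L - sitelen + 1)`); it is always
at most the approximate value and converges to it with length. Rounding is
half away from zero — the convention only matters at `.5` and has to be
fixed for reproducibility. A `markov0` null replaces `1/4` by user base
frequencies (each spacer position contributes a factor 1).

`excess_and_test()` adds an upper Poisson tail `P(X ≥ observed)` at the
unrounded expectation. The Poisson approximation ignores the (weak, in the
rare-site regime) dependence between overlapping potential sites; it is
documented as such, and `montecarlo_expected_count()` provides the
assumption-free alternative: shuffle the actual sequence preserving mono-
or dinucleotide composition (the dinucleotide case uses the
Altschul–Erickson Eulerian-walk construction, which preserves the
dinucleotide count multiset exactly) and rescan.

## The synthetic-data generator

`simulation_config()` describes a complete synthetic study:

* an i.i.d. background of given length and composition (uniform by
  default, embodying the no-composition-bias assumption of the analytic
  null); `clean_background` resamples the middle base of each accidental
  hit's left flank until none remain, so planted sites are the only hits;
* planted motif instances at chosen positions;
* an ortholog set evolved from that root: each non-focal species is an
  independent copy (star phylogeny) with per-base substitutions at
  `substitution_rate`, uniform over the three alternative bases
  (Jukes–Cantor-like, no transition bias), and optional indels (lengths
  uniform on `1..indel_max_len`), all outside `protected_intervals`, which
  are copied verbatim. Insertions open gap columns in the other members,
  deletions become gaps in the derived member, so the output is a valid
  alignment in the root coordinate frame.

The defaults reproduce the geometry of a well-characterized 680 bp
tracheal-enhancer fragment: a 3n site at position 86 and a 4n site at 219
(protected — conserved by construction) and a 3n decoy at 508 that evolves
neutrally. The default substitution rate of 0.1 per base is a divergence
on the scale seen between drosophilid noncoding regions; it was fixed once
as part of the study conditions. A star phylogeny (rather than a tree) was
chosen because presence-in-all-species is insensitive to tree topology,
and independence keeps the closed-form survival probability of a decoy
site — about `(1-r)^6` per species, plus small rescue terms from
overlapping de novo sites — tractable for validation.

`power_experiment()` runs this end to end over a grid of rates and reports
the sensitivity for protected sites (1.0 by construction) and the decoy
conserved rate, which for the default panel of 10 species at rate 0.1 is
of order `0.53^9 ≈ 0.003`.

What the simulations do **not** emulate: realistic phylogenies and branch
lengths, rate heterogeneity, CpG effects, compositional skew along the
sequence, and alignment error. Passing the simulation-based tests
therefore shows that the conservation filter behaves as specified under
its own assumptions — not that a real alignment pipeline is error-free.

## Numerical and degenerate-input choices

* Empty sequences scan to an empty hit table, not an error; a region of
  length 0 has expected count 0.
* Duplicate (start, end) intervals are reported once; 3n and 4n hits that
  merely overlap are both reported, since both classes are counted jointly.
* `cluster_hits()` refuses mixed sequence ids; the pipeline splits by
  sequence first.
* All randomness (backgrounds, spacers, evolution, shuffles) flows from
  explicit seeds; identical configurations produce byte-identical output
  files, and the run report embeds the resolved configuration (paths
  excluded) so a run can be audited.
* Problem sizes used by the validation suite were chosen to make
  Monte-Carlo error small relative to the tested tolerances: 10,000
  sequences of 2,048 bp for the analytic-agreement check, 200 replicates
  of the 680 bp fixture for conservation recovery, and 1,000 random cases
  for each oracle-equivalence property.

## Known limitations

* Conservation is presence/absence at the orthologous location; there is
  no phylogeny-aware scoring and no attempt to weight species by
  divergence.
* The candidate boundaries are cluster spans plus padding; real enhancer
  boundaries are not recoverable from site geometry alone.
* The Poisson tail inherits the independence approximation; use the
  shuffle null when composition bias is a concern.
* The exact degenerate consensus cannot find diverged sites that a weight
  matrix might; that is intentional fidelity to the site classes with
  demonstrated in vivo function.
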
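---
title: "The AEFB 463 bp marker system: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The AEFB 463 bp marker system: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardra)
```

## The marker system

Aerobic endospore-forming bacilli (AEFB) — *Bacillus* and the genera split
off from it over the last decades — dominate many soil communities, and
group-specific molecular markers are the practical way to pick them out of
mixed 16S rRNA data. The system implemented here rests on two linked
observations about the 16S rRNA gene of AEFB:

1. HaeIII (GG/CC) digestion of the amplified gene yields a restriction
   fragment of around 460 bp at a conserved position near the 3' end of the
   gene in essentially all AEFB, while other lineages carry HaeIII sites at
   different positions and so give different fragment sizes;
2. the region is flanked by sequence conserved enough to support a
   group-specific primer pair (463F/463R) that amplifies a 463 bp product
   in AEFB and fails in most other lineages — in part because the reverse
   primer's annealing site physically contains the HaeIII site
   (`AATACGTTCCCGGG`**`GGCC`-containing**`CCTT`), so lineages that lost the
   site also lose primer specificity.

Everything the package does is the computational form of this protocol:
find the sites, digest, look for the diagnostic band, run the PCR in
silico, screen panels, rediscover the marker de novo, and build
marker-based trees.

## Primer constants and the forward-primer ambiguity

The published record of the forward primer exists in two forms that differ
at the third base only: `CTAAAACTCAAAGGAATTGACG` (running text) and
`CTGAAACTCAAAGGAATTGACG` (the form listed as a perfect match for the
100%-identity taxa throughout the genus-by-genus specificity table). The
package ships both (`primer_463f("G")`, `primer_463f("A")`) and defaults to
the `CTG` form, because the specificity table is internally consistent
about it: taxa annotated as exact matches carry `CTG`, and mismatch bolding
is measured against it. Neither form is silently hidden; the CLI exposes
`--fwd-variant` and `--version` prints both.

The reverse primer is stored the way the field's tables print it: as the
sense-strand segment it anneals to (`site_463r()`), with the synthesized
oligo its reverse complement (`primer_463r()`).

## In silico PCR: the mismatch model

`find_primer_hits()` scans both strands with a Hamming (substitution-only)
model: a site is a hit when it has at most `max_mismatches` (default 2)
IUPAC-aware mismatches and **zero** mismatches in the 3'-terminal
`anchor_3prime` bases (default 3). The anchor mimics the dominant mode of
PCR failure — a mismatched 3' terminus blocks polymerase extension — and
the substitution-only model matches the observed variant spectrum, which is
substitution-only. Indel alignment is deliberately not modeled.

`insilico_pcr()` pairs hits in both orientations: forward primer on the
stored strand upstream of the reverse primer (orientation `"+"`), and the
mirrored configuration (orientation `"-"`), which published screens record
as the primer pair "in reverse order". Outer spans include both primer
sites — the convention under which the canonical marker span 909–1371 has
length 463 — and products are kept inside `product_window` (default
300–700 bp, a generous window around the 463 bp target that still excludes
nonspecific short/long pairings).

Subject-side ambiguity is conservative: an `N` in a sequence never
satisfies a concrete pattern base, so low-quality stretches cannot
manufacture cut sites or primer hits.

## Restriction digestion and gel emulation

Digestion is linear (templates are genes or amplicons, not plasmids), and
only the top-strand cut is modeled; HaeIII is blunt, so both strands share
the cut position, but for non-blunt enzymes the single `cut_offset` is a
documented simplification. `band_pattern()` emulates a 2% agarose gel with
a 100 bp ladder: fragments under `min_visible_length` (default 60 bp) run
off; remaining lengths cluster by single linkage, with a gap larger than
`bin_tolerance` (default 10 bp) separating bands; a band is reported at the
round-half-up mean of its member lengths. `has_diagnostic_band()` checks
for a band within ±15 bp of 460 bp, about the size discrimination a gel
affords at that scale.

## The restriction-site flag

The published screening table scores "presence of restriction enzyme site"
as +/- without saying which site is meant. Three readings are
implemented (`site_rule=`):

* **`rev`** (default) — an intact HaeIII site within the reverse-primer
  annealing region. This is the default because it is the reading the data
  support: the +/- column co-varies with reverse-site integrity (variants
  like `GGGTCTT` that destroy the GGCC are scored "-"), and the site inside
  the reverse-primer region is the one that delimits the diagnostic digest
  fragment. It is also the only reading compatible with the marker
  geometry itself: for a typical positive strain the *only* HaeIII site
  inside the span is the one in the reverse-primer region, and an extra
  strictly-interior site would split the ~460 bp band.
* **`interior`** — a site strictly inside the primer-delimited span,
  excluding any site overlapping the reverse-primer region.
* **`any`** — any site overlapping the span.

## Identity, distances, trees

Percent identity and distances run over optimal global alignments
(Needleman–Wunsch, affine gaps; match +1, mismatch −1, a gap of length L
costs −2 − L). Identity counts identical columns over columns where both
sequences have a base (`excluding_gaps`, the default) and is rounded
half-up to an integer for parity with published tables. The
similarity reference is always user-supplied: the published table's own
reference sequence cannot be identified from the record (it reports 95%
for a sequence that should be a self-comparison), so no default reference
is hardcoded and similarity values are treated as qualitative.

`distance_matrix()` computes p-distances (mismatches over compared columns,
gap columns excluded) or Jukes–Cantor corrections
(−3/4·ln(1 − 4p/3), an error for p ≥ 0.75). Argument order within each
pair is canonicalized by content so the distance is exactly symmetric even
when co-optimal alignments would place gaps differently.

`nj_tree()` is canonical Saitou–Nei neighbor joining with two conventions
fixed where the literature leaves slack: ties in the Q-criterion resolve to
the smallest (row, column) index pair, and negative limb estimates are
clamped to zero with the deficit transferred to the sister branch, keeping
total path lengths intact. NJ is exact on additive matrices, which the
test suite exercises directly. Pairwise distances replace a multiple
alignment deliberately: the published dendrograms are qualitative, a
pairwise pipeline is fully specifiable and testable, and a center-star or
progressive MSA is out of scope. Published tree topologies are therefore
*not* a reproduction target; clustering checks are qualitative (planted
clades must separate).

`cut_clusters()` removes the k−1 longest internal edges (ties by edge
order) and reads clusters off the components — a deterministic stand-in
for eyeballing a dendrogram into groups.

## Marker discovery and the simplified primer designer

`discover_marker()` generalizes the original observation into a procedure:
digest targets and outgroup, pool fragment lengths inside `length_window`
(default 200–800 bp), bin them like gel bands, and score each bin by
prevalence (fraction of sequences in a set with at least one member
fragment). Bins with target prevalence ≥ 0.9, outgroup prevalence ≤ 0.1
and a positive gap are reported, ranked by gap then member count.

`design_primers()` replaces an interactive primer-design program with a
deliberately simple, fully specified designer: positional consensus over
the terminal columns of the candidate fragments (anchored at starts for
forward, at ends for reverse), windows of 18–25 bp sliding up to 10 bp in
from each terminus, at most `max_degeneracy` (default 1) non-unanimous
columns per window, and a consensus Tm inside 50–65 °C by the basic GC
formula Tm = 64.9 + 41·(GC − 16.4)/L. Window pairs rank by total
non-unanimous columns, then Tm balance |Tm_f − Tm_r|, then smaller
offsets, then longer windows. The GC formula and the ranking are
simplifications chosen for determinism and testability, not thermodynamic
accuracy.

## The synthetic-sequence generator

`make_aefb_like()` emulates exactly the features of a 16S rRNA gene that
the marker system reads, and nothing else:

* a full-length gene (1550 bp) with ~55% GC background, typical of 16S;
* the forward primer site at position 909 and the reverse sense site
  placed so the span is 909–1371 (463 bp), mirroring the canonical
  100%-identity record;
* a `GGC` planted immediately upstream so the primer's leading `C`
  completes a HaeIII site: the cut after 907 and the cut inside the
  reverse site (after 1367) delimit a 460 bp digest fragment — the ~460 bp
  gel band sitting 3 bp inside the 463 bp marker;
* background `GGCC` suppressed everywhere except planted positions, so
  cut-site counts are exactly controlled and the truth record is exact;
* optional controlled lesions: primer-site substitutions (never in the
  3' anchors, never in the reverse-site GGCC), interior substitutions,
  decoy HaeIII sites outside the marker (extra gel bands), reverse-site
  ablation (amplification failure), or a second forward site (an
  indeterminate double product).

`make_cohort()` derives target sets from a shared ancestor with
per-sequence interior substitutions (default divergence 5 substitutions,
small enough to keep markers clearly homologous, large enough for non-zero
distances) and outgroup sequences that lack both primer sites and any
fragment in the diagnostic size class, with a two-clade mode (clade
ancestors 40 substitutions apart) for clustering checks.

What the generator does **not** emulate: rRNA secondary structure and
covariation, compositional heterogeneity along the gene, sequencing error
profiles, chimeras, and the real phylogenetic signal of 16S. Passing tests
therefore demonstrate that the *machinery* is correct against planted
truth — not that the marker is biologically diagnostic for any particular
real lineage; that claim belongs to the underlying wet-lab system.

## Numerical conventions and problem sizes

All coordinates are 1-based inclusive on the stored strand. Band centers
and identity percentages use round-half-up (base R's `round()` is
round-half-even). Generation is a pure function of the seed
(`withr::with_seed`), so fixtures, cohorts and CLI outputs are
byte-reproducible.

The test suite and acceptance script run at desk scale by design: digestion
properties over 1,000 random sequences, site-scan oracles over ~50 bp
strings, alignment enumeration oracles over ≤ 6 bp strings, NJ exactness
over random additive matrices with up to 6 taxa, cohorts of 10 + 10
full-length sequences, and a 52-strain screening panel. These sizes
exercise every code path while keeping a full run in the seconds-to-minutes
range on one CPU.

## Known limitations

* Hamming-only primer matching; indel variants at primer sites would be
  missed.
* One cut offset per enzyme (top strand); non-blunt cutters are modeled
  only approximately.
* The basic GC Tm formula drifts for long AT-rich oligos; it is a ranking
  device, not a melting prediction.
* Percent-similarity values against an unspecified published reference are
  not reproducible from the record and are treated as qualitative
  throughout.
* The optional NCBI fetch helper is a convenience only; no core operation,
  test or script touches the network.
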
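# ardra

An R toolkit for a PCR/restriction marker system that identifies and
classifies **aerobic endospore-forming bacilli (AEFB)** — *Bacillus* and
related genera such as *Lysinibacillus*, *Brevibacillus*, *Geobacillus*,
*Terribacillus* and *Jeotgalibacillus* — from 16S rRNA gene sequence.

## The marker system

HaeIII (recognition GG/CC) digestion of the amplified 16S rRNA gene yields a
restriction fragment of around 460 bp, at the same position near the 3' end
of the gene, across essentially all AEFB — and at different positions (hence
different fragment sizes) in other bacterial lineages. The primer-delimited
form of this region is a 463 bp marker amplified by the primer pair

```
463F  5'-CTGAAACTCAAAGGAATTGACG-3'
463R  5'-AATACGTTCCCGGGCCTT-3'   (sense-strand annealing site;
                                  synthesized oligo is its reverse complement)
```

(the forward primer is also published in a second form, `CTA`-initial; both
constants ship and are selectable — see the methods vignette). The reverse
site contains the HaeIII site `GGCC` that delimits the diagnostic digest
fragment, so a single substitution there abolishes both amplification
specificity and the restriction band.

The package implements, purely in silico:

* **restriction** — IUPAC-aware cut-site finding, linear digestion,
  gel-like band binning (`find_sites()`, `digest()`, `band_pattern()`,
  `has_diagnostic_band()`);
* **amplification** — mismatch-tolerant primer-site search with a strict
  3'-anchor and in silico PCR in both orientations (`find_primer_hits()`,
  `insilico_pcr()`);
* **marker screening** — extraction, classification
  (positive/negative/indeterminate), bracketed primer-variant annotation,
  restriction-site flag and percent identity against a reference marker
  (`extract_marker()`, `screen_panel()`, `annotate_variant()`);
* **discovery** — generalized diagnostic-fragment discovery for arbitrary
  target/outgroup sets with a simplified conserved-window primer designer
  (`discover_marker()`, `design_primers()`, Tm = 64.9 + 41·(GC − 16.4)/L);
* **phylogenetics** — pairwise p-distance / Jukes–Cantor matrices over
  markers, canonical neighbor joining with Newick I/O and tree cutting
  (`distance_matrix()`, `nj_tree()`, `write_newick()`, `cut_clusters()`);
* **fixtures** — a deterministic synthetic 16S-like sequence generator
  with planted primer sites, HaeIII sites and controlled mutations
  (`make_aefb_like()`, `make_cohort()`), so every module is testable
  without downloads.

All user-facing functions take a sequence tibble (`id`, `description`,
`accession`, `residues`) first and return tibbles, so analyses chain with
the pipe; `autoplot()`, `tidy()` and `glance()` methods cover the main
result types. Coordinates are 1-based and inclusive on the stored strand
throughout.

## Worked example

```r
library(ardra)
library(dplyr)

fx <- make_aefb_like(fixture_spec(seed = 42))   # synthetic full-length 16S

insilico_pcr(fx$sequence) |>
  select(seq_id, orientation, start, end, length)
#> # A tibble: 1 × 5
#>   seq_id   orientation start   end length
#>   <chr>    <chr>       <int> <int>  <int>
#> 1 aefb_s42 +             909  1371    463

band_pattern(digest(fx$sequence))
#> # A tibble: 4 × 3
#>   seq_id   bin_center count
#>   <chr>         <dbl> <int>
#> 1 aefb_s42        183     1
#> 2 aefb_s42        275     1
#> 3 aefb_s42        460     1
#> 4 aefb_s42        528     1

scr <- screen_panel(fx$sequence,
                    reference_marker = extract_marker(fx$sequence)$residues)
glance(scr)
#> # A tibble: 1 × 5
#>       n n_positive n_negative n_indeterminate mean_identity
#>   <int>      <int>      <int>           <int>         <dbl>
#> 1     1          1          0               0           100
```

The amplicon sits at 909–1371 (463 bp, both primer sites included), the
HaeIII digest shows the diagnostic ~460 bp band among background fragments,
and the screen classifies the sequence positive with an intact reverse-site
HaeIII flag (`site = "+"`).

The same operations are available from the shell via the `exec/ardra`
script: `ardra digest`, `ardra bands`, `ardra pcr`, `ardra screen`,
`ardra discover`, `ardra tree` and `ardra fixtures`, each a thin wrapper
over the functions above (see `ardra --help`).

## Documentation

The methods vignette (`vignettes/ardra-marker-system.Rmd`) describes the
model, its assumptions, all tunable parameters, the synthetic-data
generator, numerical conventions and known limitations.
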
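# wrkyr

Annotation and evolutionary classification of WRKY transcription factor
genes, for researchers studying the evolution of this plant
transcription-factor family and its unusual relatives: non-plant WRKY
genes and chimeric resistance-protein/WRKY (RW) genes.

## What it does

The WRKY domain is a ~60-residue DNA-binding module: a signature
heptapeptide (canonically `WRKYGQK`) followed by a zinc finger. The
family's evolutionary groups are diagnosable from sequence and gene
structure:

* **Group I** — two WRKY domains (N-terminal and C-terminal);
* **Group II** (IIa–IIe) — one domain, C2H2-type finger
  (C-X4/5-C…H-X-H); IIa/IIb carry `QVQR` inside the finger, a `DGC`
  immediately before the signature, C-X5-C spacing, and the conserved
  VQR intron; the others carry the PR intron between signature and
  finger;
* **Group III** — one domain with a C2HC (C-C-H-C) finger;
* non-plant types — fungal (`WKNNGNT` signature, C-X6-C-H-X3-C
  finger), moss Group III variant (`WKKYGNK`), algal single-domain and
  diplomonad (`WKKYGHK`) genes;
* **RW1–RW8** — chimeric genes combining NLR resistance-protein domains
  (TIR, NB-ARC, LRR) with WRKY domains, defined by their ordered domain
  architecture, e.g. `RW1 = TIR–NB-ARC–LRR–WRKY(IIe)`.

`wrkyr` implements the full inference chain: degenerate signature and
zinc-finger scanning with the curation rule (signature *and* at least
part of a finger), group classification by rule cascade plus
nearest-reference refinement, intron mapping and PR/VQR typing from
GFF3 gene models, an architecture grammar for RW1–RW8, and distance
phylogenetics exactly as the methods prescribe: p-distances with
pairwise deletion, Poisson correction *d* = −ln(1−*p*), elimination of
alignment positions with less than 95% site coverage, neighbor joining,
and bootstrap support. A seeded synthetic-data generator with
machine-readable truth tables makes every stage testable offline, and a
transcription of the published 29-gene RW catalogue ships as a fixture.

All user-facing functions take and return tibbles, so results chain
with the pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` views.

## Worked example

```r
library(wrkyr)

spec    <- synth_spec(group_counts = c(I = 2, IIb = 3, III = 3),
                      mutation_rate = 0.05, seed = 42)
pr      <- generate_proteome(spec)
domains <- scan_proteome(pr$records, list(max_mismatches = 0))
dplyr::select(domains, protein_id, index_in_protein, sig_offset,
              matched_variant, finger_class)
#> # A tibble: 10 × 5
#>   protein_id index_in_protein sig_offset matched_variant finger_class
#>   <chr>                 <int>      <int> <chr>           <chr>
#> 1 i_001                     0         73 WRKYGQK         C2H2_X4
#> 2 i_001                     1        213 WRKYGQK         C2H2_X4
#> 3 i_002                     0         70 WRKYGQK         C2H2_X4
#> 4 i_002                     1        184 WRKYGQK         C2H2_X4
#> 5 iib_001                   0         71 WRKYGQK         C2H2_X5
#> # ...
```

Each row is one called WRKY domain: `sig_offset` is the 0-based
position of its signature, `finger_class` the zinc-finger spacing class
(`C2H2_X4` here means C-X4-C…H-X-H). The two `i_00*` proteins carry two
domains each, as Group I proteins must.

```r
groups <- classify_proteome(domains, pr$records)
dplyr::count(groups, group)
#> # A tibble: 4 × 2
#>   group     n
#>   <chr> <int>
#> 1 III       3
#> 2 IIb       3
#> 3 I_CT      2
#> 4 I_NT      2
```

All ten domains recover their planted groups: the two-domain proteins
split into N- and C-terminal calls, the C2HC fingers go to Group III,
and the X5-finger domains with QVQR/DGC motifs to Group IIb.

```r
sel <- nchar(groups$domain_seq) == 54          # equal-length domains
D   <- p_distance(setNames(groups$domain_seq[sel],
                           groups$protein_id[sel]))
tr  <- nj_tree(poisson_correct(D))
glance(tr)
#> # A tibble: 1 × 4
#>   n_tips n_internal total_length clamped_branches
#>    <int>      <int>        <dbl>            <int>
#> 1      7          5         1.47             0
```

A neighbor-joining tree of the Poisson-corrected distances, in
substitutions per site; `clamped_branches` counts negative NJ branch
lengths clamped to zero (none here).

For gene structure, `generate_gene_models()` emits a genome and GFF3
with introns planted at the PR/VQR anchors, and
`type_proteome_introns(introns_from_models(read_gff3(f)), domains,
records)` types them. For RW genes, `read_domain_table()` +
`build_architecture()` + `classify_rw_proteins()` classify
architectures; `read_rw_catalogue()` returns the packaged 29-entry
catalogue. A thin command-line wrapper lives at
`inst/scripts/wrky.R` (`simulate` and `run` subcommands).

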
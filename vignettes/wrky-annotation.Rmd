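---
title: "Annotating and classifying WRKY transcription factor genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying WRKY transcription factor genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyr)
```

## The problem

WRKY transcription factors are defined by a ~60-residue DNA-binding
domain: a seven-residue signature (canonically `WRKYGQK`) followed by a
zinc finger whose chelating cysteines and histidines occur at
group-typical spacings. The family splits into evolutionary groups:
Group I proteins carry two WRKY domains; Group II proteins carry one
domain with a C2H2-type finger (subgroups IIa–IIe); Group III proteins
carry one domain with a C2HC (C-C-H-C) finger. Non-plant homologues add
further types: a fungal form with a `WKNNGNT` signature and a
C-X6-C-H-X3-C finger, a moss Group III variant (`WKKYGNK`), algal
single-domain genes, and diplomonad genes whose C-terminal domain reads
`WKKYGHK`. Two conserved introns are diagnostic at the gene level: the
PR intron that interrupts between the signature block and the finger
(Groups I, IIc, IId, IIe, III), and the VQR/QVQR intron inside the
finger (Groups IIa and IIb). Finally, some flowering plants carry
chimeric genes that combine resistance-protein (NLR) domains — TIR,
NB-ARC, LRR — with one or more WRKY domains; their architectures fall
into eight families, RW1–RW8.

`wrkyr` implements this inference chain as testable components:

1. **Domain scanning** (`scan_proteome()`): degenerate signature search
   plus zinc-finger detection, with the curation rule that a domain is
   called only when a signature is followed by at least part of a
   finger.
2. **Group classification** (`classify_proteome()`): a rule cascade on
   domain count, finger class and the IIb motifs (`QVQR` in the finger,
   `DGC` just before the signature), refined by nearest packaged
   reference where rules alone cannot separate lineages.
3. **Intron typing** (`type_proteome_introns()`): gene-model introns
   mapped to protein coordinates and classified PR / VQR / OTHER / NONE
   against motif anchors.
4. **RW architecture classification** (`classify_rw_proteins()`): a
   declarative grammar over ordered domain-annotation tokens.
5. **Distance phylogenetics** (`p_distance()`, `poisson_correct()`,
   `site_coverage_filter()`, `nj_tree()`, `bootstrap_support()`).
6. **A seeded synthetic-data generator** (`synth_spec()`,
   `generate_proteome()`, `generate_gene_models()`,
   `generate_rw_table()`) that plants all of the above with truth
   tables.

## Scanning model and its parameters

A window of width 7 is a signature hit when its Hamming distance to a
library variant (`WRKYGQK`, `WKNNGNT`, `WKKYGNK`, `WKKYGHK`;
user-extensible) is at most `max_mismatches`. Matching is anchored on
the initial tryptophan: every library variant begins with W, and
anchoring suppresses most random false positives at nonzero mismatch
budgets. The pipeline default is `max_mismatches = 1`; tests use 0
unless the test is about fuzziness itself.

Zinc fingers are matched against spacing envelopes, one per class:

| class | pattern |
|---|---|
| `C2H2_X4` | C-x(4)-C-x(20,28)-H-x(1)-H |
| `C2H2_X5` | C-x(5)-C-x(20,28)-H-x(1)-H (IIa/IIb) |
| `C2HC`    | C-x(4,7)-C-x(20,28)-H-x(1,3)-C (III) |
| `FUNGAL`  | C-x(6)-C-x(5,30)-H-x(3)-C |

The literature quotes exemplar spacings, not envelopes; the ranges above
are this package's operationalization and are configurable via
`zinc_finger_classes()`. The fungal C…H gap in particular is not pinned
down by any printed consensus, so its wide 5–30 envelope is an explicit
guess. "At least part of a zinc finger" is operationalized as ≥2
chelators in class-consistent spacing — the weakest testable reading of
the curation rule.

A domain is called when a signature is followed within `window`
(default 60 residues) by a finger. Candidate fingers are ranked: full
(4 chelators) before partial, then leftmost first chelator, then the
**most compact** hit (earliest last chelator), then class precedence
`C2H2_X4 < C2H2_X5 < C2HC < FUNGAL`. Compactness is ranked above class
precedence deliberately: a genuine C-x6-C fungal finger also satisfies
the C2HC first-gap envelope, and residues downstream of the true finger
can occasionally complete a sprawling C2HC match that shares the same
first chelators; ranking by span end keeps the tight, biologically
meaningful hit. Signatures with no downstream finger are preserved as
rejected candidates for audit (`rejected_candidates()`).

## Group classification

The cascade is deterministic and order-independent (domains are
re-sorted N→C): two C2H2-class domains give `I_NT` + `I_CT`; a single
C2HC domain gives `III` (or `III_MOSS_VARIANT` on a moss/fungal-set
signature); a single fungal finger gives `FUNGAL_TYPE`; a single
`C2H2_X5` domain with `QVQR` inside the finger or `DGC` within
`dgc_window = 5` residues before the signature is the IIa/IIb lineage,
reported `IIb`; a single `C2H2_X4` domain is the I/IIc lineage, reported
`IIc`. Everything else is `UNCLASSIFIED` with the reason recorded in the
evidence column. A `WKKYGHK` signature only ever contributes evidence,
never a group by itself.

The printed record separates IIa from IIb, and IIc from IId/IIe, only
phylogenetically, so the package does not invent sequence diagnostics
for them: `refine_by_reference()` aligns the domain
(Needleman–Wunsch, affine gaps, BLOSUM62 shipped as a plain TSV, gap
open −10, extend −1, gap cost `open + (L−1)·extend`) to every packaged
reference and assigns the nearest group by Poisson-corrected distance
over aligned non-gap columns. A margin below `tie_tol = 1e-9` keeps the
coarse label and records both candidates. Traceback ties prefer
diagonal, then the gap in the second sequence, then the first, so
alignments are reproducible.

**The reference set is synthetic.** The published consensus alignments
exist only as figures, not machine-readable text, so the packaged
references (`reference_set()`, also shipped as
`synthetic_reference_domains.faa`) are 60-residue templates *designed*
to satisfy every printed diagnostic — signature variant, finger
spacing, QVQR/DGC, PR/VQR anchors — while sharing one coordinate frame.
They are labelled synthetic everywhere; no invented residues are
presented as published data.

## Intron typing

Intron positions come from cumulative coding bases in transcription
order: after `c` bases the intron falls after residue `floor(c/3)` with
phase `c mod 3`; minus-strand models are walked in descending genomic
order, which makes strand-mirrored twins exactly equivalent. An intron
types PR when it interrupts within ±2 codons of the R of the P-R
dipeptide between signature end and first chelator (the one nearest the
finger when several occur, since the PR intron abuts the finger); VQR
within ±2 codons of the final R of a `VQR`/`QVQR` match inside the
finger; OTHER inside the domain ±10 residues; otherwise NONE. The two
anchor regions are disjoint by construction, so PR and VQR calls are
mutually exclusive. Phase is reported but not used to discriminate —
no published phases exist to calibrate against. The half-width of ±2
codons absorbs small annotation jitter and is configurable.

## RW grammar

Architectures are token strings built from sorted annotation rows:
overlaps >50% mutual resolve to the higher score, adjacent LRR rows
within 30 residues collapse, WRKY tokens carry their group call. The
shipped grammar (`rw_grammar()`, an editable TSV) encodes:

```
RW1  TIR NB-ARC LRR WRKY(IIe)
RW2  TIR NB-ARC LRR WRKY(III) [WRKY(III)]
RW3  PAH WRKY(I_NT) WRKY(I_CT) NB-ARC [MAPKKK]
RW4  TIR NB-ARC LRR WRKY(III)
RW5  [B3] LRR NB-ARC LRR WRKY(IIe)
RW6  NB-ARC LRR WRKY(III) [WRKY(III)] [NAC]
RW7  LRR WRKY(III) WRKY(IId) CAMB WRKY(IIc)   (wildcard WRKY slots)
RW8  WRKY(III) NB-ARC LRR
```

Matching is strict — extra tokens fail, except leading/trailing
`OTHER:*` tokens, which are ignored; bracketed tokens expand 0/1.
RW7's slots additionally accept unclassifiable WRKY tokens, because its
known members carry truncated domains. A single-WRKY(III) TIR
architecture is inherently ambiguous between RW2 and RW4; a species
`lineage_hint` resolves it (strawberry → RW2, soybean → RW4) and is
never allowed to override an unambiguous match. Architectures with a
WRKY token and an R domain but no rule are `RW_NOVEL`; everything else
is `NOT_RW`.

## Distance phylogenetics

Ambiguous positions are gaps and `X` — the only ambiguity classes in
the data model. `p_distance()` supports pairwise deletion (per-pair
column exclusion) and complete deletion; a pair with zero comparable
sites is an error naming the pair. `poisson_correct()` is
`d = −ln(1−p)`. `site_coverage_filter()` *retains* columns with
coverage ≥ the threshold, because the stated rule eliminates positions
with coverage strictly below 95%. Neighbor joining delegates to
`ape::nj()`; negative branch lengths are clamped to zero with a warning
and a recorded count (topology unchanged). `bootstrap_support()`
resamples columns with replacement, re-runs the whole distance pipeline
per replicate, and reports per-bipartition support on the full-data
tree; the RNG is seeded once per call and replicate *r* consumes the
*r*-th draw, so results are reproducible for a fixed replicate count
but not stream-stable when the count changes. Taxon order is
canonicalized internally so supports are invariant to input
permutation.

## What the generator emulates — and what it does not

`generate_proteome()` plants group templates inside random linkers
drawn from the 19 residues excluding W (no accidental signatures);
point mutations hit only non-diagnostic template positions and
substitute from residues excluding W, C and H, so mutations cannot
fabricate signatures or chelators. `generate_gene_models()`
reverse-translates with a fixed one-codon-per-residue table, inserts
one GT…AG intron (60–300 nt) exactly at the planned anchor and phase,
and emits every second model on the minus strand with mirrored
coordinates. `generate_rw_table()` emits one grammar witness per
requested family with optional tokens toggled by a seeded coin, plus
NLR-only and WRKY-only decoys.

Defaults are the package's study conditions: 10 proteins per group,
mutation rate 0.05 (roughly within-group divergence while keeping
diagnostics intact; the hard cap is 0.2), linkers 20–80 residues,
intron plan 50 PR / 50 VQR / 20 OTHER / 20 NONE, one witness per RW
family with two decoys of each kind.

Passing tests on this material shows that the *rules are implemented
faithfully with respect to their stated diagnostics*. It does not show
robustness to what real proteomes add: domain boundary erosion,
signature variants outside the library, fingers outside the envelopes,
fragmented gene models, overlapping or nested domain annotations from
real HMM scans, or alignment error — none of which the generator
produces. The four-lineage clade checks use template-derived domains in
a shared coordinate frame, which sidesteps multiple sequence alignment
entirely; with real sequences, alignment quality would dominate.

## Problem sizes and runtime choices

The shipped tests use 60–300 proteins per scenario, refinement accuracy
at n = 100 per group, 100 random 5–8 leaf trees for NJ consistency, and
200 bootstrap replicates for the clade checks (1000 remains the
pipeline default). These sizes keep the full suite fast while leaving
every statistical conclusion comfortably away from its threshold
(observed accuracies are 1.0 against a 0.95 bound).

## Known limitations

* Groups IIa/IIb and IIc/IId/IIe are separated only by
  nearest-reference distance; with synthetic references this is exact
  by construction, with real data it stands in for true tree placement.
* The published 664-domain supplementary alignment is not packaged, so
  the coverage-filter check against its printed dimensions (664 rows
  in, 58 columns out) cannot run here; the filter semantics are tested
  on constructed alignments instead.
* `read_gff3()` expects clean CDS features with `Parent` attributes —
  no GTF, no alternative splicing, no splice-site validation.
* The RW catalogue records family membership only where the source
  text states it; most entries are deliberately unassigned.
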
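---
title: "Consensus enzyme design and pathway arithmetic with consenzyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus enzyme design and pathway arithmetic with consenzyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consenzyme)
```

## The problem

Expressing eukaryotic enzymes in bacterial hosts often fails or yields poorly
active protein. One remedy is *consensus* ("wholesale") design: instead of
transplanting any single natural homolog, a new protein is composed by taking,
at every column of a multiple sequence alignment (MSA) of a homolog family,
the most frequent residue. Averaging over the family's evolutionary history
tends to produce thermostable, functional sequences. The motivating
application is a *trans*-cinnamic acid decarboxylase designed from fungal
ferulic acid decarboxylase (FDC) homologs and expressed in *Pseudomonas
putida*, completing a two-step pathway

$$\text{L-Phe} \;\xrightarrow{\text{PAL}}\; t\text{CA}
  \;\xrightarrow{\text{FDC}}\; \text{styrene},$$

where each step is 1:1 molar. `consenzyme` implements the full in-silico
side of that workflow — homolog stratification, consensus derivation, gene
design, design scoring — plus the pathway's quantitative arithmetic, and a
synthetic-data module so every stage can be exercised and tested offline.

## The consensus rule cascade

For an MSA with members $s_1,\dots,s_n$ and columns $j = 1,\dots,L$, let
$c_j(x)$ be the count of character $x$ (gap `-` included) in column $j$. The
per-column decision, in order:

1. **Gap deletion.** If `-` is the *unique* most frequent character, the
   column is deleted — the designed protein simply lacks that residue
   (rule `gap_delete`). A `majority-gap-deletes` variant requiring a strict
   gap majority is also provided.
2. **Plurality.** If a unique most frequent residue exists, it is chosen
   (rule `plurality`; labelled `gap_rescue` when gaps are present but
   outnumbered — the column "was due to non-matching amino acids" and the
   highest-proportion residue wins).
3. **Tie.** If two or more residues tie for the plurality, one of the tied
   set is selected. The original procedure chose "indiscriminately"; for
   reproducibility the default here is the alphabetical minimum, with a
   `seeded-random` mode that draws uniformly from the tied set under a
   recorded seed. Which convention produced the original designs is unknown,
   so both are first-class.
4. **No plurality at all** (every character in the column distinct):
   * with gaps present, a small neutral **filler** residue is inserted —
     alanine by default, chosen for its minimal effect on folding;
   * with the column fully occupied, a **polar uncharged fallback** keeps
     the design's charge neutral: asparagine if it occurs in the column,
     else glutamine if it occurs, else asparagine. The implemented reading
     applies the filler only to gap-containing columns and the N/Q fallback
     only to fully occupied ones, which keeps the two rules disjoint. The
     original procedure states both fallbacks without a decision tree; this
     reading is the package's own.

Every column yields a `ColumnDecision` (action, residue, rule, counts), so a
design is fully auditable (`write_decision_table()`). Degenerate alignments
whose every column is gap-deleted raise a classed error rather than
returning an empty protein.

When only an alignment program's *consensus row* is available (MultAlin
emits rows where weak columns carry class symbols), `consensus_from_row()`
expands each symbol through a configurable `symbol_map()` — default
`!` = I/V, `$` = L/M, `%` = F/Y, `#` = N/D/Q/E(/B/Z), the published MultAlin
convention — and treats the expanded set as an equal-frequency tie. The map
is overridable because the symbol legend actually used for the original
designs is not reproduced in the main text of the motivating study.

## Homolog stratification

`pairwise_identity()` aligns two proteins globally (BLOSUM62, affine gaps,
open 10 / extend 0.5 — all configurable) and reports identity under two
denominators: `aligned-columns` (matches over columns where neither symbol
is a gap; the default) or `shorter-sequence`. The source identities for the
original tiers came from BLAST, whose local-alignment identity convention
cannot be reproduced exactly from sequences alone; the gap-excluded global
denominator is the closest well-defined analogue, and both modes are
exposed. `stratify_by_identity()` retains candidates with identity
*strictly above* the threshold, mirroring ">60 %" / ">50 %" tier
definitions as printed.

## Gene design

`back_translate()` converts a designed protein to DNA:

* **max-frequency** mode takes each residue's most frequent codon
  (deterministic);
* **weighted-sampled** mode draws codons with probability equal to their
  within-amino-acid relative frequency (seed-reproducible).

One stop codon — the table's most frequent — is appended, so a 502-residue
protein yields a $3 \times 503 = 1509$ nt CDS. Forbidden motifs (defaults:
`GGATCC`/BamHI and `GAATTC`/EcoRI, the cloning sites that flank the
synthetic gene and therefore must not occur inside it) are removed by
re-choosing, among the codons each motif occurrence spans, the synonymous
substitution with the smallest frequency loss that clears the site; both
strands are scanned, and an occurrence no synonymous change can remove
raises a design-infeasible error naming the position. Commercial
codon-optimization pipelines are proprietary, so correctness here means
translation equivalence plus constraint satisfaction — never nucleotide
identity with any deposited gene.

The bundled codon-usage table (`default_codon_table()`) is a *constructed*,
GC-rich, *P. putida*-style table (strong G/C third-position preference,
TGA-favored stops), shipped as
`extdata/pputida_codon_usage_synthetic.tsv`. It is synthetic — built by a
deterministic rule, not measured from a genome — because the actual usage
reference behind the original optimization is unknown; any organism's
measured table can be supplied as a three-column TSV.

## Scoring designs against a reference

`global_align()` wraps Needleman–Wunsch global alignment with affine gaps
(via Biostrings); traceback ties are resolved by the engine's fixed rule, so
results are deterministic. `count_differences()` counts alignment columns
where the two symbols differ, **counting every gap column as one
difference** — the only reading under which a 502-residue design can differ
from a 503-residue reference by a finite residue count; the convention is
stated here prominently because difference counts depend on it.
`check_key_residues()` maps 1-based reference positions (the field's
"F397"-style numbering) through the alignment and reports the aligned
target symbol and a conserved/substituted verdict per position. Acceptance
checks re-run the difference counts over a small gap-penalty grid
(open 8/10/12 × extend 0.5/1) to confirm they are not a knife-edge artifact
of the default penalties.

## Pathway arithmetic

With 1:1:1 molar stoichiometry, mass concentrations interconvert by molar
mass ratios: $c_{to} = c_{from} \cdot M_{to}/M_{from}$, with
$M_{\text{L-Phe}} = 165.19$, $M_{t\text{CA}} = 148.16$,
$M_{\text{styrene}} = 104.15$ g/mol (standard values, exposed as
parameters). Thus 600 mg/L L-Phe corresponds to
$600 \times 104.15 / 165.19 \approx 378$ mg/L styrene;
221 mg/L styrene from 5 g/L glucose is a yield of 44.2 mg/g; and a
8.5 t/day scenario annualizes to 3100 t/yr at two significant figures.
`initial_rate()` estimates initial consumption/production rates as the
ordinary least-squares slope over all samples in the first assay window
(default 2 h, boundary **inclusive**, since "the first two hours" includes
the 2 h sample); OLS over the window is the documented choice where a
"trendline" could also mean a two-point slope. Signs are retained (negative
= consumption). `conversion_fraction()` flags, but never clamps, fractions
above 1, which can only arise from measurement noise. The 8.5 t/day
biorefinery figure is treated as an input, not re-derived, because the
sugar-to-Phe fraction assumption behind it is not stated with it.

## Synthetic data: what it emulates, and what it does not

`simulate_family()` draws a uniform-random ancestor and derives members by
per-site substitution (probability $p$, uniform over the 19 alternatives)
and geometric-length deletions recorded as gaps in the ancestor frame, so
the "alignment" is exact by construction. Mean identity to the ancestor is
$\approx 1 - p$, which lets stratification tests place families on either
side of the 0.5/0.6 thresholds ($p = 0.30 \Rightarrow \approx 70\%$
identity, $p = 0.45 \Rightarrow \approx 55\%$). The model is deliberately
minimal: no rate matrix, no tree-structured divergence, no site-rate
heterogeneity, no insertions. The consensus procedure is frequency-only, so
a richer evolutionary model would add no power to tests of the rule
cascade — but passing these tests says nothing about alignment *quality* on
real, externally aligned families, where MSA errors dominate.

`simulate_bioconversion()` produces the piecewise-linear resting-cell
pattern: substrate falls at `true_rate` from $S_0 = \text{rate} \times
\text{plateau\_time}$ to zero, the product mirrors the consumed substrate
under pathway stoichiometry, and i.i.d. Gaussian noise (floored at zero) is
added. With noise off, `initial_rate()` recovers the true rate exactly; with
noise on, OLS is unbiased, which the tests check across 200 seeds. Real
time courses have lag phases, saturation curvature and heteroscedastic
assay error — none of which are simulated, and none of which the first-two-
hours slope convention is sensitive to by design.

## The synthetic reference set

The original reference enzyme and the two designed proteins live in the
source study's supplementary material and are not redistributed with this
package. `synthetic_fdc_references()` therefore constructs, from fixed
internal seeds, a labelled-synthetic trio with the same *relational*
structure: a 503-aa reference carrying the five catalytic positions
(I189, Q192, I330, F397, I398); a 502-aa consensus design differing from it
by exactly 114 residues (113 substitutions plus one deletion) with all five
positions conserved; and a 503-aa divergent design differing by 223/230
residues from reference/consensus with F397Y and I398T.
`synthetic_fdc_family()` builds an 8-member alignment (the reference
stand-in plus seven derived homologs, all in the >60 % identity tier) whose
consensus under the default policy is exactly the 502-aa design — including
one gap-plurality column that exercises the deletion rule. All headline
numbers are recomputed from these objects at run time by the pipeline
itself; what this demonstrates is that the machinery reproduces the
documented relationships, not that it regenerates the original deposited
sequences, which would require the original alignment inputs.

## Problem sizes and numerical choices

The test suite runs at desk scale: 10,000 random small families (≤ 5
members × ≤ 8 columns) against a brute-force consensus oracle; exhaustive
alignment-score enumeration for sequences up to 8 residues; 1,000 random
proteins (1–600 aa) round-tripped through gene design in both modes; 500-aa
families for ancestor-recovery checks (≥ 99 % recovery at $p = 0.05$,
$n = 8$, monotone in $p$ over 0.01/0.05/0.20); 200 seeds for rate-recovery.
Ties everywhere are resolved deterministically unless a seeded-random mode
is explicitly requested; all randomness flows through per-call seeds, and
library calls restore the caller's RNG state.

## Limitations

* Consensus design is frequency-only: no phylogenetic weighting, no
  structure-awareness. Highly redundant families bias the consensus toward
  the over-represented clade.
* Identity stratification on globally aligned sequences will not exactly
  reproduce BLAST-reported identities; retained-set sizes are additionally
  database-version-dependent and are not meaningful reproduction targets.
* Gene design optimizes codon frequency only — no GC windowing, mRNA
  structure, or harmonization.
* The bundled codon table and the reference trio are synthetic stand-ins,
  clearly labelled; swap in measured tables and real sequences for
  production use.
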
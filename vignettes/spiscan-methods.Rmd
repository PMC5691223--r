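---
title: "Methods: SPI domain detection, annotation and expression analysis"
author: "spiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPI domain detection, annotation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiscan)
library(dplyr)
```

`spiscan` annotates serine protease inhibitor (SPI) proteins: it detects
the seven common insect SPI domain families on raw sequences, predicts
inhibitory specificity from P1 residues, maps disulfide frameworks,
processes Pacifastin precursors, classifies thioester-containing
proteins, builds neighbor-joining trees, and calls venom-gland-specific
genes from expression data. This vignette records the models, the
tunable parameters, and the design decisions behind each stage — and
what the passing test suite does and does not demonstrate about real
data.

## Cysteine-framework detection

Canonical SPI domains (Kazal, Pacifastin, TIL, Kunitz/BPTI, WAP) are
small and disulfide-locked; what survives sequence divergence is the
number and spacing of the framework cysteines. `scan_cysteine_framework()`
therefore matches PROSITE-style spacing envelopes: for a family with
$k$ cysteines, $k-1$ windows $(\min_i, \max_i)$ constrain the number of
residues between successive framework cysteines. The default envelopes
(see `default_spacing()`) are deliberately generous, e.g. Kazal
`C-x(1,12)-C-x(4,12)-C-x(1,14)-C-x(4,16)-C-x(6,30)-C`. They are **this
package's own defaults**: no published per-family spacing bounds back
them, so applying the scanner to a real proteome is a calibration
exercise, typically by fitting the windows on a curated alignment of the
target clade.

Matching is deterministic: the scanner walks cysteines left to right,
prefers the smaller admissible gap when several cysteines fit a window
(leftmost-compact rule), forbids overlapping hits within a family, and
pads hit coordinates by a 3-residue flank clipped so adjacent hits stay
disjoint. All coordinates are 1-based inclusive.

Because a cysteine run satisfying a 10-cysteine TIL envelope almost
always contains a 6-cysteine sub-chain satisfying the Kazal envelope,
raw per-family scans overlap by construction. `detect_spi_domains()`
arbitrates overlapping canonical hits per protein: the more specific
pattern wins (larger framework, then higher score, then leftmost). This
mirrors how domain databases resolve nested pattern matches. The
remaining truly ambiguous case — two six-cysteine families claiming the
same run — is rare under the default windows and is excluded from the
synthetic ground truth by rejection sampling, because no motif-level
rule can break that tie.

## Serpin hinge, RCL and P1

Inhibitory serpins conserve a small-residue consensus in the hinge
(P17–P9) at the N-terminal end of the reactive center loop.
`detect_serpin_domain()` searches the hinge consensus as the regular
expression `[ED].{0,2}G[TS][EKRQ][AG][AGS][AGST][AGSTV]` and requires at
least 200 residues upstream — the motif must sit in the C-terminal third
of a plausible 300–500-residue serpin domain. Motifs closer than 250
residues collapse into one domain; well-separated motifs yield one hit
each, which is how twin-domain serpins are reported (sub-domain labels
`gene-1`, `gene-2`).

`locate_rcl()` transfers coordinates from an annotated reference serpin
by global pairwise alignment (BLOSUM62, gap open 10, extension 1 —
deterministic and standard). The packaged reference is **synthetic**,
with fixture-defined hinge start and P1 position; it plays the role a
structurally characterized serpin plays in practice without asserting
any real protein's numbering. P-numbering follows the standard serpin
convention: hinge = P17–P9, P1 = last RCL residue before the scissile
bond, P1′ immediately after, so `p1_position = rcl_end - 1`. When fewer
than half of the reference RCL columns align to positively scoring
query residues the RCL is declared unmappable, the behaviour expected
for degenerate serpins missing the definitive hinge residues. The hinge
consensus score is the fraction of the nine positions carrying a
preferred residue; 6/9 or better flags an inhibitory-competent hinge.

P1 specificity follows the classical substrate-mimicry rules: Arg/Lys ⇒
trypsin-like; Phe/Tyr/Leu/Ile ⇒ chymotrypsin-like; Ala/Val ⇒
elastase-like; all other residues yield no call. Multi-domain
inhibitors aggregate the union of per-domain calls, which is monotone:
adding a domain never removes a predicted activity.

## Canonical P1 anchors and disulfide maps

The disulfide connectivity per family (Kazal 1–5/2–4/3–6, Kunitz
1–6/2–4/3–5, Pacifastin 1–4/2–6/3–5, WAP 1–6/2–7/3–5/4–8, TIL
1–7/2–6/3–5/4–10/8–9) is fixed biology and is applied as a constant
table. The **P1 anchor offsets** (`p1_anchors()`: e.g. Kazal anchor
Cys2 + 2) are a pragmatic device: in practice P1 residues are read off
curated alignments, and no closed-form rule exists. Fixed offsets make
the pipeline deterministic and let the synthetic generator plant P1
residues the pipeline must recover; on real sequences the offsets are a
calibration target, and genes whose P1 cannot be assigned keep an empty
specificity set rather than being called non-inhibitors.

## Pacifastin precursor processing

Pacifastin precursors carry a signal peptide and several inhibitor
domains that are proteolytically separated at dibasic sites (RR, RK or
KK — KR is deliberately not a site). `split_precursor()` cleaves
C-terminal of the pair, a bookkeeping choice (the processing chemistry
is not modelled) that conserves total length; whether the enzyme cuts
N- or C-terminal of the pair is unknown, and the choice is recorded in
the output. Sites inside or within one residue of a detected domain
span are suppressed so no inhibitor domain is ever bisected, and
overlapping usable sites resolve greedily left to right. Products tile
the precursor exactly; products without a complete domain are flagged
`domainless`.

## TEP classification

TEP features are motif-level: the thioester `[GD]CGEQ` (canonical
`GCGEQ` preferred when both occur), a catalytic His in the window
thioester + 100 ± 20 (the literature says only "approximately 100
residues", hence the configurable ±20; nearest-to-+100 wins, ties to
the smaller position), the `FPETW` bait-region motif, and the Cys
fraction of the last 150 residues (cysteine-rich at ≥ 0.06). The rule
cascade — canonical motif + His + bait ⇒ A2M; canonical motif + His ⇒
iTEP; variant motif or missing His ⇒ atypical; no motif ⇒ not a TEP —
is a motif-level surrogate for the phylogenetic placement practitioners
ultimately rely on; `nj_tree()` on a user-supplied reference panel can
refine the call, and a divergent gene whose tree placement disagrees
with its motif profile should carry the tree placement as a note rather
than a class change.

## Neighbor joining and bootstrap

Distances are p-distances (mismatches over compared columns) with
pairwise deletion by default — the simplest, closed-form choice for
protein alignments, configurable to complete deletion. `nj_tree()` is
the Saitou–Nei agglomeration with the standard Q-criterion and
two-point branch lengths, the last three lineages resolved by the
three-point formulas. Determinism is guaranteed by breaking Q ties on
the lowest index pair; negative branch-length estimates are clamped to
zero with the deficit recorded in an attribute (the convention used by
the common desktop implementations). Bootstrap supports resample
columns with replacement, rebuild distance + NJ per replicate, and
report the percentage of replicates containing each internal
bipartition of the full-data tree; replicates in which some pair has no
comparable column are discarded with a warning. Supports are integer
percentages on internal node labels; taxa are sorted before resampling
so supports are invariant to input order.

## Expression analysis

The venom-specificity call preserves the three-part threshold exactly:
BH-adjusted p < 0.001, log2(FPKM~VG~/FPKM~carcass~) > 1 with a
pseudocount of 1 on both sides (how zeros were originally handled is
unstated; the pseudocount makes the ratio total), and FPKM~VG~ > 10.
The p-value engine behind it is a declared, deterministic stand-in for
a count-based two-library differential test: FPKM values are scaled to
pseudo-counts (× 10) and tested with an exact one-sided binomial test
against a 50:50 split. The engine is swappable; the scientific content
lies in the threshold. Genes never exceeding FPKM 1 in any sample are
flagged putative pseudogenes, and profiling uses log2(FPKM + 1).

A consequence worth recording: under the binomial stand-in, any gene
passing both the FPKM gate (> 10) and the ratio gate (> twofold)
necessarily has a vanishing p-value, so a gene violating *only* the
p-gate cannot exist. The synthetic expression panel therefore plants
its "p-gate" near-misses with carcass expression close to venom-gland
expression, which also fails the ratio gate; the truth table records
this.

qPCR quantification is the standard 2^−ΔΔCt^: replicates are averaged
per (gene, sample) before any differencing, ΔCt = Ct~target~ −
Ct~reference~, ΔΔCt is taken against the calibrator sample (fold 1 by
construction), and shifting every Ct by a constant leaves folds
unchanged.

## Physicochemical properties

Molecular weight sums average residue masses plus one water; unknown
`X` residues contribute the mean residue mass. The isoelectric point
bisects the Henderson–Hasselbalch net charge over the termini and the
D/E/C/Y/H/K/R side chains with the Bjellqvist-style pKa constants used
by the familiar web calculators, to 0.01 pH — matching their spirit,
not their last digit. The signal-peptide check is an explicitly labeled
heuristic (a hydrophobic ≥ 8-residue stretch with mean Kyte–Doolittle
hydropathy > 1.6 in the first 30 residues, preceded by a basic residue
or starting within the first 6 positions); it is not a replacement for
a dedicated predictor and can simply be ignored downstream.

## The synthetic generators, and what the tests show

Every generator is deterministic given its seed, and its truth tables
share the detector's coordinate schema, so recovery metrics are joins.

- `generate_proteome()` plants domains **inside** the detection
  windows, with cysteine-free backgrounds in planted genes, ≥ 31-residue
  linkers (longer than any window maximum, so no chain bridges two
  domains), and rejection sampling of (a) decoys containing any
  framework-compatible run or qualifying hinge motif (decoy cysteine
  frequency ≤ 0.02), (b) same-size cross-family ambiguous domains, and
  (c) backgrounds faking a serpin hinge. Synthetic serpins are diverged
  copies (15% substitutions, no indels) of the packaged reference, so
  alignment-based RCL location has genuine homology to work with. The
  default architecture plants 12 domains over 9 genes per canonical
  family (60 domains), 6 serpin genes including one twin-domain gene,
  one TEP per class, and 200 decoys — the scale at which the acceptance
  tests measure precision and recall.
- `generate_expression()` plants 8 venom-specific genes passing all
  three gates with margin (VG ≥ 20, ratio ≥ 4×), per-gate near-misses,
  5 pseudogenes and low-variance background genes (per-sample noise SD
  0.15 on the log2 scale, small enough that a background gene passing
  the ratio gate by chance is vanishingly rare) across a nine-sample
  stage/tissue panel.
- `generate_ct()` uses Ct = baseline − log2(fold) + N(0, sd); with the
  default three replicates and sd 0.1, a Monte-Carlo calculation puts a
  single fold estimate within ±25% of truth with probability ≈ 0.997,
  which is the basis of the ≥ 95%-of-genes tolerance used in the tests
  (200 genes).
- Phylogenetics is validated on additive matrices from random trees
  (n ≤ 8, branch lengths 0.1–1, 200 cases), against an exhaustive
  least-squares quartet oracle, and on a two-cluster alignment whose
  central split must reach 100% bootstrap support.

Passing these tests shows the pipeline implements its stated rules
exactly and recovers planted structure whose generating process matches
those rules. It does **not** show that the default spacing windows,
hinge regex, P1 offsets or the binomial expression stand-in are
well-calibrated for any real proteome or RNA-seq design: synthetic
backgrounds are i.i.d. residues, real domains drift outside any fixed
envelope, real P1 positions come from alignments, and the original
differential-expression engine had its own statistics. Those are
calibration tasks the package exposes through its configuration
arguments, not properties its tests can certify.

## Known limitations

- No HMM-based detection; accessory (non-inhibitor) domains are
  accepted as precomputed annotations, never detected.
- Multiple sequence alignment is out of scope; trees require pre-aligned
  input, and only pairwise alignment to a reference is implemented.
- No genome coordinates: scaffold clustering and gene-structure
  analyses are not addressed.
- The serpin detector assumes the hinge consensus; strongly diverged or
  non-inhibitory serpins (degenerate hinges) are reported only through
  the unmappable-RCL path.
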
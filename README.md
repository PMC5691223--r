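# spiscan

Genome-wide annotation and characterization of **serine protease
inhibitor (SPI) genes** in insects, built around the SPI repertoire of the
pupal parasitoid wasp *Pteromalus puparum* (57 genes, 7 domain families,
three mode-of-action categories).

Serine proteases drive digestion, development and innate immunity, and
their inhibitors keep those cascades in check. Insect SPIs fall into three
mechanistic classes:

- **Serpins** — metastable single-domain inhibitors that trap their target
  protease covalently after cleavage of the reactive center loop (RCL).
  The residue at the P1 position of the scissile bond sets the target
  class: Arg/Lys ⇒ trypsin-like, Phe/Tyr/Leu/Ile ⇒ chymotrypsin-like,
  Ala/Val ⇒ elastase-like.
- **Canonical inhibitors** (Kazal, Pacifastin, TIL, Kunitz/BPTI, WAP) —
  small, disulfide-stabilized domains binding reversibly in substrate-like
  mode, recognizable by family-specific cysteine frameworks
  (6/6/6/8/10 cysteines; disulfide connectivity 1–5, 2–4, 3–6 for Kazal;
  1–6, 2–4, 3–5 for Kunitz; 1–4, 2–6, 3–5 for Pacifastin; 1–6, 2–7, 3–5,
  4–8 for WAP; 1–7, 2–6, 3–5, 4–10, 8–9 for TIL).
- **Alpha-2-macroglobulins (A2M)** — large thioester-containing proteins
  (TEPs) carrying a diagnostic GCGEQ thioester motif, a catalytic His
  ~100 residues downstream and, in true A2Ms, an FPETW bait-region motif.

`spiscan` implements the full annotation pipeline as composable,
tibble-in/tibble-out R functions:

| stage | functions |
| --- | --- |
| I/O | `read_fasta()`, `read_alignment()`, `read_inventory()`, `read_fpkm()`, `write_newick()` |
| domain detection | `scan_cysteine_framework()`, `detect_serpin_domain()`, `detect_a2m_like()`, `detect_spi_domains()`, `classify_gene()` |
| serpin annotation | `locate_rcl()`, `classify_specificity()`, `hinge_consensus_score()`, `annotate_serpins()` |
| canonical annotation | `assign_disulfide_pairs()`, `call_domain_p1()`, `aggregate_specificities()`, `flag_mixed_type()` |
| Pacifastin processing | `find_dibasic_sites()`, `split_precursor()` |
| TEP classification | `find_thioester_motif()`, `check_catalytic_his()`, `find_bait_region()`, `classify_tep()` |
| phylogenetics | `p_distance()`, `nj_tree()`, `bootstrap_support()`, `is_monophyletic()` |
| expression | `log2_profile()`, `flag_pseudogene()`, `call_venom_specific()`, `bh_adjust()`, `ddct()` |
| properties | `molecular_weight()`, `isoelectric_point()`, `signal_peptide_heuristic()`, `count_summary()` |
| synthetic data | `generate_proteome()`, `generate_pacifastin_precursors()`, `generate_tep_sequences()`, `generate_expression()`, `generate_ct()` |

Because the underlying genome and transcriptomes are unpublished, every
stage ships with a ground-truthed synthetic generator, and the packaged
gene inventory (`spi_inventory()`) transcribes the published per-gene
domain table.

## Worked example

```r
library(spiscan)

# the packaged P. puparum inventory
count_summary(spi_inventory())[c("total_genes", "by_category")]
#> $total_genes
#> [1] 57
#> $by_category
#>    serpin canonical       A2M
#>        10        44         3

# a synthetic proteome with planted domains, annotated end to end
sim  <- generate_proteome(seed = 42)
hits <- detect_spi_domains(sim$proteins)
dplyr::count(hits, family)
#>   family       n
#> 1 A2M          3
#> 2 Kazal       12
#> 3 Kunitz_BPTI 12
#> 4 Pacifastin  12
#> 5 TIL         12
#> 6 WAP         12
#> 7 serpin       7

# disulfide connectivity of the first Kazal hit: 3 pairs, 1-5 / 2-4 / 3-6
kaz <- dplyr::filter(hits, family == "Kazal")[1, ]
assign_disulfide_pairs(kaz)

# venom-gland-specific genes from a synthetic FPKM panel
ex    <- generate_expression(seed = 42)
calls <- call_venom_specific(ex$fpkm, "venom_gland", "carcass")
glance(calls)
#>   n_genes n_pass alpha min_log2_ratio min_fpkm_vg
#> 1     100      8 0.001              1          10
```

The eight passing genes are exactly the planted venom-specific set: a
gene passes only when the BH-adjusted enrichment p-value is below 0.001,
the pseudocounted log2 venom-gland/carcass ratio exceeds 1, and
venom-gland FPKM exceeds 10.

## What is and is not desk-reproducible

The packaged fixtures and generators reproduce the *rules* of the
analysis, not the original data, which are unpublished or external. The
following published results are therefore **not reproducible** from this
package and are not claimed by its tests: the discovery of the 57 SPI
genes from the *P. puparum* genome (BLAST against an unavailable
assembly); the serpin and TEP tree topologies (external GenBank
reference sequences); the real stage/tissue FPKM heatmap values; the
identity of the real 8 venom-specific SPI genes (the venom filter is
validated on planted synthetic data instead); the scaffold gene-cluster
analysis; and the microbe-induction qPCR measurements. The cysteine
spacing windows and P1 anchor offsets are this package's own defaults
and require calibration before use on real proteomes (see the methods
vignette).
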
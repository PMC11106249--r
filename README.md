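# appendhom

Cross-species assessment of gene-expression homology for ruminant cranial
appendages, with a phylogenetic outgroup.

Bovid horns and cervid antlers both consist of a permanent bony outgrowth
of the skull with a family-specific covering. If the bony core descends
from a single rudimentary outgrowth in the ruminant common ancestor, the
tissues that build it should share derived expression programs. But horn
buds are essentially skin, and bone programs are conserved across all
bone — so shared expression alone proves nothing. `appendhom` implements
the three-step test that deals with both confounders:

1. **Within-species DE**: every test tissue (appendage tissues and
   skin/bone/cartilage comparators) is contrasted against a pooled
   reference of six somatic organs with negative-binomial quasi-likelihood
   GLMs (edgeR; TMM normalization, BH-FDR at 0.05).
2. **Within-species distinctness**: appendage signals that match the
   species' own skin or bone control in the *same* direction are excluded;
   opposite-direction control signals are kept and flagged.
3. **Outgroup conditioning**: a signal shared by both ingroups is called
   *homologous* only if every outgroup tissue is not significant, absent,
   or significant in the opposite direction. With no outgroup the verdict
   is `untestable_missing_outgroup`, by design.

The same logic runs on three evidence modes — per-gene DE, the tau
tissue-specificity index (`tau = sum(1 - x/max(x)) / (n - 1)`, strict
`tau >= 0.9` and relaxed `tau >= 0.75` lists), and competitive gene-set
ranking with inter-gene correlation (`VIF = 1 + (m - 1) * rho`) — plus a
complementary self-organizing-map / k-medoid clustering view with
gap-statistic model selection. A negative-binomial simulator with planted
gene classes (homologous, skin-shared, outgroup-shared, taxon-specific,
tissue-specific, null) makes every stage testable against known truth.

## Worked example

```r
library(appendhom)

sim <- simulate_dataset(sim_config(n_genes = 800, rng_seed = 7,
                                   dispersion_range = c(0.05, 0.2)))
res <- run_pipeline(sim$datasets, analysis_config(rng_seed = 7))
table(res$calls$de$status)
#> excluded_outgroup        homologous        not_shared
#>                38                44                86
score_against_truth(res$calls$de, sim$truth)
#> $sensitivity                  [1] 1
#> $specificity_skin_shared      [1] 1
#> $specificity_outgroup_shared  [1] 0.95
#> $specificity_taxon_specific   [1] 1
#> $false_calls                  [1] 2
```

All 40 planted homologous genes are recovered (`sensitivity = 1`); planted
skin-shared genes are removed by the within-species filter and planted
outgroup-shared bone-program genes by the outgroup condition
(`specificity >= 0.95`), with 2 of 600 null genes leaking through at the
0.05 FDR. The package ships machine-readable transcriptions of the
published strict (9 genes) and relaxed (41 rows) homolog tables;
`shared_proportions()` on the relaxed table reproduces the published
sharing summaries, e.g. 12 of 18 two-month horn-bud genes shared with the
bulk antler tip (0.67) and 16 of 30 four-month genes with the isolated
antler transition zone (0.53).

A thin command-line front end over the same functions is installed at
`inst/cli/appendhom.R` (subcommands `simulate`, `preprocess`, `de`, `tau`,
`gsrank`, `som`, `run-all`).

## Package layout

- `R/` — configuration and I/O (`analysis_config`, `read_counts`,
  `read_gmt`), simulator (`simulate_dataset`), preprocessing
  (`filter_by_expression`, `tmm_factors`, `grouped_lcpm`), DE (`fit_de`,
  `combined_vs_separate`), gene sets (`camera_rank`, `regulator_overlap`),
  specificity (`tau`, `specificity_lists`), clustering (`train_som`,
  `gap_statistic_k`, `cluster_summaries`), homology
  (`within_species_distinct`, `call_homology`, `tau_homology`,
  `shared_proportions`, `build_report`) and the `run_pipeline` driver.
- `inst/extdata/` — the published homolog bullet tables as TSV.
- `vignettes/homology-assessment.Rmd` — the model, its assumptions,
  parameter choices and limitations.
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (hand-coded TMM, brute-force BH, combinatorial
  hypergeometric sums, exhaustive homology truth tables).
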
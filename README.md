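# cernaxis

Discovery of drug-response-predictive ceRNA axes from small-cohort
expression profiles.

## The problem

A competing endogenous RNA (ceRNA) axis couples three transcripts: a
lncRNA and an mRNA that carry recognition elements for the same miRNA
compete for its binding, so the lncRNA "sponges" the miRNA and
de-represses the mRNA.  Given a tiny discovery cohort of treatment
responders and nonresponders (3 vs 3 here) plus a larger validation
cohort (27 vs 18), the task is to find an axis whose three members are
coherently dysregulated between response groups and to turn it into a
qPCR-measurable biomarker panel.

`cernaxis` implements the full screen:

1. **Differential expression** with the random-variance-model (RVM)
   moderated t-test — feature precisions share a Gamma(a, b) prior, the
   moderated variance is `(m·s² + 2/b)/(m + 2a)` on `m + 2a` degrees of
   freedom — plus fold-change and optional Benjamini–Hochberg filters
   (`fit_rvm()`, `rvm_t_test()`, `de_screen()`).
2. **Differential coexpression**: group-specific bipartite lncRNA–mRNA
   networks at `|r| ≥ 0.99`, node importance as *relative degree*
   (degree / max degree), core nodes = top five per class by the
   between-group relative-degree difference (`build_network()`,
   `differential_centrality()`, `core_nodes()`).
3. **Target prediction**, self-contained: canonical seed classes (8mer,
   7mer-m8, 7mer-A1, 6mer), position-weighted Smith–Waterman
   complementarity alignment, and nearest-neighbour duplex free energy
   (`seed_sites()`, `duplex_align()`, `duplex_dG()`,
   `predict_targets()`).
4. **Three-criterion ceRNA screen**: shared MRE, signed anticorrelation
   of the miRNA with both targets, and sponge competition
   (`S_lnc > S_mrna` and `ΔG_lnc < ΔG_mrna`); axes whose lncRNA and mRNA
   are both core nodes are nominated (`screen_axes()`).
5. **Response prediction**: NIPALS PLS classifier on the three axis
   RNAs, Youden operating point from training only, Mann–Whitney AUC and
   paired DeLong comparisons on the validation cohort (`fit_pls()`,
   `evaluate_response_model()`, `compare_roc()`), plus comparative-Ct
   qPCR helpers (`ddct()`, `dct_features()`).

A synthetic-cohort generator (`simulate_cohort()`,
`simulate_sequences()`, `simulate_qpcr()`) plants a ground-truth axis —
expression shifts, sponge-patterned correlations, and real binding sites
in generated sequences — so every stage is testable.  See the methods
vignette (`vignettes/cerna-axis-discovery.Rmd`) for the model, parameter
rationale, and known limitations.

## Worked example

```r
library(cernaxis)
cfg <- pipeline_config(synth = synth_config(rng_seed = 3))
res <- run_pipeline(cfg)
#> simulate: 50 lncRNA, 20 miRNA, 100 mRNA over 51 samples
#> diffexpr: passing lncRNA=1 miRNA=1 mRNA=1
#> coexnet: edges responder=0 nonresponder=1; core lnc=1 mrna=1
#> targets: 2 retained miRNA-target pairs
#> cerna: 1 triples, 1 candidates, 1 nominated
#> response: axis lnc_0001-mir_0001-mrna_0001, validation AUC=0.955 accuracy=0.756

res$screen$nominated[, c("lnc", "mir", "mrna", "r_mir_lnc", "r_mir_mrna",
                         "S_lnc", "dG_lnc", "S_mrna", "dG_mrna")]
#>        lnc      mir      mrna  r_mir_lnc r_mir_mrna S_lnc dG_lnc S_mrna dG_mrna
#> 1 lnc_0001 mir_0001 mrna_0001 -0.9987898 -0.9899475   145 -53.43     91  -23.68

res$roc
#> ROC: AUC = 0.955, accuracy = 0.756 at threshold 0.702
```

The screen recovered exactly the planted triple: the lncRNA site
out-scores (145 vs 91) and out-stabilises (−53.4 vs −23.7 kcal/mol) the
mRNA site, both targets are strongly anticorrelated with the miRNA, and
the three-RNA panel separates validation responders from nonresponders
with AUC 0.955.  Passing `outdir =` to `run_pipeline()` writes a
deterministic result bundle (TSV tables, GraphML networks, model JSON,
run log); identical configuration and seed give byte-identical files.

A thin command-line wrapper is installed at
`inst/scripts/cernaxis-cli.R` (`simulate` and `run` subcommands).

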
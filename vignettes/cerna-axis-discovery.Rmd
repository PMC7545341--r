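---
title: "Methods: screening drug-response-predictive ceRNA axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening drug-response-predictive ceRNA axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaxis)
```

## The scientific problem

Competing endogenous RNA (ceRNA) regulation links three transcripts: a
long non-coding RNA (lncRNA) and an mRNA that share binding sites for the
same miRNA compete for a common miRNA pool, so an abundant lncRNA
"sponges" the miRNA and de-represses the mRNA.  In a treatment-response
setting the hypothesis is that such an axis — lncRNA up, miRNA down, mRNA
up (or the mirror pattern) — differs systematically between patients who
respond to a drug and those who do not, and that the three RNAs together
form a small predictive biomarker panel measurable by qPCR.

The practical obstacle is cohort size.  Discovery cohorts for expensive
multi-omic profiling are tiny (here: 3 responders vs 3 nonresponders),
which rules out standard per-gene testing without variance moderation and
makes every downstream threshold choice consequential.  `cernaxis`
implements the complete screen — differential expression, differential
coexpression, target prediction, the three-criterion ceRNA screen, and
validation-cohort response prediction — together with a synthetic-cohort
generator that plants a known axis, so every stage can be checked against
ground truth.

## Synthetic cohorts with planted axes

`simulate_cohort()` draws log2-scale expression for three RNA classes
(default 50 lncRNA, 20 miRNA, 100 mRNA) over a 3+3 discovery and a 27+18
validation cohort.  For each planted axis a per-sample latent factor
$F \sim N(0,1)$ loads $+\rho$ on the lncRNA and mRNA and $-\rho$ on the
miRNA (`axis_corr`, default 0.9), which induces the sponge correlation
pattern: lncRNA and mRNA positively correlated, both anticorrelated with
the miRNA.  Responders additionally receive a group shift of $d$ total
standard deviations (`axis_effect`, default 2) — positive on the miRNA,
negative on the lncRNA and mRNA.  All remaining features are independent
Gaussian noise with residual standard deviation `noise_sd` (default 0.1).

Two generator choices deserve justification:

* **`noise_sd = 0.1`** encodes the high-precision, strong-signal regime
  implied by the published near-unity correlation cutoffs: coexpression
  edges at $|r| \ge 0.99$ are only attainable when the shared factor
  dominates the residual noise.  With $\rho = 0.9$ and
  $\sigma = 0.1$ the planted pairwise correlations approach
  $\rho^2/(\rho^2+\sigma^2) \approx 0.99$.
* **Asymmetric planted sites.** `simulate_sequences()` gives the planted
  lncRNA a near-fully complementary site (reverse complement of miRNA
  positions 2–22 followed by an A) but gives the mRNA 3'UTR only a
  canonical 8mer seed site.  This encodes the mechanistic premise of
  sponging — the lncRNA binds the miRNA more strongly than the mRNA
  does — and makes the competition criterion below decidable from
  sequence alone.  Decoy transcripts are rejection-sampled to contain no
  6mer seed core of any planted miRNA, so decoys can only enter the
  screen through chance expression correlations, never through real
  binding sites.

`simulate_qpcr()` converts the planted-axis expression to cycle-threshold
tables (`Ct = 35 - expr + noise`) with the internal controls GAPDH, 18S
and U6 at group-independent levels, supporting the comparative-Ct methods
(`ddct()`, `dct_features()`).

## Differential expression: the random-variance model

With $m = n_1 + n_2 - 2 = 4$ residual degrees of freedom, per-feature
variance estimates are hopeless.  The random-variance model treats the
feature precisions $1/\sigma_i^2$ as draws from a Gamma$(a, b)$ prior,
under which the scaled sample variances satisfy
$s_i^2\,a\,b \sim F(m, 2a)$ across features.  `fit_rvm()` obtains
$(\hat a, \hat b)$ by maximum likelihood and `rvm_t_test()` replaces each
$s_i^2$ by the moderated variance

$$\tilde\sigma_i^2 = \frac{m\,s_i^2 + 2/\hat b}{m + 2\hat a},$$

tested on $m + 2\hat a$ degrees of freedom.  Both limits behave
correctly: a vague prior returns the ordinary t-test, a concentrated
prior pools all features to the common variance.  On null data with
precisions drawn from the fitted prior the test is calibrated (type-I
fraction ≈ 0.05 at $p < .05$; see the acceptance tests).

`de_screen()` flags features with fold change $> 1.2$ or $< 0.83$
(inclusive window protected: a feature with FC inside $[0.83, 1.2]$ is
never called, regardless of p-value) and $p < .05$, per RNA class.  Two
FDR modes are provided.  `"q_lt"` additionally requires a
Benjamini–Hochberg $q < $ `fdr_q`.  `"none"` applies no FDR
filter; it reproduces screens whose stated FDR bound excludes nothing.
The pipeline default is `"none"` because at 3 vs 3 samples a
$q < .05$ filter removes essentially every feature and the screen's
operating characteristics are then governed by the planted-recovery and
null-nomination rates reported below.

## Differential coexpression and core nodes

`build_network()` links a differentially expressed lncRNA and mRNA when
their Pearson correlation across one group's samples reaches
`corr_cutoff` (default 0.99), separately for responders and
nonresponders.  `relative_degree()` scales each node's degree by the
maximum degree of its network, and `differential_centrality()` ranks
nodes by $|\Delta rd| = |rd_\text{resp} - rd_\text{nonresp}|$; a node
absent from one network has relative degree 0 there.  `core_nodes()`
keeps the top five nodes per class (ties broken deterministically by
maximum degree, then id).  Core nodes are the hubs whose wiring changes
most between response groups.

## In-package target prediction

Rather than shipping external tool output, the package re-implements the
two classical detection mechanisms and requires agreement of both:

* **Seed classes** (`seed_sites()`): canonical sites are classified from
  the 6mer seed core (miRNA positions 2–7) plus the position-8 match and
  the target adenine opposite position 1, yielding 8mer, 7mer-m8,
  7mer-A1 and 6mer classes, reported at the most specific class per
  locus.
* **Complementarity alignment** (`duplex_align()`): Smith–Waterman local
  alignment with affine gaps (+5 Watson–Crick, +1 G:U wobble, −3
  mismatch, −9/−4 gap open/extend) of the miRNA against the reversed
  target window, with seed positions 2–8 doubly weighted.  A perfect
  22-nt duplex scores $5(7 \cdot 2 + 15) = 145$; a bare 6mer seed scores
  60, which is the default retention threshold `s_min`.
* **Duplex free energy** (`duplex_dG()`): nearest-neighbour stacking
  ΔG°37 summed over consecutive paired columns, using the published
  Watson–Crick stack table (stored in full two-strand notation, closed
  under 180° rotation).  Three simplifications keep the model
  conservative and fully auditable: any stack touching a wobble pair
  contributes a constant −1.0 kcal/mol; the duplex initiation term is
  set to 0 because the screen uses ΔG *comparatively* (lncRNA site vs
  mRNA site for the same miRNA, so a constant offset cancels); terminal
  AU/GU helix ends pay the standard +0.45 penalty.  Interior loops and
  bulges contribute no stacking term.

`predict_targets()` retains a (miRNA, target) pair when some seed site
also reaches `s_min = 60` and `dg_max = -7` kcal/mol in the alignment
re-scoring over a 40-nt window 5' of the site.

## The three-criterion ceRNA screen

`screen_axes()` assembles all (lncRNA, miRNA, mRNA) triples in which the
miRNA has retained sites on both targets (shared MRE), then requires

1. **Shared targeting** — by construction of the triple;
2. **Anticorrelation** — the miRNA is *negatively* correlated with both
   the lncRNA and the mRNA at or beyond `anticorr_cutoff` (signed test:
   a strong positive correlation fails);
3. **Competition** — the lncRNA site strictly beats the mRNA site on
   both alignment score and thermal stability
   ($S_\text{lnc} > S_\text{mrna}$ and
   $\Delta G_\text{lnc} < \Delta G_\text{mrna}$; ties fail).

Axes whose lncRNA *and* mRNA are both core nodes are **nominated**.  The
function-level default for the anticorrelation cutoff is the published
0.99; the *pipeline* default is 0.7 because with six discovery samples
and realistic noise an empirical correlation of 0.99 is an unstable
order statistic — at the generator's default settings the planted axis
correlation concentrates near −0.99 but individual seeds fall short, and
0.7 separates planted from decoy axes essentially without error (decoy
correlations at n = 6 rarely exceed 0.7 jointly against two targets in
the signed direction *and* survive the sequence criteria).

## Response prediction

For the top nominated axis, `fit_pls()` trains a one-response PLS
(NIPALS) classifier on the three axis RNAs of the discovery cohort,
centring and scaling with training statistics only; with all components
retained it coincides with ordinary least squares, which the test suite
exploits as a cross-check.  The classification threshold is the
training-score maximiser of Youden's J, applied unchanged to the
validation cohort.  `evaluate_response_model()` reports the ROC curve,
the Mann–Whitney AUC and the operating-point accuracy;
`compare_roc()` runs paired DeLong tests of the panel against each
single marker.

Two operating regimes matter for interpreting the panel's value:

* With **independent features** (per-feature effect $d = 2$, no latent
  correlation), the three-RNA panel attains mean validation AUC ≈ 0.97
  over 50 simulations, versus ≈ 0.50 under within-cohort label
  permutation.
* With the **correlated default generator** ($\rho = 0.9$), the three
  panel members are nearly collinear along the single latent direction,
  so the panel carries little more information than the best single
  marker and mean validation AUC drops to ≈ 0.82 (the
  information-theoretic ceiling for one effective dimension at these
  settings is ≈ 0.92).  A perfect-separation validation AUC observed on
  one small cohort should therefore be read as an optimistic draw, not a
  stable property of the panel.

## Operating characteristics and honest limitations

The acceptance suite (in `tests/testthat/test-acceptance.R`) fixes the
following properties: calibration of the moderated test; recovery of the
variance prior within 20%; equivalence of the core primitives
(relative degree, seed classification, alignment on short windows, ΔG,
BH adjustment, AUC) with independent brute-force oracles; exactness of
the comparative-Ct example; protection of the fold-change window; and
byte-identical result bundles for identical configuration and seed
(provenance headers deliberately carry no timestamps).

One target is reported honestly as out of reach: requiring the full
pipeline to nominate *exactly* the planted triple in at least 19 of 20
seeds at the default study condition ($d = 2$, 3 vs 3).  The
noncentrality of any calibrated two-sample test at these sizes is
$d/\sqrt{2/3} \approx 2.45$, giving per-feature power ≈ 0.69 even for an
oracle test with known variance; the pipeline needs all three planted
features to pass, and the observed exact-recovery rate is ≈ 0.6.  The
corresponding test is left failing rather than weakening the condition,
because the gap reflects the statistics of the design, not a defect of
the implementation: every failing seed traces to a planted feature whose
moderated p-value lands above .05 by sampling noise.  On cohorts with no
planted signal the pipeline nominates nothing in 100 of 100 seeds.  Note
that "no signal" must mean no group effect *and* no latent correlation:
with the correlation retained, the three high-variance planted features
sit far above the decoy-dominated variance prior, the moderated test
becomes anticonservative for them, and spurious nominations reach ~17%.
This is a real and documented failure mode of variance moderation under
heteroscedastic minorities, and a reason to treat single-cohort ceRNA
nominations as hypotheses for orthogonal validation (qPCR, knockdown),
not findings.
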
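---
title: "Guild-based integration of gut metagenome and serum metabolome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild-based integration of gut metagenome and serum metabolome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildlink)
```

## The analysis problem

Case-control multi-omics studies of rare diseases — the motivating setting is
hereditary transthyretin amyloidosis (hATTR), with around a dozen patients and
two dozen healthy controls — produce three feature tables per cohort: serum
metabolite intensities from untargeted LC-MS, species-level relative
abundances from shotgun metagenomics, and KEGG-ortholog (KO) functional
abundances from the same reads. The scientific questions are which features
differ between groups, whether features move together as *guilds*
(co-abundance groups of species, correlated modules of metabolites), and how
those guilds relate to each other and to clinical phenotypes such as cardiac
amyloidosis.

`guildlink` implements that workflow end to end: QC filtering and
normalization, univariate and latent-variable differential analysis,
correlation-guild detection, co-occurrence networks, set enrichment, ROC
evaluation, cross-block correlation with Sankey chain construction — plus a
synthetic cohort generator with planted ground truth, because in this setting
the method has to be validated on data where the right answer is known.

## The statistical workflow, stage by stage

### Metabolome

1. **QC filter.** Features with a coefficient of variation of 30% or more
   across pooled QC injections are unreliable and removed
   (`qc_filter_metabolites()`, strict `CV < 0.30`).
2. **Auto-scaling.** Each feature is centered and scaled to unit variance
   (`autoscale()`) before multivariate modelling, so influence does not scale
   with mean intensity.
3. **OPLS-DA.** `fit_oplsda()` removes class-orthogonal structured variation
   (Trygg-Wold weights $w_{\perp} \propto p - (w'p)\,w$, extracted
   recursively) and fits one predictive NIPALS PLS1 component on the filtered
   matrix. The response is the class indicator coded $\{0,1\}$ and centered.
   Model quality is summarised by $R^2Y$ (fit) and $Q^2 = 1 - PRESS/SS$
   (7-fold cross-validated prediction), and validated by refitting under
   label permutations (`permutation_test()`, conventionally 99 draws, with
   the add-one empirical p-value so p never reaches 0).
4. **Feature selection.** A metabolite is differential when the two-sided
   equal-variance Student's t-test gives $p < 0.05$ *and* its VIP exceeds 1
   (`differential_metabolites()`). VIP is computed over predictive components
   only, $VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$ with
   $SS_a = q_a^2\, t_a' t_a$, so $\mathrm{mean}(VIP^2) = 1$ identically —
   VIP > 1 means "more influential than average".
5. **Metabolite modules.** Differential metabolites are clustered on the
   Spearman distance $1 - \rho$ with average linkage; the tree is cut at
   height 0.4 (`cluster_features()`). Member intensities are summed into
   module cumulative abundances (`guild_abundance()`).
6. **Set enrichment.** Case-depleted and case-enriched hits are tested
   separately against a GMT library by the exact hypergeometric upper tail
   (`ora_enrichment()`), with the enrichment ratio $k/(nK/N)$ and BH-adjusted
   q-values.

### Microbiome and function

Alpha diversity (Shannon $-\sum p_i \ln p_i$ and Gini-Simpson
$1 - \sum p_i^2$) is compared between groups with the Wilcoxon rank-sum test.
Species are selected by Wilcoxon $p < 0.05$ plus a mean relative-abundance
floor of $10^{-6}$ ("key species"); key species are clustered into CAGs at
height 0.5 on the same Spearman-distance / average-linkage scheme, and their
correlation structure is exported as a signed co-occurrence network keeping
edges with $|\rho| > 0.46$ and BH-adjusted $p < 0.05$ (both strict). KOs are
selected by Wilcoxon $p < 0.05$ and fed to the same ORA machinery against KO
pathway sets.

### Integration

`correlate_blocks()` computes Spearman correlations between any two
entity-by-sample blocks (module x clinical, CAG x module, CAG x clinical),
dropping missing clinical entries pairwise and annotating entries with the
heatmap-star convention (`*` for $p<0.05$, `**` for $p<0.01$ — raw p, because
that is the convention for those displays, whereas the co-occurrence network
uses BH q; the two conventions are deliberately kept distinct).
`build_sankey_links()` chains sign- and significance-qualified legs through
shared modules for tri-partite Sankey displays. `roc_auc()` scores guild
abundances as classifiers via the Mann-Whitney identity
$AUC = U/(n_1 n_0)$ with ties counted 0.5 (apparent AUC, no cross-validation
— the small cohorts make held-out ROC estimates too unstable to report as a
default). `braycurtis_order()` supplies the average-linkage leaf order of
samples for heatmaps.

## Parameters that matter

| parameter | default | where | why |
|---|---|---|---|
| QC CV threshold | 0.30 | `qc_filter_metabolites` | conventional untargeted-MS reliability cutoff |
| p threshold | 0.05 | all differential ops | conventional |
| VIP threshold | 1.0 | `differential_metabolites` | mean(VIP^2)=1, so 1 = average influence |
| abundance floor | 1e-6 | `differential_species` | excludes species too rare to interpret |
| module cut height | 0.4 | `cluster_features` | metabolite modules merge at Spearman rho >= 0.6 |
| CAG cut height | 0.5 | `cluster_features` | species guilds merge at rho >= 0.5 |
| network threshold | 0.46 | `cooccurrence_network` | display cutoff for co-occurrence edges |
| CV folds | 7 | chemometrics | common chemometrics default |
| component entry | dQ2 > 0.01 | `fit_plsda`/`fit_oplsda` | standard parsimony rule |
| permutations | 99 | `permutation_test` | add-one p resolution of 0.01 |

## Design choices where the design was open

* **Distance is $1-\rho$, not $1-|\rho|$.** Modules are summed into
  cumulative abundances; merging anti-correlated features would cancel their
  signal. A flag (`absolute = TRUE`) provides the other convention.
* **Guild labels** are assigned by decreasing guild size with ties broken by
  the lexicographically smallest member id, making the labelling invariant to
  feature input order. Singletons remain as their own guilds; dropping
  unclustered features is a display decision, not an analysis one.
* **Metabolite t-tests run on auto-scaled intensities.** Per feature the
  t-statistic is location/scale invariant, so this equals testing raw
  intensities while keeping a single normalized table in the workflow.
* **Equal-variance t** is the default (a Welch flag exists) to match the
  named test; the Wilcoxon switches to exact enumeration when the combined
  sample size is at most 25 with no ties — at these cohort sizes the exact
  and approximate tests differ materially.
* **"Simpson index" means Gini-Simpson** ($1-D$), the form the vegan package
  returns; `form = "dominance"` gives $D$.
* **One predictive component minimum.** A discriminant model with zero
  components has no scores, VIP, or permutation diagnostics; the
  $\Delta Q^2 > 0.01$ entry rule governs further components.
* **Heatmap stars use raw p; network edges use BH q.** Both conventions
  appear in this workflow's displays and are kept explicitly separate.
* **ORA universe** defaults to the measured features (QC-surviving
  metabolites, all profiled KOs); a reference-metabolome universe is not
  reconstructable offline, and the measured universe is the statistically
  conservative choice for compositional hit lists.
* **Sign convention:** every component is flipped so the feature with the
  largest absolute loading is positive, making fits bit-reproducible.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` plants known structure so recovery can be scored:

* **Metabolite modules** are single-factor equicorrelated blocks on the log
  scale: member $= \sqrt{\rho}\,f_m + \sqrt{1-\rho}\,\varepsilon$ plus a
  standardized group shift for designated differential modules, then
  exponentiated. The latent-factor construction gives an exact target for the
  within-guild correlation (log-scale Pearson $\rho$; Spearman
  $(6/\pi)\arcsin(\rho/2)$), which the tests verify by simulation.
* **Species tables** use the same block construction on log abundances with a
  per-species baseline spread (log-normal rank-abundance), per-entry zero
  inflation, and compositional closure *after* zeroing — correlations are
  induced on the closed scale, which is what the analysis actually sees.
* **KO tables** mix null and group-shifted features, closed to relative
  abundances, with shifted KOs concentrated in two pathway sets so ORA has
  recoverable signal.
* **Clinical flags** are Bernoulli draws through a logistic link from a
  designated driver module's latent factor, giving a known target for the
  integration stage.

Defaults mirror a 13-case / 22-control cohort with 200 metabolites in 10
modules (within-module $\rho = 0.7$, 4 differential modules at a 1.5-SD
log-scale shift), 150 species in 10 CAGs (3 differential), 30% zero
inflation, 300 KOs (30 shifted), 5 QC injections at 10% technical CV with 5%
unstable features at 50% CV, and a logistic slope of 2 for the clinical flag.
Recovery suites scale the cohort up (e.g. $n = 40$, $\rho = 0.8$) because
power at $n = 35$ is limited.

The generator does **not** emulate: raw reads or spectra, realistic taxon or
pathway names, batch effects or injection-order drift, longitudinal
structure, or missing-at-random intensity dropout. Passing recovery tests
therefore demonstrates that the estimators are correct and calibrated under
the generative model, not that any particular real cohort satisfies that
model.

## Numerical and degenerate-input policy

Zero-variance features: auto-scaling sets them to 0 with a warning;
correlation treats them as $\rho = 0$, $p = 1$ with a warning. Zero pooled
variance in the t-test: $p = 1$ for equal means, $p = 0$ with a warning
otherwise. Fully tied rank-sum inputs give $p = 1$. All-zero abundance
vectors are an error for diversity indices and Bray-Curtis. Relative
abundance columns may sum to at most $1 + 10^{-6}$. Cross-validation folds
are interleaved after a seeded shuffle and re-shuffled (with a warning) until
every fold contains both classes. Missing metabolite intensities are a hard
error unless half-minimum imputation is explicitly enabled; missing values in
species or KO tables are always an error.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(seed = 1))
met <- qc_filter_metabolites(co$metabolome, co$qc_sample_ids)
fit <- fit_oplsda(autoscale(met), co$metadata)
dm  <- differential_metabolites(autoscale(met), co$metadata, vip = fit$vip)
sm  <- spearman_matrix(met[dm$feature[dm$selected], ])
mods <- cluster_features(sm$rho, height = 0.4, prefix = "M")
mod_ab <- guild_abundance(met[dm$feature[dm$selected], ], mods)
```

`run_pipeline()` chains every stage (including species, KO, network and
integration outputs) and writes plot-ready TSVs; with a fixed seed its
outputs are byte-identical across runs. The test suite validates each stage
against independent brute-force oracles (step-up BH, pairwise AUC counting,
Wilcoxon enumeration, naive average-linkage agglomeration, hypergeometric
enumeration) and checks calibration and recovery on the generator at the
problem sizes quoted above.

## Known limitations

Two-class designs only (PLS1); no count-model differential abundance or
fold-change shrinkage; no rarefaction; correlational integration only — the
Sankey chains describe concordant correlations, not mediation; apparent
(non-cross-validated) AUC; exact Spearman p only for $n \le 9$ without ties.
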
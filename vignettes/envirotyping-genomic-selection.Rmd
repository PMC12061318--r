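---
title: "Envirotype-aware genomic selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envirotype-aware genomic selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envirogs)
```

# The problem

In multi-environment crop trials most phenotypic variance of traits such
as plant height, flowering time or grain yield is environmental or
genotype-by-environment (G×E), not genetic. A genomic selection model that
sees only marker dosages must average over that variation; one that also
sees *where* and *when* the plants grew can predict it. `envirogs`
implements a complete envirotype-aware pipeline:

1. derive nine daily environmental parameters (EPs) from raw weather;
2. align them to developmental stages via cumulative thermal time and
   reduce each environment to a 9 × 36 stage-window profile (RD_EPs);
3. find *critical windows* — stage spans in which an EP's mean drives
   trait environment means linearly;
4. fit per-genotype reaction norms on those windows, yielding phenotypic
   plasticity (PP) intercepts and slopes;
5. assemble marker + RD_EP feature sets around trait-associated markers
   (TAMs) and train a stacked ensemble regressor evaluated under
   five-fold CV and three cross-environment/cross-genotype scenarios.

A synthetic trial generator with known architecture closes the loop: every
stage of the pipeline can be validated against planted ground truth.

# Environmental parameters

Daily growing degree days use the capped-average formula
$\mathrm{GDD} = (T'_{max} + T'_{min})/2 - T_{base}$ with $T_{max}$ capped
at 86 °F and $T_{min}$ floored at $T_{base} = 50$ °F (maize defaults; a
Celsius mode uses base 10 °C / cap 30 °C). The nine EPs are day length
(DL, h), GDD (°F·day), precipitation (PRE, mm), photosynthetically active
radiation (PAR, MJ m⁻² d⁻¹), relative humidity (RH, %), photothermal time
(PTT = GDD × DL), photothermal ratio (PTR = GDD / DL), diurnal temperature
range (DTR = raw $T_{max} - T_{min}$) and photothermal sensitivity (PTS).

Two details are deliberate:

* **DTR and PTS use raw temperatures.** Capping is a thermal-time device;
  the diurnal range is a physical quantity, so clipping would distort it.
* **PTS is pluggable.** The formula circulates in typographically
  ambiguous form; the default reads the superscripts as squares,
  $(T_{max}^2 - T_{min}^2)\,\mathrm{DL}^2$, and a halved variant
  $(T_{max}/2 - T_{min}/2)\,\mathrm{DL}/2$ plus arbitrary user functions
  are available via `pts_value()`. Because PTS enters the pipeline only
  through correlations and standardised features, the choice rarely
  changes downstream conclusions; it does change the PTS scale.

Missing single values inside a weather column are linearly interpolated
with a warning; whole missing days are an error — thermal-time accumulation
cannot bridge unknown days honestly.

# Stage segmentation and RD_EPs

A stage-threshold table maps cumulative GDD to 36 ordered maize stages
(V0–R6). The exact bounds are population- and calibration-specific, so the
table is configuration: the shipped default (emergence at 100 °F·day,
vegetative stages every 62 °F·day, six reproductive stages to 2700 °F·day)
matches common maize thermal-time scales and is meant to be replaced by a
calibrated table where available; an 11-stage wheat example illustrates
non-maize use. A day belongs to the first stage whose bound exceeds its
cumulative GDD; stages a cool season never reaches are returned empty and
flagged, and empty windows propagate as missing values (never zero).

`reduce_eps()` averages each EP within each stage window — a 9 × 36 matrix
per environment. `sliding_window_means()` enumerates all $W(W+1)/2 = 666$
stage spans per EP; the span mean is the *day-count-weighted* mean of its
member windows (windows have unequal day counts, so an unweighted mean of
window means would not equal the mean of the underlying days).

# Critical windows

For each of the 9 × 666 (EP, span) pairs the Pearson correlation between
per-environment trait means and the span's per-environment EP mean is
computed; spans with $|r| \ge 0.90$ (configurable) qualify. Overlapping
qualifying spans of one EP are collapsed to the best-$|r|$ span — they
describe the same signal — with ties broken by smaller span then earlier
start, making output deterministic. Non-overlapping qualifying spans of
the same EP are all kept. Constant vectors (trait or EP) make the
correlation undefined; such pairs are skipped with a message rather than
failing the search, and environments missing a span value are dropped
pairwise. The search is validated against a brute-force double-loop
enumeration to 1e-12.

With only nine EPs derived from one weather series, several EPs can carry
statistically identical cross-environment signals (GDD, PTT and PTR are
all thermal-time functions). Recovery checks on synthetic data therefore
count a top window as correct when it overlaps the planted stage span and
either names the planted EP or names an EP whose windowed environment
vector is collinear ($|r| \ge 0.9$) with the planted one.

# Reaction norms, variance components, heritability

PP parameters are per-genotype ordinary least squares of phenotype on the
critical-window EP value across environments — intercept and slope, with
$R^2$. Genotypes observed in fewer than three environments are skipped;
a genotype whose environments show zero EP variance is degenerate and
skipped with a message. No shrinkage across genotypes is applied and
environments are unweighted: the estimates stay interpretable as each
genotype's own response line, at the cost of noisier slopes for genotypes
seen in few environments.

`variance_decomposition()` splits a genotype × environment table into G,
E and G×E-plus-residual components (one observation per cell confounds
interaction with error). The default estimator is method-of-moments on
the two-way ANOVA mean squares — exact on balanced data and closed-form,
so tests can verify it independently; negative moment estimates truncate
to zero. A REML option (`lme4`) handles unbalanced tables. Broad-sense
line-mean heritability is $H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2/L)$
with $L$ the number of environments; the error term entering $H^2$ is the
G×E-plus-residual component, since the environment main-effect variance
cancels from genotype comparisons. The divisor reading of the formula is
the standard one: multiplying by $L$ would make heritability *fall* as
replication grows, contradicting its definition.

# Marker features

QC removes markers with > 30 % missing calls and multiallelic markers,
imputes remaining missing calls by the marker's modal genotype class
(real pipelines should impute externally with a haplotype-aware tool
before import), and then removes markers where any *observed* genotype
class has frequency below 0.02 — a class absent entirely does not trigger
the rule. The filter is idempotent.

TAM feature sets expand each trait-associated marker into a flank: every
marker within ±37 kb (default) or, alternatively, the contiguous run of
markers keeping $r^2 \ge 0.5$ with the TAM. Main-TAMs and E-TAMs (G×E
plus PP categories) are kept separate and unioned into All-TAMs. QTL
intervals are the ±1 Mb regions around TAMs, merged when overlapping
(validated against a sweep-line oracle); co-localization between interval
sets counts intervals sharing ≥ 1 bp. Two random baselines mirror the
TAM sets: `random1` draws as many random anchors as there are TAMs and
expands them by the same flank rule; `random2` draws exactly the All-TAMs
feature count.

The multi-locus mixed-model GWAS that produces real TAM tables is outside
this package's scope; the TAM table is the interface. For synthetic
end-to-end tests `association_screen()` provides a simple per-marker OLS
with principal-component covariates and Bonferroni control, calibrated
under the null (family-wise error ≤ 0.05 over 200 simulations).

# The stacked ensemble

Base learners are three gradient-boosted tree configurations (depth-wise
hist, loss-guided hist, DART) and a Bayesian ridge regression fit by
evidence maximisation (no tunable hyperparameters; its regularisation is
set by type-II maximum likelihood on the SVD of the centred design).
Each tuned learner's hyperparameters are found by a sequential
model-based search: a third of the trial budget explores at random, then
candidates drawn from the prior are ranked by a Parzen good/bad density
ratio over past trials (good = top quartile by validation RMSE). The
documented spaces are: learning rate 0.03–0.3 (log), 50–200 rounds,
depth 2–7 (or 8–64 leaves), subsample 0.6–1, column subsample 0.5–1, L2
1e-3–10 (log); the default budget is 50 trials.

Out-of-fold predictions from an internal 5-fold split train the
meta-learner: non-negative least squares with a free intercept, solved
exactly by active-set enumeration (with ≤ 4 base learners all 16 active
sets are checked). Non-negativity makes the combination an interpretable
weighting and prevents the meta-learner from amplifying anti-correlated
noise; the out-of-fold construction prevents it from rewarding
overfitting. Meta-features are the base predictions only (no cascade).
The tuned learners are refit on all training rows, and the whole
procedure is deterministic under its seed (single-threaded boosting).

Accuracy is the Pearson correlation between observed and predicted values
(PCC); a constant vector leaves it undefined and it is reported as
missing, never coerced to zero. Fivefold CV uses unstratified random
folds. The three prediction scenarios hold out, respectively: a random
half of genotypes (all their rows; repeated, default 10 halvings), each
environment in turn, and each environment × a random genotype half with
both excluded from training. Scenario folds are asserted against their
exclusion contracts in the test suite.

Attribution uses permutation importance — the mean PCC drop over repeated
single-column permutations — which is model-agnostic and needs no
explainer library; a SHAP-style backend can be slotted behind the same
interface.

# The synthetic generator

`simulate_trial()` plants a known architecture:

* **Genotypes.** Two haplotypes per individual; LD blocks of length 10
  markers (10 kb spacing) in which each marker copies its neighbour with
  a 5 % per-haplotype flip probability; block-anchor MAF uniform on
  0.1–0.5.
* **Weather.** Per environment, a seasonal temperature sinusoid (mean
  75 °F, amplitude 12 °F) plus an environment offset (SD 4 °F), an
  environment-specific low-order Fourier trajectory deviation (SD 3 °F)
  and daily noise (SD 3 °F); day length from a latitude-like curve;
  showery rainfall. The trajectory deviations matter: with only constant
  offsets every thermal window would carry the same cross-environment
  signal and no specific window would be identifiable — real locations
  and years differ in the *shape* of the season.
* **Phenotypes.** $y_{ge} = \mu + g_m + (\bar\beta + s_g)(E_e - \bar E)
  + u_e + \varepsilon_{ge}$, with $g_m$ the centred sum of main-QTL
  effects, $s_g$ the centred sum of slope-QTL effects, $E_e$ the target
  EP's day-weighted mean over the planted stage window computed through
  the package's own envirotyping path, $\bar\beta$ the population mean
  response (default 1), $u_e \sim N(0, 0.5^2)$ environment main effects
  drawn independently of the EP so E and G×E variance are separately
  controllable, and residual SD 1. All components are stored, and
  phenotypes reconstruct from them exactly.

Defaults (1000 genotypes × 7 environments, 20 main + 10 slope QTL) mirror
a mid-sized hybrid trial. What the generator does *not* emulate: field
spatial trends, heteroscedastic residuals, dominance/epistasis, allele
frequency structure between subpopulations, and trait-specific
correlation between intercept and slope. Passing tests therefore show the
pipeline's contracts are correct and its estimators recover this class of
architecture — not that real-data accuracy will match any published
figure.

# Problem sizes used in validation

The test and acceptance runs use scaled-down instances chosen as the
package's own validation design: reaction-norm recovery on 500 genotypes
× 8 environments (slope-effect SD 1, residual SD 0.25) over 50 generator
seeds; variance recovery on a 200 × 10 balanced table with variances
1/2/1; and the feature-set ablation on 500 genotypes × 2000 markers × 6
environments with a two-learner ensemble and a 10-trial budget per
learner, where mean fivefold-CV PCC orders as
All-TAMs + RD_EPs > All-TAMs > All-SNPs. These sizes make every check
reproducible on a laptop; the pipeline itself has no such limits.

# Known limitations

* The moments variance estimator assumes (near-)balance; markedly
  unbalanced tables should use the REML option.
* The critical-window search tests marginal linear association only;
  nonlinear or multi-EP responses will be found, at best, through their
  linear shadow.
* Modal-class imputation ignores haplotype information; it exists so QC
  is self-contained on synthetic data, not as a recommendation.
* `ld_decay_halfmax()` computes all intra-chromosome pairs within the
  distance cap, which is quadratic per chromosome; subsample markers for
  genome-scale matrices.
* With few environments (< 6) reaction-norm slopes are noisy and the
  critical-window correlation threshold 0.90 is easily met by chance;
  treat windows found in small trials as hypotheses.
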
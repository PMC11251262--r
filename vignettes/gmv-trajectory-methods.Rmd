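---
title: "Methods: individual GMV trajectories, clustering, and downstream association analyses"
author: "gmvtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual GMV trajectories, clustering, and downstream association analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models behind `gmvtraj`, the
assumptions they rest on, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## 1. Per-subject trajectory estimation

Each of the (by default 44) regional grey-matter volumes is modelled by a
random-slope linear mixed model,

$$y_{ij} = \mathbf{x}_{ij}^\top\beta + b_i t_{ij} + \varepsilon_{ij},
\qquad b_i \sim N(0,\tau^2),\quad \varepsilon_{ij} \sim N(0,\sigma^2),$$

where $t$ is age centered at the cohort mean and $\mathbf{x}$ holds an
intercept, the age term and the confounders (sex, site, handedness,
intracranial volume; categorical covariates are treatment-coded with the
lexicographically first level as reference, for determinism). With two or
three scans per person a random intercept *and* slope is not reliably
estimable, so only the slope deviation is random. Variance components are
estimated by REML (`lme4`); maximum likelihood is available via
`reml = FALSE`. The empirical-Bayes slope
$\hat b_i = \tau^2\mathbf{t}_i^\top V_i^{-1}(\mathbf{y}_i - X_i\hat\beta)$,
$V_i = \sigma^2 I + \tau^2 \mathbf{t}_i\mathbf{t}_i^\top$, is the standard
BLUP and is what the trajectory matrix stores (plus the common fixed age
slope, so entries read directly as mm^3/yr rates). Because the age term is
also a fixed-effect column, the BLUPs sum to zero exactly at the fitted
solution — a property the tests exploit.

Choices worth knowing:

* **Centering.** Age is centered at the within-cohort mean before fitting.
  A slope-only random effect is not invariant to age translation; centering
  at the data mean stabilizes it. Shifting all ages by a constant leaves the
  EB slopes unchanged (tested).
* **Two-scan subjects** are retained; their slopes are simply shrunk harder.
  No special-casing.
* **Outlier rule.** A subject is excluded when any regional value at any
  visit falls outside $[Q_1 - 4\,\mathrm{IQR},\ Q_3 + 4\,\mathrm{IQR}]$,
  quartiles per region over all observations. A zero IQR degenerates the
  band to the constant itself, so only deviating values are flagged;
  `k_iqr = Inf` disables the rule. We read the rule per observation per
  region rather than on subject-aggregated volumes.
* **Failed fits** fall back to OLS with $\hat\tau^2 = 0$ (all EB deviations
  zero) and a warning, never silently.

## 2. Dimension reduction and clustering

The slope matrix is z-scored per column (denominator $n-1$) and decomposed
by SVD. The smallest number of components whose cumulative explained
variance reaches the target (default 0.80) is retained; component signs are
fixed by making each rotation column's largest-magnitude loading positive.

k-means uses k-means++ seeding with Lloyd iterations (`stats::kmeans`), best
of `restarts = 50` starts by within-cluster sum of squares; the
decomposition WSS + BSS = TSS is verified to 1e-6·TSS on every solution.

**Choosing k.** Candidate k are admissible when the smallest cluster holds
at least `min_frac` (default 4 %) of the sample. Among admissible k we
maximize the discrete curvature of the WSS curve *on the log scale*,
$\log W_{k-1} - 2\log W_k + \log W_{k+1}$, extending the curve one k in each
direction ($W_1 = \mathrm{TSS}$). The raw-scale second difference was
rejected deliberately: when a small, very distant cluster coexists with a
finer split of the bulk (exactly the structure of interest here), the
absolute curvature is dominated by whichever separation carries more total
variance, and selection flips between k = 2 and k = 3 from seed to seed.
The log-scale curvature compares successive *relative* WSS reductions, is
invariant to rescaling the data, and resolves hierarchical separations
stably. Weak structure is flagged by comparing the best curvature against
the curvature a smooth power-law WSS decay (the behaviour of unstructured
data) would produce; an excess below 0.1 raises a warning.

**Permutation validity.** Each of B permutations shuffles the subject order
independently within every region column — cross-region correlation is
destroyed while every marginal is preserved — then reruns standardization,
PCA and k-means at the observed k. One shared permutation for all columns
would leave the joint distribution invariant and the test powerless, which
is why the per-column reading was adopted. k stays fixed at the observed
value inside the loop (BSS/TSS grows with k, so re-selecting k under the
null would bias the reference distribution). The p-value uses the add-one
correction $p = (1 + \#\{R^{null} \ge R^{obs}\})/(B+1)$, which cannot return
an invalid 0.

## 3. Group characterization

Contrasts of per-region slopes between group pairs use pooled-variance
two-sample t tests on covariate-residualized values, Cohen's d with the
pooled SD (Welch available by flag), and Benjamini–Hochberg FDR within the
region family; the top regions by |t| are reported. A pooled SD of zero is
reported as a signed infinite d with a warning rather than an error.
Longitudinal outcomes are contrasted by linear models with group indicator
plus covariates and optional baseline adjustment; FDR families are declared
by the caller, mirroring "correction within scales".

## 4. Growth curves and peak estimation

Because a single cohort covers ages 14–23 only, group curves over 5–25 y are
anchored to a cross-sectional reference curve (polynomial or natural-spline
least squares with a study term; evaluated at the average study offset).
The deviation $d_{ij} = y_{ij} - \mathrm{ref}(a_{ij})$ follows a quadratic
mixed model with random intercept and slope; the group curve adds the group
means of the EB random effects to the population fixed part (evaluated at
the covariate means), and the reported band is the 5th/95th percentile of
the within-group individual fitted curves at each grid age — a spread across
people, not a standard error of the mean (both readings of a percentile band
exist; this one was chosen and is stated wherever the band appears).
Derivatives are analytic (quadratic + reference derivative); growth-rate
signs classify as increase/stable/decrease with `|rate| < rate_eps`
(default 500 mm^3/yr on total GMV, about 0.1 % of typical total volume)
counting as stable.

Peak total GMV uses a two-stage fit: (1) a population ICV curve on a natural
spline in centered age (default 5 df) with sex, age x sex and study terms
and random intercept + slope; (2) total GMV on a B-spline (default 12 df)
with the stage-1 fitted ICV as covariate, the same fixed terms, and random
intercept + slope. The fitted-ICV covariate is standardized before entering
stage 2 — on its raw mm^3 scale it is large and nearly constant in age,
which ill-conditions the design. Spline df are taken as basis dimension with
knots at equally spaced quantiles of observed age (knot placement is not
otherwise pinned down); BIC-based df selection is possible by refitting over
a small grid but the stated df are the defaults, favouring reproducibility.
Per-group peaks are grid argmaxes (0.05 y step); a boundary argmax is
returned with a warning since no interior maximum exists. Per-subject peak
GMV (the max of the subject-level fitted curve) feeds the mediation stage.
Singular random-effect fits retry with a random intercept only before
failing.

## 5. Proxy phenotype

ROI loadings come from a multivariable logistic regression of the contrast
label (e.g. smallest group vs the rest) on all standardized baseline ROI
volumes plus covariates, fitted by IRLS with a small L2 ridge
(default 1e-4 on the standardized scale) so a maximizer exists under
near-separation; near-separation triggers a warning, and instability of the
top-k set (no loading exceeding 3 SEs) is flagged. Loadings are ranked by
absolute *standardized* coefficient (the raw-vs-standardized choice is not
externally fixed; standardized makes the ranking unit-free). The proxy score
in a target cohort is the weighted sum of the target-standardized selected
ROIs, re-standardized. Standardizing within each cohort separately is the
assumption that makes weights transferable across cohorts with different
volume scales; it is embodied, not tested, and the accompanying
cross-cohort age-distribution caveat should be kept in mind. In the
synthetic pipeline the loadings are applied back to the one genotyped
cohort (the in-sample direction is also the sanity check: the score must
correlate positively with its own contrast label).

## 6. Association scans, polygenic scores, clumping

Genotype QC removes subjects with > 10 % missing dosages, then SNPs with
call rate < 95 % (boundary inclusive), minor-allele frequency < 0.1 %, or a
1-df Hardy–Weinberg chi-square p below 1e-10 computed on hard calls
(rounded dosages); every exclusion is reported with its reason. GWAS is
per-SNP OLS of the (standardized) phenotype on dosage plus covariates —
sex, site and the leading genotype principal components (computed from the
subject-level Gram matrix) — with subjects missing a dosage dropped for that
SNP only and monomorphic SNPs skipped with a note. EWAS is per-CpG logistic
regression of the class label on the beta value plus supplied covariate
columns (methylation-composition components are accepted as given columns;
their construction is upstream of this package), with a ridge fallback under
separation and optional SMOTE balancing of the joint predictor block.
SMOTE generates minority rows $x_i + u(x_{nn} - x_i)$, $u \sim U(0,1)$,
among the k nearest minority neighbours, to equal class counts.

Polygenic scores use the average-per-allele convention
$S_T(i) = \sum_{s: p_s \le T}\beta_s d_{is} \big/ 2m_i(T)$ with $m_i(T)$ the
subject's observed marker count at threshold $T$, averaged over thresholds
with non-empty sets. The default grid is 50 log-spaced thresholds from 5e-8
to 1 — a desk-scale stand-in for the ~20,000-point arithmetic grid, which
remains available by passing it explicitly. Effect alleles matching the
genotype table's reference allele flip the dosage to $2-d$. Clumping is
greedy: repeatedly index the smallest-p unclaimed SNP and claim unclaimed
SNPs within ±250 kb with dosage $r^2 > 0.1$; positions are 1-based, windows
inclusive.

## 7. Mediation and correlation equivalence

Mediation is the single-mediator linear decomposition: OLS of
$M \sim X + C$ (path a) and $Y \sim X + M + C$ (paths b, c'), indirect
$= ab$, total $= c' + ab$ (identical, as an OLS identity, to the X
coefficient of the reduced model — tested to 1e-10), proportion
$= ab/(c'+ab)$. A nonparametric case-resampling bootstrap (default
B = 1000) supplies SEs, percentile 95 % CIs and normal-approximation
p-values; BCa intervals were not used because only bootstrap SDs and simple
intervals are needed downstream. When $|{\rm total}| < 10^{-8}$ the
proportion is reported as NA rather than an exploding ratio.

The "inferiority" test of a correlation against a margin $\delta$ (default
0.05) is the standard equivalence construction: two one-sided tests on the
Fisher-z scale with $\mathrm{se} = 1/\sqrt{n-3}$, rejecting
$H_0: |\rho| \ge \delta$ when both one-sided p-values fall below $\alpha$;
the reported p is their maximum. Note the direction of the null: phrasing
that puts $|\rho| < \delta$ *in* the null would make the stated conclusion
("the correlation is smaller than 0.05") unprovable, so the equivalence
null is the only coherent formalization. At $r = \delta$ the p-value is
exactly 0.5; at $r = 0$, $n = 10{,}003$ it is
$1-\Phi(\operatorname{atanh}(0.05)\cdot 100) \approx 2.8\times10^{-7}$.

## 8. The synthetic cohort: what it emulates, and what it does not

`sim_config()` encodes the study conditions; all randomness flows from one
seed through named substreams (subjects / scans / genotypes / methylation /
environment / outcomes / reference / adult), so adding one component never
perturbs another, and identical configs give byte-identical bundles.

* **Groups.** Three latent trajectory groups in proportions 711 : 765 : 67
  (≈ 46.1/49.6/4.3 %), drawn with *fixed* counts (largest-remainder
  rounding, random order): the mixing fractions are the condition being
  emulated, and binomial jitter around 4.3 % would make the 4 % cluster
  admissibility rule a coin flip rather than a property of the design.
* **Trajectories.** Region-level group slope patterns encode steady
  decrease / slower decrease / increase; subject slopes add a shared
  deviation (sd 10 mm^3/yr), an independent per-region deviation
  (sd 30 mm^3/yr — regional rates vary within a person, not only by a
  common scalar), and scan noise (sd 240 mm^3). These dispersions are
  assumptions, not reported quantities; they were fixed once so that the
  implied per-region effect sizes match the magnitudes published for
  adolescent GMV-trajectory groups (top-region d near 1.3 for the two large
  groups, near 4.4 for the small group against the first). Slope deviations
  pivot at the mean scheduled visit age, so the increasing group also has
  the lowest starting volume — trajectories diverge before the first scan,
  and the slope signal stays identifiable for subjects missing a follow-up.
* **Visits.** Baseline always observed; each follow-up independently missing
  with probability 0.2; subjects with fewer than two scans are dropped,
  matching the ≥ 2-scan inclusion rule (and reproducing roughly the
  observed 64/36 split of three- vs two-scan subjects).
* **Covariates.** Sex, four sites, handedness as additive shifts; ICV
  lognormal entering as a true covariate — so covariate adjustment is
  exercised, not decorative.
* **Genetics.** Null SNPs in Hardy–Weinberg proportions with MAF ~
  U(0.05, 0.5); one causal SNP sampled retrospectively given the group so
  its per-allele log-odds for the small group equals log(OR), OR = 1.8 by
  default; a ±250 kb cluster of partially copied neighbours provides LD for
  clumping. No realistic genome-wide LD, imputation, or admixture.
* **Methylation/environment.** One causal CpG with
  $\mathrm{logit}(\beta) = \mu + a\,\mathrm{env} + \mathrm{shift}\cdot
  [\mathrm{group}=2] + \varepsilon$; its centered logit feeds back into the
  subject slope (the mediation b path). All other CpGs are independent
  logit-normal noise.
* **Reference and adult cohorts.** A cross-sectional 5–25 y cohort with
  known per-region quadratic mean curves (two study labels with a pure
  intercept offset), and an independent adult cohort whose outcomes equal
  $\rho\,z(\mathrm{PGS}) + \sqrt{1-\rho^2}\,\varepsilon$ with
  $\rho = 0.04$ by default.

Passing tests on this generator demonstrate that the estimators recover the
structure they assume, at realistic effect sizes and sample sizes. They do
not demonstrate robustness to what the generator omits: non-Gaussian scan
artifacts, site-by-age interactions, realistic LD, cell-composition
confounding in methylation, or population stratification.

A deliberate consequence of desk-scale realism: the within-cohort GWAS of
the proxy phenotype at n ≈ 1450 does *not* reach genome-wide significance
for the causal SNP — a cohort of this size is underpowered for that scan,
which is precisely why the proxy-phenotype design exists; marker-effect
recovery is therefore checked in dedicated scans at n = 8000.

## 9. Problem sizes used in tests and the acceptance script

Chosen as the package's own balance of statistical resolution against a
single-CPU run: discovery cohort n = 1500 with 44 regions and 2–3 visits;
2000 SNPs and 2000 CpGs; permutation B = 199 in the default pipeline
configuration (B is a parameter; larger values sharpen the attainable p
floor); permutation null calibration over 200 replicates of an n = 120
one-group cohort; marker-recovery scans at n = 8000 x 120 SNPs over 50
replicates; mediation recovery at n = 2000 with B = 1000 over 100
replicates; equivalence-test size over 2000 replicates at n = 400;
peak-age recovery over 50 replicates (reference n = 300, cohort n = 120,
B-spline df 8 at these sizes); end-to-end determinism on an n = 400 cohort
run twice. The full default pipeline completes in roughly a minute; the
complete acceptance script in a few minutes.

## 10. Known limitations

* The trajectory model is linear in age per subject over the observed span;
  subject-level curvature is not modelled (it is partially absorbed by the
  deviation-curve and peak stages, which are population-level).
* The elbow rule, like all internal cluster-validity indices, can prefer an
  adjacent k under genuinely ambiguous structure; the permutation test
  guards against *no* structure, not against k being off by one.
* Mediation is the linear single-mediator decomposition; no
  exposure-mediator interaction, multiple mediators, or latent variables.
* The mediation proportion is unstable when the total effect is near zero —
  it is reported with an NA guard, and should be interpreted only alongside
  its bootstrap interval.
* Proxy-score transfer assumes comparable linear change across cohorts and
  within-cohort standardization; violations shift the meaning of the score,
  and the package emits no corrective — only the age-distribution caveat
  above.
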
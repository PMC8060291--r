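---
title: "Dark-channel biomarker discovery and heteroDE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-channel biomarker discovery and heteroDE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistics it implements: the
models, their assumptions, the tunable parameters and why their defaults are
what they are, the synthetic-data generator and what it does and does not
emulate, and the numerical choices made where the underlying method left
them open.

## The data and the normalization

The unit of input is a genes × samples matrix of *strict* counts:
UMI-collapsed read pairs in which at least one mate spans an exon–exon
junction, which makes them unambiguously RNA-derived and filters
DNA contamination. Counts are normalized to reads per million,

$$\mathrm{RPM}_{gs} = \frac{K_{gs} \times 10^6}{N_s},$$

where $N_s$ is the *library-wide* total of collapsed strict mapped reads.
`compute_rpm()` takes $N_s$ as an explicit per-sample field rather than the
column sum, because a filtered matrix may omit genes that still contribute
to the library total.

"Detected" throughout the package means strict count > 0. The underlying
method used the word without defining a threshold; count > 0 is the weakest
reading and the one adopted everywhere.

## Dark channels and the DCB criteria

A *dark channel* is a gene with essentially no background expression in
non-cancer plasma: median RPM exactly 0 **and** RPM standard deviation
below `sd_threshold` (default 0.1 RPM) across the non-cancer group. The SD
convention is not fixed by the method description; the package uses the
sample convention ($n-1$ denominator) and records it in the output
attributes so a population-SD re-analysis is a one-line change.

A dark gene is called a *dark channel biomarker* for a cancer type when

1. it is detected in at least 2 samples of that cancer group (excluding
   single outliers by construction),
2. the RPM in the second-highest cancer sample exceeds `rpm_threshold`
   (default 0.1), and
3. it is differentially expressed against the non-cancer group at the
   cancer-type-specific level `de_alpha` (defaults 0.02 for lung, 0.2 for
   breast, 0.05 otherwise). The breast threshold is unusually permissive
   but is implemented as specified.

The differential-expression p-value comes from `nb_two_group_test()`: an NB
model with group-wise means, a `log(totals)` offset, and a dispersion
estimated by method of moments around the *pooled* mean (floored at 1e-8
with a Poisson fallback). Two deliberate choices here:

* **Likelihood-ratio rather than Wald.** Dark genes are all-zero in the
  non-cancer group — complete separation — where the Wald statistic
  degenerates (the Hauck–Donner effect drives the p-value toward 1 exactly
  when the evidence is overwhelming). The LRT against the intercept-only
  model remains well behaved there, and is also the default test of the
  mainstream count-regression DE tools this test stands in for.
* **Null-based dispersion.** Estimating the dispersion from the pooled-mean
  residuals (with an $n/(n-1)$ degrees-of-freedom correction) holds the
  empirical size near the nominal level in simulation; under a true effect
  it over-estimates the dispersion and therefore errs conservative, the
  right direction for a biomarker screen.

## Tissue deconvolution

Bulk cfRNA is a mixture of contributions from many tissues. Over a set of
signature genes, the observed RPM vector $y$ is modeled as
$y = X\beta + \epsilon$ with $X$ the tissues' median expression (RPM) and
$\beta \ge 0$, $\sum_i \beta_i \le 1$; the slack $1 - \sum_i \beta_i$ is
reported as the *remainder*, the share of the mixture not explained by the
profiled tissues. `deconvolve()` solves the quadratic program

$$\min_\beta \tfrac12 \beta^\top (X^\top X)\, \beta - (X^\top y)^\top \beta
\quad \text{s.t. } \beta \ge 0,\; \mathbf{1}^\top \beta \le 1$$

with `quadprog::solve.QP()`, adding a $10^{-10}$ ridge to the diagonal only
when $X^\top X$ fails a Cholesky check (collinear signatures). Deconvolution
operates in RPM space with no log transform — the mixing model is linear in
abundance. Signature genes absent from a sample are dropped from both $y$
and $X$ with a warning, which preserves the least-squares interpretation of
the remaining rows.

Signature genes are chosen by tissue specificity score,
$TSS_j = \max_i x_{ij} / \sum_i x_{ij}$, taking the top `k = 20` genes per
arg-max tissue. Ties at rank $k$ break by descending TSS then ascending
gene ID, so selection is deterministic and independent of input row order.
Genes silent in every tissue are excluded from selection. How many and
which tissues enter $X$ is left to the reference the user supplies; the
package imposes no exclusion list.

## Tumor content

For gene $i$ in patient $j$, *tumor content* is
$\mathrm{tf}_j \times e_{ij}$: the cfDNA-estimated tumor fraction times the
gene's RPM in the patient's matched tumor tissue — a per-gene, per-patient
proxy for how much of the transcript the tumor sheds into plasma.
`compute_tumor_content()` returns both the plain product (used for
detectability analyses, e.g. rank-sum comparisons of detected versus
undetected samples) and its log10 (the heteroDE covariate), floored at
`floor = 1e-6` product units since $\log_{10} 0$ is undefined; the floor is
recorded in the output. Non-cancer samples carry covariate value exactly 0,
encoding the assumption that healthy-tissue shedding of these genes is
negligible. The two variants exist because the method's own usage differs
between its detectability analyses (plain product) and its regression
covariate (log product); the package computes both and labels which is
which.

## heteroDE

Standard two-group DE assumes a common mean within each group. Plasma cfRNA
violates this badly: a gene's abundance tracks the patient's tumor fraction
and the tumor's expression of that gene, both of which vary by orders of
magnitude. heteroDE therefore regresses counts on the continuous tumor
content:

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
\log(\mu_{ij}) = \gamma_i + x_{ij}\,\beta_i \;(+\, \log N_j),$$

with variance $\mu + \alpha\mu^2$. The offset $\log N_j$ is included by
default (`use_offset = TRUE`) because counts scale with depth; setting it
off reproduces the bare regression on raw counts.

`fit_nbglm()` maximizes the likelihood by alternating IRLS for
$(\gamma, \beta)$ — with step halving so each half-step cannot decrease the
likelihood — against a Brent search for $\alpha$ on
$\log\alpha \in [-10, 5]$, collapsing to the Poisson limit when the profile
optimum does not beat $\alpha = 0$ or falls below $10^{-8}$. The
log-likelihood is asserted non-decreasing across alternations. The linear
predictor is capped at 30 to avoid overflow; all-zero genes return a
non-converged fit with no p-value; a constant covariate is an error.

Inference on $\beta$ is a two-sided Wald test with two finite-sample
calibrations: the dispersion entering the Wald variance is scaled by
$n/(n-2)$ (profile ML under-estimates $\alpha$ by roughly the ratio of
residual to total degrees of freedom, which otherwise makes the test
measurably liberal at cohort-scale $n$), and the statistic is referred to a
$t$ distribution with $n-2$ degrees of freedom rather than the normal. Both
choices move the empirical size to the nominal 0.05 in the simulation the
test suite runs; neither touches the reported $\hat\alpha$ or the
likelihood alternation. The candidate cut-off is raw `alpha_cut = 0.05` —
multiplicity handling is available (`adjust = "BH"` with `bh_q`) but off by
default, matching a discovery screen whose specificity comes from the dark
restriction and the filters rather than from FDR control.

### The bimodality filter

Population heterogeneity unrelated to cancer (an eQTL, a structural
polymorphism) produces genes that are bimodal in *both* groups; the NB
model misreads that as signal. For each group the filter fits, by EM, the
two-component mixture

$$p(x) = \pi_1\,\mathrm{Poisson}(x \mid \lambda_1) +
         \pi_2\,\mathcal{N}(x \mid \mu_2, \sigma_2),$$

on the per-sample RPM values, and calls the group bimodal when
$0.1 < \pi_1 < 0.9$ (strict). A gene bimodal in both groups is flagged; a
gene bimodal only in the cancer group — a genuine subtype-specific pattern
— is not.

Numerical choices, all of which were left open by the model statement:

* The mixture pairs a discrete with a continuous density on one variable.
  The Poisson component is evaluated at the rounded value as a continuous
  extension, and its M-step update averages the rounded values, which keeps
  EM monotone.
* The Poisson component models the minimal-expression group, so its mean is
  constrained to that regime: $\lambda_1 \le$ `lambda_max` (default 1 RPM).
  Without the bound the mixture will happily split any over-dispersed
  unimodal gene into two overlapping halves and call it bimodal; with it,
  unimodal NB genes fit $\pi_1 \approx 0$ and pass.
* $\sigma_2$ is floored at $10^{-3}$ to prevent density blow-up; all-equal
  inputs take a closed-form degenerate path assigning the single mode to
  the Poisson component when it lies at minimal expression.
* EM runs from two percentile-split starts, two boundary starts (all mass
  on one component, which guarantees the fit is at least as good as either
  single-component model) and three seeded random starts; best
  log-likelihood wins; convergence at relative change $< 10^{-8}$ or 500
  iterations. A non-converged fit is treated as not bimodal, with a
  warning, so the filter fails open rather than silently discarding
  biomarkers.

### The influential-outlier filter

A single sample with a large count at an informative covariate value can
carry an entire regression. For each significant gene the filter computes
GLM Cook's distances
$D_j = r_j^2 h_j / \big(q (1-h_j)^2\big)$ with $q = 2$, Pearson residuals
scaled by the NB variance function and leverages from the IRLS weighted hat
matrix, refits without the sample of largest $D_j$, and flags the gene if
the refit p-value is no longer below `alpha_cut`. A refit that cannot
converge (for instance, nothing but zeros remains) is flagged,
conservatively.

**Known limitation.** One-pass Cook's distance can *mask* an extreme
high-leverage outlier: when the fit passes almost exactly through the
outlying point, its residual — and hence its $D_j$ — is small, the refit
drops a different sample, and the gene stays significant. This is inherent
to the distance formula itself (the same one R's `cooks.distance()` uses);
the test suite's filter checks measure the flag rate honestly rather than
assuming it is 1.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the study
conditions the analysis assumes, plus complete ground truth, so every
downstream stage has an oracle. Defaults mirror the discovery-cohort design
the package targets:

| parameter | default | rationale |
|---|---|---|
| samples | 93 non-cancer + 79 cancer | the discovery cohort's arm sizes |
| library size | log-normal, mean 3×10⁶ strict reads, CV 0.83 | heavy-tailed per-sample yields at the reported variability |
| tumor fraction | log-uniform on (0.001, 0.1) | the ~0.1–10% range over which detectability varies |
| background genes | 1920, log₁₀ mean RPM ∈ (0.3, 1.5), NB dispersion ∈ (0.1, 0.6) | reliably expressed blood-cell background (2–30 RPM) |
| dark genes | 60, all zero | the undetected-gene mass (68% of the genome at full scale) |
| DCB genes | 10; cancer-sample mean $= \mathrm{tf}_j \, e_{gj} N_j/10^6$, $e \sim U(50, 500)$ RPM | plasma abundance proportional to tumor content |
| bimodal FPs | 5; per sample 0.5·Poisson(0.1) + 0.5·NB(mean 50, dispersion 0.2), both groups | the eQTL-like failure mode the bimodality filter targets |
| outlier FPs | 5; zero everywhere except one random cancer sample at 20× the background 99th percentile | the single-influential-sample failure mode |

Two generator-design points deserve emphasis. First, background genes live
*above* the detection threshold by design: a gene class that straddled the
threshold would be "dark by chance" in some cohorts, and the planted truth
would be ill-defined. The real transcriptome of course has such marginal
genes — this is exactly why the SD criterion exists — so truth-recovery
results on synthetic cohorts demonstrate correctness of the machinery, not
field performance. Second, the outlier's host sample is drawn uniformly:
placing it at the most extreme tumor content instead produces complete
separation, where the slope is not even estimable — not the failure mode
the filter addresses.

The strong-effect condition used by the truth-recovery checks is
`tumor_fraction_range = c(0.02, 0.1)` with
`dcb_tissue_expr_range = c(100, 500)`: high-shedding tumors with strongly
expressed markers, under which planted DCBs are unambiguous and
precision/recall of 1 is the correct answer rather than an aspiration. The
problem sizes in the test suite — cohorts of 40 + 40 samples × 2000 genes,
1000-gene calibration runs at $n = 60$, ten-seed filter sweeps — were
chosen as the smallest sizes at which the Monte-Carlo bands in the
assertions are meaningful.

What the generator does **not** emulate: raw reads and UMI sequences at
scale, fragment-length and rRNA content profiles, batch effects, sample-QC
failure modes, correlated gene–gene backgrounds, and marginal-expression
genes near the dark threshold. Passing the synthetic suite therefore says
the implementation is correct under the stated model, not that the
thresholds would perform identically on real plasma.

## Pipeline composition

`run_pipeline()` chains RPM → dark channels → per-cancer-type DCB calls →
heteroDE → union report, is deterministic given inputs and `seed`, and
degrades gracefully: without tumor fractions or matched-tissue expression
the heteroDE stage is skipped with a recorded reason and DCB results are
still produced. The heteroDE stage runs by default on the dark-channel
genes (`heterode_candidates = "dark"`). The underlying method applies its
0.05 cut-off to "biomarker candidates" without defining the candidate set;
restricting to dark channels matches the pipeline's low-background focus
and keeps the raw cut-off honest (dark genes that are all-zero yield no
p-value at all). Setting `heterode_candidates = "all"` evaluates every
gene, which is the right choice when matched-tissue expression is available
transcriptome-wide and multiplicity is handled via `adjust = "BH"`.

The union biomarker list annotates each gene with the method(s) and cancer
type(s) that selected it; `example_biomarker_sets()` ships the published
breast/lung worked example (12 + 8 DCBs sharing one gene, 7 heteroDE genes
overlapping 3) whose arithmetic the acceptance script re-derives.

## UMI error correction

`correct_umi()` implements the Hamming-distance-1 heuristic used during
duplicate collapsing: exact whitelist matches are kept, observations at
distance 1 from exactly one whitelist entry are corrected to it, and
everything else — distance > 1 everywhere, or distance 1 to two or more
entries — is discarded. `N` bases count as mismatches at every position,
including against another `N`: a conservative reading that discards
low-quality UMIs rather than rescuing them.

## Limitations

* The Cook's-distance masking described above: a sufficiently extreme
  outlier can evade the one-pass refit.
* The NB assumption is adopted cohort-wide because the regression model
  requires it; the underlying method never states a noise model for cfRNA
  counts.
* The exact/approximate switch of `rank_sum_test()` is at combined
  $n \le 12$; at $n = 6 + 6$ the continuity-corrected normal approximation
  can deviate from the exact two-sided p by up to ≈ 0.04 near mid-range
  p-values, so exact enumeration is used wherever the data are that small.
* Deconvolution quality is bounded by the signature reference; collinear
  tissues are handled numerically (ridge jitter) but remain statistically
  unidentifiable.
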
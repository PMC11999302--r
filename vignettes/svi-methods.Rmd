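---
title: "Methods: constructing tiered social vulnerability indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing tiered social vulnerability indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svindex)
```

## The model and its assumptions

A social vulnerability index ranks small areas (census tracts) by how
susceptible their population is to a specific climate hazard. The package
builds it in three stages.

**Normalization.** Every indicator column — a rate or percentage per area,
such as unemployment or the share of one-parent households — is z-scored,
`Z = (x − μ)/σ`, over its non-missing entries, and then direction-aligned:
columns declared `vulnerability_reducing` (tree cover, volunteering) are
negated so that larger always means more vulnerable. The implicit
assumptions are that each indicator is at least ordinally meaningful as a
vulnerability proxy and that a one-standard-deviation difference is
comparable across indicators. No distributional assumption is needed — the
index is used as a relative ranking, not an absolute scale.

**Tiered weighting.** The hierarchy (indicators nested in domains, domains
in the three dimensions sensitivity / adaptive capacity / enhanced
exposure) carries the weights. In the ideal situation (tier 1), each domain
distributes weight 1 equally over its `m` indicators, `W = 1/m`, so every
domain counts the same regardless of how many indicators proxy it. When the
census fails to deliver — a domain missing required indicators or reduced
to a lone indicator relative to its design (tier 2), or a whole dimension
resting on a single domain (tier 3) — depleted domains are halved to
`W = 1/(2m)`: a single surviving indicator should not speak with the voice
of a full domain. Tier 3 uses the same arithmetic as tier 2; the
distinction is epistemic, not numerical, so tier 3 results always carry a
robustness caveat. Depletion is judged *relative to design*: a domain
deliberately designed with one indicator (e.g. Mobility in the flood
preset) is complete, not depleted. The overall index is the sum (not the
mean) of domain scores, so configurations with more domains span wider
ranges — one reason scores are never comparable across configurations or
study areas.

**Tier 4 fallback.** If an entire dimension has no data, the hierarchy
collapses and no reweighting can pretend otherwise. The fallback
eigendecomposes the indicator correlation matrix, retains the leading
components, and scores each area as the variance-proportion-weighted sum of
its component scores. This handles the multicollinearity that would
otherwise let near-duplicate indicators dominate an equal-weight mean, but
it covers only the vulnerability facets the surviving indicators happen to
measure — the output is therefore flagged "not a Social Vulnerability
Index" in every export.

## Parameters that matter

* `required` (per indicator, default `TRUE`): counts toward domain
  completeness. Which indicators are "key" to a domain is an editorial
  choice; the shipped presets mark all of them required, which is the
  conservative reading (any gap depletes the domain).
* `loading` and `noise_sd` (synthetic generator, defaults 0.8 and 0.6,
  unitless on the latent z-scale): the default column–latent correlation is
  `0.8/√(0.64+0.36) = 0.8`, a strong but realistically noisy census proxy.
* `var_target` (tier 4 retention, default 0.80): smallest component set
  explaining ≥ 80% of variance — the conventional screeless cut; retaining
  all components is supported and turns the index into a full
  variance-weighted mean.
* Classification: default seven standard-deviation bands at ±0.5, ±1.5,
  ±2.5 on the standardized index, labelled *extremely low* … *extremely
  high*; septiles (`quantiles`) as the alternative. The band vocabulary is
  fixed by convention in vulnerability mapping; the boundaries themselves
  are a design choice since no canonical definition exists, and both modes
  are first-class because published maps rarely state which was used.
* Missing-data policy (default `renormalize_weights`): weights inside a
  domain are rescaled per area over the observed indicators, preserving the
  domain's weight sum. Median imputation is available but invents data;
  erroring out is available for strict pipelines. An area with a whole
  domain unobserved gets `NA`, never a silent zero.

## Numerical choices

* σ is the sample standard deviation (N−1), recorded per column in
  `normalization_params`; either convention reproduces the other since the
  choice is stored.
* Zero-variance columns error by default (a constant indicator is a data
  preparation mistake the user must see) and are treated as *unavailable*
  when profiling availability — they carry no rankable information.
* Direction alignment negates z after scoring; since z is odd in `x − μ`
  this equals negating the raw data, and double application restores the
  original (tested as an involution).
* Principal-component signs are arbitrary; each component is oriented so
  its loading sum is ≥ 0, with "first nonzero loading positive" as the
  deterministic tie-break. Numerically negative eigenvalues are clipped at
  zero before variance proportions are formed.
* Classification intervals are left-closed, right-open: boundary scores
  fall deterministically in the upper band. In quantile mode the class is
  assigned from type-7 quantile boundaries, so it is a total function of
  the score — two areas with equal scores always share a class — and
  degenerate (tied-boundary) distributions error rather than classify
  arbitrarily.
* Area ids are compared as trimmed, case-sensitive text throughout;
  geometries pass through in their CRS untouched (the package computes no
  areas or distances).

## Design choices where the design was open

* **One dimension per domain.** Census tables sometimes list a domain's
  indicators under two dimensions (housing characteristics split between
  adaptive capacity and enhanced exposure in the flood preset's source
  material). The hierarchy here is a strict tree — each domain belongs to
  exactly one dimension — because the tiered rules count *domains per
  dimension* and a shared domain would make that count ambiguous. The
  flood preset therefore keeps all five housing indicators in a single
  housing-characteristics domain under enhanced exposure, its original
  home in the lineage of this method.
* **`collected` flag.** The heat preset for the Spanish-style census
  declares a two-indicator Health domain of which only one is actually
  published; `collected: false` records the gap in the configuration so the
  synthetic generator can emulate the city-shaped table. Availability is
  always recomputed from the data actually supplied — the flag never
  overrides observation.
* **Tier 4 index as weighted sum.** Whether the "weighted mean" divides by
  the sum of retained proportions only rescales the index; the ranking,
  which is the decision-relevant output, is identical. The sum is the
  default, the normalized mean an option.
* **Geometry I/O is GeoJSON only**, read and written as plain JSON. It is
  the text-based interchange format, and the join logic — trimmed-id
  matching with a conservation-checked report — is format-independent.
  Geometry validity checking is structural (closed rings, ≥ 4 positions);
  there is no topology engine, so self-intersections are not repaired.

## What the synthetic generator emulates — and what it does not

Each area draws a latent vulnerability `L ~ N(0,1)`; indicator `j` is
`loading_j · s_j · L + ε`, with `s_j = −1` for vulnerability-reducing
indicators (so raw tables genuinely need alignment) and `ε ~ N(0,
noise_sd²)`. An optional logistic transform maps columns onto the 0–100
percent scale of census rates; being monotone it preserves every column's
ranking and, empirically, the composite ranking (Spearman ≥ 0.99 in the
test suite), though not the numerical scores, since the map is nonlinear.
Degradation scenarios delete columns — never mask them — to reproduce the
four tier situations.

The generator is deliberately simple: one latent factor, independent noise,
no spatial autocorrelation, no population-size heteroscedasticity, no
correlated indicator blocks beyond the shared factor. Passing tests
therefore demonstrate that the pipeline recovers a known ranking under
census-like noise and every availability regime — not that any particular
city's indicators satisfy a one-factor model. Test problem sizes (typically
n = 200 areas, 20 seeds; n = 500 for the recovery checks) were chosen so the
sampling error of a Spearman correlation is well below the margins being
asserted.

## Limitations

* Scores are relative to the analysed area set and configuration; they are
  not comparable across cities, hazards or indicator sets.
* Enhanced exposure rests on proxies (imperviousness, tree cover, dwelling
  age), not on hazard-model output; integrating hazard maps is upstream of
  this package.
* Tier 4 output must not drive decisions on its own — the flag is
  mandatory, not cosmetic.
* Indicator choice is contestable by nature (proxies for protected
  personal information); the package validates structure, not substance.
* No outlier treatment or winsorization is applied; cleaning beyond missing
  values is the user's responsibility upstream.
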
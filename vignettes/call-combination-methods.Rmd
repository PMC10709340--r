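---
title: "Detecting call combinations in killer whale vocal sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting call combinations in killer whale vocal sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcaseq)
```

## The problem

Killer whales produce a repertoire of stereotyped calls ("call
categories": types and subtypes). Field recordings from animal-borne
tags suggest that some categories are not produced independently but in
ordered combinations — pairs or triplets separated by short silences,
with clear rules about which category opens and which closes a
combination. `orcaseq` implements the statistical chain needed to
demonstrate such structure from an annotated call stream and to relate
it to feeding behaviour:

1. **Quality gate** — keep only high-quality calls with a band-limited
   signal-to-noise ratio (SNR) above 10 dB;
2. **Bout criterion** — estimate, by maximum likelihood, the gap length
   that separates within-bout from between-bout silences;
3. **Transition analysis** — test the first-order transition matrix of
   gated call pairs against the independence null with a Monte-Carlo
   Pearson chi-squared test and per-cell post-hoc residuals;
4. **Cluster extraction** — group categories linked by significantly
   over-represented mixed transitions into call-combination clusters;
5. **Context association** — label transitions as feeding / non-feeding
   by proximity to tail slaps (the audible correlate of herring
   feeding).

Because real tag audio cannot be bundled, the package ships a
synthetic call-stream generator whose emissions have the statistical
structure the analysis assumes. Every stage is tested against that
generator's ground truth.

## The bout model

Calling occurs in bouts. The silent gap `t` between consecutive calls
(next start minus previous end) is modelled as a two-process
exponential mixture

$$ f(t) = p\,\lambda_f e^{-\lambda_f t} +
          (1-p)\,\lambda_s e^{-\lambda_s t}, $$

where the *fast* process (rate $\lambda_f$, 1/s) generates within-bout
gaps and the *slow* process (rate $\lambda_s$) between-bout gaps, with
mixing proportion $p$. The bout criterion interval (BCI) is the gap
length at which the two weighted component densities intersect,

$$ \mathrm{BCI} = \frac{\log\!\big(p\lambda_f / ((1-p)\lambda_s)\big)}
                      {\lambda_f - \lambda_s}, $$

the standard bout-ending criterion of the maximum-likelihood framework:
shorter gaps are more plausibly within-bout, longer gaps between-bout.
Only call pairs whose gap does not exceed the BCI count as transitions.

### Numerical choices

* **Gap cap and truncation.** Only gaps below 30 s enter the fit, to
  suppress the influence of a few very long pauses. Fitting the plain
  mixture density to a capped sample is not innocuous: at realistic
  rates around a fifth of slow-process gaps exceed 30 s, and ignoring
  the cut overestimates $\lambda_s$ by most of a factor of two. The
  default likelihood is therefore right-truncated (density renormalized
  by the mixture CDF at the cap); `truncation_correction = FALSE`
  recovers the plain fit for comparison with software that does not
  correct.
* **Deterministic multi-start.** The likelihood is maximized by
  L-BFGS-B on $(\mathrm{logit}\,p, \log\lambda_f, \log\lambda_s)$ from
  a fixed grid of quantile-split and method-of-moments starts; no random
  restarts, so the fit is exactly reproducible. Rates are boxed into
  $[10^{-4}, 10^3]$ /s — outside that range the truncated likelihood
  develops numerically spurious corners (an underflowing mixture CDF)
  with no behavioural meaning. `expm1` is used for the CDF for the same
  reason.
* **Degeneracy.** A fit is flagged degenerate (and yields no BCI) when
  a component carries fewer than 5 effective observations, when the two
  rates differ by less than 5%, or when the fast process never
  dominates ($p\lambda_f \le (1-p)\lambda_s$). Zero gaps (clamped
  annotation overlaps) are excluded from the likelihood.
* **Pooling.** Gaps are pooled across tags for one global BCI; the
  method targets a population-level criterion, not per-tag ones.

## Transition testing

Within-BCI consecutive pairs form the square observed count matrix
$O_{ij}$ over the categories that appear in at least one gated event.
Under the independence null, $E_{ij} = r_i c_j / n$ from the observed
margins. The Pearson statistic $\sum (O-E)^2/E$ (over cells with
$E > 0$) is referred to a Monte-Carlo null: 2000 tables drawn uniformly
among tables with both margins fixed (Patefield's algorithm, base R
`r2dtable`), with the add-one convention
$p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(n_{sim}+1)$ so the
p-value is never zero. Expected counts are routinely small here — with
62 categories and a few thousand events most cells are nearly empty —
which is exactly why the Monte-Carlo reference is used instead of the
asymptotic distribution.

A subtlety worth stating: the events are *overlapping* pairs of one
stream, not independent draws, so the fixed-margin null is an
approximation. Its type-I error is part of the acceptance surface; at
the default world (62 categories, several hundred events per run) the
measured rejection rate at $\alpha = 0.05$ is nominal to within
sampling error.

Post-hoc, each cell gets the margin-adjusted standardized residual

$$ z_{ij} = \frac{O_{ij} - E_{ij}}
                 {\sqrt{E_{ij}\,(1 - r_i/n)\,(1 - c_j/n)}}, $$

two-sided normal p-values and Bonferroni correction over all $C^2$
cells (both choices configurable; the family size convention follows
the post-hoc packages commonly used with contingency tables). Only
cells that are significant *and over-expected* feed the downstream
cluster extraction, since the scientific claim concerns combinations
occurring more often than chance.

## Clusters and validated sequences

Significant over-expected *mixed-category* cells observed more than 10
times (strict inequality) become edges of a directed graph; its weakly
connected components with at least two categories are the
call-combination clusters, ordered by descending transition count and
labeled A, B, C, … Self-loops (same-category repetitions) are excluded:
repetitions are reported as their own share. The `min_count` gate also
acts as a firewall against spurious merging — sparse significant cells
(a handful of co-occurrences with near-zero expectation reach large
residuals) would otherwise occasionally bridge unrelated clusters.

A multi-call sequence is *validated* when every adjacent pair is both
within the BCI and significantly over-expected; assembly is
greedy-maximal left to right, and a run is assigned a cluster label
only when all of its mixed edges belong to that one cluster.

Shares are reported over gated transitions: the repetition share
(`from == to`) and the cluster share (ordered pair is a cluster edge);
they need not sum to one.

## Feeding context

A transition is labeled *feeding* when a high-quality tail slap on the
same tag lies within five minutes (symmetric window) of the
transition's timestamp, which is the start of its first call — the
window is wide relative to call durations, so this choice is
near-immaterial. Per-cluster proportions use the cluster's own
denominator; the overall outside-feeding proportion uses all gated
transitions. Both conventions are reported because they answer
different questions.

## The SNR stage

Annotated calls are gated on a band-limited SNR: the level of the call
over its 90% energy duration (between the 5% and 95% crossings of
cumulative squared amplitude) minus the level of a 200 ms ambient
segment found within 5 s before the call. Both segments are first
band-passed with a 3rd-order Butterworth filter, 450 Hz – 10 kHz,
applied forward-backward (zero phase) so annotation times are not
shifted. Design choices the protocol leaves open, fixed here:

* the 90% energy window is computed on the band-passed call, since the
  band-pass exists to confine measurement to the calls' dominant band;
* "transient-free" ambient noise is approximated as
  *annotation-free*: the search scans backwards in 50 ms steps for the
  first 200 ms stretch that intersects no annotated call;
* levels are relative (tags are uncalibrated): only the difference is
  meaningful;
* calls with no usable noise window are flagged, never silently
  dropped, and the gate retains them (with an audit entry) rather than
  discarding measurable calls for an unmeasurable quantity.

No DSP library ships with the target environment, so the filter design
(bilinear transform of the analog prototype) is implemented in the
package and verified against an external reference implementation in
the tests; filtering runs through `stats::filter` at C speed with
odd-reflection padding absorbing edge transients.

## The synthetic world

`generate_tag()` emits units — motifs (ordered 2–3 call tuples),
single background calls, or unclassifiable VARIABLE calls — with gaps
from the two-process mixture: within-motif gaps from the fast process,
between-unit gaps from the full mixture. Each unit repeats with a
fixed probability (geometric number of repeats). Ground truth (unit
kind, motif identity and position, generating gap component, slap
association) goes to a sidecar table so the pipeline cannot see it.

Defaults state the world the package is tested in:

* timing `p = 0.7`, `lambda_fast = 2` /s, `lambda_slow = 0.05` /s —
  mean within-bout gap 0.5 s, between-bout 20 s, implied BCI 2.33 s;
  call durations 1.0 ± 0.3 s (field-realistic, truncated at 50 ms);
* 62 categories, three planted clusters mirroring the structure
  reported for Icelandic herring-ground recordings: a six-category
  cluster whose three-call motifs always terminate in the same call, a
  two-category cluster, and a hub cluster converging on one second
  call; 50 background categories;
* motif weight 0.5 against background weight 1, unit repetition 0.70,
  VARIABLE probability 0.12 — derived *in closed form* (not tuned by
  simulation) so gated transitions split roughly 30% repetitions / 50%
  cluster combinations / 20% other, the share structure such analyses
  report;
* tail slaps are placed uniformly within 300 s *after* a motif
  instance of the designated cluster (association probability
  configurable), so a forced association keeps the whole instance
  inside the feeding window.

What the generator does **not** emulate: realistic call
spectro-temporal structure (waveform calls are linear chirps), ocean
noise colour, per-tag call-rate heterogeneity, exchanges between
individuals, or long slap-free travel periods — so per-cluster feeding
contrasts on short synthetic tags are compressed relative to real
recordings. A green test therefore establishes that the *estimators and
tests* behave as specified on data satisfying their assumptions, not
that real recordings satisfy those assumptions.

When a motif is cut by the requested stream length, the truth table
relabels the cut copy `motif_truncated` so that completeness claims
about planted instances stay exact.

## Known limitations

* Two mixture components only; a three-process gap structure is not
  fitted (and model selection between 2 and 3 is out of scope).
* The fixed-margin Monte-Carlo null treats overlapping chain pairs as
  a contingency table; its calibration at very short streams (tens of
  events) is not guaranteed.
* The post-hoc residual formula and Bonferroni family are conventions;
  significant-cell counts can shift under other choices. Both are
  arguments, not constants.
* Cluster boundaries are strict graph components; published groupings
  derived with an element of manual curation may merge or split
  relative to component extraction at other `min_count` values.
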
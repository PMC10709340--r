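# orcaseq

Statistical detection of **call combinations** in killer whale
(*Orcinus orca*) vocal sequences recorded on animal-borne tags.

Killer whales produce stereotyped calls ("call categories"). In
annotated tag recordings, some categories appear in ordered pairs and
triplets separated by sub-second silences, with consistent opening and
terminal calls. `orcaseq` implements the full analysis chain needed to
demonstrate such structure and relate it to feeding behaviour, plus a
synthetic call-stream generator so the whole pipeline is testable
without field audio.

## Method at a glance

- **Quality gate** — retain high-quality calls with band-limited SNR
  > 10 dB (SNR = level over the call's 90% energy duration minus the
  level of a preceding 200 ms ambient segment, both band-passed
  450 Hz–10 kHz with a zero-phase 3rd-order Butterworth filter).
- **Bout criterion interval (BCI)** — inter-call gaps
  `t = next start − previous end` (capped at 30 s) are fit by maximum
  likelihood to a two-process exponential mixture
  `f(t) = p λ_f e^(−λ_f t) + (1−p) λ_s e^(−λ_s t)`; the BCI is the
  equal-density point `log(p λ_f / ((1−p) λ_s)) / (λ_f − λ_s)`. The
  likelihood is right-truncated at the cap (see the methods vignette).
- **First-order Markov transition test** — pairs with gap ≤ BCI form a
  square count matrix; Pearson χ² against independence with a
  Monte-Carlo p-value from 2000 fixed-margin (Patefield) null tables;
  per-cell adjusted standardized residuals with Bonferroni correction
  over all C² cells.
- **Combination clusters** — significant over-expected mixed-category
  transitions observed > 10 times become edges of a directed graph;
  weakly connected components are the clusters (labels A, B, C, …).
  Repetition and cluster shares, and fully-significant multi-call
  sequences, are reported.
- **Feeding context** — a transition is "feeding" when within 5 min of
  a high-quality tail slap on the same tag.

## Worked example

```r
library(orcaseq)

ds  <- generate_dataset(n_tags = 6, n_calls_per_tag = 500, seed = 7)
cfg <- pipeline_config(n_sim = 2000, seed = 42)
res <- run_pipeline(cfg, calls = ds$calls, tail_slaps = ds$tail_slaps)
print(res)
```

```
Call-combination pipeline
  funnel: calls_in=3000 -> after_quality_gate=3000 -> after_variable_removed=2725 -> gaps=2719 -> transitions_within_bci=2191
  BCI: 2.582 s (fitted)
Pearson chi-squared (Monte-Carlo, 2000 fixed-margin replicates)
  chi2 = 66861.0, simulated p = 0.0004998 (seed 42)
3 call-combination cluster(s)
  A: {I11.4, I38.1, I38.2, I39, I69, I77}  n = 849 transitions over 11 edges
  B: {I43.2, I44, I45, I46}  n = 237 transitions over 6 edges
  C: {I63, I72.3}  n = 85 transitions over 2 edges
Transitions: 2191
  repetitions      : 656 (29.9%)
  cluster combinations: 1171 (53.4%)
    cluster A: n = 849
    cluster B: n = 237
    cluster C: n = 85
Feeding context over 2191 transitions: 60.2% within window, 39.8% outside
  cluster A: 55.1% feeding (n = 468/849)
  cluster B: 75.9% feeding (n = 180/237)
  cluster C: 64.7% feeding (n = 55/85)
```

Reading the output: 3000 synthetic calls funnel down to 2191 gated
transitions; the fitted BCI (2.58 s) is close to the generator's
implied truth (2.33 s); the transition matrix is wildly non-random
(χ² = 66 861, smallest attainable Monte-Carlo p); and cluster
extraction recovers exactly the three planted category sets, including
the six-category cluster whose three-call motifs always terminate in
I69. Shares split into ~30% repetitions and ~53% cluster combinations,
the structure the generator was calibrated to emit. Feeding
proportions on short synthetic tags are compressed relative to real
recordings (see the vignette's limitations section).

Per-call SNR measurement on audio works the same way on synthetic
waveforms:

```r
tag <- generate_tag(default_grammar(), timing_spec(), 5, seed = 1)
w   <- synthesize_waveform(tag, sample_rate = 24000, call_snr_db = 20)
measure_snr_all(w)          # ±1 dB round-trip accuracy
```

A thin CLI wrapping the same stages is installed at
`inst/cli/orcaseq` (subcommands `simulate`, `bci`, `transitions`,
`run-all`).

## Layout

- `R/` — generator, acoustic quality, bout model, transition tests,
  clusters, context, I/O and pipeline.
- `tests/testthat/` — unit + property tests; `test-acceptance.R` holds
  the acceptance criteria.
- `vignettes/call-combination-methods.Rmd` — model details, numerical
  choices, what the synthetic world does and does not establish.
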
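# duetrhythm

Rhythm, causality and synchrony analysis for interval-annotated animal
song, built for duetting species (gibbons in particular) and for anyone
who has Praat TextGrid annotations of who sang what, when.

Singing animals raise two linked questions: is an individual's note stream
*isochronous* — onsets repeating like a clock — and do co-singers
*interact*, timing their notes by each other and overlapping more (or
less) than chance? duetrhythm implements the standard quantitative
pipeline for both, plus a coupled two-singer simulator so every stage can
be tested against known ground truth without field recordings.

## What it computes

For onsets $o_1 < o_2 < \dots$ of one contribution:

* **Inter-onset intervals** $t_k = o_{k+1} - o_k$, with a 5-s ceiling
  (longer gaps are masked and never bridged), and **rhythm ratios**
  $r_k = t_k / (t_k + t_{k+1})$, where $r_k = 0.5$ marks isochrony (1:1).
* **Isochrony rate**: the count of $r_k$ in the on-isochrony band
  $[0.440, 0.555]$ over the count in the flanking off-isochrony bands
  $[0.400, 0.440) \cup (0.555, 0.600]$, per contribution or 10-s chunk.
* **Call rate**: onsets per 10-s window (Hz), with a high/low split at
  the song-type median.
* **Tempo peaks**: maxima of the pooled $t_k$ kernel density on a 1-ms
  grid; each peak's tempo is its inverse (a 0.322-s peak is 3.105 Hz).
* **Granger causality**: contributions binarized into 10-ms phonation
  indicators; nested-OLS F tests in both directions (5 lags = 50 ms of
  history); a census of reciprocal / one-way / uncoupled duets at
  p < 0.001.
* **Synchrony**: exact phonation overlap between co-singers; per-singer
  overlap rate in [0, 1]; *normalized overlap* in [0, 0.5] (0.5 =
  identical phonation); and a chunk-permutation chance distribution
  (3-min chunks, opposite-sex re-pairings from real or random couples)
  with an empirical add-one p-value.

Input is Praat TextGrid (long or short text, UTF-8 or UTF-16) or a flat
onset CSV; outputs are the per-stage CSV tables plus a joined
per-contribution `analysis_table.csv` ready for mixed-model analysis.

## Worked example

```r
library(duetrhythm)

song <- generate_duet(duet_scenario(
  coupling = coupling_params(0.8, 0.05, "bidirectional")), seed = 42)
song$contributions[[1]]
#> <contribution> duet_1 | individual F1 (female, female_duet, wild)
#>   120 notes spanning 0.000-41.016 s, total phonation 13.872 s

iois <- extract_iois(song$contributions[[1]])
counts <- classify_ratios(compute_ratios(iois))
isochrony_rate(counts)
#> <isochrony_rate> 1.87 (on 43 / off 23)

pair <- align_pair(song$contributions[[1]], song$contributions[[2]])
granger_direction(pair[[1]], pair[[2]], direction = "F_to_M")
#> <granger_result> F_to_M: F(5, 6341) = 10.53, p = 4.33e-10

overlap_metrics(song$contributions[[1]], song$contributions[[2]])
#> <overlap_result> overlap 4.813 s | rate F 0.347, rate M 0.349 | normalized 0.1740
```

Reading the output: this simulated female sings 120 notes in 41 s; 43 of
her 118 ratio observations fall in the on-isochrony band against 23 off,
an isochrony rate of 1.87 (about twice as many near-1:1 intervals as
near-band ones). Her phonation Granger-causes the male's at p ≪ 0.001 —
expected, since the duet was generated with strong bidirectional coupling
— and the pair overlap for 4.8 s, a normalized overlap of 0.174 on the
0–0.5 scale.

The full pipeline (all stage tables, census, permutation nulls, joined
analysis table, run log) is one call:

```r
run_pipeline(pipeline_config(
  simulate = list(n_groups = 3, duets_per_group = 2, solos_per_group = 1),
  n_permutations = 1000, seed = 17, out_dir = "out"))
```

or from a shell via the thin front-end `inst/cli/duetrhythm`
(`duetrhythm run --config pipeline.yaml`). A YAML config with the same
fields as `pipeline_config()` is accepted; every parameter and the seed
are echoed into `out/run_log.txt`.

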
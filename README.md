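# cinevents

Tools for analysing the event structure of shot-annotated movies: who is on
screen, where, and when — and how viewers carve the resulting stream into
events.

Popular films are experienced as *scenes* separated by **narrative shifts**:
changes of location (L), major characters (C), and/or time (T) across a cut,
coded as one of seven three-place labels (`[L C T]`, `[L C -]`, `[L - T]`,
`[L - -]`, `[- C T]`, `[- C -]`, `[- - T]`; `[- - -]` marks within-scene
junctures). A **sequence** is a run of three or more scene-like *subscenes*
joined by at least two successive identical shifts, bound by a common
soundtrack, each subscene shorter than the movie's mean scene duration; a
**montage** is a sequence of single-shot units. Viewers segment consistently
at scene boundaries, much less inside sequences, and barely inside montages
— a masking of structurally identical narrative shifts by music, shorter
shots, and flattened shot-duration profiles.

The package provides, for whoever annotates film at the shot level
(cinemetrics, event cognition, media psychology):

- an annotation data model with validated CSV/JSON readers and writers
  (`read_movie()`, `write_movie()`, `read_responses()`),
- the narrative-shift coder (`major_characters()`, `code_movie()`,
  `shift_distribution()`),
- scene segmentation and sequence/montage detection with a corpus census
  (`segment_units()`, `find_sequences()`, `classify_boundaries()`,
  `census()`),
- ordinal 200-bin / 7-bin shot-duration profile analysis with a two-level
  scene-vs-subscene model (`resample_to_bins()`, `movie_profile()`,
  `quadratic_trend()`, `compare_scene_subscene()`),
- low-level audiovisual shot features over grayscale frame stacks
  (`shot_motion()`, `shot_luminance()`, `shot_clutter()`),
- viewer segmentation statistics (`segmentation_rate()`,
  `agreement_kappa()`, `welch_cohen()`, `fit_segmentation_predictors()`),
- and a synthetic annotated-corpus generator with full ground truth
  (`generate_corpus()`, `generate_viewer_responses()`,
  `generate_frame_stacks()`), since the hand codings of commercial films
  that motivate the method cannot be redistributed.

See `vignettes/movie-event-structure.Rmd` for the methods account.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
20-movie corpus (`Rscript analysis/run_all.R`). Abridged output:

```
== 01_simulate.R ==
simulated 20 movies, 15146 shots, 15126 boundaries (seed 20260901)

== 03_detect_sequences.R ==
found 161 sequence spans (34 montages) across 20 movies
sequence count vs release year: r = 0.43, t(18) = 2.02, p = 0.0585
nondiegetic music covers 79% of sequences

== 04_profile_shapes.R ==
scenes: geometric mean shot duration 4.76 s; subscenes 3.83 s
kind effect p = 3.4e-60; kind x bin interaction p = 3e-08
quadratic trend: scenes F = 5.47 (p = 0.005), subscenes F = 0.47 (p = 0.627)

== 06_segmentation_models.R ==
segmentation rates by boundary class (percent):
  scene_boundary       85.1  (1349 boundaries)
  subscene_boundary    56.8  (385 boundaries)
  montage_internal     14.5  (211 boundaries)
  within_scene          4.1  (13181 boundaries)
mean pairwise viewer agreement: kappa = 0.52
scene vs subscene rates: t(23.5) = 15.92, p = 4.4e-14, d = 5.03
```

Reading the numbers: sequence counts trend upward across release years and
are overwhelmingly music-bound; scenes are longer-shot than subscenes and
carry a scalloped (quadratic) duration profile that subscenes lack; viewers
respond at ~85% of scene boundaries but only ~57% of subscene boundaries
and ~15% of montage-internal ones, against a ~4% false-alarm floor inside
scenes — the masking pattern the pipeline is built to quantify. The
regression stage recovers planted music (−), log-duration (+), and scale
(−) effects on segmentation consistency at α = .0001 while motion,
luminance, and clutter stay null.

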
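# Scene segmentation and sequence/montage detection.
#
# A sequence is a run of three or more consecutive scene-like units
# (subscenes) joined by at least two successive narrative-shift boundaries of
# the same type, bound by a common sound coverage class, with every subscene
# shorter than the movie's mean scene duration. A montage is a sequence whose
# units are single shots (or near-single; the cutoff is configurable).

#' Segment a coded movie into scene-level units
#'
#' A new unit starts at every non-null narrative-shift boundary, so units tile
#' the movie without gap or overlap.
#'
#' @param movie A `movie_annotation`.
#' @param codes Boundary codes from [code_movie()].
#' @return Tibble with `unit_id`, `first_shot`, `last_shot` (inclusive),
#'   `n_shots`, `duration_s`.
#' @export
segment_units <- function(movie, codes) {
  n <- n_shots(movie)
  stopifnot(nrow(codes) == n - 1)
  breaks <- which(codes$label != "[- - -]")     # unit ends after shot `b`
  first <- c(1L, breaks + 1L)
  last <- c(breaks, n)
  tibble::tibble(
    unit_id = seq_along(first),
    first_shot = first,
    last_shot = last,
    n_shots = last - first + 1L,
    duration_s = vapply(seq_along(first), function(i) {
      sum(movie$shots$duration_s[first[i]:last[i]])
    }, 1.0)
  )
}

#' Mean scene duration of a movie
#'
#' The duration criterion of sequence detection compares each candidate
#' subscene to the mean duration of the movie's scenes. Units inside already
#' detected (provisional) sequences can be excluded, which is how the
#' two-pass rule in [find_sequences()] works.
#'
#' @param units Units from [segment_units()].
#' @param spans Optional sequence spans; member units are excluded from the
#'   mean.
#' @return Mean unit duration in seconds.
#' @export
mean_scene_duration <- function(units, spans = NULL) {
  keep <- rep(TRUE, nrow(units))
  if (!is.null(spans) && nrow(spans) > 0) {
    for (k in seq_len(nrow(spans)))
      keep[units$unit_id >= spans$first_unit[k] &
           units$unit_id <= spans$last_unit[k]] <- FALSE
  }
  if (!any(keep)) keep <- rep(TRUE, nrow(units))  # degenerate: all in sequences
  mean(units$duration_s[keep])
}

# per-unit sound coverage: the single class covering every shot, else NA
unit_sound_class <- function(movie, units) {
  vapply(seq_len(nrow(units)), function(i) {
    snd <- movie$shots$sound[units$first_shot[i]:units$last_shot[i]]
    u <- unique(snd)
    if (length(u) == 1 && u != "none") u else NA_character_
  }, "")
}

detect_spans <- function(movie, codes, units, mean_dur, montage_max_shots) {
  nu <- nrow(units)
  if (nu < 3) return(empty_spans())
  # label of the boundary following unit i (i = 1..nu-1); all non-null
  blab <- codes$label[units$last_shot[seq_len(nu - 1)]]
  sound <- unit_sound_class(movie, units)
  short <- units$duration_s < mean_dur
  size_class <- ifelse(units$n_shots >= 3, "multi",
                       ifelse(units$n_shots <= montage_max_shots, "montage", "other"))
  out <- list()
  r <- rle(blab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    # boundaries starts[k]..ends[k] share one label; they flank units
    # starts[k]..ends[k]+1
    us <- starts[k]; ue <- ends[k] + 1L
    idx <- us:ue
    ok <- short[idx] & !is.na(sound[idx]) & size_class[idx] != "other"
    # a unit failing any criterion (or switching sound class / size class)
    # terminates the run before it: walk maximal homogeneous stretches
    i <- 1L
    while (i <= length(idx)) {
      if (!ok[i]) { i <- i + 1L; next }
      j <- i
      while (j < length(idx) && ok[j + 1L] &&
             sound[idx[j + 1L]] == sound[idx[i]] &&
             size_class[idx[j + 1L]] == size_class[idx[i]]) j <- j + 1L
      if (j - i + 1L >= 3L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          first_unit = units$unit_id[idx[i]],
          last_unit = units$unit_id[idx[j]],
          n_units = j - i + 1L,
          shift_type = r$values[k],
          montage = size_class[idx[i]] == "montage",
          sound_class = sound[idx[i]],
          first_shot = units$first_shot[idx[i]],
          last_shot = units$last_shot[idx[j]]
        )
      }
      i <- j + 1L
    }
  }
  if (length(out) == 0) return(empty_spans())
  spans <- dplyr::bind_rows(out)
  spans <- spans[order(spans$first_unit), ]
  spans$span_id <- seq_len(nrow(spans))
  # complex-candidate flag: abutting or overlapping spans (from runs of
  # different labels) under shared sound coverage are not simple sequences
  spans$simple <- TRUE
  if (nrow(spans) > 1) {
    for (a in seq_len(nrow(spans) - 1)) {
      for (b in (a + 1):nrow(spans)) {
        touch <- spans$first_unit[b] <= spans$last_unit[a] + 1L
        if (touch && spans$sound_class[a] == spans$sound_class[b] &&
            spans$shift_type[a] != spans$shift_type[b]) {
          spans$simple[c(a, b)] <- FALSE
        }
      }
    }
  }
  spans[c("span_id", "first_unit", "last_unit", "n_units", "shift_type",
          "montage", "simple", "sound_class", "first_shot", "last_shot")]
}

empty_spans <- function() {
  tibble::tibble(span_id = integer(0), first_unit = integer(0),
                 last_unit = integer(0), n_units = integer(0),
                 shift_type = character(0), montage = logical(0),
                 simple = logical(0), sound_class = character(0),
                 first_shot = integer(0), last_shot = integer(0))
}

#' Detect sequences and montages in a coded movie
#'
#' Finds all maximal runs of two or more successive identical non-null shift
#' labels whose flanked units each (a) have at least three shots (multi-shot
#' sequence) or at most `montage_max_shots` shots (montage), (b) are shorter
#' than the movie's mean scene duration, and (c) carry one uniform sound
#' coverage class (music, voiceover, or a pervasive ambient signal) on every
#' shot. The duration threshold is applied in two passes: pass 1 uses the mean
#' over all units, pass 2 recomputes the mean excluding the units of the
#' provisional detections and re-runs detection; the pass-2 result is final.
#'
#' @param movie A `movie_annotation`.
#' @param codes Codes from [code_movie()].
#' @param units Units from [segment_units()].
#' @param montage_max_shots Units with at most this many shots form montages
#'   (default 2; single-shot alternation plus slack for annotation jitter).
#' @param passes Number of duration-threshold passes (default 2).
#' @return Tibble of sequence spans with the mean scene duration used stored
#'   in attribute `mean_scene_s`.
#' @export
find_sequences <- function(movie, codes, units, montage_max_shots = 2,
                           passes = 2) {
  mean_dur <- mean_scene_duration(units)
  spans <- detect_spans(movie, codes, units, mean_dur, montage_max_shots)
  for (p in seq_len(max(0, passes - 1))) {
    mean_dur <- mean_scene_duration(units, spans)
    spans <- detect_spans(movie, codes, units, mean_dur, montage_max_shots)
  }
  attr(spans, "mean_scene_s") <- mean_dur
  spans
}

#' Classify every shot boundary of a movie
#'
#' Boundaries internal to a detected sequence span are `subscene_boundary`
#' (multi-shot sequences) or `montage_internal` (montages); null-shift
#' junctures are `within_scene`; every remaining narrative shift is a
#' `scene_boundary`.
#'
#' @param movie A `movie_annotation`.
#' @param codes,units,spans Pipeline outputs for the movie.
#' @return Tibble with `boundary_index`, `label`, `class`.
#' @export
classify_boundaries <- function(movie, codes, units, spans) {
  cls <- ifelse(codes$label == "[- - -]", "within_scene", "scene_boundary")
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) {
      iu <- spans$first_unit[k]:(spans$last_unit[k] - 1L)
      b <- units$last_shot[iu]   # internal boundaries of the span
      cls[b] <- if (spans$montage[k]) "montage_internal" else "subscene_boundary"
    }
  }
  tibble::tibble(boundary_index = codes$boundary_index,
                 label = codes$label, class = cls)
}

#' Corpus census of sequences
#'
#' Tallies sequences per movie, the shift-type distribution inside sequences
#' versus between scenes outside them, and the sound-class shares of detected
#' sequences, and tests the linear trend of sequence count on release year.
#'
#' @param corpus A list of per-movie results, each a list with elements
#'   `movie`, `codes`, `units`, `spans` (see [run_pipeline()]).
#' @return List with `per_movie` (movie_id, release_year, genre, counts),
#'   `shift_dist_within`, `shift_dist_outside`, `sound_shares`, and `trend`
#'   (Pearson r of sequence count on year with a two-sided t test; `r = NA`
#'   when the variance is degenerate).
#' @export
census <- function(corpus) {
  per_movie <- dplyr::bind_rows(lapply(corpus, function(x) {
    tibble::tibble(movie_id = x$movie$movie_id,
                   release_year = x$movie$release_year,
                   genre = x$movie$genre,
                   n_sequences = nrow(x$spans),
                   n_montages = sum(x$spans$montage),
                   n_simple = sum(x$spans$simple))
  }))
  all_codes <- dplyr::bind_rows(lapply(corpus, function(x) x$codes))
  inside <- unlist(lapply(corpus, function(x) {
    cb <- classify_boundaries(x$movie, x$codes, x$units, x$spans)
    cb$class %in% c("subscene_boundary", "montage_internal")
  }))
  outside <- unlist(lapply(corpus, function(x) {
    cb <- classify_boundaries(x$movie, x$codes, x$units, x$spans)
    cb$class == "scene_boundary"
  }))
  spans_all <- dplyr::bind_rows(lapply(corpus, function(x) x$spans))
  sound_shares <- if (nrow(spans_all) > 0) {
    tab <- table(factor(spans_all$sound_class, levels = SOUND_CLASSES[1:4]))
    tibble::tibble(sound_class = names(tab),
                   n = as.integer(tab),
                   percent = 100 * as.integer(tab) / nrow(spans_all))
  } else tibble::tibble(sound_class = character(0), n = integer(0),
                        percent = numeric(0))
  trend <- if (nrow(per_movie) >= 3 &&
               sd(per_movie$n_sequences) > 0 && sd(per_movie$release_year) > 0) {
    ct <- cor.test(per_movie$n_sequences, per_movie$release_year)
    list(r = unname(ct$estimate), t = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value)
  } else list(r = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_)
  list(per_movie = per_movie,
       shift_dist_within = if (any(inside)) shift_distribution(all_codes, inside) else NULL,
       shift_dist_outside = if (any(outside)) shift_distribution(all_codes, outside) else NULL,
       sound_shares = sound_shares,
       trend = trend)
}

#' Run coding, segmentation, and sequence detection for a corpus
#'
#' Convenience wrapper: for each movie, codes every boundary, segments units,
#' detects sequences, and classifies boundaries.
#'
#' @param movies List of `movie_annotation` objects.
#' @param montage_max_shots Passed to [find_sequences()].
#' @return List (one element per movie) of lists with `movie`, `codes`,
#'   `units`, `spans`, `boundary_classes`.
#' @export
run_pipeline <- function(movies, montage_max_shots = 2) {
  lapply(movies, function(m) {
    codes <- code_movie(m)
    units <- segment_units(m, codes)
    spans <- find_sequences(m, codes, units,
                            montage_max_shots = montage_max_shots)
    list(movie = m, codes = codes, units = units, spans = spans,
         boundary_classes = classify_boundaries(m, codes, units, spans))
  })
}
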
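# helper: movie with explicit per-unit structure for detection tests;
# boundaries between units get the requested labels via location/character
# manipulation (cross-cut style for [L C -], travel style for [L - T])
unit_movie <- function(unit_shots, unit_sounds, unit_durations, labels) {
  stopifnot(length(labels) == length(unit_shots) - 1)
  n_units <- length(unit_shots)
  locs <- chars <- character(n_units)
  marks <- rep("auto", n_units)
  locs[1] <- "loc_1"; chars[1] <- "A"
  loc_n <- 1
  for (i in 2:n_units) {
    L <- grepl("L", labels[i - 1], fixed = TRUE)
    C <- grepl("C", labels[i - 1], fixed = TRUE)
    Tm <- grepl("T", labels[i - 1], fixed = TRUE)
    locs[i] <- if (L) { loc_n <- loc_n + 1; paste0("loc_", loc_n) } else locs[i - 1]
    chars[i] <- if (C) if (chars[i - 1] == "A") "B" else "A" else chars[i - 1]
    marks[i] <- if (Tm && !(L && !C)) "forward_ellipsis"
                else if (!Tm && L && !C) "continuous" else "auto"
  }
  rows <- list()
  for (i in seq_len(n_units)) {
    for (s in seq_len(unit_shots[i])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        shot_index = length(rows) + 1L,
        duration_s = unit_durations[i] / unit_shots[i],
        scale = 4L, location_id = locs[i], characters = list(chars[i]),
        transition_in = if (length(rows) == 0) "none" else "cut",
        time_mark_in = if (s == 1) marks[i] else "auto",
        teleport_in = FALSE, sound = unit_sounds[i])
    }
  }
  movie_annotation("fixture", 2000, "drama", dplyr::bind_rows(rows))
}

test_that("units start at every narrative shift and tile the movie", {
  m <- unit_movie(c(2, 2), c("none", "none"), c(4, 4), "[L C -]")
  codes <- code_movie(m)
  expect_equal(codes$label, c("[- - -]", "[L C -]", "[- - -]"))
  units <- segment_units(m, codes)
  expect_equal(units$first_shot, c(1, 3))
  expect_equal(units$last_shot, c(2, 4))

  # all-null movie: a single unit spanning the movie
  shots <- m$shots
  shots$location_id <- "a"; shots$characters <- rep(list("A"), 4)
  shots$time_mark_in <- "auto"
  m2 <- movie_annotation("x", 2000, "drama", shots)
  u2 <- segment_units(m2, code_movie(m2))
  expect_equal(nrow(u2), 1)
  expect_equal(u2$duration_s, sum(shots$duration_s))
})

test_that("unit tiling holds on random corpora", {
  set.seed(5)
  for (rep in 1:30) {
    m <- random_movie(n = sample(15:50, 1))
    u <- segment_units(m, code_movie(m))
    expect_equal(u$first_shot[1], 1)
    expect_equal(u$last_shot[nrow(u)], n_shots(m))
    if (nrow(u) > 1)
      expect_equal(u$first_shot[-1], u$last_shot[-nrow(u)] + 1)
    expect_equal(sum(u$duration_s), sum(m$shots$duration_s))
  }
})

test_that("mean scene duration excludes provisional sequence members", {
  units <- tibble::tibble(unit_id = 1:2, first_shot = c(1, 4),
                          last_shot = c(3, 6), n_shots = 3L,
                          duration_s = c(10, 20))
  expect_equal(mean_scene_duration(units), 15)
  spans <- tibble::tibble(first_unit = 2L, last_unit = 2L)
  expect_equal(mean_scene_duration(units, spans), 10)
})

test_that("a planted repeated-shift run with music and short units is found", {
  # 7 units: two scenes flank a 3-subscene [L C -] sequence, then two more
  # scenes; sequence units are short and uniformly music-covered
  m <- unit_movie(
    unit_shots = c(6, 6, 3, 3, 3, 6, 6),
    unit_sounds = c("none", "none", rep("nondiegetic_music", 3), "none", "none"),
    unit_durations = c(40, 45, 12, 10, 14, 42, 38),
    labels = c("[L C T]", "[- C -]", "[L C -]", "[L C -]", "[L C T]", "[- C -]"))
  codes <- code_movie(m)
  units <- segment_units(m, codes)
  spans <- find_sequences(m, codes, units)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$first_unit, 3)
  expect_equal(spans$last_unit, 5)
  expect_equal(spans$shift_type, "[L C -]")
  expect_false(spans$montage)
  expect_true(spans$simple)
  cb <- classify_boundaries(m, codes, units, spans)
  expect_equal(sum(cb$class == "subscene_boundary"), 2)
})

test_that("alternating shift labels never form a simple sequence", {
  m <- unit_movie(
    unit_shots = rep(3, 4),
    unit_sounds = rep("nondiegetic_music", 4),
    unit_durations = rep(10, 4),
    labels = c("[L C -]", "[L C T]", "[L C -]"))
  codes <- code_movie(m)
  units <- segment_units(m, codes)
  spans <- find_sequences(m, codes, units)
  expect_equal(nrow(spans), 0)
})

test_that("single-shot alternations are detected as montages", {
  m <- unit_movie(
    unit_shots = c(6, 1, 1, 1, 1, 6),
    unit_sounds = c("none", rep("voiceover", 4), "none"),
    unit_durations = c(40, 4, 5, 4, 5, 45),
    labels = c("[L C T]", "[L - T]", "[L - T]", "[L - T]", "[L C T]"))
  codes <- code_movie(m)
  units <- segment_units(m, codes)
  spans <- find_sequences(m, codes, units)
  expect_equal(nrow(spans), 1)
  expect_true(spans$montage)
  cb <- classify_boundaries(m, codes, units, spans)
  expect_equal(sum(cb$class == "montage_internal"), 3)
})

test_that("detector matches the brute-force window oracle on random movies", {
  set.seed(77)
  for (rep in 1:500) {
    m <- random_movie(n = 60)
    codes <- code_movie(m)
    units <- segment_units(m, codes)
    spans <- find_sequences(m, codes, units, passes = 1)
    want <- oracle_find_spans(m, codes, units, mean_scene_duration(units))
    expect_equal(nrow(spans), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(spans$first_unit, want$first)
      expect_equal(spans$last_unit, want$last)
    }
  }
})

test_that("sequence spans obey the structural invariants", {
  corp <- generate_corpus(small_config(), seed = 9)
  pipe <- run_pipeline(corp$movies)
  for (x in pipe) {
    sp <- x$spans
    if (nrow(sp) == 0) next
    expect_true(all(sp$n_units >= 3))
    ms <- sp[!sp$montage, ]
    if (nrow(ms) > 1)    # multi-shot spans never overlap
      expect_true(all(ms$first_unit[-1] > ms$last_unit[-nrow(ms)]))
    for (k in seq_len(nrow(sp))) {
      ns <- x$units$n_shots[sp$first_unit[k]:sp$last_unit[k]]
      if (sp$montage[k]) expect_true(all(ns <= 2)) else expect_true(all(ns >= 3))
      expect_true(all(x$units$duration_s[sp$first_unit[k]:sp$last_unit[k]] <
                        attr(x$spans, "mean_scene_s")))
    }
  }
})

test_that("two passes of the duration threshold reach a fixed point", {
  done <- 0
  for (seed in 1:17) {
    corp <- generate_corpus(small_config(), seed = seed)
    for (m in corp$movies) {
      codes <- code_movie(m)
      units <- segment_units(m, codes)
      s2 <- find_sequences(m, codes, units, passes = 2)
      s3 <- find_sequences(m, codes, units, passes = 3)
      expect_equal(s2, s3, ignore_attr = TRUE)
      done <- done + 1
    }
  }
  expect_gte(done, 100)
})

test_that("excluding planted sequences raises the scene-duration mean", {
  corp <- generate_corpus(generator_config(n_movies = 4L), seed = 21)
  pipe <- run_pipeline(corp$movies)
  for (x in pipe) {
    expect_gt(mean_scene_duration(x$units, x$spans),
              mean_scene_duration(x$units))
  }
})

test_that("planted sequences are recovered with high precision and recall", {
  corp <- generate_corpus(generator_config(n_movies = 10L), seed = 31)
  pipe <- run_pipeline(corp$movies)
  tp <- fp <- fn <- 0
  for (id in names(pipe)) {
    ds <- pipe[[id]]$spans
    ts <- corp$truth[[id]]$spans
    hit <- if (nrow(ts) > 0) vapply(seq_len(nrow(ts)), function(k) {
      any(ds$first_unit == ts$first_unit[k] & ds$last_unit == ts$last_unit[k])
    }, TRUE) else logical(0)
    tp <- tp + sum(hit); fn <- fn + sum(!hit)
    fp <- fp + nrow(ds) - sum(hit)
  }
  expect_gte(tp / (tp + fn), 0.95)   # recall
  expect_gte(tp / (tp + fp), 0.95)   # precision
})

test_that("census tallies counts, shares, and the year trend", {
  # counts perfectly linear in year -> r = 1
  corp <- generate_corpus(small_config(n_movies = 4L, seq_rate_base = 6),
                          seed = 2)
  pipe <- run_pipeline(corp$movies)
  expect_true(all(vapply(pipe, function(x) nrow(x$spans) >= 1, TRUE)))
  fake <- pipe
  for (i in seq_along(fake)) {
    fake[[i]]$movie$release_year <- 1940L + 10L * i
    fake[[i]]$spans <- pipe[[i]]$spans[rep(1, i), ]
  }
  cen <- census(fake)
  expect_equal(cen$per_movie$n_sequences, 1:4)
  expect_equal(cen$trend$r, 1.0, tolerance = 1e-12)

  # degenerate variance -> r reported as NA
  flat <- pipe
  for (i in seq_along(flat)) flat[[i]]$movie$release_year <- 2000L
  expect_true(is.na(census(flat)$trend$r))

  # planted positive year slope recovered beyond the 95% CI of zero
  cfg <- generator_config(n_movies = 48L, n_scenes_base = 20L,
                          seq_rate_base = 6, seq_rate_slope = 0.15)
  cen <- census(run_pipeline(generate_corpus(cfg, seed = 8)$movies))
  expect_gt(cen$trend$r, 0)
  expect_lt(cen$trend$p, 0.05)
})
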
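# Independent straight-line re-implementations used as oracles. These are
# deliberately written from the coding rules directly, without sharing code
# with the package internals they check.

# narrative-shift coding rules, re-derived
oracle_code_boundary <- function(prev, next_, majors) {
  L <- prev$location_id != next_$location_id
  mp <- sort(intersect(prev$characters[[1]], majors))
  mn <- sort(intersect(next_$characters[[1]], majors))
  C <- if (length(mp) == 0 && length(mn) == 0) FALSE else !identical(mp, mn)
  mark <- next_$time_mark_in
  Tm <- if (mark %in% c("forward_ellipsis", "backward")) TRUE
        else if (mark == "continuous") FALSE
        else L && !C && length(mp) > 0 && !next_$teleport_in
  lab <- paste0("[", if (L) "L" else "-", " ", if (C) "C" else "-", " ",
                if (Tm) "T" else "-", "]")
  c(L = L, C = C, T = Tm, label = lab)
}

oracle_code_movie <- function(movie) {
  counts <- table(unlist(movie$shots$characters))
  majors <- names(counts)[counts > 0.10 * nrow(movie$shots)]
  s <- movie$shots
  t(vapply(seq_len(nrow(s) - 1), function(i) {
    oracle_code_boundary(s[i, ], s[i + 1, ], majors)
  }, c(L = "", C = "", T = "", label = "")))
}

# brute-force sequence detection: enumerate every unit window and test the
# three criteria directly; keep windows not contained in a passing superset
oracle_find_spans <- function(movie, codes, units, mean_dur,
                              montage_max_shots = 2) {
  nu <- nrow(units)
  if (nu < 3) return(data.frame())
  blab <- codes$label[units$last_shot[seq_len(nu - 1)]]
  usound <- vapply(seq_len(nu), function(i) {
    snd <- unique(movie$shots$sound[units$first_shot[i]:units$last_shot[i]])
    if (length(snd) == 1 && snd != "none") snd else NA_character_
  }, "")
  passes <- list()
  for (i in seq_len(nu - 2)) {
    for (j in (i + 2):nu) {
      labs <- blab[i:(j - 1)]
      if (length(unique(labs)) != 1) next
      snds <- usound[i:j]
      if (anyNA(snds) || length(unique(snds)) != 1) next
      if (any(units$duration_s[i:j] >= mean_dur)) next
      ns <- units$n_shots[i:j]
      multi <- all(ns >= 3)
      mont <- all(ns <= montage_max_shots)
      if (!multi && !mont) next
      passes[[length(passes) + 1]] <- c(first = i, last = j)
    }
  }
  if (length(passes) == 0) return(data.frame())
  m <- do.call(rbind, passes)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, "first"] <= m[k, "first"] & m[, "last"] >= m[k, "last"] &
           (m[, "first"] != m[k, "first"] | m[, "last"] != m[k, "last"]))
  }, TRUE)
  out <- as.data.frame(m[maximal, , drop = FALSE])
  out[order(out$first), ]
}

# Sobel gradient magnitude by explicit double loop (edge replication)
oracle_sobel_fraction <- function(m, threshold) {
  H <- nrow(m); W <- ncol(m)
  at <- function(i, j) m[min(max(i, 1), H), min(max(j, 1), W)]
  edges <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      gx <- (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
            (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))
      gy <- (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
            (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1))
      if (sqrt(gx^2 + gy^2) > threshold) edges <- edges + 1L
    }
  }
  edges / (H * W)
}

# unstructured random movie: adversarial for coder/detector equivalence
# (small pools force repeated labels, near-uniform sounds trigger candidates)
random_movie <- function(n = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cast <- paste0("p", 1:4)
  locs <- paste0("loc", 1:3)
  sounds <- c("nondiegetic_music", "diegetic_music", "none")
  shots <- tibble::tibble(
    shot_index = 1:n,
    duration_s = round(10^rnorm(n, log10(4.5), 0.3), 3),
    scale = sample(1:7, n, replace = TRUE),
    location_id = sample(locs, n, replace = TRUE),
    characters = lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) character(0) else sort(sample(cast, k))
    }),
    transition_in = c("none", sample(c("cut", "dissolve"), n - 1,
                                     replace = TRUE, prob = c(.9, .1))),
    time_mark_in = sample(c("auto", "continuous", "forward_ellipsis",
                            "backward"), n, replace = TRUE,
                          prob = c(.7, .1, .15, .05)),
    teleport_in = runif(n) < 0.05,
    sound = sample(sounds, n, replace = TRUE, prob = c(.5, .3, .2))
  )
  movie_annotation(sprintf("rnd_%04d", sample.int(9999, 1)), 1990, "drama",
                   shots)
}

# small fast generator config for structural tests; keeps the scene-dominated
# proportions of the default corpus so the two-pass duration rule behaves
small_config <- function(...) {
  generator_config(n_movies = 6L, n_scenes_base = 30L, seq_rate_base = 3,
                   seq_rate_slope = 0, montage_rate = 1, ...)
}

bind_classes <- function(pipe) {
  dplyr::bind_rows(lapply(names(pipe), function(id) {
    cb <- pipe[[id]]$boundary_classes
    cb$movie_id <- id
    cb[c("movie_id", "boundary_index", "label", "class")]
  }))
}
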
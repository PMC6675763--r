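# Synthetic annotated-movie corpus generator.
#
# Emits corpora of shot-level annotations with the statistical structure the
# analyses assume -- scenes with scalloped log-duration profiles, shorter and
# flatter subscenes embedded in sequences with repeated shift types and
# uniform sound coverage, montages of single-shot alternations, a linear
# year trend in sequence counts, and Bernoulli viewer responses with
# class-specific probabilities -- together with full ground truth.

#' Default generator configuration
#'
#' All defaults are drawn from published census values for popular Hollywood
#' films (shift-type distributions, sound-coverage shares, genre and
#' scene/subscene duration levels, boundary-class response rates); sizes and
#' noise levels are set to what a desk-scale emulation of such a corpus
#' needs. Genre duration effects are multiplicative offsets centred to
#' geometric mean 1, so the corpus-level geometric means stay at
#' `scene_geo_mean_s` / `subscene_geo_mean_s` while genres keep their
#' published ratios.
#'
#' @param ... Named overrides of any default field.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(...) {
  ref <- reference_shift_frequencies()
  cfg <- list(
    n_movies = 24L,
    years = seq(1940L, 2010L, by = 10L),
    genres = GENRES,
    # shift-type sampling (normalized at use)
    shift_probs_scene = setNames(ref$excluding_sequences, ref$label),
    shift_probs_sequence = setNames(ref$within_sequences, ref$label),
    # durations (seconds, geometric means of per-shot duration)
    scene_geo_mean_s = 4.78,
    subscene_geo_mean_s = 4.10,
    genre_geo_mean_s = c(action = 4.1, comedy = 5.5, drama = 6.7),
    log10_sd = 0.25,
    # quadratic log10-duration profile: amplitude of c*((u-.5)^2 - 1/12)
    scallop_curvature = 0.35,
    subscene_curvature = 0.05,
    # structure sizes
    scene_shots = 5:14,
    subscene_shots = 4:9,
    montage_units = 5:9,
    montage_two_shot_prob = 0.2,
    n_scenes_base = 55L,
    # sequence rate: Poisson mean, linear in release year
    seq_rate_base = 7,
    seq_rate_slope = 0.08,
    seq_rate_ref_year = 1975,
    montage_rate = 2,
    duration_margin = 0.8,
    # sound coverage
    shot_sound_probs = c(nondiegetic_music = 0.42, diegetic_music = 0.08,
                         voiceover = 0.03, ambient_signal = 0.02, none = 0.45),
    sequence_sound_probs = c(nondiegetic_music = 0.81, diegetic_music = 0.10,
                             voiceover = 0.05, ambient_signal = 0.04),
    # viewer model
    response_probs = c(scene_boundary = 0.85, subscene_boundary = 0.56,
                       montage_internal = 0.15, within_scene = 0.04),
    n_viewers = 3L,
    cast_size = 6L,
    n_minor_characters = 3L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "generator_config"))
}

validate_config <- function(cfg) {
  chk_probs <- function(p, name) {
    if (any(p < 0) || any(p > 100))
      stop("config ", name, ": probabilities out of range")
  }
  chk_probs(cfg$shift_probs_scene, "shift_probs_scene")
  chk_probs(cfg$shift_probs_sequence, "shift_probs_sequence")
  if (abs(sum(cfg$shot_sound_probs) - 1) > 1e-9)
    stop("shot_sound_probs must sum to 1")
  if (abs(sum(cfg$sequence_sound_probs) - 1) > 1e-9)
    stop("sequence_sound_probs must sum to 1")
  if (any(cfg$response_probs < 0 | cfg$response_probs > 1))
    stop("response_probs must lie in [0, 1]")
  if (cfg$subscene_geo_mean_s >= cfg$scene_geo_mean_s)
    stop("infeasible config: subscene mean must be below scene mean")
  if (cfg$n_movies < 1) stop("n_movies must be >= 1")
  cfg
}

# centred log10 genre offsets (geometric mean 1 across the three genres)
genre_offsets <- function(cfg) {
  lg <- log10(cfg$genre_geo_mean_s)
  lg - mean(lg)
}

# intended (L, C, T) triple of a canonical label
label_lct <- function(label) {
  list(L = grepl("L", label, fixed = TRUE),
       C = grepl("C", label, fixed = TRUE),
       T = grepl("T", label, fixed = TRUE))
}

sample_label <- function(probs, exclude = NULL) {
  p <- probs
  if (!is.null(exclude)) p[exclude] <- 0
  sample(names(p), 1, prob = p)
}

# per-shot log-normal durations with a quadratic ordinal profile, centred so
# the unit's expected mean log-duration equals base
unit_durations <- function(n, base_log10, curvature, sdlog10) {
  u <- (seq_len(n) - 0.5) / n
  mu <- base_log10 + curvature * ((u - 0.5)^2 - 1 / 12)
  10^(rnorm(n, mean = mu, sd = sdlog10))
}

generate_movie <- function(cfg, movie_id, year, genre, genre_off) {
  lam <- max(0, cfg$seq_rate_base +
               cfg$seq_rate_slope * (year - cfg$seq_rate_ref_year))
  n_seq <- rpois(1, lam)
  n_mont <- rpois(1, cfg$montage_rate)
  n_spans <- n_seq + n_mont
  n_scenes <- max(n_spans + 1L, cfg$n_scenes_base + rpois(1, 5))

  # span templates in random order
  span_kind <- sample(c(rep("sequence", n_seq), rep("montage", n_mont)))
  # distribute scenes into n_spans + 1 gaps, each gap >= 1 scene
  gaps <- rep(1L, n_spans + 1L)
  extra <- n_scenes - (n_spans + 1L)
  if (extra > 0) {
    add <- table(factor(sample.int(n_spans + 1L, extra, replace = TRUE),
                        levels = seq_len(n_spans + 1L)))
    gaps <- gaps + as.integer(add)
  }

  cast <- paste0("cast_", seq_len(cfg$cast_size))
  rand_subset <- function() sort(sample(cast, sample(1:3, 1)))
  loc_counter <- 0L
  new_loc <- function() {
    loc_counter <<- loc_counter + 1L
    sprintf("loc_%03d", loc_counter)
  }

  # build the unit stream: tibble of unit plans
  units <- list()
  push_unit <- function(kind, n_sh, sound) {
    units[[length(units) + 1L]] <<- list(kind = kind, n_shots = n_sh,
                                         sound = sound)
  }
  span_plans <- list()
  si <- 0L
  for (g in seq_len(n_spans + 1L)) {
    for (s in seq_len(gaps[g])) push_unit("scene", sample(cfg$scene_shots, 1), NA)
    if (g <= n_spans) {
      si <- si + 1L
      kind <- span_kind[si]
      snd <- sample_label(cfg$sequence_sound_probs)
      lab <- sample_label(cfg$shift_probs_sequence)
      if (kind == "sequence") {
        nu <- sample(3:5, 1)
        for (u in seq_len(nu)) push_unit("subscene", sample(cfg$subscene_shots, 1), snd)
      } else {
        nu <- sample(cfg$montage_units, 1)
        for (u in seq_len(nu)) {
          n_sh <- 1L + rbinom(1, 1, cfg$montage_two_shot_prob)
          push_unit("montage_shot", n_sh, snd)
        }
      }
      first_u <- length(units) - nu + 1L
      span_plans[[si]] <- list(kind = kind, first_unit = first_u,
                               last_unit = length(units), label = lab,
                               sound = snd)
    }
  }
  nu_tot <- length(units)

  # boundary labels between units
  in_span <- rep(NA_integer_, nu_tot)
  for (k in seq_along(span_plans))
    in_span[span_plans[[k]]$first_unit:span_plans[[k]]$last_unit] <- k
  blab <- character(nu_tot - 1L)
  for (i in seq_len(nu_tot - 1L)) {
    same_span <- !is.na(in_span[i]) && !is.na(in_span[i + 1]) &&
      in_span[i] == in_span[i + 1]
    if (same_span) {
      blab[i] <- span_plans[[in_span[i]]]$label
    } else {
      # top-level boundary; keep it off the labels of adjacent spans so a
      # planted run never bleeds into its flanking scenes
      excl <- c(if (!is.na(in_span[i])) span_plans[[in_span[i]]]$label,
                if (!is.na(in_span[i + 1])) span_plans[[in_span[i + 1]]]$label)
      blab[i] <- sample_label(cfg$shift_probs_scene, exclude = excl)
    }
  }

  # assign per-unit locations, characters, and the time mark of their first
  # shot so that the shift coder reproduces the intended labels
  loc <- character(nu_tot); chars <- vector("list", nu_tot)
  mark <- rep("auto", nu_tot)
  loc[1] <- new_loc(); chars[[1]] <- rand_subset()
  span_alt <- list()  # per-span alternation state: list(loc2, chars2)
  for (i in 2:nu_tot) {
    lct <- label_lct(blab[i - 1])
    sp <- in_span[i]
    same_span <- !is.na(sp) && !is.na(in_span[i - 1]) && in_span[i - 1] == sp
    if (lct$L) {
      if (same_span && lct$C) {
        # cross-cut: alternate between two locations
        key <- as.character(sp)
        if (is.null(span_alt[[key]])) span_alt[[key]] <- list(loc = new_loc())
        prev2 <- if (i >= 3 && !is.na(in_span[i - 2]) &&
                     in_span[i - 2] == sp) loc[i - 2] else NULL
        loc[i] <- if (!is.null(prev2)) prev2 else span_alt[[key]]$loc
        if (loc[i] == loc[i - 1]) loc[i] <- new_loc()
      } else loc[i] <- new_loc()
    } else loc[i] <- loc[i - 1]
    if (lct$C) {
      if (same_span) {
        prev2 <- if (i >= 3 && !is.na(in_span[i - 2]) &&
                     in_span[i - 2] == sp) chars[[i - 2]] else NULL
        cand <- if (!is.null(prev2)) prev2 else rand_subset()
        while (identical(cand, chars[[i - 1]])) cand <- rand_subset()
        chars[[i]] <- cand
      } else {
        cand <- rand_subset()
        while (identical(cand, chars[[i - 1]])) cand <- rand_subset()
        chars[[i]] <- cand
      }
    } else chars[[i]] <- chars[[i - 1]]
    # time mark on the first shot of unit i
    if (lct$T) {
      mark[i] <- if (lct$L && !lct$C) "auto" else "forward_ellipsis"
    } else {
      mark[i] <- if (lct$L && !lct$C) "continuous" else "auto"
    }
  }

  # materialize shots
  goff <- genre_off[[genre]]
  base_scene <- log10(cfg$scene_geo_mean_s) + goff
  base_sub <- log10(cfg$subscene_geo_mean_s) + goff
  # sequence units must sit clearly below the movie's mean scene duration
  # (the detection criterion); cap their totals at a fraction of the genre's
  # expected scene duration, redrawing tail draws
  scene_arith <- mean(cfg$scene_shots) * 10^base_scene *
    exp((log(10) * cfg$log10_sd)^2 / 2)
  span_cap <- cfg$duration_margin * scene_arith
  draw_capped <- function(n, base, curv) {
    for (try in 1:20) {
      d <- unit_durations(n, base, curv, cfg$log10_sd)
      if (sum(d) < span_cap) return(d)
    }
    d * (span_cap * 0.95 / sum(d))
  }
  shot_rows <- list()
  unit_first <- integer(nu_tot); unit_last <- integer(nu_tot)
  idx <- 0L
  for (i in seq_len(nu_tot)) {
    u <- units[[i]]
    n_sh <- u$n_shots
    durs <- switch(u$kind,
      scene = unit_durations(n_sh, base_scene, cfg$scallop_curvature,
                             cfg$log10_sd),
      subscene = draw_capped(n_sh, base_sub, cfg$subscene_curvature),
      montage_shot = draw_capped(n_sh, base_sub, 0))
    snd <- if (is.na(u$sound))
      sample(names(cfg$shot_sound_probs), n_sh, replace = TRUE,
             prob = cfg$shot_sound_probs)
    else rep(u$sound, n_sh)
    for (s in seq_len(n_sh)) {
      idx <- idx + 1L
      shot_rows[[idx]] <- list(
        shot_index = idx,
        duration_s = durs[s],
        scale = sample(1:7, 1, prob = c(1, 2, 4, 5, 4, 3, 1)),
        location_id = loc[i],
        characters = chars[[i]],
        transition_in =
          if (idx == 1L) "none"
          else if (s > 1L) "cut"
          else if (u$kind == "montage_shot" && runif(1) < 0.5) "dissolve"
          else "cut",
        time_mark_in = if (s == 1L && idx > 1L) mark[i] else "auto",
        teleport_in = FALSE,
        sound = snd[s])
      if (s == 1L) unit_first[i] <- idx
      if (s == n_sh) unit_last[i] <- idx
    }
  }
  shots <- tibble::tibble(
    shot_index = vapply(shot_rows, `[[`, 1L, "shot_index"),
    duration_s = vapply(shot_rows, `[[`, 1.0, "duration_s"),
    scale = vapply(shot_rows, `[[`, 1L, "scale"),
    location_id = vapply(shot_rows, `[[`, "", "location_id"),
    characters = lapply(shot_rows, `[[`, "characters"),
    transition_in = vapply(shot_rows, `[[`, "", "transition_in"),
    time_mark_in = vapply(shot_rows, `[[`, "", "time_mark_in"),
    teleport_in = vapply(shot_rows, `[[`, TRUE, "teleport_in"),
    sound = vapply(shot_rows, `[[`, "", "sound"))

  # sprinkle minor characters (appear in <=2 shots; never major)
  if (cfg$n_minor_characters > 0) {
    for (m in seq_len(cfg$n_minor_characters)) {
      hits <- sample(nrow(shots), sample(1:2, 1))
      for (h in hits)
        shots$characters[[h]] <- sort(c(shots$characters[[h]],
                                        sprintf("minor_%d", m)))
    }
  }

  movie <- movie_annotation(movie_id, year, genre, shots)

  # ground truth
  true_units <- tibble::tibble(
    unit_id = seq_len(nu_tot),
    kind = vapply(units, `[[`, "", "kind"),
    first_shot = unit_first, last_shot = unit_last)
  true_spans <- if (length(span_plans) == 0) tibble::tibble(
    kind = character(0), first_unit = integer(0), last_unit = integer(0),
    shift_type = character(0), sound_class = character(0),
    first_shot = integer(0), last_shot = integer(0))
  else dplyr::bind_rows(lapply(span_plans, function(sp) {
    tibble::tibble(kind = sp$kind, first_unit = sp$first_unit,
                   last_unit = sp$last_unit, shift_type = sp$label,
                   sound_class = sp$sound,
                   first_shot = unit_first[sp$first_unit],
                   last_shot = unit_last[sp$last_unit])
  }))
  n <- nrow(shots)
  true_class <- rep("within_scene", n - 1L)
  true_label <- rep("[- - -]", n - 1L)
  for (i in seq_len(nu_tot - 1L)) {
    b <- unit_last[i]
    sp <- in_span[i]
    same_span <- !is.na(sp) && !is.na(in_span[i + 1]) && in_span[i + 1] == sp
    true_label[b] <- blab[i]
    true_class[b] <- if (!same_span) "scene_boundary"
      else if (span_plans[[sp]]$kind == "montage") "montage_internal"
      else "subscene_boundary"
  }
  truth <- list(units = true_units, spans = true_spans,
                boundary_classes = tibble::tibble(
                  movie_id = as.character(movie_id),
                  boundary_index = seq_len(n - 1L),
                  label = true_label, class = true_class))
  list(movie = movie, truth = truth)
}

#' Generate a synthetic annotated corpus with ground truth
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the corpus is byte-identical across runs for a
#'   fixed seed.
#' @return List with `movies` (list of `movie_annotation`) and `truth`
#'   (per-movie list of true units, spans, and boundary classes).
#' @export
generate_corpus <- function(config = generator_config(), seed = 1) {
  cfg <- validate_config(config)
  set.seed(seed)
  goff <- genre_offsets(cfg)
  years <- rep(cfg$years, length.out = cfg$n_movies)
  genres <- rep(cfg$genres, length.out = cfg$n_movies)
  movies <- vector("list", cfg$n_movies)
  truth <- vector("list", cfg$n_movies)
  for (i in seq_len(cfg$n_movies)) {
    id <- sprintf("syn_%02d", i)
    res <- generate_movie(cfg, id, years[i], genres[i], goff)
    movies[[i]] <- res$movie
    truth[[i]] <- res$truth
    names(movies)[i] <- names(truth)[i] <- id
  }
  list(movies = movies, truth = truth, config = cfg)
}

#' Generate viewer segmentation responses for a corpus
#'
#' Each viewer responds independently at each boundary with the probability
#' of the boundary's true class (Bernoulli, independent across viewers and
#' boundaries).
#'
#' @param corpus Output of [generate_corpus()].
#' @param config Generator configuration (defaults to the corpus's own).
#' @param seed Integer seed.
#' @return A `viewer_responses` tibble covering all movies.
#' @export
generate_viewer_responses <- function(corpus, config = corpus$config,
                                      seed = 1) {
  set.seed(seed)
  out <- lapply(names(corpus$movies), function(id) {
    cls <- corpus$truth[[id]]$boundary_classes
    p <- config$response_probs[cls$class]
    nb <- nrow(cls)
    dplyr::bind_rows(lapply(seq_len(config$n_viewers), function(v) {
      tibble::tibble(movie_id = id,
                     boundary_index = cls$boundary_index,
                     viewer_id = sprintf("viewer_%d", v),
                     response = rbinom(nb, 1, p))
    }))
  })
  r <- dplyr::bind_rows(out)
  class(r) <- c("viewer_responses", class(r))
  r
}

#' Generate synthetic frame stacks with controlled feature levels
#'
#' Builds per-shot grayscale frame stacks whose measured motion, luminance,
#' and clutter are monotone in the requested levels: a base image at the
#' requested luminance with vertical contrast stripes (clutter), a fixed
#' smooth texture so static stacks have variance, and independent per-frame
#' noise scaled by the motion level.
#'
#' @param spec Tibble with columns `motion_level` (0--1; 0 = static),
#'   `luminance_level` (30--220), `clutter_level` (0--1), and optionally
#'   `n_frames` (default 12).
#' @param seed Integer seed.
#' @param height,width Frame dimensions (default 48 x 64).
#' @return List of `frame_stack` objects, one per spec row.
#' @export
generate_frame_stacks <- function(spec, seed = 1, height = 48, width = 64) {
  spec <- tibble::as_tibble(spec)
  stopifnot(all(c("motion_level", "luminance_level", "clutter_level") %in%
                  names(spec)))
  if (any(spec$motion_level < 0 | spec$motion_level > 1) ||
      any(spec$clutter_level < 0 | spec$clutter_level > 1) ||
      any(spec$luminance_level < 30 | spec$luminance_level > 220))
    stop("feature levels outside documented ranges")
  set.seed(seed)
  n_frames <- if ("n_frames" %in% names(spec)) spec$n_frames else
    rep(12L, nrow(spec))
  lapply(seq_len(nrow(spec)), function(i) {
    lum <- spec$luminance_level[i]
    base <- matrix(lum, height, width)
    n_str <- round(spec$clutter_level[i] * 12)
    if (n_str > 0) {
      cols <- round(seq(4, width - 4, length.out = n_str))
      for (cc in cols) base[, cc] <- pmin(255, lum + 60)
    }
    texture <- if (spec$motion_level[i] > 0) {
      # smooth horizontal ramp texture, mean zero: gives static pairs
      # variance without adding edges past the Sobel threshold
      matrix(rep(10 * sin(seq(0, 4 * pi, length.out = width)), each = height),
             height, width)
    } else matrix(0, height, width)
    noise_sd <- spec$motion_level[i] * 8
    frames <- lapply(seq_len(n_frames[i]), function(k) {
      fr <- base + texture
      if (noise_sd > 0) fr <- fr + rnorm(height * width, sd = noise_sd)
      pmin(pmax(fr, 0), 255)   # fr first: pmin/pmax keep dims of arg 1
    })
    frame_stack(frames)
  })
}

#' Generate a boundary-level predictor table with planted effects
#'
#' Emulates the per-boundary analysis table behind the segmentation
#' regression: six predictors plus a movie factor, with viewer counts drawn
#' from a logistic model. Effects default to zero (null generator).
#'
#' @param n_boundaries Rows to generate.
#' @param n_movies Number of movie levels.
#' @param effects Named list of logistic coefficients for any of
#'   `log_duration`, `scale`, `music01`, `motion`, `luminance`, `clutter`
#'   (applied to centred predictors); missing entries are 0.
#' @param base_rate Baseline response probability (default 0.3).
#' @param n_viewers Viewers per boundary (default 3).
#' @param movie_sd SD of movie-level logit intercepts (default 0.3).
#' @param seed Integer seed.
#' @return Tibble ready for [fit_segmentation_predictors()]; `mean_response`
#'   is the 0..n_viewers count.
#' @export
generate_boundary_table <- function(n_boundaries = 3000, n_movies = 20,
                                    effects = list(), base_rate = 0.3,
                                    n_viewers = 3, movie_sd = 0.3, seed = 1) {
  set.seed(seed)
  eff <- function(nm) if (is.null(effects[[nm]])) 0 else effects[[nm]]
  movie_id <- sample(sprintf("syn_%02d", seq_len(n_movies)), n_boundaries,
                     replace = TRUE)
  m_int <- setNames(rnorm(n_movies, 0, movie_sd),
                    sprintf("syn_%02d", seq_len(n_movies)))
  d <- tibble::tibble(
    movie_id = movie_id,
    log_duration = rnorm(n_boundaries, log10(5), 0.3),
    scale = sample(1:7, n_boundaries, replace = TRUE),
    music01 = rbinom(n_boundaries, 1, 0.5),
    motion = pmax(-1, pmin(1, rnorm(n_boundaries, 0.6, 0.15))),
    luminance = pmax(0, pmin(255, rnorm(n_boundaries, 120, 30))),
    clutter = pmax(0, rnorm(n_boundaries, 0.08, 0.03)))
  ctr <- function(x) x - mean(x)
  lp <- qlogis(base_rate) + m_int[d$movie_id] +
    eff("log_duration") * ctr(d$log_duration) +
    eff("scale") * ctr(d$scale) +
    eff("music01") * ctr(d$music01) +
    eff("motion") * ctr(d$motion) +
    eff("luminance") * ctr(d$luminance) +
    eff("clutter") * ctr(d$clutter)
  d$mean_response <- rbinom(n_boundaries, n_viewers, plogis(lp))
  d
}
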
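# Shot-value profile shapes.
#
# Each scene-level unit's per-shot values (log shot durations or shot scales)
# are affine-resampled onto a common 200-bin ordinal grid, averaged within a
# movie, and sampled at 7 bins for quadratic-trend analysis. Scenes show a
# scalloped profile (longer shots at the boundaries); subscenes within
# sequences are flatter.

BINS7 <- c(1L, 33L, 67L, 100L, 133L, 167L, 200L)

#' Resample per-shot values onto a fixed ordinal grid
#'
#' Each shot occupies an equal ordinal span of the unit, and bin `j` of
#' `n_bins` takes the value of the shot covering its midpoint:
#' shot `floor(((j - 0.5) / n_bins) * n) + 1`. This is ordinal
#' nearest-neighbour assignment, not temporal interpolation: the analysis unit
#' is the shot. A linear-interpolation mode (`method = "linear"`,
#' interpolating between shot midpoints) is available as an analysis option.
#'
#' @param values Numeric vector of per-shot values (length >= 1).
#' @param n_bins Number of bins (default 200); must be at least
#'   `length(values)`.
#' @param method `"nearest"` (default) or `"linear"`.
#' @return Numeric vector of length `n_bins`. Constant input gives constant
#'   output; the first and last bins always carry the first and last shots.
#' @export
resample_to_bins <- function(values, n_bins = 200L,
                             method = c("nearest", "linear")) {
  method <- match.arg(method)
  n <- length(values)
  if (n == 0) stop("cannot resample an empty shot vector")
  if (n_bins < n)
    stop("n_bins (", n_bins, ") must be >= number of shots (", n, ")")
  j <- seq_len(n_bins)
  if (method == "nearest") {
    idx <- floor(((j - 0.5) / n_bins) * n) + 1
    idx[idx > n] <- n
    values[idx]
  } else {
    if (n == 1) return(rep(values, n_bins))
    # shot midpoints on (0, 1]; clamp outside the first/last midpoint
    xm <- (seq_len(n) - 0.5) / n
    u <- (j - 0.5) / n_bins
    stats::approx(xm, values, xout = u, rule = 2)$y
  }
}

#' Average profile of a movie's units
#'
#' Resamples each qualifying unit to 200 bins and averages bin-wise within
#' the movie, then extracts the 7-bin subsample (bins 1, 33, 67, 100, 133,
#' 167, 200) used for statistics. Shot durations are log10-transformed before
#' resampling; shot scales are used raw.
#'
#' @param movie A `movie_annotation`.
#' @param units Units from [segment_units()] (any subset, e.g. only scenes or
#'   only subscenes).
#' @param measure `"log_duration"` or `"scale"`.
#' @param min_shots Units with fewer shots are dropped (default 3; shorter
#'   units cannot carry a nonlinearity).
#' @param method Resampling method, see [resample_to_bins()].
#' @return List of class `profile_vector`: `movie_id`, `measure`, `bins200`,
#'   `bins7`, `n_units_averaged`.
#' @export
movie_profile <- function(movie, units, measure = c("log_duration", "scale"),
                          min_shots = 3, method = "nearest") {
  measure <- match.arg(measure)
  keep <- units$n_shots >= min_shots
  if (!any(keep))
    stop("no units with at least ", min_shots, " shots in ", movie$movie_id)
  units <- units[keep, ]
  mat <- vapply(seq_len(nrow(units)), function(i) {
    sh <- units$first_shot[i]:units$last_shot[i]
    v <- if (measure == "log_duration") log10(movie$shots$duration_s[sh])
         else as.numeric(movie$shots$scale[sh])
    resample_to_bins(v, 200L, method = method)
  }, numeric(200))
  bins200 <- rowMeans(mat)
  structure(list(movie_id = movie$movie_id, measure = measure,
                 bins200 = bins200, bins7 = bins200[BINS7],
                 n_units_averaged = nrow(units)),
            class = "profile_vector")
}

#' Quadratic trend across the 7-bin profile
#'
#' Least-squares fit of `y ~ 1 + x + x^2` over ordinal bin positions
#' `x = 1..7` (or the length of `y`), with the overall F test of the linear
#' plus quadratic terms against the intercept-only model.
#'
#' @param y Numeric vector of bin means (typically length 7); may also be a
#'   longer stacked vector with matching `x`.
#' @param x Bin positions (default `seq_along(y)`).
#' @return List with coefficients `b0`, `b1`, `b2`, the overall `F`, degrees
#'   of freedom `df1`, `df2`, `p`, and `r_squared`.
#' @export
quadratic_trend <- function(y, x = seq_along(y)) {
  stopifnot(length(y) == length(x), all(is.finite(y)))
  fit <- lm(y ~ x + I(x^2))
  sm <- suppressWarnings(summary(fit))  # flat inputs trip the perfect-fit warning
  fs <- sm$fstatistic
  if (is.null(fs)) {                 # zero residual variance on a flat input
    fs <- c(value = NA_real_, numdf = 2, dendf = length(y) - 3)
  }
  p <- if (is.na(fs[["value"]])) NA_real_ else
    pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  b <- coef(fit)
  list(b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
       F = unname(fs[["value"]]), df1 = unname(fs[["numdf"]]),
       df2 = unname(fs[["dendf"]]), p = p,
       r_squared = sm$r.squared)
}

#' Build per-movie scene and subscene profiles for a corpus
#'
#' For each movie, units inside multi-shot sequence spans are profiled as
#' subscenes and units outside any span as scenes (montage units, having
#' fewer than `min_shots` shots, drop out of both).
#'
#' @param corpus Per-movie pipeline results, as from [run_pipeline()].
#' @param measure `"log_duration"` or `"scale"`.
#' @param min_shots Minimum shots per unit (default 3).
#' @param method Resampling method.
#' @return Long tibble with `movie_id`, `kind` (scene/subscene), `bin` (1..7),
#'   `bin200` (the source bin), `y`, `n_units`.
#' @export
corpus_profiles <- function(corpus, measure = "log_duration", min_shots = 3,
                            method = "nearest") {
  rows <- list()
  for (x in corpus) {
    in_span <- rep(FALSE, nrow(x$units))
    if (nrow(x$spans) > 0) {
      ms <- x$spans[!x$spans$montage, ]
      for (k in seq_len(nrow(ms)))
        in_span[x$units$unit_id >= ms$first_unit[k] &
                x$units$unit_id <= ms$last_unit[k]] <- TRUE
    }
    mont <- rep(FALSE, nrow(x$units))
    if (any(x$spans$montage)) {
      mm <- x$spans[x$spans$montage, ]
      for (k in seq_len(nrow(mm)))
        mont[x$units$unit_id >= mm$first_unit[k] &
             x$units$unit_id <= mm$last_unit[k]] <- TRUE
    }
    for (kind in c("scene", "subscene")) {
      sel <- if (kind == "scene") !in_span & !mont else in_span
      u <- x$units[sel & x$units$n_shots >= min_shots, ]
      if (nrow(u) == 0) next
      pr <- movie_profile(x$movie, u, measure = measure,
                          min_shots = min_shots, method = method)
      rows[[length(rows) + 1]] <- tibble::tibble(
        movie_id = x$movie$movie_id, kind = kind, bin = 1:7,
        bin200 = BINS7, y = pr$bins7, n_units = pr$n_units_averaged)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare scene and subscene profile shapes across a corpus
#'
#' Fits a two-level model to the 7-bin log-duration profiles: fixed effects
#' for unit kind (scene vs subscene), centred linear and quadratic bin terms,
#' and their interactions, with a random intercept per movie
#' (`lme4::lmer`). Reports Wald tests for the kind (level) effect and the
#' kind-by-bin interaction, per-kind quadratic F tests over the pooled
#' movie-level bins, and back-transformed geometric mean shot durations in
#' seconds.
#'
#' @param profiles Long tibble from [corpus_profiles()] with
#'   `measure = "log_duration"`.
#' @return List with `mean_scene_s`, `mean_subscene_s`, `level_test`
#'   (estimate on log10 scale, se, Wald z, p; absent if only one kind),
#'   `interaction_test` (Wald chi-square, df, p), and `quad_scene`,
#'   `quad_subscene` (per-kind [quadratic_trend()] results).
#' @export
compare_scene_subscene <- function(profiles) {
  stopifnot(all(c("movie_id", "kind", "bin", "y") %in% names(profiles)))
  kinds <- unique(profiles$kind)
  d <- profiles
  d$x1 <- d$bin - 4
  d$x2 <- d$x1^2 - mean((d$bin - 4)^2)
  gm <- function(kind) {
    yy <- d$y[d$kind == kind]
    if (length(yy) == 0) NA_real_ else 10^mean(yy)
  }
  quad <- function(kind) {
    dd <- d[d$kind == kind, ]
    if (nrow(dd) == 0) return(NULL)
    quadratic_trend(dd$y, dd$bin)
  }
  out <- list(mean_scene_s = gm("scene"),
              mean_subscene_s = gm("subscene"),
              quad_scene = quad("scene"),
              quad_subscene = quad("subscene"))
  if (length(kinds) < 2) {
    out$level_test <- NULL
    out$interaction_test <- NULL
    return(out)
  }
  d$kind <- factor(d$kind, levels = c("scene", "subscene"))
  fit <- lme4::lmer(y ~ kind * (x1 + x2) + (1 | movie_id), data = d,
                    REML = TRUE)
  fe <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  wald1 <- function(term) {
    est <- fe[[term]]; se <- sqrt(V[term, term])
    z <- est / se
    list(estimate = est, se = se, statistic = z,
         p = 2 * pnorm(-abs(z)))
  }
  out$level_test <- wald1("kindsubscene")
  it <- c("kindsubscene:x1", "kindsubscene:x2")
  b <- fe[it]
  W <- drop(t(b) %*% solve(V[it, it]) %*% b)
  out$interaction_test <- list(statistic = W, df = 2,
                               p = pchisq(W, 2, lower.tail = FALSE))
  out$model <- fit
  out
}
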
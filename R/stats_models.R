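# Segmentation-rate, agreement, and predictor models for viewer responses.

BOUNDARY_CLASSES <- c("scene_boundary", "subscene_boundary",
                      "montage_internal", "within_scene")

#' Viewer segmentation rate by boundary class
#'
#' The rate for a class is the viewer-averaged proportion of responses:
#' total responses over the class's boundaries divided by
#' (number of viewers x number of boundaries in the class).
#'
#' @param responses A `viewer_responses` tibble (one or more movies).
#' @param classes Tibble with `movie_id`, `boundary_index`, `class` --
#'   typically the bound `boundary_classes` of [run_pipeline()] output.
#' @return Tibble with `class`, `n_boundaries`, `n_responses`, `rate`
#'   (proportion in \[0, 1\]; `NA` for empty classes), and `percent`.
#' @export
segmentation_rate <- function(responses, classes) {
  r <- dplyr::inner_join(tibble::as_tibble(responses),
                         tibble::as_tibble(classes)[c("movie_id", "boundary_index", "class")],
                         by = c("movie_id", "boundary_index"))
  if (nrow(r) < nrow(tibble::as_tibble(responses)))
    stop("classes do not cover all boundaries in responses")
  agg <- dplyr::summarise(
    dplyr::group_by(r, class),
    n_boundaries = dplyr::n_distinct(paste(movie_id, boundary_index)),
    n_responses = dplyr::n(),
    rate = mean(response), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(class = BOUNDARY_CLASSES), agg,
                          by = "class")
  out$percent <- 100 * out$rate
  out
}

# Cohen's kappa for two binary vectors (closed form from the 2x2 table)
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(NA_real_)   # a rater with zero variance: kappa undefined
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  (po - pe) / (1 - pe)
}

#' Mean pairwise inter-viewer agreement (Cohen's kappa)
#'
#' Computes Cohen's kappa for every viewer pair over their 0/1 boundary
#' vectors and averages across pairs. Pairs involving a viewer with zero
#' response variance have undefined kappa and are excluded with a message.
#'
#' @param responses A `viewer_responses` tibble (>= 2 viewers).
#' @return List with `mean_kappa`, `pairs` (tibble of per-pair kappas), and
#'   `n_excluded`.
#' @export
agreement_kappa <- function(responses) {
  r <- tibble::as_tibble(responses)
  wide <- tidyr::pivot_wider(r, id_cols = c("movie_id", "boundary_index"),
                             names_from = "viewer_id",
                             values_from = "response")
  viewers <- setdiff(names(wide), c("movie_id", "boundary_index"))
  if (length(viewers) < 2) stop("agreement needs at least 2 viewers")
  pairs <- utils::combn(viewers, 2)
  res <- apply(pairs, 2, function(pr) {
    cohen_kappa(wide[[pr[1]]], wide[[pr[2]]])
  })
  excl <- sum(is.na(res))
  if (excl > 0)
    message("agreement_kappa: excluded ", excl,
            " pair(s) with a zero-variance viewer")
  list(mean_kappa = mean(res, na.rm = TRUE),
       pairs = tibble::tibble(viewer_a = pairs[1, ], viewer_b = pairs[2, ],
                              kappa = res),
       n_excluded = excl)
}

#' Welch two-sample t test with Cohen's d
#'
#' Welch t statistic with Satterthwaite (fractional) degrees of freedom via
#' `stats::t.test`, plus Cohen's d from the pooled standard deviation.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @return List with `estimate` (mean difference a - b), `se`, `statistic`,
#'   `df`, `p`, `effect_size_d`.
#' @export
welch_cohen <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  diff <- mean(group_a) - mean(group_b)
  if (va == 0 && vb == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    return(list(estimate = diff, se = 0, statistic = t,
                df = length(group_a) + length(group_b) - 2,
                p = if (diff == 0) 1 else 0, effect_size_d = if (diff == 0) 0 else Inf))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  na <- length(group_a); nb <- length(group_b)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(estimate = unname(diff),
       se = unname(tt$stderr),
       statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       effect_size_d = if (sp == 0) Inf * sign(diff) else unname(diff / sp))
}

#' Regress segmentation consistency on shot-level predictors
#'
#' Ordinary least squares of the per-boundary mean viewer response (a 0 to
#' n-viewers count treated as continuous) on six predictors -- log shot
#' duration, shot scale, music presence (0/1), motion, luminance, clutter --
#' with the movie entered as a nominal factor. Coefficients are flagged at
#' the conservative alpha = .0001. Also reports the R-squared of the reduced
#' model retaining only music, log duration, and scale (plus the movie
#' factor), and its increment over the movie-factor-only baseline.
#'
#' @param table Tibble with columns `mean_response`, `log_duration`, `scale`,
#'   `music01`, `motion`, `luminance`, `clutter`, `movie_id`.
#' @param alpha Significance flag threshold (default 1e-4).
#' @return List with `coefficients` (tibble: term, estimate, se, t, df, p,
#'   significant), `r_squared`, `r_squared_retained`,
#'   `r_squared_retained_incremental`, and the `fit` object.
#' @export
fit_segmentation_predictors <- function(table, alpha = 1e-4) {
  need <- c("mean_response", "log_duration", "scale", "music01", "motion",
            "luminance", "clutter", "movie_id")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- tibble::as_tibble(table)
  preds <- c("log_duration", "scale", "music01", "motion", "luminance",
             "clutter")
  const <- preds[vapply(preds, function(p) sd(d[[p]]) == 0, TRUE)]
  if (length(const) > 0)
    stop("constant predictor(s) after centering: ",
         paste(const, collapse = ", "))
  use_movie <- length(unique(d$movie_id)) >= 2
  if (!use_movie)
    warning("single movie: movie factor dropped from the model")
  rhs <- paste(preds, collapse = " + ")
  if (use_movie) rhs <- paste(rhs, "+ factor(movie_id)")
  fit <- lm(as.formula(paste("mean_response ~", rhs)), data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients[preds, , drop = FALSE]
  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = ct[, 1], se = ct[, 2], t = ct[, 3],
    df = fit$df.residual, p = ct[, 4],
    significant = ct[, 4] < alpha)
  rhs_ret <- "music01 + log_duration + scale"
  base_r2 <- 0
  if (use_movie) {
    rhs_ret <- paste(rhs_ret, "+ factor(movie_id)")
    base_r2 <- summary(lm(mean_response ~ factor(movie_id), data = d))$r.squared
  }
  ret <- summary(lm(as.formula(paste("mean_response ~", rhs_ret)), data = d))
  list(coefficients = coefs,
       r_squared = sm$r.squared,
       r_squared_retained = ret$r.squared,
       r_squared_retained_incremental = ret$r.squared - base_r2,
       fit = fit)
}
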
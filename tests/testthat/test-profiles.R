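test_that("ordinal resampling maps shots to equal ordinal spans", {
  expect_equal(resample_to_bins(c(5, 5, 5)), rep(5, 200))
  r <- resample_to_bins(c(2, 4))
  expect_equal(r[1:100], rep(2, 100))
  expect_equal(r[101:200], rep(4, 100))
  expect_equal(r[c(1, 33, 67, 100, 133, 167, 200)], c(2, 2, 2, 2, 4, 4, 4))
  # order preservation, endpoints
  v <- sort(runif(9))
  r <- resample_to_bins(v)
  expect_true(all(diff(r) >= 0))
  expect_equal(r[1], v[1])
  expect_equal(r[200], v[9])
  # idempotent on an already-200-length vector
  expect_equal(resample_to_bins(rep(7, 200)), rep(7, 200))
  expect_equal(resample_to_bins(seq_len(200)), seq_len(200))
  expect_error(resample_to_bins(numeric(0)), "empty")
  expect_error(resample_to_bins(1:10, n_bins = 5), "n_bins")
  # linear mode interpolates between shot midpoints and keeps endpoints
  rl <- resample_to_bins(c(2, 4), method = "linear")
  expect_equal(rl[1], 2); expect_equal(rl[200], 4)
  expect_true(all(diff(rl) >= 0))
})

mk_unit_shots <- function(durs, scales = rep(4L, length(durs))) {
  n <- length(durs)
  tibble::tibble(shot_index = seq_len(n), duration_s = durs, scale = scales,
                 location_id = "a", characters = rep(list("x"), n),
                 transition_in = c("none", rep("cut", n - 1)),
                 time_mark_in = "auto", teleport_in = FALSE, sound = "none")
}

test_that("movie profiles average units bin-wise on the log scale", {
  m <- movie_annotation("m", 2000, "drama",
                        mk_unit_shots(c(2, 2, 2, 4, 4, 4)))
  units <- tibble::tibble(unit_id = 1:2, first_shot = c(1L, 4L),
                          last_shot = c(3L, 6L), n_shots = 3L,
                          duration_s = c(6, 12))
  # two constant units: every bin is the mean of log10(2) and log10(4)
  pr <- movie_profile(m, units, measure = "log_duration")
  expect_equal(pr$bins200, rep((log10(2) + log10(4)) / 2, 200))
  expect_equal(pr$n_units_averaged, 2)
  # two identical units: profile equals either one
  pr2 <- movie_profile(m, units[c(1, 1), ], measure = "log_duration")
  expect_equal(pr2$bins200, rep(log10(2), 200))
  # brute-force per-bin mean on a random fixture
  set.seed(3)
  durs <- round(10^rnorm(9, 0.6, 0.2), 3)
  m3 <- movie_annotation("m3", 2000, "drama", mk_unit_shots(durs))
  u3 <- tibble::tibble(unit_id = 1:2, first_shot = c(1L, 5L),
                       last_shot = c(4L, 9L), n_shots = c(4L, 5L),
                       duration_s = c(sum(durs[1:4]), sum(durs[5:9])))
  pr3 <- movie_profile(m3, u3, measure = "log_duration")
  want <- (resample_to_bins(log10(durs[1:4])) +
             resample_to_bins(log10(durs[5:9]))) / 2
  expect_equal(pr3$bins200, want)
  expect_equal(pr3$bins7, want[c(1, 33, 67, 100, 133, 167, 200)])
  # units below the shot minimum are rejected
  expect_error(movie_profile(m, units[1, ][0, ], measure = "log_duration"),
               "units")
})

test_that("a duration-scaled movie shifts its log profile by a constant", {
  set.seed(4)
  durs <- 10^rnorm(12, 0.7, 0.2)
  m1 <- movie_annotation("a", 2000, "drama", mk_unit_shots(durs))
  m2 <- movie_annotation("b", 2000, "drama", mk_unit_shots(3 * durs))
  u <- tibble::tibble(unit_id = 1L, first_shot = 1L, last_shot = 12L,
                      n_shots = 12L, duration_s = sum(durs))
  p1 <- movie_profile(m1, u)
  p2 <- movie_profile(m2, u)
  expect_equal(p2$bins200 - p1$bins200, rep(log10(3), 200))
})

test_that("quadratic trend reproduces exact quadratics and flat lines", {
  x <- 1:7
  q <- quadratic_trend((x - 4)^2)
  expect_equal(q$b2, 1, tolerance = 1e-9)
  expect_equal(q$r_squared, 1, tolerance = 1e-9)
  resid <- (x - 4)^2 - (q$b0 + q$b1 * x + q$b2 * x^2)
  expect_lt(max(abs(resid)) / max((x - 4)^2), 1e-9)

  flat <- quadratic_trend(rep(2, 7))
  expect_equal(flat$b1, 0, tolerance = 1e-12)
  expect_equal(flat$b2, 0, tolerance = 1e-12)

  # normal-equations oracle on a random vector
  set.seed(6)
  y <- rnorm(7)
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  q <- quadratic_trend(y)
  expect_equal(c(q$b0, q$b1, q$b2), as.vector(beta), tolerance = 1e-8)
  expect_equal(q$df1, 2)
  expect_equal(q$df2, 4)
})

# direct null profile generator: movie intercepts + iid bin noise, no kind
# effect -- used to calibrate the multilevel comparison's type-I error
null_profiles <- function(n_movies = 20) {
  ids <- sprintf("m%02d", seq_len(n_movies))
  d <- expand.grid(movie_id = ids, kind = c("scene", "subscene"), bin = 1:7,
                   stringsAsFactors = FALSE)
  m_int <- setNames(rnorm(n_movies, log10(4.5), 0.08), ids)
  d$y <- m_int[d$movie_id] + rnorm(nrow(d), 0, 0.04)
  tibble::as_tibble(d)
}

test_that("scene/subscene comparison is calibrated under the null", {
  set.seed(12)
  rej_level <- rej_int <- 0
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    cmp <- compare_scene_subscene(null_profiles())
    rej_level <- rej_level + (cmp$level_test$p < 0.05)
    rej_int <- rej_int + (cmp$interaction_test$p < 0.05)
  }
  # nominal .05, contract <= 1.5x nominal; binomial slack on 120 reps
  expect_lte(rej_level / n_rep, 0.075 + 2 * sqrt(0.075 * 0.925 / n_rep))
  expect_lte(rej_int / n_rep, 0.075 + 2 * sqrt(0.075 * 0.925 / n_rep))
})

test_that("planted level and shape differences are recovered in direction", {
  cfg <- generator_config(n_movies = 12L, scallop_curvature = 0.6,
                          subscene_curvature = 0, subscene_geo_mean_s = 3.5)
  corp <- generate_corpus(cfg, seed = 14)
  pipe <- run_pipeline(corp$movies)
  cmp <- compare_scene_subscene(corpus_profiles(pipe))
  expect_gt(cmp$mean_scene_s, cmp$mean_subscene_s)
  expect_lt(cmp$level_test$estimate, 0)       # subscenes shorter
  expect_lt(cmp$level_test$p, 0.001)
  expect_gt(cmp$quad_scene$b2, 0)             # scalloped scenes
  expect_gt(cmp$quad_scene$b2, cmp$quad_subscene$b2)
  expect_lt(cmp$interaction_test$p, 0.05)
})

test_that("a one-kind corpus yields partial output without a level test", {
  corp <- generate_corpus(small_config(n_movies = 3L, seq_rate_base = 0.0001,
                                       montage_rate = 0.0001), seed = 5)
  pipe <- run_pipeline(corp$movies)
  pr <- corpus_profiles(pipe)
  expect_true(all(pr$kind == "scene"))
  cmp <- compare_scene_subscene(pr)
  expect_null(cmp$level_test)
  expect_true(is.na(cmp$mean_subscene_s))
  expect_false(is.null(cmp$quad_scene))
})
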
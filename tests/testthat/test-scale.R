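test_that("pooling pairs each value with the right score at the right unit", {
  # 2 mice x 2 days, complete -> paw-level modality yields 2 hind paws each
  obs <- expand.grid(mouse_id = c("m1", "m2"), day = c(35, 42),
                     paw = c("LF", "RF", "LH", "RH"),
                     stringsAsFactors = FALSE)
  obs$modality <- "clinical_score"
  obs$value <- ifelse(obs$paw == "LH", 3, ifelse(obs$paw == "RH", 1, 2))
  lat <- expand.grid(mouse_id = c("m1", "m2"), day = c(35, 42),
                     paw = c("LH", "RH"), stringsAsFactors = FALSE)
  lat$modality <- "latency_s"
  lat$value <- 9
  dist <- expand.grid(mouse_id = c("m1", "m2"), day = c(35, 42),
                      stringsAsFactors = FALSE)
  dist$paw <- NA_character_; dist$modality <- "distance_cm"; dist$value <- 3000
  all_obs <- rbind(obs, lat, dist)
  sc <- build_scorecards(all_obs)

  pp <- pool_pairs(all_obs, sc, "latency_s")
  expect_equal(nrow(pp), 8)
  expect_equal(attr(pp, "max_score"), 10)
  expect_true(all(pp$score[pp$paw == "LH"] == 3))
  expect_true(all(pp$score[pp$paw == "RH"] == 1))

  ps <- pool_pairs(all_obs, sc, "latency_s", pairing = "summed-hind")
  expect_true(all(ps$score == 4))
  expect_equal(attr(ps, "max_score"), 20)

  pd <- pool_pairs(all_obs, sc, "distance_cm")
  expect_equal(nrow(pd), 4)
  expect_true(all(pd$score == 8))
  expect_equal(attr(pd, "max_score"), 40)

  # one missing latency drops exactly that pair
  pp2 <- pool_pairs(all_obs[-(nrow(obs) + 1), ], sc, "latency_s")
  expect_equal(nrow(pp2), 7)
  expect_error(pool_pairs(all_obs, sc, "von_frey"), "unknown modality")
})

test_that("OLS agrees with brute-force normal equations to 12 digits", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- sample(0:10, n, replace = TRUE)
    if (var(x) == 0) x[1] <- x[1] + 1
    y <- 5 - 0.3 * x + rnorm(n)
    fit <- fit_linear(x, y)
    oracle <- ols_normal_equations(x, y)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-12)
  }
})

test_that("Spearman r matches an exhaustive average-rank oracle, ties included", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(0:4, n, replace = TRUE)  # heavy ties, like score grids
    if (var(x) == 0) x[1] <- x[1] + 1
    y <- rnorm(n) + sample(0:2, n, replace = TRUE)
    fit <- fit_linear(x, y)
    expect_equal(fit$r, spearman_exhaustive(x, y), tolerance = 1e-12)
    expect_equal(fit$r, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("t-approximation p-values track the exact permutation p at small n", {
  set.seed(12)
  for (i in 1:5) {
    n <- 7
    x <- sample(0:10, n, replace = TRUE)
    if (var(x) == 0) x[1] <- x[1] + 1
    y <- 10 - 0.5 * x + rnorm(n, sd = 2)
    fit <- fit_linear(x, y)
    p_exact <- spearman_perm_p(x, y)
    # the approximation must agree with the exact null in rough magnitude
    expect_lt(abs(fit$p - p_exact), 0.15)
    # and match stats::cor.test's t approximation closely
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(fit$p, unname(ct$p.value), tolerance = 1e-9)
  }
})

test_that("collinear and degenerate samples follow the documented contracts", {
  fit <- fit_linear(c(0, 10, 20), c(10, 8, 6))
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r, -1)
  expect_equal(fit$p, 0)
  # constant functional values: degenerate flag, slope 0, r 0
  deg <- fit_linear(c(0, 1, 2, 3), rep(7, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$slope, 0)
  expect_equal(deg$r, 0)
  expect_error(fit_linear(c(1, 1), c(2, 3)), "at least 3")
  expect_error(fit_linear(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("noisy slope recovery stays within 3 standard errors at n = 5000", {
  cfg <- arthrism_config(seed = 2)
  set.seed(100)
  score <- sample(0:10, 5000, replace = TRUE)
  value <- emit_functional_value("latency_s", score, cfg)
  fit <- fit_linear(score, value)
  truth <- -cfg$modality_params$latency_s$baseline *
    cfg$modality_params$latency_s$true_slope / 10
  se <- sqrt(fit$vcov["slope", "slope"])
  expect_lt(abs(fit$slope - truth), 3 * se)
})

test_that("deficit curves follow the reference formula and hand-evaluated case", {
  fit <- structure(list(slope = -0.1, intercept = 20, r = -1, p = 0, n = 3,
                        degenerate = FALSE, vcov = matrix(0, 2, 2)),
                   class = "arthrism_fit")
  curve <- build_deficit_curve(fit, max_score = 40)
  expect_equal(curve$reference, 20)
  expect_equal(curve$deficit_slope_per_pct, 0.2)   # -slope*max/intercept
  deficit <- function(s_pct) curve$deficit_slope_per_pct * s_pct
  expect_identical(deficit(0), 0)                   # exact zero anchor
  expect_equal(deficit(100), 20)                    # 20% deficit at max score
  # linearity: deficit(a*s) = a*deficit(s)
  s <- c(5, 20, 50); a <- 1.7
  expect_equal(deficit(a * s), a * deficit(s), tolerance = 1e-14)
  # positive regression slope (skin temperature) -> negative deficits, kept
  gain <- build_deficit_curve(
    structure(list(slope = 0.03, intercept = 25, r = 0.5, p = 0.01, n = 10,
                   degenerate = FALSE, vcov = matrix(0, 2, 2)),
              class = "arthrism_fit"), 10)
  expect_lt(gain$deficit_slope_per_pct, 0)
  expect_error(build_deficit_curve(
    structure(list(slope = 1, intercept = 0), class = "arthrism_fit"), 10),
    "zero intercept")
})

test_that("equal motor ground truths give matching deficit slopes (noiseless)", {
  p <- noiseless_params(slopes = list(distance_cm = 0.5, print_area_mm2 = 0.5))
  cfg <- arthrism_config(n_per_group = c(naive = 3, cia = 10, cia_mtx = 8),
                         n_experiments = 1, incidence = 1,
                         modality_params = p, seed = 13)
  scale <- arthrism(simulate_cohort(cfg))
  s <- scale$scale
  expect_equal(s$deficit_slope_per_pct[s$modality == "distance_cm"],
               s$deficit_slope_per_pct[s$modality == "print_area_mm2"],
               tolerance = 1e-10)
})

test_that("a 2:1 motor/sensory ground truth yields responsiveness ratio 2", {
  p <- noiseless_params(slopes = list(latency_s = 0.26, distance_cm = 0.52,
                                      print_area_mm2 = 0.52))
  cfg <- arthrism_config(n_per_group = c(naive = 3, cia = 10, cia_mtx = 8),
                         n_experiments = 1, incidence = 1,
                         modality_params = p, seed = 14)
  scale <- arthrism(simulate_cohort(cfg))
  expect_equal(responsiveness_ratio(scale), 2, tolerance = 1e-9)
  # printed-example arithmetic: slopes 0.55 and 0.26 give 2.1154...
  hand <- structure(list(
    scale = data.frame(modality = c("latency_s", "distance_cm", "print_area_mm2"),
                       deficit_slope_per_pct = c(0.26, 0.55, 0.55))),
    class = "arthrism")
  expect_equal(responsiveness_ratio(hand), 0.55 / 0.26, tolerance = 1e-12)
})

test_that("unfittable modalities become gaps, or errors in strict mode", {
  cohort <- simulate_cohort(tiny_config())
  expect_warning(
    scale <- arthrism(cohort, modalities = c("latency_s", "von_frey")),
    "von_frey")
  expect_equal(scale$gaps, "von_frey")
  expect_true("latency_s" %in% scale$scale$modality)
  expect_error(arthrism(cohort, modalities = c("latency_s", "von_frey"),
                        strict = TRUE), "unfittable")
  expect_error(arthrism(cohort$observations[0, ]), "empty")
})

test_that("default cohorts echo the negative pooled correlations", {
  scale <- arthrism(simulate_cohort(arthrism_config(seed = 4)))
  expect_true(all(scale$scale$r < 0))
  expect_true(all(scale$scale$p < 0.01))
})
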
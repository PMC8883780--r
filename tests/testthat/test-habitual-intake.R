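test_that("transform selection recovers log for lognormal and identity for normal data", {
  set.seed(21)
  expect_equal(select_transform(exp(rnorm(2000, 3, 1)))$lambda, 0)
  set.seed(22)
  expect_equal(select_transform(pmax(rnorm(2000, 10, 3), 0.5))$lambda, 1)
  # grid pick agrees with an independent profile-likelihood oracle
  grid <- seq(0, 1, 0.1)
  for (seed in 24:27) {
    set.seed(seed)
    y <- exp(rnorm(300, 1, runif(1, 0.2, 0.8)))
    b <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
    expect_equal(select_transform(y)$lambda, b$x[which.max(b$y)])
  }
  set.seed(21)
  y <- exp(rnorm(500, 2, 0.4))
  expect_identical(select_transform(y), select_transform(y))  # deterministic
  expect_equal(select_transform(y)$shift, 0)
  yz <- c(y, 0)
  expect_equal(select_transform(yz)$shift, min(y) / 2)
  expect_error(select_transform(rep(0, 50)), "zero")
  expect_error(select_transform(exp(rnorm(10))), "at least 20")
})

test_that("variance components match hand ANOVA arithmetic and a mixed-model fit", {
  pd <- data.frame(participant_id = rep(c("a", "b", "c"), each = 2),
                   value = c(10, 14, 20, 16, 30, 34))
  vc <- fit_variance_components(pd)
  expect_equal(vc$sigma2_within, 8)
  expect_equal(vc$sigma2_between, var(c(12, 18, 32)) - 4)
  expect_equal(vc$mu, mean(c(12, 18, 32)))

  # independent cross-check: REML variance components from lme4 on a larger
  # balanced design agree with the method-of-moments estimates
  set.seed(31)
  n <- 400
  b <- rnorm(n, 0, 2); e <- matrix(rnorm(2 * n, 0, 1.5), n)
  pd2 <- data.frame(participant_id = rep(sprintf("p%03d", 1:n), each = 2),
                    value = as.numeric(t(10 + b + e)))
  vc2 <- fit_variance_components(pd2)
  fit <- lme4::lmer(value ~ 1 + (1 | participant_id), data = pd2,
                    REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(fit))$vcov
  expect_equal(vc2$sigma2_between, v[1], tolerance = 0.02)
  expect_equal(vc2$sigma2_within, v[2], tolerance = 0.02)

  # degenerate inputs
  pd3 <- data.frame(participant_id = rep(c("a", "b"), each = 2),
                    value = c(5, 5, 9, 9))
  vc3 <- fit_variance_components(pd3)
  expect_equal(vc3$sigma2_within, 0)
  expect_equal(vc3$sigma2_between, var(c(5, 9)))
  vc4 <- fit_variance_components(
    data.frame(participant_id = rep(c("a", "b"), each = 2), value = 7))
  expect_equal(vc4$sigma2_within, 0)
  expect_equal(vc4$sigma2_between, 0)
  expect_error(fit_variance_components(
    data.frame(participant_id = "a", value = c(1, 2))), "at least 2 persons")
})

test_that("shrinkage contracts person means by the reliability factor", {
  vc <- fit_variance_components(data.frame(
    participant_id = rep(c("a", "b", "c"), each = 2),
    value = c(10, 14, 20, 16, 30, 34)))
  t32 <- shrink_person_means(vc, person_means = 32, n_days = 2)
  c_i <- sqrt(vc$sigma2_between / (vc$sigma2_between + vc$sigma2_within / 2))
  expect_equal(t32, vc$mu + c_i * (32 - vc$mu))
  expect_equal(c_i, sqrt((105 + 1 / 3 - 4) / (105 + 1 / 3)), tolerance = 1e-12)

  # sigma2_within = 0: identity; sigma2_between = 0: collapse to mu
  vc0 <- list(mu = 5, sigma2_between = 3, sigma2_within = 0)
  expect_equal(shrink_person_means(vc0, person_means = c(1, 9), n_days = 2),
               c(1, 9))
  vcb <- list(mu = 5, sigma2_between = 0, sigma2_within = 3)
  expect_equal(shrink_person_means(vcb, person_means = c(1, 9), n_days = 2),
               c(5, 5))
})

test_that("back-transformation is exact for identity and log transforms", {
  comp <- list(mu = 0, sigma2_between = 1, sigma2_within = 0.16)
  # lambda = 1 is affine: quadrature collapses analytically
  tr1 <- list(lambda = 1, shift = 0.5)
  t_vals <- c(2, 5, 11)
  expect_equal(back_transform_habitual(tr1, comp, t_vals),
               (t_vals + 1) - 0.5)
  # lambda = 0: lognormal-mean closed form to 1e-6 relative
  tr0 <- list(lambda = 0, shift = 0.25)
  got <- back_transform_habitual(tr0, comp, t_vals)
  want <- exp(t_vals + 0.16 / 2) - 0.25
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("full pipeline is the identity for noise-free input and shrinks otherwise", {
  coh <- generate_known_habitual_cohort(50, log(70), 0.3, within_sd = 0,
                                        seed = 3)
  dist <- estimate_habitual_distribution(coh$daily)
  pm <- tapply(coh$daily$value, coh$daily$participant_id, mean)
  expect_equal(dist$person$habitual,
               as.numeric(pm[dist$person$participant_id]), tolerance = 1e-9)

  coh2 <- generate_known_habitual_cohort(400, log(70), 0.25, within_sd = 0.35,
                                         seed = 4)
  dist2 <- estimate_habitual_distribution(coh2$daily)
  expect_lt(sd(dist2$person$habitual), sd(dist2$person$person_mean))
})

test_that("fraction below the cut-off is a weighted proportion", {
  dist <- structure(list(person = data.frame(
    participant_id = c("a", "b", "c"),
    habitual = c(0.5, 1.5, 0.9),
    analysis_weight = c(1, 1, 2))), class = "habitual_distribution")
  expect_equal(fraction_below(dist, 1.0, per_kg = TRUE), 0.75)
  dist$person$habitual <- c(2, 3, 4)
  expect_equal(fraction_below(dist, 1.0, per_kg = TRUE), 0)
  expect_error(fraction_below(dist, 1.0, per_kg = FALSE), "body weights")
  dist$person$body_weight_kg <- c(1, 1, 10)
  expect_equal(fraction_below(dist, 1.0, per_kg = FALSE), 0.5)

  # invariance to person order and uniform weight rescaling
  coh <- generate_known_habitual_cohort(200, log(1.1), 0.25, 0.3, seed = 8)
  w <- data.frame(participant_id = unique(coh$daily$participant_id),
                  analysis_weight = runif(200, 0.5, 2))
  d1 <- estimate_habitual_distribution(coh$daily, weights = w)
  shuf <- coh$daily[sample(nrow(coh$daily)), ]
  w2 <- w; w2$analysis_weight <- w2$analysis_weight * 37
  d2 <- estimate_habitual_distribution(shuf, weights = w2)
  expect_equal(fraction_below(d1, 1.0, per_kg = TRUE),
               fraction_below(d2, 1.0, per_kg = TRUE))
  expect_equal(sort(d1$person$habitual), sort(d2$person$habitual))
})

test_that("weighted percentiles bracket the distribution sensibly", {
  coh <- generate_known_habitual_cohort(500, log(70), 0.25, 0.3, seed = 12)
  dist <- estimate_habitual_distribution(coh$daily)
  q <- habitual_percentiles(dist, probs = c(0.25, 0.5, 0.75))
  expect_true(all(diff(q) > 0))
  expect_equal(unname(q["p50"]), median(dist$person$habitual),
               tolerance = 0.01)
})
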
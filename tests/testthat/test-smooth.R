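sim_gauss_data <- function(seed, n_subj = 8, H = 144,
                           truth = function(h) sin(2 * pi * h / 24),
                           sd = 0.2, shift = 0) {
  set.seed(seed)
  tidyr::expand_grid(subject_id = sprintf("s%d", seq_len(n_subj)),
                     hour = 0:(H - 1)) |>
    dplyr::mutate(value = truth(hour) + shift + rnorm(dplyr::n(), 0, sd))
}

test_that("a noiseless constant series is fitted exactly", {
  d <- tidyr::expand_grid(subject_id = c("a", "b"), hour = 0:47) |>
    dplyr::mutate(value = 5)
  fit <- fit_group_smooth(d, k = 10)
  expect_lt(max(abs(fit$fitted - 5)), 1e-6)
})

test_that("a smooth circadian signal is recovered under noise", {
  d <- sim_gauss_data(21)
  fit <- fit_group_smooth(d, k = 30)
  rmse <- sqrt(mean((fit$fitted - sin(2 * pi * fit$hours / 24))^2))
  expect_lt(rmse, 0.1)
  expect_true(all(fit$se >= 0))
  expect_equal(nrow(tidy(fit)), 144)
})

test_that("quasipoisson fits recover a planted dispersion of 3", {
  disp <- vapply(1:40, function(s) {
    set.seed(s)
    d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:4), hour = 0:71) |>
      dplyr::mutate(mu = exp(3 + sin(2 * pi * hour / 24)),
                    value = rpois(dplyr::n(), mu * rgamma(dplyr::n(),
                                                          shape = mu / 2,
                                                          rate = mu / 2)))
    fit_group_smooth(d, k = 15, family = "quasipoisson")$dispersion
  }, numeric(1))
  expect_gte(median(disp), 2)
  expect_lte(median(disp), 4)
})

test_that("heavy smoothing collapses the gaussian fit onto the penalty null space", {
  d <- sim_gauss_data(5, truth = function(h) 0 * h, shift = 2)
  fit <- fit_group_smooth(d, k = 20, lambda = 1e12, variance = "constant")
  # second-order penalty: the limit is the least-squares line, here the mean
  line <- lm(value ~ hour, data = d)
  pred <- unname(predict(line, data.frame(hour = fit$hours)))
  expect_lt(max(abs(fit$fitted - pred)), 0.02)
  expect_lt(abs(mean(fit$fitted) - mean(d$value)), 0.02)
})

test_that("difference curves are exact antisymmetric contrasts", {
  dA <- sim_gauss_data(31)
  dB <- sim_gauss_data(32)
  kn <- spline_knots(dA$hour, 30)
  fA <- fit_group_smooth(dA, knots = kn, group = "A")
  fB <- fit_group_smooth(dB, knots = kn, group = "B")
  ab <- difference_curve(fA, fB)
  ba <- difference_curve(fB, fA)
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$se, ba$se)
  expect_true(all(ab$ci_lo <= ab$estimate & ab$estimate <= ab$ci_hi))
  # differencing a fit with itself is identically zero and unflagged
  self <- difference_curve(fA, fA)
  expect_true(all(self$estimate == 0))
  expect_false(any(self$significant))
  # the simultaneous band is strictly wider and flags a subset of hours
  sim <- difference_curve(fA, fB, band = "simultaneous")
  expect_true(all(sim$ci_hi - sim$ci_lo > ab$ci_hi - ab$ci_lo))
  expect_true(all(which(sim$significant) %in% which(ab$significant)))
  # mismatched grids are refused
  fC <- fit_group_smooth(sim_gauss_data(33, H = 48), k = 10, group = "C")
  expect_error(difference_curve(fA, fC), "share")
})

test_that("pointwise intervals cover the null difference at close to nominal rate", {
  hits <- vapply(1:60, function(s) {
    dA <- sim_gauss_data(4000 + s, n_subj = 4, H = 72)
    dB <- sim_gauss_data(8000 + s, n_subj = 4, H = 72)
    kn <- spline_knots(dA$hour, 20)
    dc <- difference_curve(fit_group_smooth(dA, knots = kn, group = "A"),
                           fit_group_smooth(dB, knots = kn, group = "B"))
    mean(!dc$significant)   # truth is zero everywhere
  }, numeric(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("the gaussian curve agrees with an independent penalized-spline fit", {
  skip_if_not_installed("mgcv")
  d <- sim_gauss_data(77, n_subj = 6)
  fit <- fit_group_smooth(d, k = 30, variance = "constant")
  g <- mgcv::gam(value ~ s(hour, k = 30, bs = "ps") +
                   s(subject_id, bs = "re"),
                 data = dplyr::mutate(d, subject_id = factor(subject_id)),
                 method = "GCV.Cp")
  ref <- stats::predict(
    g, newdata = data.frame(hour = fit$hours,
                            subject_id = factor("s1",
                                                levels = levels(factor(d$subject_id)))),
    exclude = "s(subject_id)")
  expect_lt(sqrt(mean((fit$fitted - ref)^2)), 0.05)
})

test_that("analyze_contrast dissociates time-localized effects from overall shifts", {
  # localized, zero-mean effect: interaction should fire, overall should not
  bump <- function(h) 0.6 * (((h %% 24) < 8) - 8 / 24)
  dA <- sim_gauss_data(91, n_subj = 7, truth = function(h)
    sin(2 * pi * h / 24) + bump(h))
  dB <- sim_gauss_data(92, n_subj = 7)
  dat <- dplyr::bind_rows(dplyr::mutate(dA, group = "KO"),
                          dplyr::mutate(dB, group = "WT"))
  cf <- analyze_contrast(dat, k = 30)
  expect_lt(cf$interaction$p_value, 0.05)
  expect_gt(cf$overall$p_value, 0.05)
  # a pure shift: overall fires
  dC <- sim_gauss_data(93, n_subj = 7, shift = 0.4)
  dat2 <- dplyr::bind_rows(dplyr::mutate(dC, group = "KO"),
                           dplyr::mutate(dB, group = "WT"))
  cf2 <- analyze_contrast(dat2, k = 30)
  expect_lt(cf2$overall$p_value, 0.05)
  expect_s3_class(glance(cf2), "tbl_df")
  expect_equal(nrow(tidy(cf2)), 144)
})

test_that("smooth fits validate their inputs", {
  d <- sim_gauss_data(1, n_subj = 2, H = 24)
  expect_error(fit_group_smooth(d, k = 40), "too large|too few")
  expect_error(fit_group_smooth(dplyr::filter(d, subject_id == "s1"), k = 5),
               ">= 2 subjects")
  expect_error(fit_group_smooth(dplyr::select(d, -value), k = 5), "lack column")
  expect_error(analyze_contrast(dplyr::mutate(d, group = "only"), k = 5),
               "2 group levels")
  expect_error(spline_knots(0:10, k = 3), ">= 4")
})
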
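#' @importFrom stats pf pnorm pt qnorm coef
NULL

#' Equally spaced cubic B-spline knots for an hour grid
#'
#' @param hours numeric vector of observation times (hours).
#' @param k basis dimension; must satisfy `k >= 4` and be below the
#'   number of distinct hours.
#' @return knot vector of length `k + 4` suitable for
#'   [splines::splineDesign()] with cubic (order 4) splines.
#' @export
spline_knots <- function(hours, k = 30) {
  ux <- sort(unique(hours))
  if (k < 4) stop_socioscope("basis dimension k must be >= 4")
  if (k >= length(ux)) {
    stop_socioscope("basis dimension k = %d too large for %d distinct hours",
                    k, length(ux))
  }
  # boundary knots nudged outward so every x stays strictly inside the
  # basis support despite floating-point knot arithmetic
  pad <- 1e-6 * (max(ux) - min(ux))
  xl <- min(ux) - pad
  xr <- max(ux) + pad
  dx <- (xr - xl) / (k - 3)
  xl + (seq_len(k + 4) - 4) * dx
}

bspline_basis <- function(x, knots) {
  splines::splineDesign(knots, x, ord = 4, outer.ok = FALSE)
}

nest_term <- function(nest_s, nest_form) {
  switch(nest_form,
         log_available = log(pmax(3600 - nest_s, 1) / 3600),
         seconds = nest_s)
}

# Core penalized estimator shared by all smooth fits.
#
# X = [Xs | Xf | Xr]: smooth basis (difference-penalized), fixed
# (unpenalized) columns, ridge-penalized columns.  lambda is selected by
# GCV on a deterministic log grid unless supplied.  family "gaussian"
# solves penalized least squares; "quasipoisson" runs penalized IRLS with
# log link and a free Pearson dispersion.
fit_pspline <- function(y, Xs, Xf = NULL, Xr = NULL,
                        penalty_order = 2, lambda = NULL, ridge = 1,
                        family = c("gaussian", "quasipoisson"),
                        prior_w = NULL, cluster = NULL,
                        lambda_grid = 10^seq(-2, 8, length.out = 41)) {
  family <- match.arg(family)
  n <- length(y)
  prior_w <- prior_w %||% rep(1, n)
  ks <- ncol(Xs)
  kf <- if (is.null(Xf)) 0L else ncol(Xf)
  kr <- if (is.null(Xr)) 0L else ncol(Xr)
  X <- cbind(Xs, Xf, Xr)
  p <- ncol(X)
  D <- diff(diag(ks), differences = penalty_order)
  S <- matrix(0, p, p)
  S[seq_len(ks), seq_len(ks)] <- crossprod(D)
  R <- diag(c(rep(0, ks + kf), rep(1, kr)), p)

  solve_at <- function(lam, w = NULL, z = NULL) {
    if (is.null(w)) {
      Xw <- X * prior_w
      XtX <- crossprod(Xw, X)
      Xty <- crossprod(Xw, y)
    } else {
      Xw <- X * w
      XtX <- crossprod(Xw, X)
      Xty <- crossprod(Xw, z)
    }
    A <- XtX + lam * S + ridge * R
    Ai <- tryCatch(solve(A), error = function(e) {
      stop_socioscope("singular penalized system: lower k or raise ridge")
    })
    beta <- drop(Ai %*% Xty)
    edf <- sum(diag(Ai %*% XtX))
    list(beta = beta, Ai = Ai, XtX = XtX, edf = edf)
  }

  fit_gaussian <- function(lam) {
    s <- solve_at(lam)
    res <- y - drop(X %*% s$beta)
    rss <- sum(prior_w * res^2)
    gcv <- n * rss / (n - s$edf)^2
    c(s, list(rss = rss, gcv = gcv, fitted = y - res))
  }

  fit_qp <- function(lam, eta0) {
    eta <- eta0
    dev_old <- Inf
    for (it in 1:50) {
      mu <- exp(eta)
      w <- mu
      z <- eta + (y - mu) / mu
      s <- solve_at(lam, w = w, z = z)
      eta <- drop(X %*% s$beta)
      mu <- exp(eta)
      dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      if (abs(dev - dev_old) < 1e-8 * (abs(dev) + 1e-8)) break
      dev_old <- dev
    }
    pearson <- sum((y - mu)^2 / mu)
    gcv <- n * pearson / (n - s$edf)^2
    c(s, list(rss = pearson, gcv = gcv, fitted = mu, eta = eta))
  }

  if (family == "gaussian") {
    if (is.null(lambda)) {
      fits <- lapply(lambda_grid, fit_gaussian)
      best <- which.min(vapply(fits, `[[`, 0, "gcv"))
      lambda <- lambda_grid[best]
      f <- fits[[best]]
    } else {
      f <- fit_gaussian(lambda)
    }
    phi <- f$rss / (n - f$edf)
  } else {
    eta0 <- log(pmax(y, 0) + stats::median(y[y > 0] %||% 1) * 0.1 + 0.1)
    if (is.null(lambda)) {
      best_gcv <- Inf
      f <- NULL
      for (lam in sort(lambda_grid, decreasing = TRUE)) {
        fl <- fit_qp(lam, eta0)
        eta0 <- fl$eta   # warm start down the grid
        if (fl$gcv < best_gcv) {
          best_gcv <- fl$gcv
          f <- fl
          lambda <- lam
        }
      }
    } else {
      f <- fit_qp(lambda, eta0)
    }
    phi <- f$rss / (n - f$edf)
  }

  # cluster-robust (working-independence sandwich) covariance: hourly
  # bins of one subject are serially dependent through multi-hour nest
  # bouts, which the model-based covariance cannot see
  Vr <- NULL
  if (!is.null(cluster)) {
    U <- if (family == "gaussian") {
      X * (prior_w * (y - f$fitted))
    } else {
      X * (y - f$fitted)
    }
    Uc <- rowsum(U, as.character(cluster))
    m <- nrow(Uc)
    if (m >= 3) {
      Vr <- f$Ai %*% crossprod(Uc) %*% f$Ai * m / (m - 1)
    }
  }

  list(beta = f$beta, Vp = f$Ai * phi, Vr = Vr, edf = f$edf,
       dispersion = phi, lambda = lambda, rss = f$rss,
       fitted_values = f$fitted, n = n,
       ks = ks, kf = kf, kr = kr, family = family,
       penalty_order = penalty_order, ridge = ridge)
}

#' Fit a penalized-spline time-course for one group
#'
#' Estimates a smooth group trajectory over the hourly grid from
#' repeated-measures data: a cubic B-spline in hour with a
#' difference penalty (weight chosen by generalized cross-validation on a
#' deterministic log grid), ridge-penalized per-subject intercepts for
#' subject heterogeneity, and an optional linear nest-occupancy
#' covariate. Gaussian fits use penalized least squares (intended for
#' log-transformed duration series); quasipoisson fits use penalized
#' IRLS with a log link and free dispersion (intended for distance
#' series).
#'
#' @param data tibble with columns `subject_id`, `hour`, `value` and
#'   optionally `nest_s` (seconds in nest that hour, used as covariate).
#' @param k basis dimension (default 30 over a 144-h recording).
#' @param family `"gaussian"` or `"quasipoisson"`.
#' @param knots optional shared knot vector from [spline_knots()]; two
#'   fits to be differenced must share it.
#' @param lambda optional fixed smoothing weight; default `NULL` selects
#'   by GCV.
#' @param ridge ridge weight on the subject intercepts.
#' @param penalty_order difference-penalty order (default 2: the
#'   unpenalized null space is the linear trend).
#' @param nest_form how the nest covariate enters the linear predictor.
#'   Social behavior is unobservable while the subject is nested, so the
#'   expected hourly total scales with the out-of-nest fraction of the
#'   hour; on the log scale that is an additive `log((3600 - nest_s) /
#'   3600)` term with slope near one. `"log_available"` (default) uses
#'   that form — it also removes most of the serial dependence that
#'   multi-hour nest bouts would otherwise leave in the residuals;
#'   `"seconds"` enters raw seconds-in-nest linearly.
#' @param cov_type `"model"` (default) uses the penalized-likelihood
#'   coefficient covariance; `"cluster_robust"` substitutes a by-subject
#'   sandwich estimate (only advisable when subjects clearly outnumber
#'   the effective degrees of freedom).
#' @param variance gaussian fits only: `"by_hour_of_day"` (default)
#'   estimates a working residual variance for each of the 24 hours of
#'   day and refits with inverse-variance weights — circadian series are
#'   strongly heteroscedastic (near-zero light-phase bins against busy
#'   dark-phase bins), and a constant dispersion would miscalibrate the
#'   pointwise intervals; `"constant"` keeps a single dispersion.
#' @param group optional group label stored on the fit.
#' @return a `smooth_fit` object: coefficients and their Bayesian
#'   covariance, effective degrees of freedom, dispersion, and the
#'   fitted curve with pointwise standard errors on the hour grid
#'   (evaluated at the average subject and mean nest covariate).
#' @export
fit_group_smooth <- function(data, k = 30,
                             family = c("gaussian", "quasipoisson"),
                             knots = NULL, lambda = NULL, ridge = 1,
                             penalty_order = 2,
                             nest_form = c("log_available", "seconds"),
                             cov_type = c("model", "cluster_robust"),
                             variance = c("by_hour_of_day", "constant"),
                             group = NULL) {
  family <- match.arg(family)
  nest_form <- match.arg(nest_form)
  cov_type <- match.arg(cov_type)
  variance <- match.arg(variance)
  data <- tibble::as_tibble(data)
  for (nm in c("subject_id", "hour", "value")) {
    if (!nm %in% names(data)) stop_socioscope("data lack column `%s`", nm)
  }
  subjects <- sort(unique(data$subject_id))
  if (length(subjects) < 2) stop_socioscope("need >= 2 subjects")
  knots <- knots %||% spline_knots(data$hour, k)
  k <- length(knots) - 4L
  if (2 * k > length(unique(data$hour)) * length(subjects)) {
    stop_socioscope("too few observations for basis dimension k = %d", k)
  }
  Xs <- bspline_basis(data$hour, knots)
  has_nest <- "nest_s" %in% names(data)
  Xf <- if (has_nest) cbind(nest = nest_term(data$nest_s, nest_form)) else NULL
  Xr <- stats::model.matrix(~ 0 + factor(subject_id, levels = subjects),
                            data = data)
  colnames(Xr) <- subjects

  eng <- fit_pspline(data$value, Xs, Xf, Xr, penalty_order = penalty_order,
                     lambda = lambda, ridge = ridge, family = family,
                     cluster = data$subject_id)
  if (family == "gaussian" && variance == "by_hour_of_day") {
    # working-variance refit: residual variance by hour of day, then
    # inverse-variance weighted penalized least squares
    res <- data$value - eng$fitted_values
    hod <- data$hour %% 24
    # with few replicates per hour of day, pool the variance by phase
    g <- if (eng$n / 24 >= 20) as.character(hod)
      else if ("phase" %in% names(data)) as.character(data$phase)
      else as.character(hod %/% 12)
    v <- tapply(res^2, g, mean) * eng$n / max(eng$n - eng$edf, 1)
    if (max(v) > 1e-10) {
      v <- pmax(v, 1e-3 * max(v))
      eng <- fit_pspline(data$value, Xs, Xf, Xr,
                         penalty_order = penalty_order, lambda = lambda,
                         ridge = ridge, family = family,
                         prior_w = as.numeric(1 / v[g]),
                         cluster = data$subject_id)
    }
  }

  Vp <- if (cov_type == "cluster_robust" && !is.null(eng$Vr)) eng$Vr else
    eng$Vp
  hours <- sort(unique(data$hour))
  nest_mean <- if (has_nest) mean(nest_term(data$nest_s, nest_form)) else NULL
  Cg <- cbind(bspline_basis(hours, knots),
              if (has_nest) matrix(nest_mean, length(hours), 1),
              matrix(1 / length(subjects), length(hours), length(subjects)))
  est <- drop(Cg %*% eng$beta)
  se <- sqrt(pmax(rowSums((Cg %*% Vp) * Cg), 0))

  structure(
    list(group = group, family = family, knots = knots, k = k,
         penalty_order = penalty_order, lambda = eng$lambda,
         ridge = ridge, beta = eng$beta, Vp = Vp, cov_type = cov_type,
         edf = eng$edf,
         dispersion = eng$dispersion, rss = eng$rss, n = eng$n,
         hours = hours, fitted = est, se = se, subjects = subjects,
         has_nest = has_nest, nest_form = nest_form, nest_mean = nest_mean,
         Cgrid = Cg, data = data),
    class = "smooth_fit"
  )
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf(
    "<smooth_fit%s> %s, k = %d, lambda = %.3g, edf = %.1f, dispersion = %.3g\n",
    if (is.null(x$group)) "" else paste0(": ", x$group),
    x$family, x$k, x$lambda, x$edf, x$dispersion))
  cat(sprintf("  %d obs, %d subjects, %d hours%s\n", x$n,
              length(x$subjects), length(x$hours),
              if (x$has_nest) ", nest covariate" else ""))
  invisible(x)
}

#' Tidy a smooth fit into its per-hour curve
#'
#' @param x a `smooth_fit`.
#' @param ... unused.
#' @return tibble `hour`, `estimate`, `se` (and `group` when labelled).
#' @export
tidy.smooth_fit <- function(x, ...) {
  out <- tibble::tibble(hour = x$hours, estimate = x$fitted, se = x$se)
  if (!is.null(x$group)) out <- dplyr::mutate(out, group = x$group, .before = 1)
  out
}

#' @rdname tidy.smooth_fit
#' @export
glance.smooth_fit <- function(x, ...) {
  tibble::tibble(family = x$family, k = x$k, lambda = x$lambda,
                 edf = x$edf, dispersion = x$dispersion, n = x$n,
                 n_subjects = length(x$subjects))
}

#' Smooth group contrast over time with pointwise intervals
#'
#' The difference plot: `estimate(t) = fitted_A(t) - fitted_B(t)` with
#' pointwise variance summed from the two independent fits' coefficient
#' covariances. Hours whose interval excludes zero are flagged
#' significant; no multiplicity correction is applied (a flagged hour is
#' a pointwise statement). The attribute `overall_p` carries a Wald test
#' of the mean offset of curve A over curve B across the grid.
#'
#' @param fitA,fitB two [fit_group_smooth()] objects sharing knots and
#'   hour grid.
#' @param level pointwise confidence level (default 0.95).
#' @param band `"pointwise"` (default) flags hours whose individual 95%
#'   interval excludes zero, mirroring how difference plots are read;
#'   `"simultaneous"` widens the critical value to cover the whole
#'   curve at `level`, using the max-statistic of the fitted curves'
#'   joint covariance (deterministic Monte Carlo).
#' @return a `difference_curve` tibble: `hour`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `significant`.
#' @export
difference_curve <- function(fitA, fitB, level = 0.95,
                             band = c("pointwise", "simultaneous")) {
  band <- match.arg(band)
  if (!isTRUE(all.equal(fitA$knots, fitB$knots)) ||
      !isTRUE(all.equal(fitA$hours, fitB$hours))) {
    stop_socioscope("fits do not share basis knots and hour grid")
  }
  est <- fitA$fitted - fitB$fitted
  se <- sqrt(fitA$se^2 + fitB$se^2)
  if (band == "pointwise") {
    z <- qnorm(1 - (1 - level) / 2)
  } else {
    # simultaneous critical value: quantile of max_t |Z(t)| under the
    # joint gaussian law of the standardized difference curve
    V <- fitA$Cgrid %*% fitA$Vp %*% t(fitA$Cgrid) +
      fitB$Cgrid %*% fitB$Vp %*% t(fitB$Cgrid)
    R <- V / tcrossprod(sqrt(pmax(diag(V), 1e-300)))
    L <- chol(R + diag(1e-8, nrow(R)))
    z <- with_seed(1L, {
      mx <- vapply(seq_len(5000), function(i) {
        max(abs(drop(crossprod(L, stats::rnorm(nrow(R))))))
      }, numeric(1))
      stats::quantile(mx, level, names = FALSE)
    })
  }
  out <- tibble::tibble(
    hour = fitA$hours, estimate = est, se = se,
    ci_lo = est - z * se, ci_hi = est + z * se
  ) |>
    dplyr::mutate(significant = .data$ci_lo > 0 | .data$ci_hi < 0)

  cbarA <- colMeans(fitA$Cgrid)
  cbarB <- colMeans(fitB$Cgrid)
  mean_off <- mean(est)
  var_off <- drop(cbarA %*% fitA$Vp %*% cbarA + cbarB %*% fitB$Vp %*% cbarB)
  wald_z <- mean_off / sqrt(var_off)

  structure(out,
            class = c("difference_curve", class(out)),
            groups = c(fitA$group %||% "A", fitB$group %||% "B"),
            level = level,
            overall_p = 2 * pnorm(-abs(wald_z)))
}

#' Two-group longitudinal contrast with interaction and overall tests
#'
#' Orchestrates the full comparison behind a KO-vs-WT (or drug-vs-vehicle)
#' panel: per-group penalized-spline fits on a shared basis, the
#' difference curve with pointwise intervals, an F-type test of the
#' group-by-time interaction (separate smooths vs a shared smooth plus a
#' group offset, on effective degrees of freedom), and an overall group
#' effect assessed as a Welch test on per-subject mean responses — the
#' Wald test of the group mean offset that respects between-subject
#' variation under repeated measures.
#'
#' @param data tibble with columns `subject_id`, `hour`, `value`, a group
#'   column with exactly two levels, and optionally `nest_s`.
#' @param group_col name of the group column (default `"group"`).
#' @inheritParams fit_group_smooth
#' @param level pointwise level for the difference curve.
#' @return a `contrast_fit` object with elements `fits` (named list of
#'   the two `smooth_fit`s, first level minus second), `curve`
#'   (the [difference_curve()]), `interaction` and `overall` test
#'   tibbles.
#' @export
analyze_contrast <- function(data, group_col = "group", k = 30,
                             family = c("gaussian", "quasipoisson"),
                             lambda = NULL, ridge = 1, level = 0.95,
                             nest_form = c("log_available", "seconds"),
                             cov_type = c("model", "cluster_robust")) {
  family <- match.arg(family)
  nest_form <- match.arg(nest_form)
  cov_type <- match.arg(cov_type)
  data <- tibble::as_tibble(data)
  if (!group_col %in% names(data)) {
    stop_socioscope("data lack group column `%s`", group_col)
  }
  lv <- sort(unique(as.character(data[[group_col]])))
  if (length(lv) != 2) stop_socioscope("need exactly 2 group levels, got %d",
                                       length(lv))
  knots <- spline_knots(data$hour, k)
  fits <- lapply(stats::setNames(lv, lv), function(g) {
    fit_group_smooth(data[data[[group_col]] == g, ], k = k, family = family,
                     knots = knots, lambda = lambda, ridge = ridge,
                     nest_form = nest_form, cov_type = cov_type, group = g)
  })
  curve <- difference_curve(fits[[1]], fits[[2]], level = level)

  # interaction: does allowing separate smooths beat one shared smooth
  # plus a constant group offset?  Compared on unweighted RSS so the two
  # nested fits are on the same scale.
  shared <- fit_shared_smooth(data, group_col, lv, knots, family, ridge,
                              nest_form)
  sep <- if (family == "gaussian") {
    lapply(lv, function(g) {
      fit_group_smooth(data[data[[group_col]] == g, ], k = k,
                       family = family, knots = knots, lambda = lambda,
                       ridge = ridge, nest_form = nest_form,
                       cov_type = "model", variance = "constant", group = g)
    })
  } else fits
  rss1 <- sep[[1]]$rss + sep[[2]]$rss
  edf1 <- sep[[1]]$edf + sep[[2]]$edf
  df1 <- max(edf1 - shared$edf, 0.5)
  df2 <- max(nrow(data) - edf1, 1)
  Fstat <- max((shared$rss - rss1) / df1, 0) / (rss1 / df2)
  interaction <- tibble::tibble(
    statistic = Fstat, edf_separate = edf1, edf_shared = shared$edf,
    df1 = df1, df2 = df2, p_value = pf(Fstat, df1, df2, lower.tail = FALSE)
  )

  # overall group offset on per-subject means (link scale for counts)
  link_val <- if (family == "quasipoisson") log(data$value + 1) else data$value
  subj <- tibble::tibble(subject_id = data$subject_id,
                         g = as.character(data[[group_col]]),
                         v = link_val) |>
    dplyr::group_by(.data$subject_id, .data$g) |>
    dplyr::summarise(m = mean(.data$v), .groups = "drop")
  tt <- stats::t.test(subj$m[subj$g == lv[1]], subj$m[subj$g == lv[2]])
  overall <- tibble::tibble(
    estimate = unname(diff(rev(tt$estimate))), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value
  )

  structure(
    list(fits = fits, curve = curve, interaction = interaction,
         overall = overall, family = family, groups = lv, k = k),
    class = "contrast_fit"
  )
}

fit_shared_smooth <- function(data, group_col, lv, knots, family, ridge,
                              nest_form = "log_available") {
  Xs <- bspline_basis(data$hour, knots)
  gdum <- as.numeric(as.character(data[[group_col]]) == lv[1])
  Xf <- cbind(group = gdum,
              if ("nest_s" %in% names(data)) {
                cbind(nest = nest_term(data$nest_s, nest_form))
              })
  subjects <- sort(unique(data$subject_id))
  Xr <- stats::model.matrix(~ 0 + factor(subject_id, levels = subjects),
                            data = data)
  fit_pspline(data$value, Xs, Xf, Xr, ridge = ridge, family = family)
}

#' @export
print.contrast_fit <- function(x, ...) {
  cat(sprintf("<contrast_fit> %s vs %s  [%s, k = %d]\n",
              x$groups[1], x$groups[2], x$family, x$k))
  cat(sprintf("  interaction: F = %.2f (edf %.1f vs %.1f), p = %.3g\n",
              x$interaction$statistic, x$interaction$edf_separate,
              x$interaction$edf_shared, x$interaction$p_value))
  cat(sprintf("  overall: t = %.2f, df = %.1f, p = %.3g\n",
              x$overall$statistic, x$overall$df, x$overall$p_value))
  cat(sprintf("  flagged hours: %d of %d\n", sum(x$curve$significant),
              nrow(x$curve)))
  invisible(x)
}

#' Tidy / summarise a two-group contrast
#'
#' @param x a `contrast_fit`.
#' @param ... unused.
#' @return [tidy()] the per-hour difference curve; [glance()] a one-row
#'   summary with interaction and overall tests.
#' @export
tidy.contrast_fit <- function(x, ...) tibble::as_tibble(x$curve)

#' @rdname tidy.contrast_fit
#' @export
glance.contrast_fit <- function(x, ...) {
  tibble::tibble(
    group_a = x$groups[1], group_b = x$groups[2], family = x$family,
    interaction_F = x$interaction$statistic,
    interaction_df1 = x$interaction$df1, interaction_df2 = x$interaction$df2,
    interaction_p = x$interaction$p_value,
    overall_estimate = x$overall$estimate, overall_p = x$overall$p_value,
    n_hours_flagged = sum(x$curve$significant), n_hours = nrow(x$curve)
  )
}
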
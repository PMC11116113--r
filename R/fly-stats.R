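#' Shapiro-Wilk normality gate
#'
#' Arena-level responses are screened for normality before model choice:
#' responses passing the gate are analyzed with a gaussian linear model,
#' counts failing it with a log-link Poisson GLM and per-event mean
#' durations with a log-link Gamma GLM.
#'
#' @param values numeric vector, at least 3 finite values.
#' @param alpha gate level; the default 0.05 is used throughout.
#' @return one-row tibble: `W`, `p_value`, `normal` (`p_value >= alpha`).
#' @export
#' @examples
#' normality_gate(rnorm(20))
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop_socioscope("normality gate needs at least 3 finite values")
  }
  if (stats::sd(values) == 0) {
    stop_socioscope("normality gate undefined for a constant vector")
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value,
                 normal = sw$p.value >= alpha)
}

#' Fit the arena-level group model for one fly response
#'
#' Fits `response ~ sex + genotype` on arena summaries (one row per group
#' of flies; the arena, not the fly, is the unit of analysis). The family
#' follows the response type: gaussian linear model for speed, Poisson
#' GLM (log link) for interaction counts, Gamma GLM (log link) for mean
#' event durations. Per-term type-II analysis-of-deviance statistics are
#' reported alongside the joint test of both design terms against the
#' intercept-only model.
#'
#' @param summaries data frame with one row per arena, containing the
#'   response column plus factors `sex` and `genotype`.
#' @param response name of the response column.
#' @param family `"gaussian"`, `"poisson"` or `"gamma"`.
#' @return a `fly_stats_fit` object; see [tidy.fly_stats_fit()] and
#'   [glance.fly_stats_fit()].
#' @export
fit_group_model <- function(summaries, response,
                            family = c("gaussian", "poisson", "gamma")) {
  family <- match.arg(family)
  summaries <- tibble::as_tibble(summaries)
  for (nm in c(response, "sex", "genotype")) {
    if (!nm %in% names(summaries)) {
      stop_socioscope("summaries lack column `%s`", nm)
    }
  }
  summaries <- dplyr::filter(summaries, is.finite(.data[[response]]))
  if (length(unique(summaries$genotype)) < 2) {
    stop_socioscope("need at least 2 genotype levels")
  }
  y <- summaries[[response]]
  if (family == "gamma" && any(y <= 0)) {
    stop_socioscope("Gamma family requires strictly positive responses")
  }

  fml <- stats::as.formula(paste(response, "~ sex + genotype"))
  fit <- switch(
    family,
    gaussian = stats::lm(fml, data = summaries),
    poisson = stats::glm(fml, data = summaries,
                         family = stats::poisson(link = "log")),
    gamma = stats::glm(fml, data = summaries,
                       family = stats::Gamma(link = "log"))
  )

  # type-II per-term tests: each design term adjusted for the other
  an <- car::Anova(fit, type = "II",
                   test.statistic = if (family == "gaussian") "F" else "LR")
  an_df <- as.data.frame(an)
  terms_tb <- tibble::tibble(
    term = rownames(an_df),
    statistic = an_df[[1]],
    df = an_df[["Df"]],
    p_value = an_df[[grep("^Pr", names(an_df))[1]]]
  ) |>
    dplyr::filter(.data$term %in% c("sex", "genotype"))

  # joint 2-df test of sex + genotype against the intercept-only model
  null_fit <- stats::update(fit, . ~ 1)
  if (family == "gaussian") {
    cmp <- stats::anova(null_fit, fit)
    joint <- tibble::tibble(statistic = cmp$F[2], df = cmp$Df[2],
                            df_resid = cmp$Res.Df[2], p_value = cmp$`Pr(>F)`[2],
                            test = "F")
  } else {
    cmp <- stats::anova(null_fit, fit, test = "LRT")
    joint <- tibble::tibble(statistic = cmp$Deviance[2], df = cmp$Df[2],
                            df_resid = stats::df.residual(fit),
                            p_value = cmp$`Pr(>Chi)`[2], test = "chisq")
  }

  gate <- normality_gate(y)
  structure(
    list(model = fit, response = response, family = family,
         terms = terms_tb, joint = joint, normality = gate,
         n = nrow(summaries)),
    class = "fly_stats_fit"
  )
}

#' Suggest a model family from the normality gate
#'
#' @param values arena-level response values.
#' @param response_type `"count"`, `"duration"` or `"speed"`; decides
#'   which GLM family replaces the gaussian model when the gate fails.
#' @return `"gaussian"`, `"poisson"` or `"gamma"`.
#' @export
choose_family <- function(values,
                          response_type = c("count", "duration", "speed")) {
  response_type <- match.arg(response_type)
  if (normality_gate(values)$normal) return("gaussian")
  switch(response_type, count = "poisson", duration = "gamma",
         speed = "gaussian")
}

#' @export
print.fly_stats_fit <- function(x, ...) {
  cat(sprintf("<fly_stats_fit> %s ~ sex + genotype  [%s, n = %d arenas]\n",
              x$response, x$family, x$n))
  cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.3g\n",
              x$normality$W, x$normality$p_value))
  cat(sprintf("  joint (sex+genotype): %s = %.3f, df = %d, p = %.3g\n",
              x$joint$test, x$joint$statistic, x$joint$df, x$joint$p_value))
  print(x$terms)
  invisible(x)
}

#' Tidy / summarise a fly group-model fit
#'
#' @param x a `fly_stats_fit`.
#' @param ... unused.
#' @return [tidy()] a tibble of per-term type-II statistics; [glance()]
#'   a one-row model summary.
#' @importFrom generics tidy glance
#' @export
tidy.fly_stats_fit <- function(x, ...) {
  dplyr::mutate(x$terms, response = x$response, family = x$family,
                .before = 1)
}

#' @rdname tidy.fly_stats_fit
#' @export
glance.fly_stats_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, family = x$family, n = x$n,
    shapiro_W = x$normality$W, shapiro_p = x$normality$p_value,
    joint_statistic = x$joint$statistic, joint_df = x$joint$df,
    joint_p = x$joint$p_value,
    genotype_coef = tryCatch(
      stats::coef(x$model)[[grep("^genotype", names(stats::coef(x$model)))[1]]],
      error = function(e) NA_real_)
  )
}
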
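#' Between-study heterogeneity: Cochran's Q, I-squared, DL tau-squared
#'
#' With inverse-variance weights `w_i = 1/se_i^2` and the fixed-effect
#' pooled log OR `m = sum(w_i * theta_i) / sum(w_i)`, Cochran's Q is
#' `sum(w_i * (theta_i - m)^2)`, referred to a chi-squared distribution
#' with `k - 1` degrees of freedom. `I2 = max(0, (Q - df) / Q) * 100` is
#' the percentage of total variation attributable to heterogeneity rather
#' than chance, and `tau2` is the DerSimonian-Laird moment estimate of the
#' between-study variance, `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' @param effects A tibble with columns `log_or` and `se`, as produced by
#'   [study_effects()].
#' @return A one-row tibble: `k`, `q`, `df`, `p_q`, `i2`, `tau2`.
#' @examples
#' rs1564282_studies() |> study_effects() |> heterogeneity()
#' @export
heterogeneity <- function(effects) {
  check_effects(effects, min_k = 2)
  theta <- effects$log_or
  w <- 1 / effects$se^2
  k <- length(theta)
  m <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - m)^2)
  df <- k - 1
  p_q <- pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  tibble(k = k, q = q, df = df, p_q = p_q, i2 = i2, tau2 = tau2)
}

#' Choose the pooling model from the heterogeneity result
#'
#' Returns `"random"` if and only if the Q-test p-value is below
#' `p_threshold` AND I-squared exceeds `i2_threshold` - both conditions are
#' required - and `"fixed"` otherwise.
#'
#' @param het A one-row tibble from [heterogeneity()].
#' @param p_threshold Q-test p-value threshold (default 0.1).
#' @param i2_threshold I-squared threshold in percent (default 50).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, p_threshold = 0.1, i2_threshold = 50) {
  if (isTRUE(het$p_q < p_threshold) && isTRUE(het$i2 > i2_threshold)) {
    "random"
  } else {
    "fixed"
  }
}

#' Pool per-study effects by inverse-variance weighting
#'
#' Pools log odds ratios with inverse-variance weights. Under the fixed
#' effect model `w_i = 1/se_i^2`; under the DerSimonian-Laird random
#' effects model `w_i = 1/(se_i^2 + tau2)` with `tau2` from
#' [heterogeneity()]. `model = "auto"` (the default) applies
#' [select_model()]: random effects only when the Q test is significant at
#' `q_p_threshold` and I-squared exceeds `i2_threshold`. The pooled log OR
#' is tested with a two-sided Z test.
#'
#' @param effects A tibble with columns `study_id`, `log_or`, `se`.
#' @param model `"auto"`, `"fixed"`, or `"random"`.
#' @param alpha Two-sided level for the pooled CI (default 0.05).
#' @param q_p_threshold,i2_threshold Model-selection thresholds, see
#'   [select_model()].
#' @return A `pooled_or` object: a list with the pooled `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p`, the `model` used, normalized
#'   per-study `weights`, the `heterogeneity` tibble and the input
#'   `effects`. Use [tidy()][generics::tidy] and
#'   [glance()][generics::glance] for tibble views.
#' @examples
#' rs1564282_studies() |> study_effects() |> pool_effects()
#' @export
pool_effects <- function(effects, model = c("auto", "fixed", "random"),
                         alpha = 0.05, q_p_threshold = 0.1, i2_threshold = 50) {
  model <- match.arg(model)
  check_effects(effects, min_k = 1)
  k <- nrow(effects)
  het <- if (k >= 2) {
    heterogeneity(effects)
  } else {
    tibble(k = 1L, q = NA_real_, df = 0L, p_q = NA_real_, i2 = NA_real_,
           tau2 = 0)
  }
  if (model == "auto") {
    model <- if (k >= 2) select_model(het, q_p_threshold, i2_threshold) else "fixed"
  }
  if (model == "random" && k < 2) {
    abort("Random-effects pooling needs at least 2 studies.",
          class = "allelemeta_insufficient_studies")
  }
  tau2 <- if (model == "random") het$tau2 else 0
  w <- 1 / (effects$se^2 + tau2)
  log_or <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- log_or / se
  p <- 2 * pnorm(-abs(z))
  zq <- z_quantile(alpha)
  structure(
    list(
      model = model,
      log_or = log_or,
      se = se,
      or = exp(log_or),
      ci_low = exp(log_or - zq * se),
      ci_high = exp(log_or + zq * se),
      z = z,
      p = p,
      alpha = alpha,
      k = k,
      weights = tibble(
        study_id = effects$study_id,
        weight = w / sum(w),
        weight_pct = 100 * w / sum(w)
      ),
      heterogeneity = het,
      effects = as_tibble(effects)
    ),
    class = "pooled_or"
  )
}

#' Mantel-Haenszel pooled odds ratio
#'
#' Stratified Mantel-Haenszel estimate over the per-study allele 2x2
#' tables, with the Robins-Breslow-Greenland variance for its log. Provided
#' as an independent cross-check on the inverse-variance pooling - it is
#' not the default pipeline estimator.
#'
#' @param effects A tibble with allele-count columns `case_t`, `case_c`,
#'   `control_t`, `control_c`, as produced by [study_effects()] or
#'   [allele_counts()].
#' @param alpha Two-sided level for the CI (default 0.05).
#' @return A one-row tibble: `or`, `log_or`, `se`, `ci_low`, `ci_high`.
#' @export
or_mantel_haenszel <- function(effects, alpha = 0.05) {
  need <- c("case_t", "case_c", "control_t", "control_c")
  if (!all(need %in% names(effects))) {
    abort("`effects` must carry the four allele-count columns.",
          class = "allelemeta_format_error")
  }
  a <- effects$case_t; b <- effects$case_c
  c_ <- effects$control_t; d <- effects$control_c
  n <- a + b + c_ + d
  r <- a * d / n
  s <- b * c_ / n
  or <- sum(r) / sum(s)
  p_ <- (a + d) / n
  q_ <- (b + c_) / n
  var_log <- sum(p_ * r) / (2 * sum(r)^2) +
    sum(p_ * s + q_ * r) / (2 * sum(r) * sum(s)) +
    sum(q_ * s) / (2 * sum(s)^2)
  se <- sqrt(var_log)
  zq <- z_quantile(alpha)
  tibble(or = or, log_or = log(or), se = se,
         ci_low = exp(log(or) - zq * se), ci_high = exp(log(or) + zq * se))
}

check_effects <- function(effects, min_k = 1) {
  if (!is.data.frame(effects) || !all(c("log_or", "se") %in% names(effects))) {
    abort("`effects` must be a data frame with columns `log_or` and `se`.",
          class = "allelemeta_format_error")
  }
  if (nrow(effects) < min_k) {
    abort(sprintf("At least %d studies required, got %d.", min_k, nrow(effects)),
          class = "allelemeta_insufficient_studies")
  }
  if (any(!is.finite(effects$se)) || any(effects$se <= 0)) {
    abort("All standard errors must be finite and > 0.",
          class = "allelemeta_validation_error")
  }
  if (any(!is.finite(effects$log_or))) {
    abort("All log odds ratios must be finite.",
          class = "allelemeta_validation_error")
  }
  invisible(effects)
}

#' @export
print.pooled_or <- function(x, ...) {
  cat(sprintf("Pooled odds ratio (%s-effect, inverse variance, k = %d)\n",
              x$model, x$k))
  cat(sprintf("  OR %.2f, %d%% CI %.2f-%.2f, Z = %.2f, p %s\n",
              x$or, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$z,
              format_p(x$p)))
  if (x$k >= 2) {
    cat(sprintf("  Heterogeneity: Q = %.2f (df = %d, p = %s), I2 = %.0f%%, tau2 = %.4g\n",
                x$heterogeneity$q, x$heterogeneity$df,
                format_p(x$heterogeneity$p_q), x$heterogeneity$i2,
                x$heterogeneity$tau2))
  }
  invisible(x)
}

#' @rdname pool_effects
#' @param x A `pooled_or` object.
#' @param ... Unused.
#' @export
tidy.pooled_or <- function(x, ...) {
  tibble(
    term = "pooled_log_or", model = x$model,
    estimate = x$log_or, std.error = x$se,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    statistic = x$z, p.value = x$p
  )
}

#' @rdname pool_effects
#' @export
glance.pooled_or <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model = x$model, or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
           z = x$z, p = x$p),
    x$heterogeneity
  )
}

format_p <- function(p) {
  ifelse(p < 1e-15, "< 1e-15", sprintf("%.2g", p))
}
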
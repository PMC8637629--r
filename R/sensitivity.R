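#' Leave-one-out sensitivity analysis
#'
#' Omits each study in turn and re-runs the whole downstream pipeline on
#' the remaining studies: allele-table construction, per-study effects,
#' heterogeneity assessment, model selection and pooling. The fixed/random
#' choice is re-applied within every reduced set rather than frozen at the
#' full-data choice.
#'
#' @param studies A study-table data frame with at least 3 studies.
#' @param correction,alpha,effect_allele Passed to [study_effects()].
#' @param q_p_threshold,i2_threshold Passed to [pool_effects()].
#' @return A tibble with one row per omitted study: `omitted_study_id`,
#'   `model`, `or`, `ci_low`, `ci_high`, `z`, `p`, `i2`.
#' @examples
#' rs1564282_studies() |> leave_one_out()
#' @export
leave_one_out <- function(studies, correction = c("add_half_if_zero", "none"),
                          alpha = 0.05, effect_allele = c("T", "C"),
                          q_p_threshold = 0.1, i2_threshold = 50) {
  correction <- match.arg(correction)
  effect_allele <- match.arg(effect_allele)
  studies <- validate_study_table(studies)
  k <- nrow(studies)
  if (k < 3) {
    abort("Leave-one-out needs at least 3 studies.",
          class = "allelemeta_insufficient_studies")
  }
  purrr::map_dfr(seq_len(k), function(i) {
    pooled <- studies[-i, ] |>
      study_effects(correction = correction, alpha = alpha,
                    effect_allele = effect_allele) |>
      pool_effects(model = "auto", alpha = alpha,
                   q_p_threshold = q_p_threshold, i2_threshold = i2_threshold)
    tibble(
      omitted_study_id = studies$study_id[i],
      model = pooled$model,
      or = pooled$or, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
      z = pooled$z, p = pooled$p, i2 = pooled$heterogeneity$i2
    )
  })
}

#' Funnel-plot coordinates
#'
#' One point per study - the study effect against the standard error of
#' its log odds ratio (the conventional funnel, drawn with the y axis
#' inverted). The pooled reference effect and the pseudo-95% funnel
#' boundary (`pooled log OR +/- 1.959964 * se` over a grid of standard
#' errors from 0 to the largest observed) are attached as attributes
#' `"reference"` and `"boundary"` for plotting.
#'
#' @param effects A tibble with `study_id`, `log_or`, `se`.
#' @param scale `"or"` (default) to place x on the odds-ratio scale, or
#'   `"log_or"`.
#' @param pooled Optional `pooled_or` object giving the reference line; if
#'   omitted a fixed-effect pool of `effects` is used (requires k >= 2; a
#'   single study is its own reference).
#' @param boundary_n Number of grid points in the boundary table.
#' @return A tibble with columns `study_id`, `x`, `se`, plus attributes
#'   `reference` (scalar, on the chosen scale) and `boundary` (tibble
#'   `se`, `low`, `high`).
#' @examples
#' rs1564282_studies() |> study_effects() |> funnel_points()
#' @export
funnel_points <- function(effects, scale = c("or", "log_or"), pooled = NULL,
                          boundary_n = 50) {
  scale <- match.arg(scale)
  check_effects(effects, min_k = 1)
  mu <- if (!is.null(pooled)) {
    pooled$log_or
  } else if (nrow(effects) >= 2) {
    pool_effects(effects, model = "fixed")$log_or
  } else {
    effects$log_or[1]
  }
  on_scale <- if (scale == "or") exp else identity
  se_grid <- seq(0, max(effects$se), length.out = boundary_n)
  boundary <- tibble(
    se = se_grid,
    low = on_scale(mu - Z_975 * se_grid),
    high = on_scale(mu + Z_975 * se_grid)
  )
  out <- tibble(
    study_id = effects$study_id,
    x = on_scale(effects$log_or),
    se = effects$se
  )
  attr(out, "reference") <- on_scale(mu)
  attr(out, "boundary") <- boundary
  attr(out, "scale") <- scale
  out
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' The classic precision form: unweighted ordinary least squares of the
#' standardized effect `z_i = log_or_i / se_i` on the precision
#' `x_i = 1 / se_i`. Under no small-study effect the intercept is zero;
#' it is tested with a two-sided Student t test on `k - 2` degrees of
#' freedom. A weighted variant (weights `1/se^2`, equivalent to regressing
#' the effect on its standard error) is available as `variant = "weighted"`.
#'
#' @param effects A tibble with `log_or` and `se` for at least 3 studies.
#' @param alpha Significance threshold for the bias call (default 0.01).
#' @param variant `"precision"` (default, classic) or `"weighted"`.
#' @return An `egger_test` object with `intercept`, `se_intercept`, `t`,
#'   `df`, `p`, `slope`, `significant`. `tidy()` and `glance()` return
#'   tibble views.
#' @examples
#' rs1564282_studies() |> study_effects() |> egger_test()
#' @export
egger_test <- function(effects, alpha = 0.01,
                       variant = c("precision", "weighted")) {
  variant <- match.arg(variant)
  check_effects(effects, min_k = 3)
  k <- nrow(effects)
  zs <- effects$log_or / effects$se
  x <- 1 / effects$se
  if (stats::var(x) < 1e-300 && stats::var(zs) < 1e-300) {
    abort("Degenerate regression: all precisions and effects identical.",
          class = "allelemeta_degenerate_error")
  }
  fit <- if (variant == "precision") {
    lm(zs ~ x)
  } else {
    lm(effects$log_or ~ effects$se, weights = 1 / effects$se^2)
  }
  cf <- summary(fit)$coefficients
  structure(
    list(
      intercept = cf[1, 1], se_intercept = cf[1, 2],
      t = cf[1, 3], df = k - 2L, p = cf[1, 4],
      slope = cf[2, 1], alpha = alpha, variant = variant, k = k,
      significant = cf[1, 4] < alpha
    ),
    class = "egger_test"
  )
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger regression test (%s form, k = %d)\n", x$variant, x$k))
  cat(sprintf("  intercept %.3f (SE %.3f), t = %.3f on %d df, p = %s\n",
              x$intercept, x$se_intercept, x$t, x$df, format_p(x$p)))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "Significant asymmetry" else "No significant asymmetry",
              x$alpha))
  invisible(x)
}

#' @rdname egger_test
#' @param x An `egger_test` object.
#' @param ... Unused.
#' @export
tidy.egger_test <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, NA_real_),
    statistic = c(x$t, NA_real_),
    p.value = c(x$p, NA_real_)
  )
}

#' @rdname egger_test
#' @export
glance.egger_test <- function(x, ...) {
  tibble(intercept = x$intercept, t = x$t, df = x$df, p = x$p,
         significant = x$significant, variant = x$variant, k = x$k)
}
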
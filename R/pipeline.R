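#' Run the full genotype-count meta-analysis
#'
#' Executes, in order: validation, Hardy-Weinberg screen of the control
#' arms (warn only), per-study allele-model effects, heterogeneity
#' assessment, fixed/random model selection, inverse-variance pooling,
#' leave-one-out sensitivity analysis, funnel coordinates and Egger's
#' regression test. Sensitivity and Egger blocks are `NULL` when fewer
#' than 3 studies are supplied.
#'
#' @param studies A study-table data frame, a path to a TSV/CSV study
#'   file, or the keyword `"bundled"` for the packaged rs1564282 dataset.
#' @param correction,alpha,effect_allele Passed to [study_effects()].
#' @param hwe_threshold Hardy-Weinberg screen p-value cutoff (default
#'   0.001).
#' @param q_p_threshold,i2_threshold Model-selection thresholds (defaults
#'   0.1 and 50).
#' @param egger_alpha Egger-test significance threshold (default 0.01).
#' @return A `meta_report` list with elements `studies`, `hwe`, `effects`,
#'   `pooled` (a `pooled_or`), `sensitivity`, `funnel`, `egger`, and
#'   `config`. Print it for a narrative summary; serialize with
#'   [write_report()].
#' @examples
#' meta_analysis("bundled")
#' @export
meta_analysis <- function(studies = "bundled",
                          correction = c("add_half_if_zero", "none"),
                          alpha = 0.05, effect_allele = c("T", "C"),
                          hwe_threshold = 0.001, q_p_threshold = 0.1,
                          i2_threshold = 50, egger_alpha = 0.01) {
  correction <- match.arg(correction)
  effect_allele <- match.arg(effect_allele)
  if (is.character(studies) && length(studies) == 1) {
    studies <- if (identical(studies, "bundled")) {
      rs1564282_studies()
    } else {
      dialect <- if (grepl("\\.csv$", studies, ignore.case = TRUE)) "csv" else "tsv"
      read_study_table(studies, dialect = dialect)
    }
  }
  studies <- validate_study_table(studies)
  k <- nrow(studies)
  hwe <- hwe_screen(studies, arm = "control", threshold = hwe_threshold)
  effects <- study_effects(studies, correction = correction, alpha = alpha,
                           effect_allele = effect_allele)
  pooled <- pool_effects(effects, model = "auto", alpha = alpha,
                         q_p_threshold = q_p_threshold,
                         i2_threshold = i2_threshold)
  sensitivity <- if (k >= 3) {
    leave_one_out(studies, correction = correction, alpha = alpha,
                  effect_allele = effect_allele,
                  q_p_threshold = q_p_threshold, i2_threshold = i2_threshold)
  } else NULL
  funnel <- funnel_points(effects, scale = "or", pooled = pooled)
  egger <- if (k >= 3) egger_test(effects, alpha = egger_alpha) else NULL
  structure(
    list(
      studies = studies, hwe = hwe, effects = effects, pooled = pooled,
      sensitivity = sensitivity, funnel = funnel, egger = egger,
      config = list(
        correction = correction, alpha = alpha,
        effect_allele = effect_allele, hwe_threshold = hwe_threshold,
        q_p_threshold = q_p_threshold, i2_threshold = i2_threshold,
        egger_alpha = egger_alpha
      )
    ),
    class = "meta_report"
  )
}

#' @export
print.meta_report <- function(x, ...) {
  cat(sprintf("Allele-model meta-analysis of %d case-control studies\n",
              nrow(x$studies)))
  cat(sprintf("  Cases %d, controls %d\n",
              sum(x$studies$case_cc + x$studies$case_ct + x$studies$case_tt),
              sum(x$studies$control_cc + x$studies$control_ct + x$studies$control_tt)))
  n_fail <- sum(!x$hwe$passes)
  cat(sprintf("  HWE screen (controls, p < %g): %s\n", x$config$hwe_threshold,
              if (n_fail == 0) "all pass" else
                paste(n_fail, "flagged:",
                      paste(x$hwe$study_id[!x$hwe$passes], collapse = ", "))))
  print(x$pooled)
  if (!is.null(x$sensitivity)) {
    excl1 <- all(x$sensitivity$ci_low > 1 | x$sensitivity$ci_high < 1)
    cat(sprintf("  Leave-one-out: pooled OR %.2f-%.2f; %s\n",
                min(x$sensitivity$or), max(x$sensitivity$or),
                if (excl1) "every CI excludes 1" else "some CI crosses 1"))
  }
  if (!is.null(x$egger)) {
    cat(sprintf("  Egger test: intercept %.2f, p = %s (%ssignificant at %g)\n",
                x$egger$intercept, format_p(x$egger$p),
                if (x$egger$significant) "" else "not ", x$egger$alpha))
  }
  invisible(x)
}

#' Serialize a meta-analysis report to disk
#'
#' Writes `report.json` (all numbers at full precision - a serialization
#' of the in-memory result, not a recomputation), `report.md` (rounded
#' narrative: OR/CI to 2 decimals, I2 as integer percent, p to 2
#' significant figures), and plot-ready tables `forest.tsv`,
#' `sensitivity.tsv`, `funnel.tsv` and `funnel_boundary.tsv`.
#'
#' @param report A `meta_report` from [meta_analysis()].
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "meta_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- report$pooled

  forest <- dplyr::left_join(
    report$effects[c("study_id", "or", "ci_low", "ci_high", "log_or", "se")],
    report$pooled$weights[c("study_id", "weight_pct")],
    by = "study_id"
  )
  readr::write_tsv(forest, file.path(dir, "forest.tsv"), progress = FALSE)
  if (!is.null(report$sensitivity)) {
    readr::write_tsv(report$sensitivity, file.path(dir, "sensitivity.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(as_tibble(report$funnel), file.path(dir, "funnel.tsv"),
                   progress = FALSE)
  readr::write_tsv(attr(report$funnel, "boundary"),
                   file.path(dir, "funnel_boundary.tsv"), progress = FALSE)

  json <- list(
    config = report$config,
    studies = report$studies,
    hwe = report$hwe,
    effects = report$effects,
    heterogeneity = p$heterogeneity,
    pooled = list(
      model = p$model, log_or = p$log_or, se = p$se, or = p$or,
      ci_low = p$ci_low, ci_high = p$ci_high, z = p$z, p = p$p,
      weights = p$weights
    ),
    sensitivity = report$sensitivity,
    egger = if (!is.null(report$egger)) {
      report$egger[c("intercept", "se_intercept", "t", "df", "p", "slope",
                     "variant", "significant")]
    }
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  md <- c(
    "# Allele-model meta-analysis report", "",
    sprintf("- Studies: %d (%d cases, %d controls)",
            nrow(report$studies),
            sum(report$studies$case_cc + report$studies$case_ct + report$studies$case_tt),
            sum(report$studies$control_cc + report$studies$control_ct + report$studies$control_tt)),
    sprintf("- HWE screen (controls, p < %g): %s", report$config$hwe_threshold,
            if (all(report$hwe$passes)) "all studies pass"
            else paste("flagged:", paste(report$hwe$study_id[!report$hwe$passes],
                                         collapse = ", "))),
    sprintf("- Heterogeneity: Q = %.2f (df = %d, p = %s), I2 = %.0f%%",
            p$heterogeneity$q, p$heterogeneity$df,
            format_p(p$heterogeneity$p_q), p$heterogeneity$i2),
    sprintf("- Model: %s effect", p$model),
    sprintf("- Pooled OR = %.2f, 95%% CI = %.2f-%.2f, Z = %.2f, p = %s",
            p$or, p$ci_low, p$ci_high, p$z, format_p(p$p)),
    if (!is.null(report$sensitivity)) {
      sprintf("- Leave-one-out pooled OR range: %.2f-%.2f",
              min(report$sensitivity$or), max(report$sensitivity$or))
    },
    if (!is.null(report$egger)) {
      sprintf("- Egger test: intercept = %.2f, p = %s (threshold %g)",
              report$egger$intercept, format_p(report$egger$p),
              report$egger$alpha)
    }
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Read studies, analyse, and write the report in one call
#'
#' Thin composition of [meta_analysis()] and [write_report()]; the
#' command-line wrapper in `inst/scripts/allelemeta` calls this.
#'
#' @inheritParams meta_analysis
#' @param out_dir Output directory for the serialized report; `NULL`
#'   skips writing.
#' @return The `meta_report`, invisibly.
#' @export
run_pipeline <- function(studies = "bundled", out_dir = NULL, ...) {
  report <- meta_analysis(studies, ...)
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}
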
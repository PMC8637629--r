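#' Allele-model 2x2 tables from genotype counts
#'
#' Collapses each study's genotype counts to allele counts under the
#' additive (allele) model: every individual contributes two alleles, so
#' the effect-allele (T) count in an arm is `ct + 2 * tt` and the
#' reference-allele (C) count is `2 * cc + ct`.
#'
#' @param studies A study-table data frame (see [study_table]).
#' @param effect_allele `"T"` (default) or `"C"`. With `"C"` the table is
#'   oriented the other way round, which inverts every odds ratio.
#' @return A tibble with columns `study_id`, `population`, `case_t`,
#'   `case_c`, `control_t`, `control_c`.
#' @examples
#' allele_counts(rs1564282_studies())
#' @export
allele_counts <- function(studies, effect_allele = c("T", "C")) {
  effect_allele <- match.arg(effect_allele)
  studies <- validate_study_table(studies)
  out <- tibble(
    study_id = studies$study_id,
    population = studies$population,
    case_t = studies$case_ct + 2L * studies$case_tt,
    case_c = 2L * studies$case_cc + studies$case_ct,
    control_t = studies$control_ct + 2L * studies$control_tt,
    control_c = 2L * studies$control_cc + studies$control_ct
  )
  if (effect_allele == "C") {
    out <- dplyr::rename(out,
      case_t = "case_c", case_c = "case_t",
      control_t = "control_c", control_c = "control_t"
    )
    out <- dplyr::relocate(out, "case_t", "case_c", "control_t", "control_c",
                           .after = "population")
  }
  out
}

#' Per-study odds ratios with Woolf standard errors
#'
#' Computes, for each study, the allele-model odds ratio
#' `(case_t * control_c) / (case_c * control_t)`, its log, the Woolf
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and a normal-theory
#' confidence interval on the OR scale.
#'
#' A zero cell makes the odds ratio degenerate. Under the default
#' `correction = "add_half_if_zero"` (Woolf-Haldane-Anscombe), 0.5 is added
#' to all four cells of a study if and only if at least one of them is
#' zero, and that study is flagged in the `corrected` column. With
#' `correction = "none"` a zero cell is an error.
#'
#' @param studies A study-table data frame, or a tibble already produced by
#'   [allele_counts()].
#' @param correction `"add_half_if_zero"` (default) or `"none"`.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @param effect_allele Passed to [allele_counts()] when `studies` is a
#'   genotype table.
#' @return A tibble with columns `study_id`, `population`, the four allele
#'   counts (after any correction), `corrected`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`.
#' @examples
#' rs1564282_studies() |> study_effects()
#' @export
study_effects <- function(studies, correction = c("add_half_if_zero", "none"),
                          alpha = 0.05, effect_allele = c("T", "C")) {
  correction <- match.arg(correction)
  if (!all(c("case_t", "case_c", "control_t", "control_c") %in% names(studies))) {
    studies <- allele_counts(studies, effect_allele = effect_allele)
  }
  tab <- as_tibble(studies)
  cells <- c("case_t", "case_c", "control_t", "control_c")
  for (col in cells) {
    if (any(tab[[col]] < 0)) {
      abort(sprintf("Negative allele count in '%s'.", col),
            class = "allelemeta_validation_error")
    }
  }
  arm_case <- tab$case_t + tab$case_c
  arm_control <- tab$control_t + tab$control_c
  if (any(arm_case == 0 | arm_control == 0)) {
    abort("A study has an arm with zero total allele count.",
          class = "allelemeta_validation_error")
  }
  has_zero <- (tab$case_t == 0) | (tab$case_c == 0) |
    (tab$control_t == 0) | (tab$control_c == 0)
  if (correction == "none" && any(has_zero)) {
    abort(
      sprintf("Zero cell in study '%s' with correction = \"none\".",
              tab$study_id[which(has_zero)[1]]),
      class = "allelemeta_degenerate_error"
    )
  }
  adj <- ifelse(correction == "add_half_if_zero" & has_zero, 0.5, 0)
  a <- tab$case_t + adj
  b <- tab$case_c + adj
  c_ <- tab$control_t + adj
  d <- tab$control_c + adj
  log_or <- log(a) + log(d) - log(b) - log(c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- z_quantile(alpha)
  tibble(
    study_id = tab$study_id,
    population = if ("population" %in% names(tab)) tab$population else NA_character_,
    case_t = a, case_c = b, control_t = c_, control_c = d,
    corrected = has_zero & correction == "add_half_if_zero",
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se)
  )
}
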
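#' Hardy-Weinberg equilibrium test for one genotype arm
#'
#' Tests observed CC/CT/TT counts against Hardy-Weinberg proportions at the
#' arm's estimated effect-allele frequency `q = (ct + 2 tt) / (2 n)`. The
#' default method is the Pearson chi-squared goodness-of-fit test on the
#' three genotype classes with 1 degree of freedom (2 classes estimated
#' frequencies minus 1 fitted parameter) and no continuity correction;
#' classes with zero expected count contribute nothing (they can only occur
#' with zero observed count, at `q` of 0 or 1). `method = "exact"` runs the
#' conditional exact test that enumerates all heterozygote counts
#' compatible with the observed allele counts and sums the probabilities of
#' outcomes no more likely than the observed one.
#'
#' @param cc,ct,tt Genotype counts (vectors are tested element-wise).
#' @param threshold p-value cutoff below which the arm is flagged as
#'   deviating (default 0.001).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A tibble with one row per arm: `chi2` (NA for the exact test),
#'   `p`, `effect_allele_freq`, `passes`.
#' @examples
#' hwe_test(331, 89, 1)
#' @export
hwe_test <- function(cc, ct, tt, threshold = 0.001, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- cc + ct + tt
  if (any(n < 1) || any(c(cc, ct, tt) < 0)) {
    abort("Genotype counts must be non-negative with total >= 1.",
          class = "allelemeta_validation_error")
  }
  q <- (ct + 2 * tt) / (2 * n)
  if (method == "chisq") {
    expected <- cbind(n * (1 - q)^2, 2 * n * q * (1 - q), n * q^2)
    observed <- cbind(cc, ct, tt)
    terms <- ifelse(expected > 0, (observed - expected)^2 / expected, 0)
    chi2 <- rowSums(terms)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- rep(NA_real_, length(n))
    p <- mapply(hwe_exact_p, cc, ct, tt)
  }
  tibble(chi2 = chi2, p = p, effect_allele_freq = q, passes = p >= threshold)
}

## Conditional exact HWE p-value: enumerate heterozygote counts with the
## parity of the minor-allele count, probabilities in log space.
hwe_exact_p <- function(cc, ct, tt) {
  n <- cc + ct + tt
  n_minor <- min(ct + 2 * tt, ct + 2 * cc)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  log_p <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    h * log(2) + lfactorial(n) -
      lfactorial(hom_minor) - lfactorial(h) - lfactorial(hom_major)
  }, numeric(1))
  log_p <- log_p - max(log_p)
  prob <- exp(log_p) / sum(exp(log_p))
  obs <- prob[hets == ct]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

#' Hardy-Weinberg screen across a study table
#'
#' Applies [hwe_test()] to one arm (controls by default) of every study.
#' Studies that deviate at the threshold are reported and trigger a
#' warning, never an exclusion: the screen is a quality flag and dropping
#' studies is left to the analyst.
#'
#' @param studies A study-table data frame.
#' @param arm `"control"` (default) or `"case"`.
#' @param threshold p-value cutoff (default 0.001).
#' @param method Passed to [hwe_test()].
#' @return A tibble with columns `study_id`, `arm`, `chi2`, `p`,
#'   `effect_allele_freq`, `method`, `passes`.
#' @examples
#' rs1564282_studies() |> hwe_screen()
#' @export
hwe_screen <- function(studies, arm = c("control", "case"), threshold = 0.001,
                       method = c("chisq", "exact")) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  studies <- validate_study_table(studies)
  pick <- function(g) studies[[paste0(arm, "_", g)]]
  res <- hwe_test(pick("cc"), pick("ct"), pick("tt"),
                  threshold = threshold, method = method)
  out <- dplyr::bind_cols(
    tibble(study_id = studies$study_id, arm = arm),
    res[c("chi2", "p", "effect_allele_freq")],
    tibble(method = method, passes = res$passes)
  )
  if (any(!out$passes)) {
    warn(sprintf(
      "Hardy-Weinberg deviation at p < %g in %s arm of: %s (flagged, not excluded).",
      threshold, arm, paste(out$study_id[!out$passes], collapse = ", ")
    ))
  }
  out
}
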
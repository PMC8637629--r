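#' Simulate one case-control genotype study
#'
#' Controls are drawn multinomially from Hardy-Weinberg proportions
#' `((1-q)^2, 2q(1-q), q^2)` at effect-allele frequency `q`. Cases are
#' drawn from the tilted distribution `p_g` proportional to
#' `HWE_g(q) * psi^g` for genotype `g` in 0,1,2 copies of the effect
#' allele - the additive odds model, under which the allele-level
#' case-control odds ratio converges to `psi` as the arm sizes grow.
#'
#' Draws come from the current R random number stream; seed management for
#' whole tables lives in [simulate_studies()].
#'
#' @param n_case,n_control Arm sizes (positive integers).
#' @param q Control effect-allele frequency, in (0, 1).
#' @param psi True per-allele odds ratio (> 0).
#' @param study_id,population Labels for the emitted row.
#' @return A one-row study-table tibble.
#' @examples
#' set.seed(1)
#' simulate_study(500, 500, q = 0.1, psi = 1.3)
#' @export
simulate_study <- function(n_case, n_control, q, psi,
                           study_id = "sim1", population = "simulated") {
  if (q <= 0 || q >= 1 || psi <= 0 || n_case < 1 || n_control < 1) {
    abort("Need 0 < q < 1, psi > 0 and arm sizes >= 1.",
          class = "allelemeta_validation_error")
  }
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  case_p <- hwe * psi^(0:2)
  case_p <- case_p / sum(case_p)
  control <- as.integer(rmultinom(1, n_control, hwe))
  case <- as.integer(rmultinom(1, n_case, case_p))
  tibble(
    study_id = study_id, population = population,
    case_cc = case[1], case_ct = case[2], case_tt = case[3],
    control_cc = control[1], control_ct = control[2], control_tt = control[3]
  )
}

## deterministic 31-bit substream seed; independent of how many other
## substreams exist, so tables are stable under reordering or resizing
substream <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 48271 + i * 1009) %% 2147483647)
}

#' Simulate a table of independent case-control studies with known truth
#'
#' Generates `k` studies via [simulate_study()]. With `tau > 0`, each
#' study's log odds ratio is drawn from `Normal(log(psi), tau^2)` before
#' the genotype draws (heterogeneity enters through the effect only, not
#' the allele frequency). Every study uses its own seed substream derived
#' from `seed` and the study index, so the same `(config, seed)` always
#' reproduces the same table and individual studies do not depend on `k`.
#'
#' @param k Number of studies.
#' @param n_case,n_control Arm sizes; scalars or length-`k` vectors.
#' @param q Control effect-allele frequency; scalar or length-`k`.
#' @param psi Median per-allele odds ratio (> 0).
#' @param tau Between-study SD of the log odds ratio (>= 0; 0 =
#'   homogeneous).
#' @param seed Integer seed; `NULL` uses the current RNG stream (and is
#'   then not reproducible by this function alone).
#' @return A study-table tibble with a `truth` attribute: a tibble of the
#'   per-study `psi_i`, `q`, arm sizes and `tau` used.
#' @examples
#' sim <- simulate_studies(7, n_case = 500, n_control = 500, q = 0.09,
#'                         psi = 1.28, seed = 42)
#' attr(sim, "truth")
#' @export
simulate_studies <- function(k, n_case, n_control, q, psi = 1, tau = 0,
                             seed = NULL) {
  if (k < 1 || tau < 0) {
    abort("Need k >= 1 and tau >= 0.", class = "allelemeta_validation_error")
  }
  n_case <- rep_len(n_case, k)
  n_control <- rep_len(n_control, k)
  q <- rep_len(q, k)
  rows <- vector("list", k)
  psi_i <- numeric(k)
  for (i in seq_len(k)) {
    if (!is.null(seed)) set.seed(substream(seed, i))
    psi_i[i] <- if (tau > 0) exp(rnorm(1, log(psi), tau)) else psi
    rows[[i]] <- simulate_study(
      n_case[i], n_control[i], q[i], psi_i[i],
      study_id = sprintf("sim%02d", i)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- tibble(
    study_id = out$study_id, psi = psi_i, q = q,
    n_case = n_case, n_control = n_control, tau = tau
  )
  out
}

#' Monte Carlo rejection rate of the pooled Z test
#'
#' Repeatedly simulates a study table, runs the full pipeline (per-study
#' effects, heterogeneity-driven model selection, inverse-variance
#' pooling), and counts how often the pooled two-sided Z-test p-value
#' falls below `alpha`. With `psi = 1` this estimates the type-I error of
#' the pipeline; with `psi != 1` its power.
#'
#' @param reps Number of replicates (>= 1).
#' @param alpha Test level (default 0.05).
#' @param k,n_case,n_control,q,psi,tau Passed to [simulate_studies()].
#' @param seed Integer seed; each replicate gets its own substream.
#' @return A one-row tibble: `reps`, `rejections`, `rate`, and the exact
#'   (Clopper-Pearson) 95% binomial interval `ci_low`, `ci_high`.
#' @examples
#' rejection_rate(50, k = 7, n_case = 500, n_control = 500, q = 0.09,
#'                psi = 1, seed = 7)
#' @export
rejection_rate <- function(reps, alpha = 0.05, k = 7, n_case = 500,
                           n_control = 500, q = 0.09, psi = 1, tau = 0,
                           seed = NULL) {
  if (reps < 1) {
    abort("Need reps >= 1.", class = "allelemeta_validation_error")
  }
  hits <- 0L
  for (r in seq_len(reps)) {
    rep_seed <- if (is.null(seed)) NULL else substream(seed, 100000L + r)
    tab <- simulate_studies(k, n_case, n_control, q, psi = psi, tau = tau,
                            seed = rep_seed)
    pooled <- tab |> study_effects() |> pool_effects(model = "auto")
    if (pooled$p < alpha) hits <- hits + 1L
  }
  ci <- stats::binom.test(hits, reps)$conf.int
  tibble(reps = reps, rejections = hits, rate = hits / reps,
         ci_low = ci[1], ci_high = ci[2])
}
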
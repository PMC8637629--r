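# Independent brute-force oracles, written deliberately differently from the
# package internals (explicit loops, closed-form OLS) so agreement is a real
# cross-check and not the same code twice.

oracle_log_or <- function(a, b, c, d) {
  log((a * d) / (b * c))
}

oracle_se <- function(a, b, c, d) {
  sqrt(1 / a + 1 / b + 1 / c + 1 / d)
}

# two-pass Cochran's Q with scalar loops
oracle_q <- function(log_or, se) {
  k <- length(log_or)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    num <- num + log_or[i] / se[i]^2
    den <- den + 1 / se[i]^2
  }
  m <- num / den
  q <- 0
  for (i in seq_len(k)) {
    q <- q + (log_or[i] - m)^2 / se[i]^2
  }
  list(q = q, pooled = m, se = 1 / sqrt(den))
}

oracle_i2 <- function(q, k) {
  if (q <= k - 1 || q == 0) 0 else (q - (k - 1)) / q * 100
}

# closed-form simple linear regression of y on x with intercept t-test
oracle_ols_intercept <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_int <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  t <- intercept / se_int
  list(intercept = intercept, se = se_int, t = t,
       p = 2 * pt(-abs(t), df = n - 2), slope = slope)
}

# random small study table with no zero genotype-derived allele cells
random_study_table <- function(k) {
  tibble::tibble(
    study_id = sprintf("s%02d", seq_len(k)),
    population = "random",
    case_cc = sample(50:400, k, replace = TRUE),
    case_ct = sample(10:150, k, replace = TRUE),
    case_tt = sample(1:20, k, replace = TRUE),
    control_cc = sample(50:400, k, replace = TRUE),
    control_ct = sample(10:150, k, replace = TRUE),
    control_tt = sample(1:20, k, replace = TRUE)
  )
}

table1_arm_sizes <- function() {
  tab <- rs1564282_studies()
  list(
    n_case = tab$case_cc + tab$case_ct + tab$case_tt,
    n_control = tab$control_cc + tab$control_ct + tab$control_tt
  )
}
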
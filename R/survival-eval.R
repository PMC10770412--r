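#' Concordance index between a risk score and censored survival times
#'
#' Counts ordered pairs literally: the numerator is
#' `sum over (i, j) of 1{eta_i < eta_j} 1{T_i > T_j} delta_j` and the
#' denominator `sum over (i, j) of 1{T_i > T_j} delta_j` — a pair is
#' comparable only when the shorter time ends in an observed event and the
#' two times differ; tied scores add nothing to the numerator (no 0.5
#' credit; set `tie_credit = TRUE` for the Harrell convention).
#'
#' @param pi Tibble (`sample_id`, `pi`) from [forward_pi()], or a numeric
#'   vector of risk scores aligned with `surv`.
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @param tie_credit Give 0.5 numerator credit to score ties (default FALSE,
#'   the literal formula).
#' @return A `concordance_result` list: `c_index`, `n_comparable_pairs`,
#'   `n_concordant`.
#' @examples
#' surv <- tibble::tibble(
#'   sample_id = c("A", "B", "C"), time = c(3, 5, 8), event = c(1, 1, 0)
#' )
#' concordance_index(c(A = 2, B = 3, C = 0.5), surv)$c_index # 2/3
#' @export
concordance_index <- function(pi, surv, tie_credit = FALSE) {
  eta <- align_pi(pi, surv)
  t <- surv$time
  d <- surv$event
  # comparable[i, j] = 1{T_i > T_j} * delta_j
  time_gt <- outer(t, t, ">")
  comparable <- sweep(time_gt, 2, d, "*")
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs (all censored or all times tied)")
  score_lt <- outer(eta, eta, "<")
  n_conc <- sum(score_lt * comparable)
  if (tie_credit) {
    n_conc <- n_conc + 0.5 * sum(outer(eta, eta, "==") * comparable)
  }
  structure(
    list(
      c_index = n_conc / n_comp,
      n_comparable_pairs = n_comp,
      n_concordant = n_conc
    ),
    class = "concordance_result"
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` and returns the step function as a tidy table.
#'
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @return A `km_estimate` tibble: `time`, `n_risk`, `n_event`, `survival`
#'   (non-increasing, starting from 1 at time 0).
#' @export
km_estimate <- function(surv) {
  stopifnot(nrow(surv) > 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv
  )
  class(out) <- c("km_estimate", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival curves of the
#' high- and low-risk groups, via `survival::survdiff`.
#'
#' @param groups A `risk_groups` tibble from [assign_risk_groups()] or any
#'   data frame with `sample_id` and `risk_group`.
#' @param surv Survival tibble covering the same samples.
#' @return A `test_result` tibble: `statistic`, `p_value`, `method`.
#' @export
logrank_test <- function(groups, surv) {
  df <- dplyr::inner_join(
    surv, groups[, c("sample_id", "risk_group")], by = "sample_id"
  )
  if (length(unique(df$risk_group)) < 2) {
    stop("log-rank test needs two non-empty groups")
  }
  if (sum(df$event) < 1) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ risk_group, data = df)
  test_result(sd$chisq, stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
              "log-rank")
}

test_result <- function(statistic, p_value, method) {
  tibble::tibble(
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value), method = method
  )
}

#' Two-sided Wilcoxon signed-rank test for matched samples
#'
#' Used to compare matched testing-set C-indices from two models evaluated
#' on identical splits. Zero differences are dropped; the exact null
#' distribution is used for n <= 25 remaining pairs, the normal
#' approximation with continuity correction beyond that.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return A `test_result` tibble (`statistic` = the positive-rank sum V,
#'   `p_value`, `method`).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  diffs <- a - b
  diffs <- diffs[diffs != 0]
  if (length(diffs) == 0) {
    warning("all differences are zero; p = 1")
    return(test_result(0, 1, "wilcoxon-signed-rank"))
  }
  n <- length(diffs)
  r <- rank(abs(diffs))
  v <- sum(r[diffs > 0])
  if (n <= 25) {
    # exact null distribution of the positive-rank sum by convolution over
    # sign assignments; doubled ranks keep tied (half-integer) ranks integral
    r2 <- as.integer(round(2 * r))
    f <- 1
    for (ri in r2) {
      g <- c(f, rep(0, ri))
      g[seq_along(f) + ri] <- g[seq_along(f) + ri] + f
      f <- g
    }
    probs <- f / 2^n
    support <- seq_along(probs) - 1 # values of 2V
    p_le <- sum(probs[support <= 2 * v + 1e-9])
    p_ge <- sum(probs[support >= 2 * v - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result(v, p, "wilcoxon-signed-rank")
}

#' Univariate Cox proportional-hazards fit for a binary covariate
#'
#' Fits one binary regressor by Breslow partial likelihood
#' (`survival::coxph`), reporting the hazard ratio, Wald 95% confidence
#' interval and likelihood-ratio p-value — the screening model used per key
#' gene (dummy = expression above the median), with p-values across genes
#' adjusted by [bh_adjust()].
#'
#' @param covariate 0/1 vector, both levels present.
#' @param surv Survival tibble aligned with `covariate`.
#' @return A tibble: `beta`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `monotone` (TRUE when the likelihood is monotone / separation was
#'   flagged, in which case the CI is unbounded).
#' @export
univariate_cox <- function(covariate, surv) {
  stopifnot(length(covariate) == nrow(surv), all(covariate %in% c(0, 1)))
  if (length(unique(covariate)) < 2) stop("covariate must take both levels")
  if (sum(surv$event) < 1) stop("no events")
  df <- data.frame(time = surv$time, event = surv$event, x = covariate)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "breslow")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  monotone <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  lrt_p <- stats::pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
  z <- stats::qnorm(0.975)
  tibble::tibble(
    beta = beta,
    hr = exp(beta),
    ci_lower = if (monotone) 0 else exp(beta - z * se),
    ci_upper = if (monotone) Inf else exp(beta + z * se),
    p_value = lrt_p,
    monotone = monotone
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1), via
#'   `stats::p.adjust(method = "BH")`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Schoenfeld detectable hazard-ratio bounds
#'
#' Post-hoc power computation for a standardised (unit-variance) continuous
#' covariate in a Cox model: the detectable log hazard ratio at two-sided
#' level `alpha` and the given power is
#' `(z_{1 - alpha/2} + z_{power}) / sqrt(n_events)`; the detectable bounds
#' are `exp(+/- logHR)`, exact reciprocals of each other.
#'
#' @param n_events Number of observed events.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return A tibble with `hr_upper` and `hr_lower`.
#' @examples
#' schoenfeld_detectable_hr(222)$hr_upper # ~1.21
#' @export
schoenfeld_detectable_hr <- function(n_events, alpha = 0.05, power = 0.8) {
  stopifnot(n_events >= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  log_hr <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n_events)
  tibble::tibble(hr_upper = exp(log_hr), hr_lower = exp(-log_hr))
}
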
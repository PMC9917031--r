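#' Immunohistochemistry H-score
#'
#' `H = 3 * pct_strong + 2 * pct_medium + 1 * pct_weak`, giving a value in
#' \[0, 300\]. Negative cells (the remainder to 100%) carry weight 0.
#'
#' @param pct_strong,pct_medium,pct_weak staining percentages in \[0, 100\],
#'   summing to at most 100 per core. Vectorized.
#' @return Numeric H-scores.
#' @examples
#' h_score(20, 30, 40) # 160
#' @export
h_score <- function(pct_strong, pct_medium, pct_weak) {
  pct <- cbind(pct_strong, pct_medium, pct_weak)
  if (any(pct < 0) || any(pct > 100)) stop("percentages must lie in [0, 100]")
  if (any(rowSums(pct) > 100 + 1e-9)) stop("percentages must sum to at most 100")
  3 * pct_strong + 2 * pct_medium + 1 * pct_weak
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @return A `data.frame` with columns `time`, `n_risk`, `n_event`, `surv`
#'   (the step-function values at the observed event/censoring times).
#' @export
km_estimate <- function(time, event) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Logrank (Cox-Mantel) test
#'
#' Standard observed-minus-expected logrank statistic with hypergeometric
#' variance, referred to a 1-df chi-square.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group labels.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("logrank_test requires exactly 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Automatic best-cutoff dichotomization
#'
#' Evaluates every distinct expression value inside a quantile window as a
#' cutoff splitting the cohort into high (> cutoff) and low (<= cutoff)
#' expression, and returns the cutoff minimizing the logrank p-value.
#' Because min-p scanning inflates significance, a permutation-adjusted
#' p-value (re-scanning under shuffled expression) is available via
#' `adjust = "permutation"`.
#'
#' @param time,event follow-up times and event indicators.
#' @param expression continuous expression values.
#' @param quantile_window quantile range of candidate cutoffs
#'   (default c(0.1, 0.9)).
#' @param adjust `"none"` (report the naive minimum p) or `"permutation"`.
#' @param n_perm permutations for the adjusted p.
#' @param return_scan also return the full table of evaluated cutoffs.
#' @return list with `cutoff`, `chisq`, `p`, `n_high`, `n_low`, and
#'   optionally `p_adjusted` and `scan`.
#' @export
best_cutoff <- function(time, event, expression,
                        quantile_window = c(0.1, 0.9),
                        adjust = c("none", "permutation"),
                        n_perm = 1000L, return_scan = FALSE) {
  adjust <- match.arg(adjust)
  qs <- quantile(expression, quantile_window)
  cand <- sort(unique(expression[expression >= qs[1] & expression <= qs[2]]))
  # a cutoff must leave both sides non-empty
  cand <- cand[cand < max(expression)]
  if (length(cand) < 1L) stop("fewer than 2 distinct expression values in window")

  scan_min <- function(expr) {
    best <- list(p = Inf)
    scan <- if (return_scan) vector("list", length(cand)) else NULL
    for (i in seq_along(cand)) {
      g <- expr > cand[i]
      lr <- logrank_test(time, event, g)
      if (lr$p < best$p) {
        best <- list(cutoff = cand[i], chisq = lr$chisq, p = lr$p,
                     n_high = sum(g), n_low = sum(!g))
      }
      if (return_scan) scan[[i]] <- data.frame(cutoff = cand[i],
                                               chisq = lr$chisq, p = lr$p)
    }
    if (return_scan) best$scan <- do.call(rbind, scan)
    best
  }
  best <- scan_min(expression)
  if (adjust == "permutation") {
    obs <- best$p
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pb <- scan_min(sample(expression))$p
      if (pb <= obs) hits <- hits + 1L
    }
    best$p_adjusted <- (hits + 1L) / (n_perm + 1L)
  }
  best
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with a single covariate (continuous expression or
#' a dichotomized indicator), Efron handling of tied event times.
#'
#' @param time,event follow-up times and event indicators.
#' @param covariate numeric (or 0/1) covariate.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return list with `log_hr`, `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_univariate <- function(time, event, covariate, conf_level = 0.95) {
  if (length(unique(covariate)) < 2L) {
    # no variation: the partial likelihood is flat at coefficient 0
    return(list(log_hr = 0, hr = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                p = 1))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "efron")
  s <- summary(fit, conf.int = conf_level)
  list(log_hr = unname(stats::coef(fit)),
       hr = unname(s$conf.int[1, "exp(coef)"]),
       ci_lower = unname(s$conf.int[1, 3L]),
       ci_upper = unname(s$conf.int[1, 4L]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]))
}
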
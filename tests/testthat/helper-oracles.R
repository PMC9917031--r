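# Independent straight-line reimplementations used as oracles. These are
# deliberately naive if/else chains kept separate from the vectorized
# package code paths they check.

naive_score_lines <- function(n) {
  vapply(n, function(k) {
    if (k == 14) 0
    else if (k == 13) 0.5
    else if (k == 12) 1.5
    else if (k == 11) 3
    else if (k == 10) 5
    else if (k == 9) 7.5
    else if (k == 8) 10
    else if (k == 7) 15
    else 30
  }, numeric(1))
}

naive_score_abundance <- function(m) {
  vapply(m, function(x) {
    if (x >= 2.5e9) 0
    else if (x >= 1e9) 1
    else if (x >= 5e8) 2
    else if (x >= 2.5e8) 3
    else if (x >= 1e8) 4
    else if (x >= 5e7) 5
    else if (x >= 2.5e7) 6
    else if (x >= 1e7) 7
    else if (x >= 5e6) 8
    else 9
  }, numeric(1))
}

naive_score_fc <- function(fc) {
  vapply(fc, function(x) {
    if (x >= 10) 0
    else if (x >= 6) 0.5
    else if (x >= 5) 1
    else if (x >= 4) 1.5
    else if (x >= 3) 2
    else if (x >= 2) 2.5
    else if (x >= 1) 3
    else 3.5
  }, numeric(1))
}

naive_score_controls <- function(n) {
  vapply(n, function(k) if (k == 0) 0 else if (k == 1) 2.5 else 5, numeric(1))
}

naive_score_pdx <- function(n) {
  vapply(n, function(k) {
    if (k == 3) 0 else if (k == 2) 0.5 else if (k == 1) 1 else 1.5
  }, numeric(1))
}

naive_score_mrna <- function(normal, tumor, n_ctrl, fc) {
  s_n <- vapply(normal, function(x) {
    if (x < 5) 0 else if (x < 10) 0.5 else if (x < 50) 1.5
    else if (x < 100) 3 else if (x < 250) 5 else if (x < 500) 7.5 else 10
  }, numeric(1))
  s_t <- vapply(tumor, function(x) {
    if (x > 500) 0 else if (x >= 250) 0.5 else if (x >= 100) 1.5
    else if (x >= 50) 3 else if (x >= 25) 5 else if (x >= 10) 7.5
    else if (x >= 5) 10 else 15
  }, numeric(1))
  s_c <- vapply(n_ctrl, function(k) c(0, 0.25, 0.5, 0.75, 1, 1.25)[k + 1],
                numeric(1))
  s_f <- vapply(fc, function(x) {
    if (x >= 5) 0 else if (x >= 4) 1 else if (x >= 3) 2 else if (x >= 2) 3
    else if (x >= 1.5) 4 else if (x >= 1) 5 else 10
  }, numeric(1))
  data.frame(s_normal = s_n, s_tumor = s_t, s_ctrl_tissues = s_c, s_fc = s_f,
             total = s_n + s_t + s_c + s_f)
}

# Brute-force logrank: loop over distinct event times, accumulating observed
# minus expected events in group 1 and the hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}
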
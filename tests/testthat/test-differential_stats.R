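test_that("EB prior fit recovers simulated hyperparameters", {
  set.seed(1)
  d0 <- 4; s0sq <- 1; d <- 4; n <- 5000
  sigma2 <- s0sq * d0 / rchisq(n, d0)       # scaled inverse chi-square prior
  s2 <- sigma2 * rchisq(n, d) / d           # observed residual variances
  prior <- fit_eb_prior(s2, d)
  expect_gt(prior$d0, 3); expect_lt(prior$d0, 5)
  expect_gt(prior$s0sq, 0.9); expect_lt(prior$s0sq, 1.1)
})

test_that("EB prior fit matches the limma moment estimator", {
  set.seed(2)
  s2 <- (1.5 * 4 / rchisq(1000, 4)) * rchisq(1000, 4) / 4
  prior <- fit_eb_prior(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0sq, sq$var.prior, tolerance = 1e-6)
})

test_that("degenerate variance spreads give an infinite-df prior without error", {
  prior <- fit_eb_prior(rep(2, 50), 4)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0sq, 2, tolerance = 0.15)
  # two proteins only: finite fit or +Inf fallback, never an exception
  expect_no_error(fit_eb_prior(c(1, 2), 4))
})

test_that("moderated t has the stated limits and symmetry", {
  a <- c(10.2, 11.1, 9.8); b <- c(8.1, 7.9, 8.6)
  # d0 = 0 recovers the ordinary pooled two-sample t exactly
  r0 <- moderated_t(a, b, d0 = 0)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r0$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r0$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r0$df_total, 4)
  # hand formula
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  expect_equal(r0$t, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3)), tolerance = 1e-12)

  # d0 = Inf fixes the variance at s0^2
  rinf <- moderated_t(a, b, d0 = Inf, s0sq = 2)
  expect_equal(rinf$t, (mean(a) - mean(b)) / sqrt(2 * (2 / 3)), tolerance = 1e-12)

  # identical groups
  same <- moderated_t(a, a, d0 = 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry in group order
  r <- moderated_t(a, b, d0 = 3, s0sq = 1)
  rswap <- moderated_t(b, a, d0 = 3, s0sq = 1)
  expect_equal(r$t, -rswap$t)
  expect_equal(r$log2fc, -rswap$log2fc)
  expect_error(moderated_t(1, b), "at least 2")
})

test_that("class selection intersects the three tumor classes", {
  mk <- function(p, cl, lfc, t) data.frame(protein_id = p, class = cl,
                                           line = "l", control = "c",
                                           log2fc = lfc, t = t)
  eb <- rbind(
    mk("HIT", "FP_RMS", 2.5, 2.2), mk("HIT", "FN_RMS", 2.5, 2.2),
    mk("HIT", "PDX", 2.5, 2.2),
    mk("PARTIAL", "FP_RMS", 2.5, 2.2), mk("PARTIAL", "FN_RMS", 2.5, 2.2),
    mk("PARTIAL", "PDX", 2.5, 1.0))
  sel <- eb_select(eb)
  expect_true(sel$selected_all[sel$protein_id == "HIT"])
  expect_false(sel$selected_all[sel$protein_id == "PARTIAL"])
  expect_true(sel$selected_FP_RMS[sel$protein_id == "PARTIAL"])

  # raising either threshold never grows the selected set
  sel_hi_t <- eb_select(eb, t_threshold = 3)
  sel_hi_l <- eb_select(eb, lfc_threshold = 3)
  expect_true(all(sel_hi_t$selected_all <= sel$selected_all))
  expect_true(all(sel_hi_l$selected_all <= sel$selected_all))
})

test_that("per-comparison EB statistics average correctly within classes", {
  pan <- small_panel(n_proteins = 50, n_targets = 5, seed = 20)
  q <- quantify(impute_peptides(normalize_peptides(pan$peptides), seed = 20),
                raw = pan$peptides)
  eb <- eb_stats(q)
  # 14 tumor lines x 2 controls = 28 comparisons per protein
  expect_equal(nrow(eb), 28L * length(q$protein_id))
  expect_true(all(eb$p > 0 & eb$p <= 1))
  sel <- eb_select(eb)
  manual <- mean(eb$t[eb$protein_id == "TARGET001" & eb$class == "FP_RMS"])
  expect_equal(sel$avg_t_FP_RMS[sel$protein_id == "TARGET001"], manual)
  # planted control-absent targets are selected in every class
  expect_true(all(sel$selected_all[grepl("^TARGET", sel$protein_id)]))
})

test_that("the mixed model matches the fixed-effects t-test when line variance is zero", {
  set.seed(5)
  design <- default_design()
  idx <- design$group %in% c("FP_RMS", "CONTROL")
  y <- rnorm(sum(idx), 20, 0.5)   # no between-line component
  r <- suppressWarnings(fit_lmm(y, design$line_id[idx], design$group[idx]))
  tt <- summary(lm(y ~ factor(design$group[idx],
                              levels = c("CONTROL", "FP_RMS"))))$coefficients
  expect_equal(r$lmm_p, tt[2, 4], tolerance = 0.1)
  expect_equal(r$lmm_log2fc, tt[2, 1], tolerance = 1e-6)
})

test_that("the mixed model recovers a planted fold change", {
  design <- default_design()
  idx <- design$group %in% c("FP_RMS", "CONTROL")
  dsub <- design[idx, ]
  n_sim <- 200
  set.seed(77)
  est <- vapply(seq_len(n_sim), function(i) {
    line_eff <- rnorm(length(unique(dsub$line_id)), 0, 0.25)
    names(line_eff) <- unique(dsub$line_id)
    y <- 20 + 2 * (dsub$group == "FP_RMS") + line_eff[dsub$line_id] +
      rnorm(nrow(dsub), 0, 0.35)
    suppressWarnings(fit_lmm(y, dsub$line_id, dsub$group))$lmm_log2fc
  }, numeric(1))
  expect_gte(mean(est >= 1.5 & est <= 2.5), 0.9)
})

test_that("the mixed model is calibrated under the null", {
  design <- default_design()
  idx <- design$group %in% c("PDX", "CONTROL")
  dsub <- design[idx, ]
  n_sim <- 200
  set.seed(31)
  pvals <- vapply(seq_len(n_sim), function(i) {
    line_eff <- rnorm(length(unique(dsub$line_id)), 0, 0.3)
    names(line_eff) <- unique(dsub$line_id)
    y <- 20 + line_eff[dsub$line_id] + rnorm(nrow(dsub), 0, 0.4)
    suppressWarnings(fit_lmm(y, dsub$line_id, dsub$group))$lmm_p
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.35)  # roughly uniform, not degenerate
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  p <- runif(50)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_lte(max(adj), 1)
})

test_that("volcano flags follow the fold-change and significance gates", {
  res <- data.frame(lmm_log2fc = c(1.2, -1.2, 0.5, 2),
                    lmm_p_adj = c(0.01, 0.01, 0.01, 0.2))
  v <- volcano_table(res)
  expect_equal(v$flag, c("up", "down", "ns", "ns"))
  expect_equal(v$neg_log10_p[1], 2)
})
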
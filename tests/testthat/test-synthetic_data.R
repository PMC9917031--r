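test_that("control-absent targets are fully censored in control columns", {
  pan <- small_panel(n_proteins = 30, n_targets = 3, seed = 2)
  pt <- pan$peptides
  ctrl <- pt$design$group == "CONTROL"
  target_rows <- pt$protein_id %in% sprintf("TARGET%03d", 1:3)
  expect_true(all(is.na(pt$intensity[target_rows, ctrl])))
  expect_true(all(!pt$detected[target_rows, ctrl]))
  # and detected at least somewhere in tumor columns
  expect_true(all(rowSums(pt$detected[target_rows, !ctrl, drop = FALSE]) > 0))
})

test_that("panel generation is deterministic given the seed", {
  a <- generate_panel(truth_spec(n_proteins = 25, n_targets = 2, seed = 13))
  b <- generate_panel(truth_spec(n_proteins = 25, n_targets = 2, seed = 13))
  expect_identical(a$peptides$intensity, b$peptides$intensity)
  expect_identical(a$truth, b$truth)
  c <- generate_panel(truth_spec(n_proteins = 25, n_targets = 2, seed = 14))
  expect_false(identical(a$peptides$intensity, c$peptides$intensity))
})

test_that("background peptide intensities match the configured distribution", {
  # Monte-Carlo check: with >500 background peptides, the empirical mean of
  # the true (uncensored) log2 intensities must sit within 3 SE of the
  # configured base mean.
  tr <- truth_spec(n_proteins = 150, n_targets = 0, base_mean = 24,
                   base_sd = 2, peptide_sd = 1, missingness = FALSE, seed = 31)
  pan <- generate_panel(tr)
  L <- log2(pan$peptides$intensity)
  expect_gt(length(pan$peptides$peptide_id), 500)
  per_pep_sd <- sqrt(tr$base_sd^2 + tr$peptide_sd^2)
  # peptides within a protein share the protein mean; use per-protein means
  prot_means <- tapply(rowMeans(L), pan$peptides$protein_id, mean)
  se <- tr$base_sd / sqrt(length(prot_means))
  expect_lt(abs(mean(prot_means) - 24), 3 * se + 0.2)
  expect_gt(per_pep_sd, sd(rowMeans(L)) * 0.5) # spread is of the right order
})

test_that("planted means are reproduced exactly when noise is disabled", {
  tr <- truth_spec(n_proteins = 10, n_targets = 2, target_log2fc = 3,
                   control_absent = FALSE, peptide_sd = 0, line_sd = 0,
                   rep_sd = 0, missingness = FALSE, seed = 8)
  pan <- generate_panel(tr)
  L <- log2(pan$peptides$intensity)
  design <- pan$peptides$design
  for (g in c("FP_RMS", "FN_RMS", "PDX", "CONTROL")) {
    cols <- design$group == g
    truth_col <- if (g == "CONTROL") pan$truth$base_log2 else
      pan$truth[[paste0("true_mean_", g)]]
    expected <- truth_col[match(pan$peptides$protein_id, pan$truth$protein_id)]
    expect_equal(unname(rowMeans(L[, cols, drop = FALSE])), expected,
                 tolerance = 1e-12)
  }
})

test_that("detection probability increases with true intensity", {
  tr <- truth_spec(n_proteins = 60, n_targets = 0, base_mean = 20,
                   base_sd = 3, detect_mid = 20, detect_scale = 1, seed = 21)
  pan <- generate_panel(tr)
  # bin by the *true* protein means: censoring biases observed means upward
  base <- pan$truth$base_log2[match(pan$peptides$protein_id,
                                    pan$truth$protein_id)]
  det_frac <- rowMeans(pan$peptides$detected)
  expect_gt(mean(det_frac[base > 21]), mean(det_frac[base < 19]))
})

test_that("synthetic annotation lists nest correctly around the truth", {
  tr <- truth_spec(n_proteins = 80, n_targets = 10, seed = 4,
                   surface_frac_background = 0.4, membrane_extra_frac = 0.25)
  lists <- generate_annotation_lists(tr)
  targets <- sprintf("TARGET%03d", 1:10)
  expect_true(all(targets %in% lists$list_a$ids))
  expect_true(all(lists$list_a$ids %in% lists$list_b$ids))
  expect_lte(length(lists$list_a$ids), length(lists$list_b$ids))
  # some background proteins are in neither list
  outside <- setdiff(tr$proteins$protein_id, lists$list_b$ids)
  expect_gt(length(outside), 0)
  expect_false(any(tr$proteins$surface[match(outside, tr$proteins$protein_id)]))
})

test_that("synthetic FPKM tables plant clean tumor/normal contrasts", {
  tr <- truth_spec(n_proteins = 50, n_targets = 5, seed = 6)
  fp <- generate_fpkm(tr)
  expect_true(all(c("BRAIN", "HEART", "KIDNEY", "LIVER", "LUNG") %in%
                    colnames(fp$fpkm)))
  targets <- sprintf("TARGET%03d", 1:5)
  t_tumor <- apply(fp$fpkm[targets, fp$tumor_cols], 1, median)
  t_normal <- apply(fp$fpkm[targets, fp$normal_cols], 1, max)
  expect_true(all(t_tumor > 300))
  expect_true(all(t_normal < 5))
  # background genes: tumor close to normal (within the jitter envelope)
  bg <- setdiff(rownames(fp$fpkm), targets)
  ratio <- apply(fp$fpkm[bg, fp$tumor_cols], 1, median) /
    apply(fp$fpkm[bg, fp$normal_cols], 1, median)
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("clinical cohorts respect their contracts", {
  cl <- generate_clinical(n_patients = 120, beta = 0.8, censor_rate = 0.3,
                          seed = 3)
  expect_true(all(cl$survival$time >= 0))
  expect_true(all(cl$survival$event %in% c(0, 1)))
  pct <- cl$ihc[, c("pct_strong", "pct_medium", "pct_weak")]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(rowSums(pct) <= 100 + 1e-9))
  # alveolar-like cores carry the high H-scores
  h <- h_score(cl$ihc$pct_strong, cl$ihc$pct_medium, cl$ihc$pct_weak)
  expect_gt(median(h[cl$ihc$subtype == "ARMS"]),
            median(h[cl$ihc$subtype == "ERMS"]))
})

test_that("null cohorts give calibrated median-split logrank tests", {
  n_sim <- 300
  pvals <- vapply(seq_len(n_sim), function(i) {
    cl <- generate_clinical(n_patients = 100, beta = 0, censor_rate = 0.2,
                            seed = 1000 + i)
    s <- cl$survival
    g <- s$expression > median(s$expression)
    logrank_test(s$time, s$event, g)$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})

test_that("best-cutoff logrank detects a strong expression effect", {
  n_sim <- 30
  hits <- vapply(seq_len(n_sim), function(i) {
    cl <- generate_clinical(n_patients = 300, beta = 1, censor_rate = 0.2,
                            seed = 2000 + i)
    s <- cl$survival
    best_cutoff(s$time, s$event, s$expression)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
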
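test_that("median_log2 removes constant shifts and is idempotent", {
  design <- tiny_design(n_reps = 1)[1:2, ]
  set.seed(1)
  base <- 2^rnorm(50, 20, 2)
  m <- cbind(base, base * 2^1.7)  # second sample shifted by 1.7 on log2
  pt <- pt_from_matrix(m, protein_id = rep("A", 50), design)
  norm <- normalize_peptides(pt)
  meds <- apply(norm$intensity, 2, median)
  expect_equal(meds[[1]], meds[[2]], tolerance = 1e-9)
  # a second pass changes nothing
  norm2 <- normalize_peptides(norm)
  expect_equal(norm2$intensity, norm$intensity, tolerance = 1e-9)
})

test_that("arsinh normalization compresses low-intensity variance", {
  design <- tiny_design(n_reps = 1)[1:2, ]
  set.seed(7)
  mu <- 2^runif(400, 8, 26)
  # heteroscedastic additive + multiplicative noise
  m <- cbind(mu + rnorm(400, 0, 50) + mu * rnorm(400, 0, 0.1),
             mu + rnorm(400, 0, 50) + mu * rnorm(400, 0, 0.1))
  m[m <= 0] <- 1
  pt <- pt_from_matrix(m, protein_id = paste0("P", 1:400), design)
  vsn <- normalize_peptides(pt, method = "vsn_arsinh")
  logd <- normalize_peptides(pt, method = "median_log2")
  bottom <- rank(mu) <= 40
  expect_lt(sd(vsn$intensity[bottom, 1]), sd(logd$intensity[bottom, 1]))
})

test_that("normalization names a sample with zero detected peptides", {
  design <- tiny_design(n_reps = 1)[1:2, ]
  m <- cbind(c(2, 4, 8), c(0, 0, 0))
  pt <- pt_from_matrix(m, protein_id = c("A", "A", "B"), design)
  expect_error(normalize_peptides(pt), "CTRL_r1")
})

test_that("stage-1 draws follow the down-shifted Gaussian", {
  # One line of 3 replicates; 4000 fully-missing peptides per column give
  # stage-1 draws whose column statistics must match
  # Normal(mu - 2.8 sd, (0.3 sd)^2) with mu = 20, sd = 2 (drawn mean 14.4,
  # SD 0.6).
  design <- tiny_design()[1:3, ]
  n_det <- 4000; n_mis <- 4000
  set.seed(5)
  v <- rnorm(n_det)
  v <- (v - mean(v)) / sd(v) * 2 + 20   # exact moments: mean 20, sd 2
  L <- rbind(matrix(rep(v, 3), ncol = 3),
             matrix(NA_real_, n_mis, 3))
  colnames(L) <- design$sample_id
  det <- !is.na(L)
  pt <- peptide_table(paste0("p", seq_len(nrow(L))),
                      paste0("P", seq_len(nrow(L))), L, det, design,
                      scale = "log2")
  imp <- impute_peptides(pt, shift = 2.8, width = 0.3, seed = 99)
  draws <- imp$intensity[(n_det + 1):(n_det + n_mis), 1]
  se_mean <- 0.6 / sqrt(n_mis)
  se_sd <- 0.6 / sqrt(2 * n_mis)
  expect_lt(abs(mean(draws) - 14.4), 3 * se_mean)
  expect_lt(abs(sd(draws) - 0.6), 3 * se_sd)
  # stochastically below the column mean of detected values
  expect_true(all(draws < 20))
})

test_that("groups with two detected replicates use the MLE fill, not the down-shift", {
  design <- tiny_design()[1:3, ]
  # 30 detected background peptides so column stats exist; one peptide with
  # 2 of 3 detected
  set.seed(11)
  bg <- matrix(rnorm(90, 20, 2), ncol = 3)
  L <- rbind(bg, c(24, 26, NA))
  colnames(L) <- design$sample_id
  pt <- peptide_table(paste0("p", 1:31), paste0("P", 1:31), L, !is.na(L),
                      design, scale = "log2")
  imp <- impute_peptides(pt, seed = 1)
  expect_equal(imp$intensity[31, 3], mean(c(24, 26)))
})

test_that("imputation is the identity on complete tables and preserves detected values", {
  pan <- small_panel(n_proteins = 20, n_targets = 0, seed = 3,
                     missingness = FALSE)
  norm <- normalize_peptides(pan$peptides)
  expect_identical(impute_peptides(norm, seed = 1), norm)

  pan2 <- small_panel(n_proteins = 20, n_targets = 2, seed = 3)
  norm2 <- normalize_peptides(pan2$peptides)
  imp2 <- impute_peptides(norm2, seed = 1)
  expect_identical(imp2$intensity[norm2$detected], norm2$intensity[norm2$detected])
  expect_identical(imp2$detected, norm2$detected)
  expect_false(anyNA(imp2$intensity))
  expect_error(impute_peptides(norm2, shift = -1), "shift")
})

test_that("iTop3 sums the three largest peptide intensities", {
  design <- tiny_design(n_reps = 1)[1:2, ]
  m <- matrix(c(8, 8, 5, 5, 3, 3, 2, 2, 4, 4, 1, 1), ncol = 2, byrow = TRUE)
  pt <- pt_from_matrix(m, protein_id = c("A", "A", "A", "A", "B", "B"), design)
  it <- itop3(pt)
  expect_equal(unname(it["A", ]), c(16, 16))  # 8 + 5 + 3
  expect_equal(unname(it["B", ]), c(5, 5))    # all peptides when < 3

  # permuting peptide rows leaves iTop3 unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  pt_perm <- pt_from_matrix(m[perm, ], protein_id = c("A", "A", "A", "A", "B", "B")[perm],
                            design)
  expect_equal(itop3(pt_perm)[rownames(it), ], it)
})

test_that("iTop3 is monotone and matches a brute-force sum for <= 3 peptides", {
  design <- tiny_design(n_reps = 1)[1:2, ]
  set.seed(2)
  prot <- rep(paste0("P", 1:30), times = sample(1:3, 30, replace = TRUE))
  m <- matrix(2^rnorm(length(prot) * 2, 20, 2), ncol = 2)
  pt <- pt_from_matrix(m, protein_id = prot, design)
  it <- itop3(pt)
  brute <- rowsum(m, prot)[rownames(it), ]
  expect_equal(unname(it), unname(brute))

  # increasing any peptide never decreases its protein's iTop3
  m2 <- m
  m2[10, 1] <- m2[10, 1] * 5
  it2 <- itop3(pt_from_matrix(m2, protein_id = prot, design))
  expect_true(all(it2 >= it - 1e-9))
})

test_that("detection calls require signal in enough replicates of the raw data", {
  design <- tiny_design()
  # protein A: 3/3 replicates in FP1, 1/3 in CTRL; protein B: never detected
  m <- rbind(c(4, 5, 6, 2, 0, 0),
             c(0, 0, 0, 0, 0, 0))
  pt <- pt_from_matrix(m, protein_id = c("A", "B"), design)
  det <- detect_lines(pt, min_replicates = 2)
  expect_true(det["A", "FP1"])
  expect_false(det["A", "CTRL"])   # 1/3 replicates is below the threshold
  expect_false(any(det["B", ]))    # imputed-everywhere proteins detected nowhere
  det1 <- detect_lines(pt, min_replicates = 1)
  expect_true(det1["A", "CTRL"])
})

test_that("group fold changes follow the ratio and fixed-substitution rules", {
  design <- default_design()
  pr <- c("RATIO", "ABSENT", "EQUAL")
  m <- matrix(0, 3, nrow(design), dimnames = list(NULL, design$sample_id))
  fp <- design$group == "FP_RMS"
  ctrl <- design$group == "CONTROL"
  m[1, ] <- 1e8; m[1, fp] <- 8e8
  m[2, !ctrl] <- 2e8                       # absent in both controls
  m[3, ] <- 5e7
  L <- log2(m); L[m == 0] <- NA_real_
  pt <- peptide_table(paste0("pep", 1:3), pr, L, m > 0, design, scale = "log2")
  q <- quantify(impute_peptides(pt, seed = 1), raw = pt)
  expect_equal(unname(q$log2fc["RATIO", "FP_RMS_vs_CTRL_FIBRO"]), 3,
               tolerance = 1e-9)
  expect_true(all(q$log2fc["ABSENT", ] == 10))
  expect_true(all(abs(q$log2fc["EQUAL", ]) < 1e-9))
  expect_equal(unname(q$n_controls), c(2, 0, 2))
})
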
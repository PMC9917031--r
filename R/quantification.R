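#' Normalize peptide intensities
#'
#' Two methods are available. `median_log2` (default) log2-transforms the
#' detected intensities and shifts each sample so that all per-sample medians
#' equal the mean of the original medians: a pure location correction that is
#' idempotent on already-centered data. `vsn_arsinh` applies an affine/arsinh
#' generalized-log calibration: samples are first rescaled so that their
#' medians agree, then transformed with
#' `glog2(x) = log2(x + sqrt(x^2 + c^2)) - 1`, with `c` set to the 10th
#' percentile of the rescaled detected intensities. For large intensities
#' `glog2` coincides with `log2`, while near the detection floor it
#' compresses the variance instead of exploding it.
#'
#' Missing (undetected) entries are untouched by either method.
#'
#' @param pt a [peptide_table()] on the linear or log2 scale.
#' @param method `"median_log2"` or `"vsn_arsinh"`.
#' @return A [peptide_table()] on the log2 scale.
#' @export
normalize_peptides <- function(pt, method = c("median_log2", "vsn_arsinh")) {
  method <- match.arg(method)
  stopifnot(inherits(pt, "PeptideTable"))
  if (ncol(pt$intensity) < 2L) stop("normalization requires >= 2 samples")
  n_det <- colSums(pt$detected)
  if (any(n_det == 0L)) {
    stop("sample(s) with zero detected peptides: ",
         paste(colnames(pt$intensity)[n_det == 0L], collapse = ", "))
  }
  x <- pt$intensity
  if (method == "median_log2") {
    L <- if (pt$scale == "linear") log2(x) else x
    med <- apply(L, 2, median, na.rm = TRUE)
    L <- sweep(L, 2, med) + mean(med)
  } else {
    lin <- if (pt$scale == "log2") 2^x else x
    med <- apply(lin, 2, median, na.rm = TRUE)
    b <- exp(mean(log(med))) / med
    scaled <- sweep(lin, 2, b, "*")
    c0 <- quantile(scaled[pt$detected], 0.1, na.rm = TRUE)
    L <- log2(scaled + sqrt(scaled^2 + c0^2)) - 1
  }
  peptide_table(pt$peptide_id, pt$protein_id, L, pt$detected, pt$design,
                scale = "log2")
}

#' Two-stage left-censored imputation
#'
#' Implements the two-stage rule for missing peptide intensities, applied on
#' the log2 scale with replicate groups defined by the line (cell line, PDX
#' or control culture):
#'
#' * Stage 1 (down-shift): for every (peptide, line) with at most one
#'   detected replicate, missing replicates are drawn from
#'   `Normal(mu_s - shift * sigma_s, (width * sigma_s)^2)`, where `mu_s` and
#'   `sigma_s` are the mean and SD of the detected values in that sample
#'   column. This treats near-complete absence within a line as evidence the
#'   peptide sits below the detection limit (missing-not-at-random).
#' * Stage 2 (MLE): remaining missing values — groups with two or more
#'   detected replicates — are filled with the Gaussian maximum-likelihood
#'   conditional mean, i.e. the mean of the detected replicates of that
#'   peptide within the line.
#'
#' Detected values are never altered and detection flags are preserved, so
#' downstream detection calls remain based on the raw data.
#'
#' @param pt a normalized [peptide_table()] on the log2 scale.
#' @param shift,width down-shift parameters in sample-SD units (defaults 2.8
#'   and 0.3).
#' @param seed optional integer seed for the stage-1 draws.
#' @return A [peptide_table()] with no missing values.
#' @export
impute_peptides <- function(pt, shift = 2.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(pt, "PeptideTable"))
  if (pt$scale != "log2") stop("impute_peptides expects a log2-scale table; normalize first")
  if (shift <= 0) stop("shift must be > 0")
  if (width <= 0) stop("width must be > 0")
  x <- pt$intensity
  if (!anyNA(x)) return(pt)
  if (!is.null(seed)) set.seed(seed)

  det <- pt$detected
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sdv))) {
    stop("sample(s) with fewer than 2 detected peptides: ",
         paste(colnames(x)[!is.finite(sdv)], collapse = ", "))
  }

  linefac <- factor(pt$design$line_id, levels = unique(pt$design$line_id))
  line_of <- as.integer(linefac)
  n_det_line <- t(rowsum(t(det * 1), linefac))            # peptide x line
  cnt <- n_det_line[, line_of, drop = FALSE]              # peptide x sample
  stage1 <- is.na(x) & cnt <= 1L
  stage2 <- is.na(x) & cnt >= 2L

  for (j in seq_len(ncol(x))) {
    idx <- which(stage1[, j])
    if (length(idx)) {
      x[idx, j] <- rnorm(length(idx), mean = mu[j] - shift * sdv[j],
                         sd = width * sdv[j])
    }
  }

  if (any(stage2)) {
    x0 <- pt$intensity
    x0[is.na(x0)] <- 0
    sum_line <- t(rowsum(t(x0 * det), linefac))
    mean_line <- sum_line / pmax(n_det_line, 1L)
    fill <- mean_line[, line_of, drop = FALSE]
    x[stage2] <- fill[stage2]
  }

  peptide_table(pt$peptide_id, pt$protein_id, x, det, pt$design, scale = "log2")
}

#' iTop3 protein roll-up
#'
#' For every (protein, sample), iTop3 is the sum of the three largest peptide
#' intensities on the linear scale (all peptides when a protein has fewer
#' than three). The input must be fully imputed; log2-scale tables are
#' back-transformed before summation.
#'
#' @param pt an imputed [peptide_table()].
#' @return A numeric protein x sample matrix of iTop3 values.
#' @export
itop3 <- function(pt) {
  stopifnot(inherits(pt, "PeptideTable"))
  if (anyNA(pt$intensity)) stop("itop3 requires a fully imputed table")
  lin <- if (pt$scale == "log2") 2^pt$intensity else pt$intensity
  prot <- factor(pt$protein_id, levels = unique(pt$protein_id))
  idx <- split(seq_along(pt$protein_id), prot)
  out <- matrix(NA_real_, nrow = length(idx), ncol = ncol(lin),
                dimnames = list(names(idx), colnames(lin)))
  top3sum <- function(v) {
    if (length(v) > 3L) v <- sort(v, decreasing = TRUE)[1:3]
    sum(v)
  }
  for (j in seq_len(ncol(lin))) {
    col <- lin[, j]
    out[, j] <- vapply(idx, function(i) top3sum(col[i]), numeric(1))
  }
  out
}

#' Detection calls per (protein, line)
#'
#' A protein counts as detected in a line when at least `min_replicates` of
#' that line's replicates carry at least one peptide with nonzero raw
#' intensity. Calls are always made on the pre-imputation table: a protein
#' whose values are entirely imputed is detected nowhere.
#'
#' @param raw the raw (pre-imputation) [peptide_table()].
#' @param min_replicates required replicates with signal (default 2).
#' @return A logical protein x line matrix.
#' @export
detect_lines <- function(raw, min_replicates = 2L) {
  stopifnot(inherits(raw, "PeptideTable"))
  prot <- factor(raw$protein_id, levels = unique(raw$protein_id))
  # any peptide detected per (protein, sample)
  det_ps <- rowsum(raw$detected * 1, prot) > 0
  linefac <- factor(raw$design$line_id, levels = unique(raw$design$line_id))
  reps_with_signal <- t(rowsum(t(det_ps * 1), linefac))
  reps_with_signal >= min_replicates
}

#' Group-vs-control log2 fold changes
#'
#' For each tumor group (FP-RMS, FN-RMS, PDX) and each control line, the
#' fold change is `log2(group mean iTop3 / control line mean iTop3)`. When
#' the protein is not detected in that control line the ratio is undefined
#' on the data and the fixed value `absent_control_value` (default 10) is
#' substituted, which maps to the best fold-change score downstream. A
#' protein whose tumor-group mean is zero gets `NA` for that comparison and
#' is dropped from ranking.
#'
#' @param quant a [quantify()] result.
#' @param absent_control_value fixed log2FC for control-undetected proteins.
#' @return Numeric matrix, proteins x (group x control line) comparisons,
#'   with columns named `"<group>_vs_<control line>"`.
#' @export
group_log2fc <- function(quant, absent_control_value = 10) {
  stopifnot(inherits(quant, "ProteinQuant"))
  design <- quant$design
  ctrl_lines <- unique(design$line_id[design$group == "CONTROL"])
  combos <- expand.grid(group = TUMOR_GROUPS, ctrl = ctrl_lines,
                        stringsAsFactors = FALSE)
  fc <- matrix(NA_real_, nrow = length(quant$protein_id), ncol = nrow(combos),
               dimnames = list(quant$protein_id,
                               paste0(combos$group, "_vs_", combos$ctrl)))
  for (k in seq_len(nrow(combos))) {
    g_mean <- quant$group_means[, combos$group[k]]
    c_mean <- quant$line_means[, combos$ctrl[k]]
    ctrl_det <- quant$detected_line[, combos$ctrl[k]]
    val <- ifelse(!ctrl_det, absent_control_value, log2(g_mean / c_mean))
    val[g_mean <= 0] <- NA_real_
    fc[, k] <- val
  }
  fc
}

#' Protein-level quantification
#'
#' Rolls an imputed peptide table up to a `ProteinQuant` object: the iTop3
#' matrix, detection calls from the raw table, per-line and per-group iTop3
#' means, the RMS cell-line abundance mean, detection counts (RMS cell
#' lines, PDXs, controls), and the group-vs-control log2 fold-change matrix
#' with the fixed substitution for control-undetected proteins.
#'
#' @param imputed an imputed [peptide_table()] (log2 or linear scale).
#' @param raw the pre-imputation [peptide_table()] used for detection calls;
#'   defaults to `imputed` when it still carries original flags.
#' @param min_replicates detection threshold per line, see [detect_lines()].
#' @param absent_control_value see [group_log2fc()].
#' @return An object of class `"ProteinQuant"`.
#' @export
quantify <- function(imputed, raw = imputed, min_replicates = 2L,
                     absent_control_value = 10) {
  design <- imputed$design
  it <- itop3(imputed)
  detected_line <- detect_lines(raw, min_replicates = min_replicates)
  stopifnot(identical(rownames(it), rownames(detected_line)))

  line_group <- design$group[!duplicated(design$line_id)]
  names(line_group) <- design$line_id[!duplicated(design$line_id)]
  cl_lines <- names(line_group)[line_group %in% CELL_LINE_GROUPS]
  pdx_lines <- names(line_group)[line_group == "PDX"]
  ctrl_lines <- names(line_group)[line_group == "CONTROL"]

  linefac <- factor(design$line_id, levels = unique(design$line_id))
  line_means <- t(rowsum(t(it), linefac) / as.vector(table(linefac)))

  group_means <- sapply(TUMOR_GROUPS, function(g) {
    cols <- design$sample_id[design$group == g]
    rowMeans(it[, cols, drop = FALSE])
  })

  cl_samples <- design$sample_id[design$group %in% CELL_LINE_GROUPS]
  itop3_mean <- rowMeans(it[, cl_samples, drop = FALSE])

  quant <- structure(
    list(protein_id = rownames(it), itop3 = it,
         detected_line = detected_line, line_means = line_means,
         group_means = group_means, itop3_mean = itop3_mean,
         n_rms_lines = rowSums(detected_line[, cl_lines, drop = FALSE]),
         n_pdx = rowSums(detected_line[, pdx_lines, drop = FALSE]),
         n_controls = rowSums(detected_line[, ctrl_lines, drop = FALSE]),
         design = design),
    class = "ProteinQuant"
  )
  quant$log2fc <- group_log2fc(quant, absent_control_value = absent_control_value)
  quant
}

#' Subset a ProteinQuant by protein identifiers
#'
#' @param quant a `ProteinQuant`.
#' @param ids character protein identifiers to keep (order preserved from
#'   `quant`).
#' @return A `ProteinQuant` restricted to the matching proteins.
#' @export
subset_proteins <- function(quant, ids) {
  stopifnot(inherits(quant, "ProteinQuant"))
  keep <- quant$protein_id %in% toupper(ids)
  out <- quant
  out$protein_id <- quant$protein_id[keep]
  for (f in c("itop3", "detected_line", "line_means", "group_means", "log2fc")) {
    out[[f]] <- quant[[f]][keep, , drop = FALSE]
  }
  for (f in c("itop3_mean", "n_rms_lines", "n_pdx", "n_controls")) {
    out[[f]] <- quant[[f]][keep]
  }
  out
}

#' @export
print.ProteinQuant <- function(x, ...) {
  cat(sprintf("ProteinQuant: %d proteins x %d samples (%d lines)\n",
              length(x$protein_id), ncol(x$itop3), ncol(x$detected_line)))
  invisible(x)
}

#' @export
as.data.frame.ProteinQuant <- function(x, ...) {
  data.frame(protein_id = x$protein_id,
             n_rms_lines = x$n_rms_lines, n_pdx = x$n_pdx,
             n_controls = x$n_controls, itop3_mean = x$itop3_mean,
             x$log2fc, check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}
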
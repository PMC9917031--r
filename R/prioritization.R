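#' Table-1 component scores
#'
#' The proteomics scoring grid assigns penalty points per component; lower
#' totals identify better targets (abundant, ubiquitous in tumor material,
#' absent from controls). All printed ranges are interpreted as
#' lower-inclusive, upper-exclusive on the better-scoring side.
#'
#' * `score_lines(n)`: detections across the 14 tumor lines (11 RMS cell
#'   lines + 3 PDXs): 14 -> 0, 13 -> 0.5, 12 -> 1.5, 11 -> 3, 10 -> 5,
#'   9 -> 7.5, 8 -> 10, 7 -> 15, <= 6 -> 30.
#' * `score_abundance(m)`: RMS cell-line iTop3 mean, decade-style bins from
#'   >= 2.5e9 -> 0 down to \[5e6, 1e7) -> 8; means below 5e6 (under the last
#'   printed bin) continue the unit-step pattern with score 9 and are
#'   flagged in reports.
#' * `score_fc(fc)`: log2 fold change vs a control; the fixed value 10
#'   (control-undetected) -> 0, then \[6, 10) -> 0.5 down to < 1 -> 3.5
#'   (negative fold changes included in the < 1 bin).
#' * `score_controls(n)`: detection in 0/1/2 control lines -> 0 / 2.5 / 5.
#' * `score_pdx(n)`: detection in 3/2/1/0 PDXs -> 0 / 0.5 / 1 / 1.5.
#'
#' @param n integer detection counts.
#' @param m non-negative iTop3 means.
#' @param fc log2 fold changes.
#' @return Numeric score vectors on the respective grids.
#' @name table1_scores
NULL

#' @rdname table1_scores
#' @export
score_lines <- function(n) {
  stopifnot(all(n >= 0 & n <= 14, na.rm = TRUE))
  lut <- c(rep(30, 7), 15, 10, 7.5, 5, 3, 1.5, 0.5, 0)  # n = 0..14
  lut[as.integer(n) + 1L]
}

#' @rdname table1_scores
#' @export
score_abundance <- function(m) {
  stopifnot(all(m >= 0, na.rm = TRUE))
  breaks <- c(5e6, 1e7, 2.5e7, 5e7, 1e8, 2.5e8, 5e8, 1e9, 2.5e9)
  9 - findInterval(m, breaks)
}

#' @rdname table1_scores
#' @export
score_fc <- function(fc) {
  s <- 3.5 - 0.5 * findInterval(fc, c(1, 2, 3, 4, 5, 6))
  s[fc >= 10] <- 0
  s[is.na(fc)] <- NA_real_
  s
}

#' @rdname table1_scores
#' @export
score_controls <- function(n) {
  stopifnot(all(n %in% 0:2, na.rm = TRUE))
  c(0, 2.5, 5)[as.integer(n) + 1L]
}

#' @rdname table1_scores
#' @export
score_pdx <- function(n) {
  stopifnot(all(n %in% 0:3, na.rm = TRUE))
  c(1.5, 1, 0.5, 0)[as.integer(n) + 1L]
}

#' RMS-specificity bonus
#'
#' A bonus of -3 for proteins that are abundant (RMS cell-line iTop3 mean
#' above 1e7), undetected in both controls (i.e. carrying the fixed
#' log2FC of 10), and detected in at least 13 of the 14 tumor lines.
#'
#' @param itop3_mean RMS cell-line iTop3 mean.
#' @param log2fc_effective the effective log2FC vs controls; the bonus
#'   requires the fixed control-absent value (10).
#' @param n_lines detections across the 14 tumor lines.
#' @return `-3` where all three conditions hold, else `0`.
#' @export
specificity_bonus <- function(itop3_mean, log2fc_effective, n_lines) {
  ifelse(itop3_mean > 1e7 & log2fc_effective == 10 & n_lines >= 13, -3, 0)
}

#' Score quantified proteins (Table-1 scorecards)
#'
#' Applies the full proteomics scoring to a `ProteinQuant`: cell-line count
#' (RMS cell lines + PDXs), abundance, fold change (each group x control
#' comparison scored on the grid and averaged, preserving the printed
#' \[0, 3.5\] range), control detection, PDX bonus and the RMS-specificity
#' bonus. Proteins with no detectable tumor signal (any undefined fold
#' change) receive `NA` totals and are dropped at ranking.
#'
#' @param quant a [quantify()] (optionally [filter_surface()]ed) result.
#' @return A `data.frame` scorecard with one row per protein: components
#'   `s_lines`, `s_abundance`, `s_fc`, `s_ctrl`, `s_pdx`, `s_bonus`, their
#'   sum `total`, and a `below_last_bin` flag for abundance means under the
#'   last printed bin.
#' @export
score_protein <- function(quant) {
  stopifnot(inherits(quant, "ProteinQuant"))
  n_cl <- quant$n_rms_lines + quant$n_pdx
  fc_scores <- apply(quant$log2fc, 2, score_fc)
  if (is.null(dim(fc_scores))) fc_scores <- matrix(fc_scores, nrow = 1)
  s_fc <- rowMeans(fc_scores)
  s <- data.frame(
    protein_id = quant$protein_id,
    s_lines = score_lines(n_cl),
    s_abundance = score_abundance(quant$itop3_mean),
    s_fc = s_fc,
    s_ctrl = score_controls(quant$n_controls),
    s_pdx = score_pdx(quant$n_pdx),
    s_bonus = specificity_bonus(quant$itop3_mean,
                                ifelse(quant$n_controls == 0, 10, 0), n_cl),
    itop3_mean = quant$itop3_mean,
    below_last_bin = quant$itop3_mean < 5e6,
    stringsAsFactors = FALSE, row.names = NULL
  )
  s$total <- s$s_lines + s$s_abundance + s$s_fc + s$s_ctrl + s$s_pdx + s$s_bonus
  s
}

#' Rank scorecards and report the Top-K
#'
#' Ascending by total score (lower is better); ties are broken by
#' descending iTop3 mean, then lexicographic protein id, so the ordering is
#' independent of input order. Ranks are 1-based.
#'
#' @param scorecards a [score_protein()] result.
#' @param top_k number of proteins to return (default 100; the whole list
#'   when larger than it).
#' @return The top `top_k` rows with a `rank` column prepended.
#' @export
rank_targets <- function(scorecards, top_k = 100L) {
  drop <- is.na(scorecards$total)
  if (any(drop)) {
    warning(sprintf("%d protein(s) without a defined total dropped from ranking",
                    sum(drop)))
    scorecards <- scorecards[!drop, , drop = FALSE]
  }
  o <- order(scorecards$total, -scorecards$itop3_mean, scorecards$protein_id)
  out <- scorecards[o, , drop = FALSE]
  out <- utils::head(out, top_k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Table-2 mRNA scores
#'
#' Scores transcript-level evidence for the top proteomics candidates from
#' an FPKM summary: expression in normal tissues (high is penalized, 0-10),
#' expression in RMS tumors (low is penalized, 0-15), number of the five
#' reference control tissues (brain, heart, kidney, liver, lung) with
#' appreciable expression (0-1.25), and the tumor-vs-normal log2 fold
#' change (0-10). All inputs are vectorized.
#'
#' @param normal_fpkm summary FPKM across normal tissues.
#' @param tumor_fpkm summary FPKM across RMS tumor samples.
#' @param n_ctrl_tissues number of control tissues (0-5) with expression.
#' @param log2fc tumor-vs-normal log2 fold change.
#' @return A `data.frame` with components `s_normal`, `s_tumor`,
#'   `s_ctrl_tissues`, `s_fc` and their sum `total`.
#' @export
score_mrna <- function(normal_fpkm, tumor_fpkm, n_ctrl_tissues, log2fc) {
  stopifnot(all(n_ctrl_tissues %in% 0:5, na.rm = TRUE))
  s_normal <- c(0, 0.5, 1.5, 3, 5, 7.5, 10)[
    findInterval(normal_fpkm, c(5, 10, 50, 100, 250, 500)) + 1L]
  s_tumor <- c(15, 10, 7.5, 5, 3, 1.5)[
    pmin(findInterval(tumor_fpkm, c(5, 10, 25, 50, 100, 250)) + 1L, 6L)]
  s_tumor[tumor_fpkm >= 250 & tumor_fpkm <= 500] <- 0.5
  s_tumor[tumor_fpkm > 500] <- 0
  s_ctrl <- c(0, 0.25, 0.5, 0.75, 1, 1.25)[as.integer(n_ctrl_tissues) + 1L]
  s_fc <- c(10, 5, 4, 3, 2, 1, 0)[findInterval(log2fc, c(1, 1.5, 2, 3, 4, 5)) + 1L]
  data.frame(s_normal = s_normal, s_tumor = s_tumor,
             s_ctrl_tissues = s_ctrl, s_fc = s_fc,
             total = s_normal + s_tumor + s_ctrl + s_fc)
}

#' mRNA scorecards from an FPKM matrix
#'
#' Computes the Table-2 inputs from a gene x sample FPKM matrix and scores
#' them. Summary statistics: maximum FPKM across normal tissues (the most
#' conservative choice for target safety), median FPKM across tumor
#' samples; a control tissue counts as expressing the gene at FPKM >= 5
#' (the lowest bin edge of the grid); log2FC compares the two summaries
#' (defined as the best bin when the normal summary is zero).
#'
#' @param fpkm numeric gene x sample matrix (upper-cased gene rownames).
#' @param tumor_cols,normal_cols column names of tumor samples and normal
#'   tissues.
#' @param ctrl_tissues control tissue column names (default the five
#'   reference tissues present in `normal_cols`).
#' @param expressed_fpkm control-tissue expression threshold (default 5).
#' @return A `data.frame` with gene ids, the summaries and the
#'   [score_mrna()] components, sorted by total ascending.
#' @export
score_mrna_from_fpkm <- function(fpkm, tumor_cols, normal_cols,
                                 ctrl_tissues = intersect(CONTROL_TISSUES,
                                                          toupper(normal_cols)),
                                 expressed_fpkm = 5) {
  stopifnot(all(tumor_cols %in% colnames(fpkm)),
            all(normal_cols %in% colnames(fpkm)))
  normal_max <- apply(fpkm[, normal_cols, drop = FALSE], 1, max)
  tumor_med <- apply(fpkm[, tumor_cols, drop = FALSE], 1, median)
  ctrl_cols <- colnames(fpkm)[toupper(colnames(fpkm)) %in% ctrl_tissues]
  n_ctrl <- rowSums(fpkm[, ctrl_cols, drop = FALSE] >= expressed_fpkm)
  log2fc <- ifelse(normal_max > 0, log2(tumor_med / normal_max), Inf)
  log2fc[tumor_med <= 0] <- -Inf
  scores <- score_mrna(normal_max, tumor_med, n_ctrl, log2fc)
  out <- cbind(
    data.frame(gene_id = rownames(fpkm), normal_fpkm = normal_max,
               tumor_fpkm = tumor_med, n_ctrl_tissues = n_ctrl,
               log2fc = log2fc, stringsAsFactors = FALSE, row.names = NULL),
    scores)
  out <- out[order(out$total, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate abundance summary
#'
#' Per-candidate distribution of log2(iTop3) across all samples, with group
#' labels and per-candidate medians; candidates are ordered by median
#' descending, matching the usual dot-plot presentation.
#'
#' @param quant a [quantify()] result.
#' @param candidates character protein identifiers.
#' @return A long `data.frame` (protein_id, sample_id, group, log2_itop3,
#'   median_log2_itop3), proteins in median-descending order.
#' @export
candidate_summary <- function(quant, candidates) {
  stopifnot(inherits(quant, "ProteinQuant"))
  candidates <- toupper(candidates)
  missing_ids <- setdiff(candidates, quant$protein_id)
  if (length(missing_ids)) {
    stop("candidate(s) not quantified: ", paste(missing_ids, collapse = ", "))
  }
  m <- log2(quant$itop3[candidates, , drop = FALSE])
  med <- apply(m, 1, median)
  ord <- names(sort(med, decreasing = TRUE))
  out <- do.call(rbind, lapply(ord, function(p) {
    data.frame(protein_id = p, sample_id = colnames(m),
               group = quant$design$group,
               log2_itop3 = m[p, ], median_log2_itop3 = med[[p]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}
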
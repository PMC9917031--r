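#' Fit the empirical-Bayes variance prior
#'
#' Moment-matching fit of a scaled inverse-chi-square prior to a collection
#' of residual variances, via the distribution of log variances: with
#' `e = log(s^2) - digamma(d/2) + log(d/2)`, the excess spread of `e` over
#' `trigamma(d/2)` determines the prior degrees of freedom `d0` through the
#' inverse trigamma function, and its mean determines the prior variance
#' `s0^2`. When the observed spread does not exceed the sampling spread the
#' prior is degenerate: `d0 = Inf` and `s0^2` the (geometric-mean based)
#' common variance.
#'
#' @param s2 numeric vector of residual variances (one per protein).
#' @param df residual degrees of freedom (scalar or vector).
#' @return A list of class `"EBPrior"` with elements `d0` and `s0sq`.
#' @export
fit_eb_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  df <- if (length(df) > 1L) df[ok] else rep(df, length(s2))
  if (length(s2) < 2L) {
    return(structure(list(d0 = Inf, s0sq = if (length(s2)) s2 else NA_real_),
                     class = "EBPrior"))
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(structure(list(d0 = Inf, s0sq = mean(s2)), class = "EBPrior"))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0sq = s0sq), class = "EBPrior")
}

# Newton solve of trigamma(x) = y for x > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Moderated two-sample t-statistic
#'
#' Shrinks the pooled per-protein variance toward the empirical-Bayes prior:
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)` with `d = nA + nB - 2`, and
#' `t = (meanA - meanB) / sqrt(s2_tilde * (1/nA + 1/nB))` on `d0 + d`
#' degrees of freedom. `d0 = 0` recovers the ordinary pooled-variance
#' two-sample t exactly; `d0 = Inf` fixes the variance at `s0^2`.
#'
#' @param a,b numeric vectors of (log2) values for the two groups, each of
#'   length >= 2.
#' @param prior an [fit_eb_prior()] result, or NULL to pass `d0`/`s0sq`.
#' @param d0,s0sq prior degrees of freedom and variance (used when `prior`
#'   is NULL).
#' @return A list with `log2fc` (meanA - meanB), `t`, `df_total` and the
#'   two-sided `p`.
#' @export
moderated_t <- function(a, b, prior = NULL, d0 = 0, s0sq = NA_real_) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("moderated_t requires at least 2 values per group")
  }
  if (!is.null(prior)) {
    d0 <- prior$d0
    s0sq <- prior$s0sq
  }
  nA <- length(a); nB <- length(b)
  d <- nA + nB - 2L
  s2 <- ((nA - 1L) * var(a) + (nB - 1L) * var(b)) / d
  s2_tilde <- if (is.infinite(d0)) s0sq else if (d0 == 0) s2 else
    (d0 * s0sq + d * s2) / (d0 + d)
  lfc <- mean(a) - mean(b)
  tt <- lfc / sqrt(s2_tilde * (1 / nA + 1 / nB))
  df_total <- d0 + d
  # floor at the smallest positive double so extreme statistics never
  # report an exact zero
  p <- max(2 * pt(-abs(tt), df = df_total), .Machine$double.xmin)
  list(log2fc = lfc, t = tt, df_total = df_total, p = p)
}

#' Per-comparison empirical-Bayes statistics
#'
#' For every tumor line (cell line or PDX) versus every control line, the
#' log2 fold change of log2(iTop3) replicate means and a moderated t are
#' computed for each protein. With triplicates on both sides the residual
#' degrees of freedom per comparison is 4, matching the 95th-percentile
#' threshold of 2.132 used for selection. The variance prior is fitted per
#' comparison across all proteins in `quant` (typically the filtered
#' List-C set).
#'
#' @param quant a [quantify()] result (usually after [filter_surface()]).
#' @return A long `data.frame`: protein_id, class (FP_RMS/FN_RMS/PDX),
#'   line, control, log2fc, t, df_total, p.
#' @export
eb_stats <- function(quant) {
  stopifnot(inherits(quant, "ProteinQuant"))
  design <- quant$design
  L <- log2(quant$itop3)
  line_group <- design$group[!duplicated(design$line_id)]
  names(line_group) <- design$line_id[!duplicated(design$line_id)]
  tumor_lines <- names(line_group)[line_group %in% TUMOR_GROUPS]
  ctrl_lines <- names(line_group)[line_group == "CONTROL"]
  if (!length(ctrl_lines)) stop("eb_stats requires at least one CONTROL line")

  stats_line <- function(line) {
    cols <- design$sample_id[design$line_id == line]
    if (length(cols) < 2L) stop("line with fewer than 2 replicates: ", line)
    m <- L[, cols, drop = FALSE]
    list(mean = rowMeans(m), var = apply(m, 1, var), n = length(cols))
  }
  by_line <- lapply(setNames(nm = c(tumor_lines, ctrl_lines)), stats_line)

  out <- list()
  for (tl in tumor_lines) {
    for (cl in ctrl_lines) {
      st <- by_line[[tl]]; sc <- by_line[[cl]]
      d <- st$n + sc$n - 2L
      s2 <- ((st$n - 1L) * st$var + (sc$n - 1L) * sc$var) / d
      prior <- fit_eb_prior(s2, d)
      s2_tilde <- if (is.infinite(prior$d0)) rep(prior$s0sq, length(s2)) else
        (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
      lfc <- st$mean - sc$mean
      tt <- lfc / sqrt(s2_tilde * (1 / st$n + 1 / sc$n))
      out[[paste(tl, cl, sep = "_vs_")]] <- data.frame(
        protein_id = quant$protein_id, class = unname(line_group[tl]),
        line = tl, control = cl, log2fc = unname(lfc), t = unname(tt),
        df_total = prior$d0 + d,
        p = pmax(2 * pt(-abs(unname(tt)), prior$d0 + d), .Machine$double.xmin),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Class-level selection from EB statistics
#'
#' Within each class (FP-RMS, FN-RMS, PDX) the per-comparison log2 fold
#' changes and moderated t statistics are averaged; a protein is selected
#' in a class when both averages meet their thresholds, and in the
#' "all-classes" set when selected in every class. The default t threshold
#' 2.132 is the 0.95 quantile of Student's t with 4 degrees of freedom.
#'
#' @param eb an [eb_stats()] result.
#' @param lfc_threshold minimum class-average log2 fold change (default 2).
#' @param t_threshold minimum class-average moderated t (default 2.132).
#' @return A wide `data.frame` per protein with `avg_log2fc_<class>`,
#'   `avg_t_<class>`, `selected_<class>` and `selected_all`.
#' @export
eb_select <- function(eb, lfc_threshold = 2, t_threshold = 2.132) {
  classes <- intersect(TUMOR_GROUPS, unique(eb$class))
  prot <- unique(eb$protein_id)
  out <- data.frame(protein_id = prot, stringsAsFactors = FALSE)
  sel <- matrix(TRUE, nrow = length(prot), ncol = 0)
  for (cl in classes) {
    sub <- eb[eb$class == cl, ]
    key <- factor(sub$protein_id, levels = prot)
    avg_lfc <- tapply(sub$log2fc, key, mean)
    avg_t <- tapply(sub$t, key, mean)
    s <- avg_lfc >= lfc_threshold & avg_t >= t_threshold
    out[[paste0("avg_log2fc_", cl)]] <- as.numeric(avg_lfc)
    out[[paste0("avg_t_", cl)]] <- as.numeric(avg_t)
    out[[paste0("selected_", cl)]] <- as.logical(s)
    sel <- cbind(sel, s)
  }
  out$selected_all <- rowSums(!sel) == 0L
  rownames(out) <- NULL
  out
}

#' Linear mixed model for one protein and group
#'
#' Fits `log2(iTop3) ~ group + (1 | line)` by REML for one tumor group
#' versus the controls, treating each line's replicates as repeated
#' measurements. The p-value for the group coefficient uses Satterthwaite
#' degrees of freedom. When the random-intercept variance estimates to zero
#' (singular fit) or the group has fewer than two lines, the model falls
#' back to the fixed-effects t-test, flagged in the output.
#'
#' @param values numeric response (log2 iTop3 per sample).
#' @param line_id line of each sample.
#' @param group group label of each sample; exactly two levels, one of
#'   which must be `"CONTROL"`.
#' @return list with `lmm_log2fc`, `lmm_p` and logical `fallback`.
#' @export
fit_lmm <- function(values, line_id, group) {
  lev <- unique(group)
  if (length(lev) != 2L || !"CONTROL" %in% lev) {
    stop("fit_lmm expects exactly two group levels including CONTROL")
  }
  tumor <- setdiff(lev, "CONTROL")
  dat <- data.frame(y = values, line = factor(line_id),
                    g = factor(group, levels = c("CONTROL", tumor)))
  fixed_fallback <- function() {
    fit <- stats::lm(y ~ g, data = dat)
    co <- summary(fit)$coefficients
    list(lmm_log2fc = unname(co[2L, 1L]), lmm_p = unname(co[2L, 4L]),
         fallback = TRUE)
  }
  n_tumor_lines <- length(unique(dat$line[dat$g == tumor]))
  if (n_tumor_lines < 2L) {
    warning("group ", tumor, " has fewer than 2 lines; using fixed-effects t-test")
    return(fixed_fallback())
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      y ~ g + (1 | line), data = dat, REML = TRUE,
      control = lme4::lmerControl(
        check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    return(fixed_fallback())
  }
  co <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(co) || nrow(co) < 2L || is.na(co[2L, 5L])) return(fixed_fallback())
  list(lmm_log2fc = unname(co[2L, 1L]), lmm_p = unname(co[2L, 5L]),
       fallback = FALSE)
}

#' Mixed-model statistics across proteins and groups
#'
#' Runs [fit_lmm()] for each requested protein and tumor group versus the
#' controls, then applies Benjamini-Hochberg adjustment within each group
#' comparison.
#'
#' @param quant a [quantify()] result.
#' @param proteins protein identifiers to test (default: all in `quant`).
#' @param groups tumor groups to compare (default all three).
#' @param alpha significance level used for the `significant` flag.
#' @return A long `data.frame`: protein_id, group, lmm_log2fc, lmm_p,
#'   lmm_p_adj, fallback, significant.
#' @export
lmm_stats <- function(quant, proteins = quant$protein_id,
                      groups = TUMOR_GROUPS, alpha = 0.05) {
  stopifnot(inherits(quant, "ProteinQuant"))
  proteins <- toupper(proteins)
  design <- quant$design
  L <- log2(quant$itop3)
  res <- list()
  for (g in groups) {
    idx <- design$group %in% c(g, "CONTROL")
    rows <- lapply(proteins, function(p) {
      r <- suppressWarnings(
        fit_lmm(L[p, idx], design$line_id[idx], design$group[idx]))
      data.frame(protein_id = p, group = g, lmm_log2fc = r$lmm_log2fc,
                 lmm_p = r$lmm_p, fallback = r$fallback,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$lmm_p_adj <- adjust_bh(tab$lmm_p)
    tab$significant <- tab$lmm_p_adj <= alpha
    res[[g]] <- tab
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the single
#' adjustment entry point of the pipeline.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Volcano significance flags
#'
#' Flags each result as `"up"`, `"down"` or `"ns"` from its fold change and
#' adjusted p-value; the defaults (adjusted p <= 0.05, i.e.
#' -log10 >= 1.3, and |log2FC| >= 1) match the usual volcano-plot gates.
#'
#' @param results `data.frame` containing the fold-change and p columns.
#' @param p_cut adjusted p-value cutoff.
#' @param lfc_cut absolute log2 fold-change cutoff.
#' @param fc_col,p_col column names of the log2 fold change and adjusted p.
#' @return `results` with `neg_log10_p` and `flag` columns appended.
#' @export
volcano_table <- function(results, p_cut = 0.05, lfc_cut = 1,
                          fc_col = "lmm_log2fc", p_col = "lmm_p_adj") {
  stopifnot(all(c(fc_col, p_col) %in% names(results)))
  fc <- results[[fc_col]]
  p <- results[[p_col]]
  results$neg_log10_p <- -log10(p)
  results$flag <- ifelse(p <= p_cut & fc >= lfc_cut, "up",
                         ifelse(p <= p_cut & fc <= -lfc_cut, "down", "ns"))
  results
}
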
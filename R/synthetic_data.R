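#' Ground-truth specification for synthetic panels
#'
#' Describes a synthetic surfaceome experiment: background proteins with
#' log-normal peptide intensities, a set of planted target proteins with
#' known group fold changes, and a left-censoring (MNAR) missingness model
#' in which detection probability increases with true intensity.
#'
#' Defaults mirror the study conditions emulated throughout the package:
#' 1,000 proteins of which 20 are planted surface targets, absent from the
#' controls and highly abundant in tumor lines (log2 peptide mean 29.5,
#' placing their iTop3 in the top abundance bin), against a background
#' centered at log2 24 (iTop3 around 5e7). Intensities are generated as
#' `2^x` of Gaussian log2 values, with per-line random effects (so that
#' mixed models have genuine repeated-measures structure) and replicate
#' noise.
#'
#' @param n_proteins total number of proteins.
#' @param n_targets number of planted targets (ignored when
#'   `planted_targets` is supplied).
#' @param target_log2fc log2 fold change of targets in each tumor group
#'   (scalar or named vector over FP_RMS/FN_RMS/PDX).
#' @param target_base_log2 log2 peptide mean of target proteins.
#' @param control_absent should targets be fully censored in controls?
#' @param planted_targets optional `data.frame` overriding the default
#'   targets, with columns `protein_id`, `base_log2`, `lfc_FP_RMS`,
#'   `lfc_FN_RMS`, `lfc_PDX`, `surface`, `control_absent`.
#' @param peptides_per_protein integer range (min, max) of peptides.
#' @param base_mean,base_sd background distribution of protein log2 means.
#' @param peptide_sd SD of per-peptide offsets around the protein mean.
#' @param line_sd SD of per-(protein, line) random effects.
#' @param rep_sd replicate noise SD.
#' @param detect_mid,detect_scale logistic detection model: a value with
#'   true log2 intensity `x` is detected with probability
#'   `plogis((x - detect_mid) / detect_scale)`; monotone non-decreasing in
#'   `x` (left-censoring).
#' @param missingness disable to generate complete tables.
#' @param surface_frac_background fraction of background proteins that are
#'   surface-annotated.
#' @param membrane_extra_frac fraction of non-surface proteins additionally
#'   included in the comprehensive (List-B style) list.
#' @param seed integer seed; all generators derive from it.
#' @return A list of class `"TruthSpec"`; element `proteins` is the
#'   per-protein truth table.
#' @export
truth_spec <- function(n_proteins = 1000L, n_targets = 20L,
                       target_log2fc = 2, target_base_log2 = 29.5,
                       control_absent = TRUE, planted_targets = NULL,
                       peptides_per_protein = c(3L, 8L),
                       base_mean = 24, base_sd = 2, peptide_sd = 1,
                       line_sd = 0.3, rep_sd = 0.4,
                       detect_mid = 18, detect_scale = 1.5,
                       missingness = TRUE,
                       surface_frac_background = 0.5,
                       membrane_extra_frac = 0.2, seed = 1L) {
  stopifnot(n_proteins >= 1L, base_sd > 0, peptide_sd >= 0, rep_sd >= 0,
            line_sd >= 0, detect_scale > 0,
            surface_frac_background >= 0, surface_frac_background <= 1)
  if (length(target_log2fc) == 1L) {
    target_log2fc <- setNames(rep(target_log2fc, 3L), TUMOR_GROUPS)
  }
  set.seed(seed)
  if (is.null(planted_targets)) {
    n_targets <- min(n_targets, n_proteins)
    planted_targets <- data.frame(
      protein_id = sprintf("TARGET%03d", seq_len(n_targets)),
      base_log2 = rep(target_base_log2, n_targets),
      lfc_FP_RMS = rep(target_log2fc[["FP_RMS"]], n_targets),
      lfc_FN_RMS = rep(target_log2fc[["FN_RMS"]], n_targets),
      lfc_PDX = rep(target_log2fc[["PDX"]], n_targets),
      surface = rep(TRUE, n_targets),
      control_absent = rep(control_absent, n_targets),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(is.finite(as.matrix(
    planted_targets[, c("lfc_FP_RMS", "lfc_FN_RMS", "lfc_PDX")]))))
  n_bg <- n_proteins - nrow(planted_targets)
  if (n_bg < 0L) stop("more planted targets than proteins")
  background <- data.frame(
    protein_id = sprintf("BG%04d", seq_len(n_bg)),
    base_log2 = rnorm(n_bg, base_mean, base_sd),
    lfc_FP_RMS = 0, lfc_FN_RMS = 0, lfc_PDX = 0,
    surface = runif(n_bg) < surface_frac_background,
    control_absent = FALSE, stringsAsFactors = FALSE)
  proteins <- rbind(planted_targets, background)
  proteins$is_target <- c(rep(TRUE, nrow(planted_targets)), rep(FALSE, n_bg))
  structure(
    list(proteins = proteins,
         peptides_per_protein = as.integer(peptides_per_protein),
         base_mean = base_mean, base_sd = base_sd, peptide_sd = peptide_sd,
         line_sd = line_sd, rep_sd = rep_sd,
         detect_mid = detect_mid, detect_scale = detect_scale,
         missingness = missingness,
         membrane_extra_frac = membrane_extra_frac, seed = as.integer(seed)),
    class = "TruthSpec"
  )
}

#' Generate a synthetic peptide panel
#'
#' Draws a peptide-level intensity table for the given design from a
#' [truth_spec()]. Per peptide and sample, the true log2 intensity is
#' `base + group fold change + peptide offset + line effect + replicate
#' noise`; intensities are `2^x` on the linear scale. Detection follows the
#' logistic left-censoring model; planted targets flagged `control_absent`
#' are censored in every control replicate regardless of intensity.
#'
#' @param truth a [truth_spec()].
#' @param design a [sample_design()] (default [default_design()]).
#' @return list with `peptides` (a [peptide_table()], linear scale) and
#'   `truth` (the per-protein truth table with true group means).
#' @export
generate_panel <- function(truth, design = default_design()) {
  stopifnot(inherits(truth, "TruthSpec"))
  set.seed(truth$seed)
  pr <- truth$proteins
  n_pep <- sample(seq(truth$peptides_per_protein[1L],
                      truth$peptides_per_protein[2L]),
                  nrow(pr), replace = TRUE)
  protein_of <- rep(seq_len(nrow(pr)), n_pep)
  n_total <- length(protein_of)
  peptide_id <- sprintf("%s_pep%d", pr$protein_id[protein_of],
                        sequence(n_pep))
  offset <- rnorm(n_total, 0, truth$peptide_sd)

  lines <- unique(design$line_id)
  line_of_sample <- match(design$line_id, lines)
  line_eff <- matrix(rnorm(nrow(pr) * length(lines), 0, truth$line_sd),
                     nrow = nrow(pr))

  shift_of <- function(group) {
    switch(group, FP_RMS = pr$lfc_FP_RMS, FN_RMS = pr$lfc_FN_RMS,
           PDX = pr$lfc_PDX, CONTROL = rep(0, nrow(pr)))
  }
  n_samp <- nrow(design)
  x <- matrix(NA_real_, n_total, n_samp,
              dimnames = list(NULL, design$sample_id))
  for (j in seq_len(n_samp)) {
    shifts <- shift_of(design$group[j])
    x[, j] <- pr$base_log2[protein_of] + shifts[protein_of] + offset +
      line_eff[cbind(protein_of, line_of_sample[j])] +
      rnorm(n_total, 0, truth$rep_sd)
  }
  det <- if (truth$missingness) {
    matrix(runif(length(x)) <
             plogis((x - truth$detect_mid) / truth$detect_scale),
           nrow = n_total, dimnames = dimnames(x))
  } else {
    matrix(TRUE, n_total, n_samp, dimnames = dimnames(x))
  }
  ctrl_cols <- design$group == "CONTROL"
  absent <- pr$control_absent[protein_of]
  det[absent, ctrl_cols] <- FALSE

  intensity <- 2^x
  intensity[!det] <- NA_real_
  pt <- peptide_table(peptide_id, pr$protein_id[protein_of], intensity, det,
                      design, scale = "linear")

  truth_rec <- pr
  for (g in TUMOR_GROUPS) {
    truth_rec[[paste0("true_mean_", g)]] <-
      pr$base_log2 + shift_of(g)
  }
  truth_rec$true_mean_CONTROL <- ifelse(pr$control_absent, NA_real_,
                                        pr$base_log2)
  list(peptides = pt, truth = truth_rec)
}

#' Generate synthetic surface-annotation lists
#'
#' Produces a curated (List-A style) and a comprehensive (List-B style)
#' annotation list from the truth table: the curated list contains exactly
#' the surface-flagged proteins (all planted surface targets included); the
#' comprehensive list is its superset, adding a configurable fraction of
#' the remaining proteins; everything else is excluded from both. Real
#' published lists need not be nested, and no downstream code assumes it.
#'
#' @param truth a [truth_spec()].
#' @return list with [annotation_list()]s `list_a` and `list_b`.
#' @export
generate_annotation_lists <- function(truth) {
  stopifnot(inherits(truth, "TruthSpec"))
  set.seed(truth$seed + 1L)
  pr <- truth$proteins
  a_ids <- pr$protein_id[pr$surface]
  non_surface <- pr$protein_id[!pr$surface]
  extra <- non_surface[runif(length(non_surface)) < truth$membrane_extra_frac]
  list(list_a = annotation_list(a_ids, source = "synthetic_curated"),
       list_b = annotation_list(c(a_ids, extra), source = "synthetic_comprehensive"))
}

#' Generate a synthetic tumor/normal FPKM table
#'
#' Emulates a gene x sample transcript-abundance matrix with fusion-positive
#' and fusion-negative tumor columns and a panel of normal tissues that
#' always includes the five reference control tissues (brain, heart,
#' kidney, liver, lung). Planted targets receive high tumor and low normal
#' FPKM; background genes have tumor expression close to normal.
#'
#' @param truth a [truth_spec()].
#' @param n_fp,n_fn numbers of FP / FN tumor samples (defaults 38 and 60).
#' @param tissues normal tissue names; the five reference control tissues
#'   are always included.
#' @param target_tumor_fpkm,target_normal_fpkm planted target levels.
#' @return list with `fpkm` (matrix), `tumor_cols`, `normal_cols`.
#' @export
generate_fpkm <- function(truth, n_fp = 38L, n_fn = 60L,
                          tissues = c(CONTROL_TISSUES, "CEREBRUM", "SKIN",
                                      "MUSCLE", "COLON", "TESTIS"),
                          target_tumor_fpkm = 600, target_normal_fpkm = 2) {
  stopifnot(inherits(truth, "TruthSpec"))
  set.seed(truth$seed + 2L)
  tissues <- unique(toupper(c(CONTROL_TISSUES, tissues)))
  pr <- truth$proteins
  n_genes <- nrow(pr)
  tumor_cols <- c(sprintf("FP_T%02d", seq_len(n_fp)),
                  sprintf("FN_T%02d", seq_len(n_fn)))
  base <- ifelse(pr$is_target, target_normal_fpkm,
                 rlnorm(n_genes, log(30), 1))
  jitter <- function(n) matrix(runif(n_genes * n, 0.6, 1.4), n_genes)
  normal <- base * jitter(length(tissues))
  tumor_level <- ifelse(pr$is_target, target_tumor_fpkm, base)
  tumor <- tumor_level * jitter(length(tumor_cols))
  m <- cbind(tumor, normal)
  dimnames(m) <- list(pr$protein_id, c(tumor_cols, tissues))
  list(fpkm = m, tumor_cols = tumor_cols, normal_cols = tissues)
}

#' Generate a synthetic clinical cohort
#'
#' Survival times are exponential with hazard proportional to
#' `exp(beta * z)`, where `z` is the standardized log expression;
#' censoring is independent exponential with rate tuned to the requested
#' censoring fraction at `beta = 0`. The IHC table draws staining
#' percentages such that a configurable fraction of alveolar-like
#' (`"ARMS"`) cores have high H-scores while embryonal-like (`"ERMS"`)
#' cores are mostly negative.
#'
#' @param n_patients cohort size (default 147).
#' @param beta log-hazard per SD of log expression.
#' @param censor_rate approximate censoring fraction under the null.
#' @param seed integer seed.
#' @param n_cores number of IHC cores (default 77 evaluable cores).
#' @param frac_arms fraction of alveolar-like cores.
#' @param arms_high_frac fraction of alveolar-like cores with high staining.
#' @param base_hazard baseline event rate per time unit.
#' @return list with `survival` (id, time, event, expression, subtype) and
#'   `ihc` (core_id, pct_strong, pct_medium, pct_weak, subtype) tables.
#' @export
generate_clinical <- function(n_patients = 147L, beta = 1, censor_rate = 0.3,
                              seed = 1L, n_cores = 77L, frac_arms = 0.25,
                              arms_high_frac = 0.85, base_hazard = 0.1) {
  set.seed(seed)
  expression <- rlnorm(n_patients, log(60), 0.9)
  z <- as.numeric(scale(log(expression)))
  t_event <- rexp(n_patients, rate = base_hazard * exp(beta * z))
  cens_rate <- base_hazard * censor_rate / max(1 - censor_rate, 1e-6)
  t_cens <- rexp(n_patients, rate = cens_rate)
  subtype <- sample(c("ARMS", "ERMS"), n_patients, replace = TRUE,
                    prob = c(frac_arms, 1 - frac_arms))
  surv <- data.frame(
    id = sprintf("PT%03d", seq_len(n_patients)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    expression = expression, subtype = subtype,
    stringsAsFactors = FALSE)

  core_subtype <- sample(c("ARMS", "ERMS"), n_cores, replace = TRUE,
                         prob = c(frac_arms, 1 - frac_arms))
  high <- (core_subtype == "ARMS") & (runif(n_cores) < arms_high_frac)
  pct_strong <- ifelse(high, runif(n_cores, 50, 90), runif(n_cores, 0, 5))
  pct_medium <- pmin(ifelse(high, runif(n_cores, 5, 30),
                            runif(n_cores, 0, 10)), 100 - pct_strong)
  pct_weak <- pmin(runif(n_cores, 0, 20), 100 - pct_strong - pct_medium)
  ihc <- data.frame(
    core_id = sprintf("CORE%03d", seq_len(n_cores)),
    pct_strong = pct_strong, pct_medium = pct_medium, pct_weak = pct_weak,
    subtype = core_subtype, stringsAsFactors = FALSE)
  list(survival = surv, ihc = ihc)
}
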
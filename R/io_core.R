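#' Construct and validate a sample design
#'
#' The design table describes one mass-spectrometry run per row: which cell
#' line / PDX / control culture the sample comes from, which biological group
#' that line belongs to, and the replicate index. All downstream stages
#' (imputation replicate groups, detection calls, fold changes, mixed models)
#' are driven by this table.
#'
#' @param sample_id character, unique sample identifiers (one per MS run).
#' @param group character, one of `"FP_RMS"`, `"FN_RMS"`, `"PDX"`, `"CONTROL"`.
#' @param line_id character, the cell line / PDX / control culture name.
#'   Every line must belong to exactly one group.
#' @param replicate positive integer replicate index within a line.
#'
#' @return A `data.frame` of class `"SampleDesign"` with the four columns.
#' @examples
#' sample_design(
#'   sample_id = c("FP1_r1", "FP1_r2", "CTRL_r1"),
#'   group = c("FP_RMS", "FP_RMS", "CONTROL"),
#'   line_id = c("FP1", "FP1", "CTRL"),
#'   replicate = c(1, 2, 1)
#' )
#' @export
sample_design <- function(sample_id, group, line_id, replicate) {
  design <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    line_id = as.character(line_id),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_design(design)
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  required <- c("sample_id", "group", "line_id", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("sample_ids must be unique")
  }
  bad_group <- setdiff(unique(design$group), RMS_GROUPS)
  if (length(bad_group)) {
    stop("unknown group(s): ", paste(bad_group, collapse = ", "),
         " (expected ", paste(RMS_GROUPS, collapse = "/"), ")")
  }
  if (any(design$replicate < 1L) || anyNA(design$replicate)) {
    stop("replicate must be a positive integer")
  }
  # a line must map to exactly one group
  by_line <- tapply(design$group, design$line_id, function(g) length(unique(g)))
  if (any(by_line > 1L)) {
    stop("line_id mapped to more than one group: ",
         paste(names(by_line)[by_line > 1L], collapse = ", "))
  }
  class(design) <- c("SampleDesign", "data.frame")
  design
}

#' Default RMS panel design
#'
#' The panel used throughout the synthetic module: six fusion-positive
#' cell lines, five fusion-negative cell lines, three PDXs and two normal
#' controls (a fibroblast-like and a myoblast-like culture), each measured
#' in triplicate.
#'
#' @param n_replicates replicates per line (default 3).
#' @return A [sample_design()] with `16 * n_replicates` rows.
#' @export
default_design <- function(n_replicates = 3) {
  lines <- c(paste0("FP", 1:6), paste0("FN", 1:5), paste0("PDX", 1:3),
             "CTRL_FIBRO", "CTRL_MYO")
  groups <- c(rep("FP_RMS", 6), rep("FN_RMS", 5), rep("PDX", 3),
              rep("CONTROL", 2))
  line_id <- rep(lines, each = n_replicates)
  group <- rep(groups, each = n_replicates)
  replicate <- rep(seq_len(n_replicates), times = length(lines))
  sample_design(
    sample_id = paste0(line_id, "_r", replicate),
    group = group, line_id = line_id, replicate = replicate
  )
}

#' Read a sample design table
#'
#' @param path TSV file with columns sample_id, group, line_id, replicate.
#' @return A validated [sample_design()].
#' @export
read_design <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(tab)
}

#' Construct a peptide-level intensity table
#'
#' In-memory container for peptide intensities: a peptide x sample matrix on
#' the linear or log2 scale plus a parallel logical matrix recording which
#' cells were actually detected (as opposed to absent on input or imputed
#' later). On disk, absent values are written as 0 (MaxQuant convention);
#' in memory they are `NA` so that no arithmetic can silently use them.
#'
#' @param peptide_id,protein_id character vectors, one entry per row. Each
#'   peptide maps to exactly one protein.
#' @param intensity numeric matrix (peptides x samples); `NA` = absent.
#' @param detected logical matrix, same shape; `FALSE` where absent/imputed.
#' @param design a [sample_design()]; columns of `intensity` must match
#'   `design$sample_id` in order.
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `"PeptideTable"`.
#' @export
peptide_table <- function(peptide_id, protein_id, intensity, detected,
                          design, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(intensity), nrow(intensity) == length(peptide_id),
            length(protein_id) == length(peptide_id))
  if (missing(detected) || is.null(detected)) {
    detected <- !is.na(intensity)
  }
  stopifnot(identical(dim(detected), dim(intensity)))
  if (!identical(colnames(intensity), design$sample_id)) {
    stop("intensity columns must match design sample_ids in order")
  }
  if (scale == "linear" && any(intensity < 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be non-negative")
  }
  rownames(intensity) <- rownames(detected) <- peptide_id
  structure(
    list(peptide_id = as.character(peptide_id),
         protein_id = toupper(as.character(protein_id)),
         intensity = intensity, detected = detected,
         design = design, scale = scale),
    class = "PeptideTable"
  )
}

#' @export
print.PeptideTable <- function(x, ...) {
  cat(sprintf(
    "PeptideTable: %d peptides, %d proteins, %d samples (%s scale), %.1f%% detected\n",
    length(x$peptide_id), length(unique(x$protein_id)), ncol(x$intensity),
    x$scale, 100 * mean(x$detected)
  ))
  invisible(x)
}

#' Read a MaxQuant-style peptide intensity table
#'
#' Expects a TSV with header columns `peptide_id`, `protein_id`, and one
#' intensity column per sample in the design. Zero intensities are recorded
#' as not detected (missing); the column order is realigned to the design.
#'
#' @param path TSV file path.
#' @param design a [sample_design()].
#' @return A [peptide_table()] on the linear scale.
#' @export
read_peptide_table <- function(path, design) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("peptide_id", "protein_id")) {
    if (!col %in% names(tab)) stop("peptide table is missing column: ", col)
  }
  absent <- setdiff(design$sample_id, names(tab))
  if (length(absent)) {
    stop("peptide table is missing sample column(s): ",
         paste(absent, collapse = ", "))
  }
  if (anyDuplicated(tab$peptide_id)) {
    stop("duplicate peptide_id rows: ",
         paste(unique(tab$peptide_id[duplicated(tab$peptide_id)]), collapse = ", "))
  }
  intensity <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(intensity) <- "double"
  if (anyNA(intensity)) stop("peptide intensities must be numeric and non-NA on disk")
  if (any(intensity < 0)) stop("negative intensity values are not allowed")
  detected <- intensity > 0
  intensity[!detected] <- NA_real_
  peptide_table(tab$peptide_id, tab$protein_id, intensity, detected,
                design, scale = "linear")
}

#' Write a peptide table to TSV
#'
#' Absent (NA) cells are written as 0, matching the input convention.
#' @param pt a [peptide_table()].
#' @param path output file.
#' @export
write_peptide_table <- function(pt, path) {
  m <- pt$intensity
  m[is.na(m)] <- 0
  out <- data.frame(peptide_id = pt$peptide_id, protein_id = pt$protein_id,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a validated tabular input
#'
#' One reader for the remaining input formats, dispatched on a schema id:
#' \describe{
#'   \item{`"annotation"`}{one identifier per line (optional second `source`
#'     column); identifiers are upper-cased and de-duplicated with a warning.}
#'   \item{`"fpkm"`}{first column `gene_id`, remaining columns numeric FPKM
#'     values (>= 0), one per tumor sample or normal tissue.}
#'   \item{`"survival"`}{columns `id`, `time` (>= 0), `event` (0/1),
#'     `expression`, optional `subtype`.}
#'   \item{`"ihc"`}{columns `core_id`, `pct_strong`, `pct_medium`,
#'     `pct_weak` in `[0, 100]`, summing to at most 100, optional `subtype`.}
#' }
#'
#' @param path TSV file path.
#' @param schema one of `"annotation"`, `"fpkm"`, `"survival"`, `"ihc"`.
#' @return For `"annotation"`, an [annotation_list()]; otherwise a validated
#'   `data.frame` (for `"fpkm"`, gene x sample with `gene_id` rownames).
#' @export
read_table <- function(path, schema = c("annotation", "fpkm", "survival", "ihc")) {
  schema <- match.arg(schema)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty table: ", path)
  switch(schema,
    annotation = {
      ids <- as.character(tab[[1L]])
      src <- if (ncol(tab) >= 2L) as.character(tab[[2L]][1L]) else
        sub("\\.[^.]+$", "", basename(path))
      annotation_list(ids, source = src)
    },
    fpkm = {
      if (names(tab)[1L] != "gene_id") stop("FPKM table must start with a gene_id column")
      m <- as.matrix(tab[, -1L, drop = FALSE])
      storage.mode(m) <- "double"
      if (anyNA(m)) stop("FPKM values must be numeric")
      if (any(m < 0)) stop("negative FPKM values are not allowed")
      rownames(m) <- toupper(tab$gene_id)
      m
    },
    survival = {
      need <- c("id", "time", "event", "expression")
      miss <- setdiff(need, names(tab))
      if (length(miss)) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
      if (any(tab$time < 0)) stop("survival times must be non-negative")
      if (!all(tab$event %in% c(0, 1))) stop("event must be 0 or 1")
      tab
    },
    ihc = {
      need <- c("core_id", "pct_strong", "pct_medium", "pct_weak")
      miss <- setdiff(need, names(tab))
      if (length(miss)) stop("IHC table missing column(s): ", paste(miss, collapse = ", "))
      pct <- as.matrix(tab[, c("pct_strong", "pct_medium", "pct_weak")])
      if (any(pct < 0) || any(pct > 100)) stop("staining percentages must lie in [0, 100]")
      if (any(rowSums(pct) > 100 + 1e-9)) stop("staining percentages must sum to at most 100 per core")
      tab
    }
  )
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the whole pipeline with validation.
#' Defaults follow the study conditions: down-shift imputation with
#' shift 2.8 and width 0.3 sample-SD units, fixed log2 fold change of 10 for
#' proteins undetected in the controls, selection at average log2FC >= 2 and
#' average moderated t >= 2.132, BH-adjusted alpha 0.05, Top-100 ranking.
#'
#' @param normalization `"median_log2"` (default) or `"vsn_arsinh"`.
#' @param shift,width down-shift imputation parameters (both > 0).
#' @param seed integer seed used for all stochastic stages.
#' @param lfc_threshold,t_threshold selection thresholds on the class-average
#'   log2 fold change and moderated t statistic.
#' @param alpha BH-adjusted significance level in (0, 1).
#' @param top_k number of ranked proteins to report (>= 1).
#' @param absent_control_value fixed log2FC assigned when a protein is not
#'   detected in a control line.
#' @param min_replicates replicates with signal required to call a protein
#'   detected in a line.
#' @param paths optional named list of input file paths (`peptides`,
#'   `design`, `list_a`, `list_b`, `fpkm`, `survival`, `ihc`).
#' @return A list of class `"RunConfig"`.
#' @export
run_config <- function(normalization = c("median_log2", "vsn_arsinh"),
                       shift = 2.8, width = 0.3, seed = 1L,
                       lfc_threshold = 2, t_threshold = 2.132,
                       alpha = 0.05, top_k = 100L,
                       absent_control_value = 10,
                       min_replicates = 2L,
                       paths = list()) {
  normalization <- match.arg(normalization)
  if (shift <= 0) stop("shift must be > 0")
  if (width <= 0) stop("width must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(
    list(normalization = normalization, shift = shift, width = width,
         seed = as.integer(seed), lfc_threshold = lfc_threshold,
         t_threshold = t_threshold, alpha = alpha, top_k = as.integer(top_k),
         absent_control_value = absent_control_value,
         min_replicates = as.integer(min_replicates), paths = paths),
    class = "RunConfig"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#' @param path YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full prioritization pipeline
#'
#' Chains the pipeline stages: normalization, two-stage imputation, iTop3
#' roll-up with detection calls and group fold changes, surface-annotation
#' filtering (List C), Table-1 scoring with Top-K ranking, and the
#' empirical-Bayes per-line statistics with class-level selection. The linear
#' mixed model, being the most expensive stage, is run on the EB-selected
#' proteins by default (set `lmm_proteins = "all"` to run it on the whole
#' filtered set).
#'
#' Inputs may be passed as in-memory objects or read from `config$paths`.
#' All stochastic steps derive from `config$seed`, so a rerun with the same
#' config is reproducible.
#'
#' @param config a [run_config()].
#' @param peptides a [peptide_table()] (or NULL to read `config$paths$peptides`).
#' @param design a [sample_design()] (or NULL to read `config$paths$design`).
#' @param list_a,list_b [annotation_list()]s; `list_a` drives the List-C
#'   filter, `list_b` only the enrichment summary (may be NULL).
#' @param lmm_proteins `"eb_selected"` (default) or `"all"`.
#' @param out_dir optional directory; when given, every stage output is
#'   written there as TSV.
#' @return A list with elements `quant`, `filtered`, `enrichment`,
#'   `scorecards`, `top`, `eb`, `selection`, `lmm` and `config`.
#' @export
run_pipeline <- function(config, peptides = NULL, design = NULL,
                         list_a = NULL, list_b = NULL,
                         lmm_proteins = c("eb_selected", "all"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  lmm_proteins <- match.arg(lmm_proteins)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res
  }

  if (is.null(design)) {
    design <- stage("design", read_design(config$paths$design))
  }
  if (is.null(peptides)) {
    peptides <- stage("peptides", read_peptide_table(config$paths$peptides, design))
  }
  if (is.null(list_a) && !is.null(config$paths$list_a)) {
    list_a <- stage("list_a", read_table(config$paths$list_a, "annotation"))
  }
  if (is.null(list_b) && !is.null(config$paths$list_b)) {
    list_b <- stage("list_b", read_table(config$paths$list_b, "annotation"))
  }
  if (is.null(list_a)) stop("run_pipeline requires a List-A style annotation list")
  if (!any(design$group == "CONTROL")) {
    stop("design must contain at least one CONTROL line")
  }

  message(sprintf("stage normalize: %d peptides x %d samples",
                  length(peptides$peptide_id), nrow(design)))
  norm <- stage("normalize", normalize_peptides(peptides, method = config$normalization))
  imp <- stage("impute", impute_peptides(norm, shift = config$shift,
                                         width = config$width, seed = config$seed))
  quant <- stage("quantify", quantify(imp, raw = peptides,
                                      min_replicates = config$min_replicates,
                                      absent_control_value = config$absent_control_value))
  message(sprintf("stage quantify: %d proteins", length(quant$protein_id)))

  filtered <- stage("filter", filter_surface(quant, list_a))
  message(sprintf("stage filter: %d of %d proteins retained (List C)",
                  length(filtered$protein_id), length(quant$protein_id)))
  enrichment <- if (!is.null(list_b)) {
    enrichment_summary(quant$protein_id, list_a, list_b)
  } else NULL

  scorecards <- stage("score", score_protein(filtered))
  top <- stage("rank", rank_targets(scorecards, top_k = config$top_k))
  message(sprintf("stage rank: top %d of %d scorecards", nrow(top), nrow(scorecards)))

  eb <- stage("stats_eb", eb_stats(filtered))
  selection <- stage("stats_select",
                     eb_select(eb, lfc_threshold = config$lfc_threshold,
                               t_threshold = config$t_threshold))
  lmm_ids <- if (lmm_proteins == "all") filtered$protein_id else
    selection$protein_id[selection$selected_all]
  lmm <- if (length(lmm_ids)) {
    stage("stats_lmm", lmm_stats(filtered, proteins = lmm_ids, alpha = config$alpha))
  } else NULL
  message(sprintf("stage stats: %d EB-selected proteins, LMM on %d",
                  sum(selection$selected_all), length(lmm_ids)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peptide_table(imp, file.path(out_dir, "peptides_imputed.tsv"))
    wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(as.data.frame(quant), "protein_quant.tsv")
    wt(as.data.frame(filtered), "list_c.tsv")
    wt(scorecards, "scorecards.tsv")
    wt(top, "top_ranked.tsv")
    wt(eb, "eb_stats.tsv")
    wt(selection, "eb_selection.tsv")
    if (!is.null(lmm)) wt(lmm, "lmm_stats.tsv")
  }

  list(quant = quant, filtered = filtered, enrichment = enrichment,
       scorecards = scorecards, top = top, eb = eb, selection = selection,
       lmm = lmm, config = config)
}

#' Reproduce list-size and filter counts from deposited supplementary tables
#'
#' Given locally downloaded copies of the deposited quantified-protein table
#' and the two published surface-annotation lists, recomputes the annotation
#' list sizes and the number of quantified proteins retained by the List-A
#' filter. No download is attempted; all three files must be supplied.
#'
#' @param itop3_path TSV of the deposited protein iTop3 table (first column
#'   protein identifiers).
#' @param list_a_path,list_b_path annotation list TSVs.
#' @return list with `n_list_a`, `n_list_b`, `n_quantified`, `n_list_c`.
#' @export
deposited_filter_counts <- function(itop3_path, list_a_path, list_b_path) {
  for (p in c(itop3_path, list_a_path, list_b_path)) {
    if (!file.exists(p)) stop("deposited table not found: ", p)
  }
  list_a <- read_table(list_a_path, "annotation")
  list_b <- read_table(list_b_path, "annotation")
  tab <- read.delim(itop3_path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- unique(toupper(as.character(tab[[1L]])))
  list(n_list_a = length(list_a$ids), n_list_b = length(list_b$ids),
       n_quantified = length(ids), n_list_c = sum(ids %in% list_a$ids))
}
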
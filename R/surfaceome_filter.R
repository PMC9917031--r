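#' Surface-protein annotation list
#'
#' Identifiers are upper-cased and de-duplicated (with a warning) so that
#' matching against quantified proteins is by exact upper-case symbol
#' equality. No alias expansion is attempted: identifiers are expected to be
#' pre-harmonized gene symbols, and mismatches are reported rather than
#' guessed.
#'
#' @param ids character identifiers.
#' @param source short label for provenance (e.g. `"ListA"`).
#' @return An object of class `"AnnotationList"` with elements `ids`, `source`.
#' @export
annotation_list <- function(ids, source = "list") {
  ids <- toupper(as.character(ids))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("annotation list is empty")
  if (anyDuplicated(ids)) {
    warning(sprintf("annotation list '%s': %d duplicate id(s) removed",
                    source, sum(duplicated(ids))))
    ids <- unique(ids)
  }
  structure(list(ids = ids, source = source), class = "AnnotationList")
}

#' @export
print.AnnotationList <- function(x, ...) {
  cat(sprintf("AnnotationList '%s': %d identifiers\n", x$source, length(x$ids)))
  invisible(x)
}

#' Filter quantified proteins against a surface-annotation list
#'
#' Retains exactly the quantified proteins whose identifier appears in the
#' list. Applied with a curated surface-protein list this produces the
#' filtered candidate set ("List C") on which scoring and statistics run.
#' An empty intersection yields an empty result with a warning, not an
#' error.
#'
#' @param quant a [quantify()] result.
#' @param list an [annotation_list()].
#' @return The filtered `ProteinQuant`.
#' @export
filter_surface <- function(quant, list) {
  stopifnot(inherits(quant, "ProteinQuant"), inherits(list, "AnnotationList"))
  keep <- quant$protein_id[quant$protein_id %in% list$ids]
  if (!length(keep)) {
    warning(sprintf("no quantified protein matches list '%s'", list$source))
  }
  message(sprintf("filter_surface: %d of %d proteins in '%s'",
                  length(keep), length(quant$protein_id), list$source))
  subset_proteins(quant, keep)
}

#' Three-way surface-annotation enrichment summary
#'
#' Partitions a set of detected protein identifiers into annotated surface
#' proteins (in list A), additionally predicted membrane proteins (in list B
#' but not A), and background (in neither). Used to compare the surface
#' enrichment achieved by different isolation protocols.
#'
#' @param ids character identifiers of detected proteins.
#' @param list_a,list_b [annotation_list()]s (curated and comprehensive).
#' @return A `data.frame` with one row per category (`in_A`, `in_B_only`,
#'   `in_neither`) and columns `n`, `fraction`. Fractions sum to 1.
#' @export
enrichment_summary <- function(ids, list_a, list_b) {
  ids <- unique(toupper(as.character(ids)))
  in_a <- ids %in% list_a$ids
  in_b_only <- !in_a & ids %in% list_b$ids
  n <- c(in_A = sum(in_a), in_B_only = sum(in_b_only),
         in_neither = sum(!in_a & !in_b_only))
  data.frame(category = names(n), n = as.integer(n),
             fraction = if (length(ids)) as.numeric(n) / length(ids) else
               rep(NA_real_, 3L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-method detection overlap
#'
#' Standard two-set partition of the proteins detected by two isolation
#' methods.
#'
#' @param ids_method1,ids_method2 character identifier vectors.
#' @return Named integer vector `(n1_only, n_shared, n2_only)`.
#' @export
overlap_summary <- function(ids_method1, ids_method2) {
  a <- unique(toupper(as.character(ids_method1)))
  b <- unique(toupper(as.character(ids_method2)))
  c(n1_only = length(setdiff(a, b)),
    n_shared = length(intersect(a, b)),
    n2_only = length(setdiff(b, a)))
}
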
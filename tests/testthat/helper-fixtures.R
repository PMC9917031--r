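# Small reusable fixtures, all built in code.

# Two-line design (one tumor line, one control), n replicates each.
tiny_design <- function(n_reps = 3) {
  sample_design(
    sample_id = c(paste0("FP1_r", seq_len(n_reps)),
                  paste0("CTRL_r", seq_len(n_reps))),
    group = rep(c("FP_RMS", "CONTROL"), each = n_reps),
    line_id = rep(c("FP1", "CTRL"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2)
  )
}

# Peptide table from an explicit linear-scale matrix (0 = absent).
pt_from_matrix <- function(m, protein_id, design,
                           peptide_id = paste0("pep", seq_len(nrow(m)))) {
  colnames(m) <- design$sample_id
  det <- m > 0
  m[!det] <- NA_real_
  peptide_table(peptide_id, protein_id, m, det, design, scale = "linear")
}

# A noise-free panel: every peptide at exactly 2^value per sample group.
# `values` is a list mapping protein -> named group log2 values.
small_panel <- function(n_proteins = 40, n_targets = 4, seed = 42, ...) {
  tr <- truth_spec(n_proteins = n_proteins, n_targets = n_targets,
                   seed = seed, ...)
  generate_panel(tr)
}
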
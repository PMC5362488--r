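# Shared fixtures, built once per test run.

# small simulated study reused across QC / differential / panel tests
small_cfg <- simulation_config(n_proteins = 150, seed = 101)
small_truth <- simulate_catalog(small_cfg)
small_matrix <- simulate_matrix(small_truth, small_cfg)

# a tiny hand-built IntensityMatrix: 4 proteins, one parent BR with one SR
# and one TR, plus a second BR condition partner
tiny_design <- data.frame(
  sample = c("A_BR1", "A_BR2", "A_SR1", "A_TR1"),
  cell_line = "L", treatment = "ctl", timepoint = "8h",
  bio_rep = c(1, 2, 1, 1),
  rep_kind = c("BR", "BR", "SR", "TR"),
  parent_sample = c("A_BR1", "A_BR2", "A_BR1", "A_BR1"),
  stringsAsFactors = FALSE)

tiny_matrix <- function(values) {
  # values: 4 x 4 matrix (proteins x samples), NA allowed
  rownames(values) <- paste0("P", seq_len(nrow(values)))
  colnames(values) <- tiny_design$sample
  intensity_matrix(values, tiny_design)
}

# design table for n BR samples in two groups of three (no SR/TR), used by
# the statistical tests
two_group_design <- function(g1 = 3, g2 = 3) {
  n <- g1 + g2
  data.frame(
    sample = sprintf("S%02d", seq_len(n)),
    cell_line = "L",
    treatment = rep(c("trt", "ctl"), c(g1, g2)),
    timepoint = "8h",
    bio_rep = c(seq_len(g1), seq_len(g2)),
    rep_kind = "BR",
    parent_sample = sprintf("S%02d", seq_len(n)),
    stringsAsFactors = FALSE)
}

matrix_from <- function(x, design, scale = "log2") {
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  colnames(x) <- design$sample
  intensity_matrix(x, design, scale = scale)
}

# path helpers for the bundled published-panel fixtures
hx_annotation_path <- function()
  system.file("extdata", "hx_panel_annotations.tsv", package = "lfq2mrm",
              mustWork = TRUE)
hx_literature_path <- function()
  system.file("extdata", "hx_literature_markers.txt", package = "lfq2mrm",
              mustWork = TRUE)
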
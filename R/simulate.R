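#' Simulation configuration for a replicate-structured LFQ study
#'
#' Captures the design of a three cell line x two treatment x two timepoint
#' discovery experiment with three biological replicates (BR) per condition
#' plus sample-replicate (SR, split before digestion) and technical-replicate
#' (TR, repeated injection after preparation) columns, and the noise /
#' effect-size parameters of the generative model on the log2 scale.
#'
#' Noise is nested: a biological deviate (`sigma_bio`) is shared by a BR
#' column and all of its SR/TR injections; a preparation deviate
#' (`sigma_tech`) is shared by a BR and its TR but redrawn for an SR; an
#' injection deviate (`sigma_inj`) is independent per column. Hence
#' `sigma_bio > sigma_tech >= sigma_inj` is required.
#'
#' Default noise levels (`sigma_bio` 0.5, `sigma_tech` 0.1, `sigma_inj`
#' 0.05 log2 units) put SR coefficients of variation near 10% and TR CVs
#' near 5% with replicate Pearson correlations above 0.98 — the replicate
#' behaviour a well-run label-free experiment exhibits.
#'
#' @param n_proteins number of proteins in the simulated catalog.
#' @param cell_lines character vector of cell-line labels; the *first* is
#'   treated as the androgen-sensitive line when cell-line effects are drawn.
#' @param treatments character vector; the *first* label is the treated arm.
#' @param timepoints character vector of timepoint labels.
#' @param n_bio_reps biological replicates per condition (>= 2).
#' @param n_sr,n_tr number of SR / TR injections attached to the first
#'   biological replicate of each condition.
#' @param frac_de_hx fraction of proteins with a treatment (hypoxia) effect.
#' @param frac_de_as fraction with a cell-line (androgen-sensitivity) effect.
#' @param effect_log2 effect size on the log2 scale.
#' @param sigma_bio,sigma_tech,sigma_inj noise standard deviations (log2).
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param detection_limit log2 intensity below which a value is censored to
#'   missing (set to `-Inf` for complete data).
#' @param frac_missing_random additional completely-at-random missingness.
#' @param frac_secreted,frac_biomarker,frac_exosome,frac_dbmatch,frac_prior
#'   annotation-flag prevalences.
#' @param frac_housekeeping fraction of proteins flagged as housekeeping
#'   (zero treatment and cell-line effects).
#' @param seed integer RNG seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_proteins = 500,
                              cell_lines = c("LNCaP", "Abl", "Hof"),
                              treatments = c("DMOG", "control"),
                              timepoints = c("8h", "24h"),
                              n_bio_reps = 3, n_sr = 1, n_tr = 1,
                              frac_de_hx = 0.05, frac_de_as = 0.10,
                              effect_log2 = 1.5,
                              sigma_bio = 0.5, sigma_tech = 0.1,
                              sigma_inj = 0.05,
                              baseline_mean = 25, baseline_sd = 2,
                              detection_limit = 20,
                              frac_missing_random = 0,
                              frac_secreted = 0.1, frac_biomarker = 0.1,
                              frac_exosome = 0.6, frac_dbmatch = 0.05,
                              frac_prior = 0.02, frac_housekeeping = 0.05,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), cell_lines = cell_lines,
              treatments = treatments, timepoints = timepoints,
              n_bio_reps = as.integer(n_bio_reps), n_sr = as.integer(n_sr),
              n_tr = as.integer(n_tr), frac_de_hx = frac_de_hx,
              frac_de_as = frac_de_as, effect_log2 = effect_log2,
              sigma_bio = sigma_bio, sigma_tech = sigma_tech,
              sigma_inj = sigma_inj, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, detection_limit = detection_limit,
              frac_missing_random = frac_missing_random,
              frac_secreted = frac_secreted, frac_biomarker = frac_biomarker,
              frac_exosome = frac_exosome, frac_dbmatch = frac_dbmatch,
              frac_prior = frac_prior,
              frac_housekeeping = frac_housekeeping, seed = as.integer(seed))
  fracs <- c("frac_de_hx", "frac_de_as", "frac_missing_random",
             "frac_secreted", "frac_biomarker", "frac_exosome",
             "frac_dbmatch", "frac_prior", "frac_housekeeping")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("invalid SimulationConfig field `", f, "`: must be in [0, 1]")
  }
  for (s in c("sigma_bio", "sigma_tech", "sigma_inj")) {
    v <- cfg[[s]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("invalid SimulationConfig field `", s, "`: must be >= 0")
  }
  if (cfg$n_proteins < 1)
    stop("invalid SimulationConfig field `n_proteins`: must be >= 1")
  if (cfg$n_bio_reps < 2)
    stop("invalid SimulationConfig field `n_bio_reps`: must be >= 2")
  if (!is.finite(cfg$effect_log2))
    stop("invalid SimulationConfig field `effect_log2`: must be finite")
  if (!(cfg$sigma_bio >= cfg$sigma_tech && cfg$sigma_tech >= cfg$sigma_inj))
    stop("invalid SimulationConfig field `sigma_bio`: ",
         "requires sigma_bio >= sigma_tech >= sigma_inj")
  class(cfg) <- "SimulationConfig"
  cfg
}

# random protein sequence; K+R boosted to 12% combined so tryptic peptides
# of usable length (7-25) are common
.random_sequence <- function(len) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]   # 18 non-K/R residues
  p <- c(rep(0.88 / 18, 18), 0.06, 0.06)
  paste(sample(c(aa, "K", "R"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Simulate the ground-truth protein catalog
#'
#' Draws, for each protein, a log2 baseline abundance, per-cell-line and
#' treatment effects, annotation flags at the configured prevalences, a
#' housekeeping membership flag (housekeeping proteins have zero effects),
#' a peptide count and a random amino-acid sequence.
#'
#' @param config a [simulation_config()].
#' @return a `GroundTruth` data.frame with one row per protein: `accession`,
#'   `baseline`, `hx_effect` (treatment effect, identical across cell
#'   lines), one `cl_effect_<line>` column per cell line, annotation flag
#'   columns, `housekeeping`, `peptides` and `sequence`; the config is
#'   attached as attribute `config`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_proteins
  acc <- sprintf("SIM%04d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  housekeeping <- stats::runif(n) < config$frac_housekeeping

  hx_de <- stats::runif(n) < config$frac_de_hx & !housekeeping
  hx_effect <- ifelse(hx_de, sample(c(-1, 1), n, replace = TRUE) *
                        config$effect_log2, 0)

  as_de <- stats::runif(n) < config$frac_de_as & !housekeeping
  cl_eff <- matrix(0, n, length(config$cell_lines),
                   dimnames = list(acc, config$cell_lines))
  # androgen-sensitivity effect: the first cell line is offset from the rest
  cl_eff[, 1] <- ifelse(as_de, sample(c(-1, 1), n, replace = TRUE) *
                          config$effect_log2, 0)

  truth <- data.frame(
    accession = acc, baseline = baseline, hx_effect = hx_effect,
    stringsAsFactors = FALSE)
  for (cl in config$cell_lines)
    truth[[paste0("cl_effect_", cl)]] <- cl_eff[, cl]
  truth$prior_evidence <- stats::runif(n) < config$frac_prior
  truth$biomarker_or_drug_target <- stats::runif(n) < config$frac_biomarker
  truth$secreted <- stats::runif(n) < config$frac_secreted
  truth$exosome <- stats::runif(n) < config$frac_exosome
  truth$database_match <- stats::runif(n) < config$frac_dbmatch
  truth$housekeeping <- housekeeping
  truth$peptides <- 2L + stats::rpois(n, 8)
  truth$sequence <- vapply(sample(100:600, n, replace = TRUE),
                           .random_sequence, character(1))
  attr(truth, "config") <- config
  class(truth) <- c("GroundTruth", "data.frame")
  truth
}

# design table for a config: BR columns per condition plus SR/TR injections
# attached to the first biological replicate of each condition
.design_from_config <- function(config) {
  grid <- expand.grid(bio_rep = seq_len(config$n_bio_reps),
                      treatment = config$treatments,
                      cell_line = config$cell_lines,
                      timepoint = config$timepoints,
                      stringsAsFactors = FALSE)
  br <- data.frame(
    sample = sprintf("%s_%s_%s_BR%d", grid$cell_line, grid$treatment,
                     grid$timepoint, grid$bio_rep),
    cell_line = grid$cell_line, treatment = grid$treatment,
    timepoint = grid$timepoint, bio_rep = grid$bio_rep, rep_kind = "BR",
    stringsAsFactors = FALSE)
  br$parent_sample <- br$sample
  extra <- list()
  parents <- br[br$bio_rep == 1L, ]
  for (kind in c("SR", "TR")) {
    n_k <- if (kind == "SR") config$n_sr else config$n_tr
    if (n_k < 1) next
    for (i in seq_len(n_k)) {
      e <- parents
      e$sample <- sub("BR1$", sprintf("%s%d", kind, i), parents$sample)
      e$rep_kind <- kind
      e$parent_sample <- parents$sample
      extra[[paste0(kind, i)]] <- e
    }
  }
  out <- rbind(br, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Simulate the LFQ intensity matrix from a ground-truth catalog
#'
#' Builds the expected log2 intensity of every protein in every sample
#' (baseline + cell-line effect + treatment effect in treated samples),
#' adds nested biological / preparation / injection noise, censors values
#' below the detection limit to missing, and returns linear-scale
#' intensities.
#'
#' @param truth a `GroundTruth` from [simulate_catalog()].
#' @param config the same [simulation_config()]; defaults to the one
#'   attached to `truth`.
#' @return an [intensity_matrix()] on the linear scale.
#' @export
simulate_matrix <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(truth, "GroundTruth"),
            inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  design <- .design_from_config(config)
  n <- nrow(truth)
  treated <- config$treatments[1]

  # expected value per protein x sample
  mu <- matrix(truth$baseline, n, nrow(design),
               dimnames = list(truth$accession, design$sample))
  for (j in seq_len(nrow(design))) {
    cl <- design$cell_line[j]
    mu[, j] <- mu[, j] + truth[[paste0("cl_effect_", cl)]]
    if (design$treatment[j] == treated) mu[, j] <- mu[, j] + truth$hx_effect
  }

  # nested noise: bio per parent BR, prep per digestion, injection per column
  parent_ids <- unique(design$parent_sample)
  bio <- matrix(stats::rnorm(n * length(parent_ids), 0, config$sigma_bio),
                n, length(parent_ids), dimnames = list(NULL, parent_ids))
  # one preparation deviate per BR (shared with its TRs); SRs get their own
  prep_group <- ifelse(design$rep_kind == "SR", design$sample,
                       design$parent_sample)
  prep_ids <- unique(prep_group)
  prep <- matrix(stats::rnorm(n * length(prep_ids), 0, config$sigma_tech),
                 n, length(prep_ids), dimnames = list(NULL, prep_ids))
  inj <- matrix(stats::rnorm(n * nrow(design), 0, config$sigma_inj),
                n, nrow(design))

  log2i <- mu + bio[, design$parent_sample, drop = FALSE] +
    prep[, prep_group, drop = FALSE] + inj
  log2i[log2i < config$detection_limit] <- NA_real_
  if (config$frac_missing_random > 0) {
    drop <- matrix(stats::runif(length(log2i)) < config$frac_missing_random,
                   n, ncol(log2i))
    log2i[drop] <- NA_real_
  }
  intensity_matrix(2^log2i, design, peptides = truth$peptides)
}

#' Write all pipeline input fixtures for a simulated study
#'
#' Serialises a simulated study as the plain-text files the pipeline reads:
#' a MaxQuant-dialect protein-groups TSV (missing intensity encoded as 0,
#' flags marked `+`), the sample design TSV, the annotation-flag TSV, the
#' housekeeping identifier list, a FASTA of protein sequences, a spectral
#' library table, and the ground-truth table itself. A configurable fraction
#' of rows is marked Reverse / Potential contaminant / Only identified by
#' site to exercise the identification filters.
#'
#' @param truth `GroundTruth` from [simulate_catalog()].
#' @param m matching [simulate_matrix()] output.
#' @param out_dir output directory (created if absent).
#' @param frac_flagged fraction of rows to mark with a (randomly chosen)
#'   decoy/contaminant/site flag.
#' @param frac_observed probability that an eligible peptide is marked as
#'   observed in the spectral library table.
#' @param seed RNG seed for flag and library sampling.
#' @return (invisibly) a named character vector of the file paths written.
#' @export
write_fixtures <- function(truth, m, out_dir, frac_flagged = 0.02,
                           frac_observed = 0.6,
                           seed = attr(truth, "config")$seed + 2L) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(m, "IntensityMatrix"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  set.seed(seed)
  n <- nrow(truth)

  flagged <- stats::runif(n) < frac_flagged
  which_flag <- sample(c("Reverse", "Potential contaminant",
                         "Only identified by site"), n, replace = TRUE)
  fmt <- function(x) ifelse(is.na(x), "0", sprintf("%.17g", x))
  pg <- data.frame(`Protein IDs` = truth$accession,
                   Peptides = truth$peptides,
                   Reverse = ifelse(flagged & which_flag == "Reverse", "+", ""),
                   `Potential contaminant` =
                     ifelse(flagged & which_flag == "Potential contaminant",
                            "+", ""),
                   `Only identified by site` =
                     ifelse(flagged & which_flag == "Only identified by site",
                            "+", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (s in samples(m))
    pg[[paste0("LFQ intensity ", s)]] <- fmt(m$intensity[, s])

  paths <- c(protein_groups = file.path(out_dir, "protein_groups.tsv"),
             design = file.path(out_dir, "design.tsv"),
             annotations = file.path(out_dir, "annotations.tsv"),
             housekeeping = file.path(out_dir, "housekeeping.txt"),
             fasta = file.path(out_dir, "proteins.fasta"),
             library = file.path(out_dir, "library.tsv"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  wtsv <- function(d, p) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(pg, paths["protein_groups"])
  wtsv(m$design, paths["design"])

  ann <- data.frame(protein = truth$accession,
                    prior_evidence = as.integer(truth$prior_evidence),
                    biomarker_or_drug_target =
                      as.integer(truth$biomarker_or_drug_target),
                    secreted = as.integer(truth$secreted),
                    exosome = as.integer(truth$exosome),
                    database_match = as.integer(truth$database_match))
  wtsv(ann, paths["annotations"])

  writeLines(truth$accession[truth$housekeeping], paths["housekeeping"])

  seqs <- Biostrings::AAStringSet(truth$sequence)
  names(seqs) <- truth$accession
  Biostrings::writeXStringSet(seqs, paths["fasta"])

  lib <- do.call(rbind, lapply(seq_len(n), function(i) {
    peps <- digest(truth$sequence[i])
    peps <- peps[nchar(peps$peptide) >= 7 & nchar(peps$peptide) <= 25, ]
    if (!nrow(peps)) return(NULL)
    data.frame(protein = truth$accession[i], peptide = peps$peptide,
               observed = as.integer(stats::runif(nrow(peps)) <
                                       frac_observed),
               stringsAsFactors = FALSE)
  }))
  lib$intensity_rank <- stats::ave(seq_len(nrow(lib)), lib$protein,
                                   FUN = function(ix) sample(seq_along(ix)))
  wtsv(lib, paths["library"])

  tt <- truth
  attr(tt, "config") <- NULL
  class(tt) <- "data.frame"
  wtsv(tt, paths["truth"])
  invisible(paths)
}
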
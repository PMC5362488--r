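#' Run the full discovery-to-assay pipeline
#'
#' Executes the whole chain on file inputs: read + identification filters,
#' replicate QC (SR/TR Pearson correlations, biological-replicate overlap,
#' per-protein CVs), log2 transform + left-censored imputation, per cell
#' line treated-vs-control t-tests and per-timepoint cell-line ANOVA, PCA,
#' clustering of significant proteins, CV-gated candidate assembly, additive
#' evidence scoring and panel selection, housekeeping normalizer selection,
#' and MRM transition-list design for both panels. All artifacts are
#' written to `out_dir` as plain text.
#'
#' Statistical contrasts use biological-replicate (BR) columns only; SR/TR
#' injections enter the CV and correlation QC.
#'
#' @param matrix_path protein-groups TSV.
#' @param design_path design TSV.
#' @param annotations_path annotation-flag TSV (optional).
#' @param hk_path housekeeping identifier list (optional; skips normalizer
#'   selection when absent).
#' @param fasta_path protein FASTA (optional; skips MRM design when
#'   absent).
#' @param library_path spectral library TSV (optional).
#' @param out_dir output directory.
#' @param literature accessions of literature hypoxia markers.
#' @param cfg an [analysis_config()].
#' @param rules a [design_rules()].
#' @param cv_max CV gate (%) for panels and normalizers.
#' @param score_threshold panel selection score threshold.
#' @param top_n number of housekeeping normalizers.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the intermediate objects (`matrix`,
#'   `cv`, `ttests`, `anova`, `pca`, `panels`, `housekeeping`, `assays`)
#'   and `files`, the artifact paths.
#' @export
run_pipeline <- function(matrix_path, design_path, annotations_path = NULL,
                         hk_path = NULL, fasta_path = NULL,
                         library_path = NULL, out_dir = ".",
                         literature = character(),
                         cfg = analysis_config(), rules = design_rules(),
                         cv_max = 20, score_threshold = 2, top_n = 17,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.table(as.data.frame(d), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[name]] <<- p
    p
  }

  say("reading protein groups ...")
  m0 <- read_protein_groups(matrix_path, design_path)
  m <- filter_identifications(m0, quiet = quiet)

  say("replicate QC ...")
  qc_sr <- pearson_pairs(m, "SR")
  qc_tr <- pearson_pairs(m, "TR")
  wtsv(rbind(cbind(scope = "SR", qc_sr), cbind(scope = "TR", qc_tr)),
       "qc_pearson.tsv")
  d <- m$design
  br <- d[d$rep_kind == "BR", ]
  conds <- unique(br[, c("cell_line", "treatment", "timepoint")])
  ov <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    g <- br$sample[br$cell_line == conds$cell_line[i] &
                     br$treatment == conds$treatment[i] &
                     br$timepoint == conds$timepoint[i]]
    if (length(g) < 2) return(NULL)
    data.frame(conds[i, ], overlap_pct = replicate_overlap(m, g)$overlap_pct)
  }))
  wtsv(ov, "qc_overlap.tsv")
  cv <- compute_cv(m)
  wtsv(cv, "qc_cv.tsv")

  say("differential analysis ...")
  ml <- impute_constant(log2_transform(m), cfg)
  ttests <- list()
  for (cl in unique(br$cell_line)) for (tp in unique(br$timepoint)) {
    trt <- unique(br$treatment)
    ga <- br$sample[br$cell_line == cl & br$timepoint == tp &
                      br$treatment == trt[1]]
    gb <- br$sample[br$cell_line == cl & br$timepoint == tp &
                      br$treatment == trt[2]]
    if (length(ga) < 2 || length(gb) < 2) next
    lab <- sprintf("%s %s %s vs %s", cl, tp, trt[1], trt[2])
    ttests[[lab]] <- ttest_contrast(ml, ga, gb, cfg, contrast = lab)
  }
  anovas <- list()
  for (tp in unique(br$timepoint)) {
    grp <- split(br$sample[br$timepoint == tp],
                 br$cell_line[br$timepoint == tp])
    if (length(grp) < 2 || any(lengths(grp) < 2)) next
    a <- anova_all_groups(ml, grp, cfg)
    a$contrast <- sprintf("ANOVA %s cell lines", tp)
    anovas[[tp]] <- a
  }
  all_diff <- do.call(rbind, c(lapply(ttests, function(x)
    x[, c("protein", "contrast", "estimate", "p_value", "p_adjusted",
          "significant")]),
    lapply(anovas, function(x)
      x[, c("protein", "contrast", "estimate", "p_value", "p_adjusted",
            "significant")])))
  wtsv(all_diff, "differential.tsv")

  pca <- pca_samples(ml)
  wtsv(data.frame(sample = rownames(pca$scores),
                  pca$scores[, seq_len(min(5, ncol(pca$scores)))]),
       "pca_scores.tsv")

  sig <- unique(all_diff$protein[all_diff$significant])
  if (length(sig) >= 2) {
    cl_tree <- cluster_significant(ml, sig, cfg)
    p <- file.path(out_dir, "significant_clusters.nwk")
    writeLines(cl_tree$newick, p)
    files[["significant_clusters.nwk"]] <- p
  }

  say("panel assembly ...")
  annotations <- if (!is.null(annotations_path))
    utils::read.delim(annotations_path, stringsAsFactors = FALSE) else NULL
  hx_cand <- assemble_candidates(ttests, cv, "Hx", cv_max)
  hx_panel <- select_panel(hx_cand, annotations, literature,
                           score_threshold)
  as_cand <- assemble_candidates(anovas, cv, "AS", cv_max)
  as_panel <- select_panel(as_cand, annotations, character(),
                           score_threshold)
  wtsv(hx_panel, "panel_hx.tsv")
  wtsv(as_panel, "panel_as.tsv")

  hk <- NULL
  if (!is.null(hk_path)) {
    say("housekeeping normalizer selection ...")
    hk <- tryCatch(select_housekeeping(m, hk_path, cv, cv_max, top_n),
                   error = function(e) {
                     say("normalizer selection skipped: ",
                         conditionMessage(e))
                     NULL
                   })
    if (!is.null(hk)) {
      wtsv(hk$table, "housekeeping_selection.tsv")
      wtsv(data.frame(sample = names(hk$factors), factor = hk$factors),
           "normalization_factors.tsv")
    }
  }

  assays <- list()
  if (!is.null(fasta_path)) {
    say("MRM assay design ...")
    fasta <- read_fasta(fasta_path)
    library <- if (!is.null(library_path))
      utils::read.delim(library_path, stringsAsFactors = FALSE) else NULL
    for (kind in c("Hx", "AS")) {
      panel <- if (kind == "Hx") hx_panel else as_panel
      sel <- panel$protein[panel$selected]
      if (!length(sel)) next
      assay <- design_assay(sel, fasta, library, rules)
      assays[[kind]] <- assay
      p <- file.path(out_dir,
                     sprintf("transitions_%s.csv", tolower(kind)))
      write_transition_list(assay$transitions, p)
      files[[basename(p)]] <- p
      if (nrow(assay$failures))
        wtsv(assay$failures, sprintf("design_failures_%s.tsv",
                                     tolower(kind)))
    }
  }
  say("done.")
  invisible(list(matrix = ml, raw = m, cv = cv, ttests = ttests,
                 anova = anovas, pca = pca,
                 panels = list(Hx = hx_panel, AS = as_panel),
                 housekeeping = hk, assays = assays, files = files))
}

#' Command line interface
#'
#' Subcommand dispatcher used by the `lfq2mrm` script in `inst/exec`:
#' `simulate`, `qc`, `diff`, `panel`, `normalizers`, `mrm` and `pipeline`.
#' Options are `--key value` pairs; run with no arguments for usage.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lfq2mrm <command> [--key value ...]",
    "  simulate     --out DIR [--n-proteins N] [--seed N]",
    "  qc           --matrix TSV --design TSV --out DIR",
    "  diff         --matrix TSV --design TSV --out DIR",
    "  panel        --kind hx|as --matrix TSV --design TSV",
    "               [--annotations TSV] [--literature TXT] --out DIR",
    "  normalizers  --matrix TSV --design TSV --hk-list TXT --out DIR",
    "  mrm          --panel TSV --fasta FA [--library TSV] --out CSV",
    "  pipeline     --matrix TSV --design TSV [--annotations TSV]",
    "               [--hk-list TXT] [--fasta FA] [--library TSV] --out DIR",
    sep = "\n")
  if (!length(args)) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--"))
      stop("unexpected argument: ", rest[i])
    key <- sub("^--", "", rest[i])
    opts[[gsub("-", "_", key)]] <- rest[i + 1]
    i <- i + 2
  }
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required option --",
                                 gsub("_", "-", k))
    opts[[k]]
  }
  num <- function(k, default) if (is.null(opts[[k]])) default
  else as.numeric(opts[[k]])

  switch(cmd,
    simulate = {
      cfg <- simulation_config(n_proteins = num("n_proteins", 500),
                               seed = num("seed", 1))
      truth <- simulate_catalog(cfg)
      paths <- write_fixtures(truth, simulate_matrix(truth, cfg),
                              need("out"))
      message("wrote: ", paste(basename(paths), collapse = ", "))
    },
    qc = {
      m <- filter_identifications(
        read_protein_groups(need("matrix"), need("design")))
      out <- need("out")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(rbind(cbind(scope = "SR", pearson_pairs(m, "SR")),
                               cbind(scope = "TR", pearson_pairs(m, "TR"))),
                         file.path(out, "qc_pearson.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(compute_cv(m), file.path(out, "qc_cv.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    diff = ,
    panel = ,
    normalizers = ,
    pipeline = {
      res <- run_pipeline(need("matrix"), need("design"),
                          annotations_path = opts$annotations,
                          hk_path = opts$hk_list,
                          fasta_path = opts$fasta,
                          library_path = opts$library,
                          out_dir = need("out"),
                          literature = if (!is.null(opts$literature))
                            readLines(opts$literature) else character())
      message("artifacts: ", paste(basename(res$files), collapse = ", "))
    },
    mrm = {
      panel <- utils::read.delim(need("panel"),
                                 stringsAsFactors = FALSE)
      library <- if (!is.null(opts$library))
        utils::read.delim(opts$library, stringsAsFactors = FALSE) else NULL
      assay <- design_assay(panel, need("fasta"), library)
      write_transition_list(assay$transitions, need("out"))
      message(nrow(assay$transitions), " transitions written")
    },
    {
      cat(usage, "\n")
      return(invisible(1L))
    })
  invisible(0L)
}
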
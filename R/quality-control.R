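#' Read a MaxQuant-style protein-groups table with its sample design
#'
#' Parses a tab-separated protein-groups file in the MaxQuant dialect:
#' per-sample columns named `LFQ intensity <sample>`, `+`-marked flag
#' columns `Reverse`, `Potential contaminant` and `Only identified by
#' site`, a `Peptides` count column and a `Protein IDs` accession column.
#' A zero intensity encodes a missing measurement and becomes `NA`.
#'
#' @param path protein-groups TSV.
#' @param design_path design TSV with columns `sample`, `cell_line`,
#'   `treatment`, `timepoint`, `bio_rep`, `rep_kind`, `parent_sample`.
#' @return an [intensity_matrix()] on the linear scale, protein order as in
#'   the file.
#' @export
read_protein_groups <- function(path, design_path) {
  pg <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(pg)) stop("no `Protein IDs` column in ", path)
  if (anyDuplicated(pg[["Protein IDs"]]))
    stop("duplicate accession(s): ",
         paste(unique(pg[["Protein IDs"]][duplicated(pg[["Protein IDs"]])]),
               collapse = ", "))
  lfq_cols <- grep("^LFQ intensity ", names(pg), value = TRUE)
  if (!length(lfq_cols)) stop("no `LFQ intensity` columns in ", path)
  snames <- sub("^LFQ intensity ", "", lfq_cols)
  unmatched <- setdiff(snames, design$sample)
  if (length(unmatched))
    stop("LFQ column(s) absent from design: ",
         paste(unmatched, collapse = ", "))
  intensity <- as.matrix(pg[, lfq_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  intensity[intensity == 0] <- NA_real_
  dimnames(intensity) <- list(pg[["Protein IDs"]], snames)
  getflag <- function(col) {
    if (!col %in% names(pg)) return(logical(nrow(pg)))
    v <- as.character(pg[[col]])
    v[is.na(v)] <- ""          # an all-empty column parses as logical NA
    trimws(v) == "+"
  }
  flags <- data.frame(reverse = getflag("Reverse"),
                      contaminant = getflag("Potential contaminant"),
                      only_by_site = getflag("Only identified by site"))
  peptides <- if ("Peptides" %in% names(pg)) pg$Peptides else rep(2L, nrow(pg))
  intensity_matrix(intensity, design, peptides = peptides, flags = flags)
}

#' Apply the standard identification filters
#'
#' Removes reverse-database hits, potential contaminants, proteins only
#' identified by a modification site, and proteins identified by fewer than
#' `min_peptides` peptides. Removal counts per reason are attached as
#' attribute `filter_log` and reported via `message()`.
#'
#' @param m an [intensity_matrix()].
#' @param min_peptides minimum peptide count to retain a protein.
#' @param quiet suppress the log message.
#' @return the filtered `IntensityMatrix`.
#' @export
filter_identifications <- function(m, min_peptides = 2, quiet = FALSE) {
  stopifnot(inherits(m, "IntensityMatrix"))
  log <- c(reverse = sum(m$flags$reverse),
           contaminant = sum(m$flags$contaminant),
           only_by_site = sum(m$flags$only_by_site),
           few_peptides = sum(m$peptides < min_peptides))
  keep <- !(m$flags$reverse | m$flags$contaminant | m$flags$only_by_site |
              m$peptides < min_peptides)
  out <- m[keep, ]
  attr(out, "filter_log") <- log
  if (!quiet)
    message(sprintf(
      "filter_identifications: kept %d/%d (reverse %d, contaminant %d, only-by-site %d, <%d peptides %d)",
      sum(keep), length(keep), log[1], log[2], log[3], min_peptides, log[4]))
  out
}

# log2 of the intensity matrix regardless of stored scale
.log2_values <- function(m) {
  if (m$scale == "log2") m$intensity else log2(m$intensity)
}

#' Pairwise Pearson correlations between replicate columns
#'
#' Correlations are computed on log2 intensities over the proteins present
#' (non-missing) in both members of a pair. For `scope = "SR"` / `"TR"`
#' each replicate injection is paired with its parent biological-replicate
#' column; for `scope = "BR"` all pairs of biological replicates sharing a
#' design condition (cell line, treatment, timepoint) are compared. Pairs
#' with fewer than 3 shared proteins get `NA`.
#'
#' @param m an [intensity_matrix()].
#' @param scope `"SR"`, `"TR"` or `"BR"`.
#' @return data.frame with columns `sample1`, `sample2`, `r`, `n_shared`.
#' @export
pearson_pairs <- function(m, scope = c("SR", "TR", "BR")) {
  scope <- match.arg(scope)
  d <- m$design
  if (scope %in% c("SR", "TR")) {
    reps <- d[d$rep_kind == scope, , drop = FALSE]
    if (nrow(reps) < 1)
      stop("scope `", scope, "` selects < 2 samples: no ", scope,
           " rows in the design")
    pairs <- data.frame(sample1 = reps$parent_sample, sample2 = reps$sample,
                        stringsAsFactors = FALSE)
  } else {
    br <- d[d$rep_kind == "BR", , drop = FALSE]
    key <- interaction(br$cell_line, br$treatment, br$timepoint, drop = TRUE)
    pairs <- do.call(rbind, lapply(split(br$sample, key), function(s) {
      if (length(s) < 2) return(NULL)
      cmb <- utils::combn(sort(s), 2)
      data.frame(sample1 = cmb[1, ], sample2 = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs) || nrow(pairs) < 1)
      stop("scope `BR` selects < 2 samples per condition")
    rownames(pairs) <- NULL
  }
  x <- .log2_values(m)
  res <- t(apply(pairs, 1, function(p) {
    a <- x[, p[[1]]]; b <- x[, p[[2]]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) c(NA_real_, sum(ok))
    else c(stats::cor(a[ok], b[ok]), sum(ok))
  }))
  data.frame(pairs, r = res[, 1], n_shared = as.integer(res[, 2]))
}

#' Identification overlap across a biological-replicate group
#'
#' A protein counts as identified in a sample when its intensity is
#' present. The group overlap is the Jaccard index of the identified sets,
#' `100 * |intersection| / |union|`; all pairwise Jaccard values are
#' returned alongside.
#'
#' @param m an [intensity_matrix()].
#' @param group character vector (>= 2) of sample identifiers.
#' @return list with `overlap_pct` (scalar, `NA` when the union is empty)
#'   and `pairwise`, a data.frame of per-pair Jaccard percentages.
#' @export
replicate_overlap <- function(m, group) {
  stopifnot(inherits(m, "IntensityMatrix"))
  group <- as.character(group)
  if (length(group) < 2) stop("`group` must name >= 2 samples")
  missing_s <- setdiff(group, samples(m))
  if (length(missing_s))
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  sets <- lapply(group, function(s) proteins(m)[!is.na(m$intensity[, s])])
  names(sets) <- group
  un <- Reduce(union, sets)
  overlap <- if (!length(un)) NA_real_ else
    100 * length(Reduce(intersect, sets)) / length(un)
  cmb <- utils::combn(group, 2)
  pw <- apply(cmb, 2, function(p) {
    u <- union(sets[[p[1]]], sets[[p[2]]])
    if (!length(u)) NA_real_ else
      100 * length(intersect(sets[[p[1]]], sets[[p[2]]])) / length(u)
  })
  list(overlap_pct = overlap,
       pairwise = data.frame(sample1 = cmb[1, ], sample2 = cmb[2, ],
                             jaccard_pct = pw))
}

#' Per-protein replicate coefficients of variation
#'
#' For every protein, the CV% (100 * sd / mean, n-1 standard deviation) of
#' its intensities over each replicate group — a parent biological-replicate
#' column together with its SR injections, or together with its TR
#' injections. Missing values are excluded; a group contributes only when
#' >= 2 values remain; when several parents carry replicate injections the
#' per-group CVs are summarised by their median. CVs are computed on linear
#' intensities by default (`scale = "log2"` switches to log-scale values).
#'
#' @param m an [intensity_matrix()].
#' @param scale `"linear"` (default) or `"log2"`.
#' @return a `CvTable` data.frame: `protein`, `cv_sr`, `cv_tr` (%, `NA`
#'   when undefined), `n_sr`, `n_tr` (measurements used).
#' @export
compute_cv <- function(m, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(inherits(m, "IntensityMatrix"))
  d <- m$design
  x <- if (scale == "linear") {
    if (m$scale == "linear") m$intensity else 2^m$intensity
  } else .log2_values(m)

  one_kind <- function(kind) {
    reps <- d[d$rep_kind == kind, , drop = FALSE]
    if (!nrow(reps))
      stop("no ", kind, " columns: the design needs rows with rep_kind = ",
           kind, " and a parent_sample")
    groups <- split(reps$sample, reps$parent_sample)
    cv_mat <- matrix(NA_real_, nrow(x), length(groups))
    n_mat <- matrix(0L, nrow(x), length(groups))
    for (g in seq_along(groups)) {
      v <- x[, c(names(groups)[g], groups[[g]]), drop = FALSE]
      cnt <- rowSums(!is.na(v))
      mu <- rowMeans(v, na.rm = TRUE)
      sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
      cv_mat[, g] <- ifelse(cnt >= 2, 100 * sdv / mu, NA_real_)
      n_mat[, g] <- ifelse(cnt >= 2, cnt, 0L)
    }
    cv <- apply(cv_mat, 1, function(row)
      if (all(is.na(row))) NA_real_ else stats::median(row, na.rm = TRUE))
    list(cv = cv, n = as.integer(rowSums(n_mat)))
  }
  sr <- one_kind("SR")
  tr <- one_kind("TR")
  out <- data.frame(protein = proteins(m), cv_sr = sr$cv, cv_tr = tr$cv,
                    n_sr = sr$n, n_tr = tr$n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CvTable", "data.frame")
  out
}
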
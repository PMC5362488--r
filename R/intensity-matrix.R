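#' Intensity matrix with sample design metadata
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' label-free quantification (LFQ) intensities plus per-sample design
#' metadata and per-protein identification metadata. Intensities are stored
#' on the linear scale by default (`scale = "linear"`); missing measurements
#' are `NA`. [log2_transform()] switches the scale flag to `"log2"`.
#'
#' @param intensity numeric matrix, proteins in rows (unique rownames =
#'   accessions), samples in columns (colnames = sample identifiers).
#'   Missing values are `NA`; present values must be non-negative on the
#'   linear scale.
#' @param design data.frame with one row per sample and columns `sample`,
#'   `cell_line`, `treatment`, `timepoint`, `bio_rep`, `rep_kind` (one of
#'   `"BR"`, `"SR"`, `"TR"`) and `parent_sample` (the biological-replicate
#'   column an SR/TR injection duplicates; equal to `sample` for BR rows).
#' @param peptides integer vector of peptide counts per protein (same order
#'   as rows). Defaults to 2 for every protein.
#' @param flags data.frame of per-protein logical columns `reverse`,
#'   `contaminant`, `only_by_site`. Defaults to all `FALSE`.
#' @param scale `"linear"` or `"log2"`.
#'
#' @return An object of class `IntensityMatrix`: a list with elements
#'   `intensity`, `design`, `peptides`, `flags`, `scale` and (after
#'   imputation) `mask`, the logical presence matrix.
#' @export
intensity_matrix <- function(intensity, design, peptides = NULL,
                             flags = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("`intensity` must have unique rownames (protein accessions)")
  if (is.null(colnames(intensity)))
    stop("`intensity` must have colnames (sample identifiers)")
  if (scale == "linear" && any(intensity < 0, na.rm = TRUE))
    stop("linear intensities must be >= 0 where present")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample", "cell_line", "treatment", "timepoint", "bio_rep",
              "rep_kind", "parent_sample")
  miss <- setdiff(needed, names(design))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  unmatched <- setdiff(colnames(intensity), design$sample)
  if (length(unmatched))
    stop("sample column(s) absent from design: ",
         paste(unmatched, collapse = ", "))
  design <- design[match(colnames(intensity), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (!all(design$rep_kind %in% c("BR", "SR", "TR")))
    stop("rep_kind must be one of BR, SR, TR")
  n <- nrow(intensity)
  if (is.null(peptides)) peptides <- rep(2L, n)
  if (length(peptides) != n) stop("`peptides` length must equal nrow")
  if (is.null(flags))
    flags <- data.frame(reverse = logical(n), contaminant = logical(n),
                        only_by_site = logical(n))
  flags <- as.data.frame(flags)
  for (f in c("reverse", "contaminant", "only_by_site")) {
    if (is.null(flags[[f]])) stop("flags table lacks column ", f)
    flags[[f]] <- as.logical(flags[[f]])
  }
  structure(list(intensity = intensity, design = design,
                 peptides = as.integer(peptides),
                 flags = flags[, c("reverse", "contaminant", "only_by_site")],
                 scale = scale, mask = NULL),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$intensity), ncol(x$intensity), x$scale))
  cat(sprintf("  rep_kind: %s\n",
              paste(sprintf("%s=%d", names(table(x$design$rep_kind)),
                            table(x$design$rep_kind)), collapse = " ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$intensity)

#' Subset an IntensityMatrix by proteins and/or samples
#'
#' @param x an `IntensityMatrix`.
#' @param i protein index (row selector).
#' @param j sample index (column selector).
#' @param ... ignored.
#' @return an `IntensityMatrix` restricted to the selection.
#' @export
`[.IntensityMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensity))
  if (missing(j)) j <- seq_len(ncol(x$intensity))
  out <- x
  out$intensity <- x$intensity[i, j, drop = FALSE]
  out$design <- x$design[match(colnames(out$intensity), x$design$sample), ,
                         drop = FALSE]
  rownames(out$design) <- NULL
  ridx <- match(rownames(out$intensity), rownames(x$intensity))
  out$peptides <- x$peptides[ridx]
  out$flags <- x$flags[ridx, , drop = FALSE]
  rownames(out$flags) <- NULL
  if (!is.null(x$mask)) out$mask <- x$mask[i, j, drop = FALSE]
  out
}

#' Protein accessions of an IntensityMatrix
#' @param x an `IntensityMatrix`.
#' @return character vector of accessions.
#' @export
proteins <- function(x) rownames(x$intensity)

#' Sample identifiers of an IntensityMatrix
#' @param x an `IntensityMatrix`.
#' @return character vector of sample names.
#' @export
samples <- function(x) colnames(x$intensity)
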
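#' Configuration of the differential-analysis layer
#'
#' @param alpha significance level for t-tests and ANOVA (default 0.05).
#' @param imputation_offset log2 downshift below the global minimum used by
#'   [impute_constant()] (default 1.0).
#' @param lsd_alpha level of the Fisher least-significant-difference
#'   critical value attached to the ANOVA (default 0.05).
#' @param linkage agglomeration method for [cluster_significant()]
#'   (default `"average"`).
#' @param welch use Welch's unequal-variance t-test instead of the
#'   equal-variance Student's t-test.
#' @param per_sample_impute impute with a per-sample minimum instead of the
#'   global minimum.
#' @param p_adjust method passed to [stats::p.adjust()] for the adjusted
#'   p-value column reported alongside raw p-values (default `"BH"`;
#'   significance calls always use the raw p-value).
#' @return list of class `AnalysisConfig`.
#' @export
analysis_config <- function(alpha = 0.05, imputation_offset = 1.0,
                            lsd_alpha = 0.05, linkage = "average",
                            welch = FALSE, per_sample_impute = FALSE,
                            p_adjust = "BH") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  if (!is.numeric(imputation_offset) || imputation_offset < 0)
    stop("`imputation_offset` must be >= 0")
  if (!is.numeric(lsd_alpha) || lsd_alpha <= 0 || lsd_alpha >= 1)
    stop("`lsd_alpha` must be in (0, 1)")
  structure(list(alpha = alpha, imputation_offset = imputation_offset,
                 lsd_alpha = lsd_alpha, linkage = linkage, welch = welch,
                 per_sample_impute = per_sample_impute,
                 p_adjust = p_adjust),
            class = "AnalysisConfig")
}

#' Log2-transform an intensity matrix
#'
#' Present values are replaced by their log2; missing values stay missing.
#'
#' @param m an [intensity_matrix()] on the linear scale.
#' @return the matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale == "log2") return(m)
  m$intensity <- log2(m$intensity)
  m$scale <- "log2"
  m
}

#' Impute missing values with a constant below the observed minimum
#'
#' Every missing cell is set to the global minimum observed log2 intensity
#' minus `cfg$imputation_offset`, a left-censored convention that lets
#' downstream tests treat absence as low abundance. The presence/absence
#' mask is retained in the `mask` element.
#'
#' @param m an [intensity_matrix()] on the log2 scale.
#' @param cfg an [analysis_config()].
#' @return the imputed matrix (complete, with `mask` set).
#' @export
impute_constant <- function(m, cfg = analysis_config()) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("impute_constant expects a log2-scale matrix")
  if (all(is.na(m$intensity)))
    stop("matrix is fully missing: no observed minimum to impute from")
  m$mask <- !is.na(m$intensity)
  if (cfg$per_sample_impute) {
    for (j in seq_len(ncol(m$intensity))) {
      col <- m$intensity[, j]
      fill <- if (all(is.na(col))) min(m$intensity, na.rm = TRUE)
      else min(col, na.rm = TRUE)
      m$intensity[is.na(col), j] <- fill - cfg$imputation_offset
    }
  } else {
    fill <- min(m$intensity, na.rm = TRUE) - cfg$imputation_offset
    m$intensity[is.na(m$intensity)] <- fill
  }
  m
}

# vectorised two-sample t-test over matrix rows; equal-variance by default.
# zero pooled variance: equal means -> p = 1, unequal -> p = 0.
.row_ttest <- function(a, b, welch = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  est <- ma - mb
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(est))
  }
  tt <- est / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero & est == 0] <- 1
  p[zero & est != 0] <- 0
  list(estimate = est, t = tt, p = p, df = df)
}

#' Per-protein two-sample t-test between two sample groups
#'
#' Two-sided Student's t-test (equal variance unless `cfg$welch`) on the
#' imputed log2 matrix; the estimate is `mean(groupA) - mean(groupB)`.
#' With zero pooled variance the convention is p = 1 for equal means and
#' p = 0 otherwise.
#'
#' @param m imputed log2 [intensity_matrix()].
#' @param groupA,groupB disjoint character vectors of sample identifiers,
#'   each of length >= 2.
#' @param cfg an [analysis_config()].
#' @param contrast label recorded in the result (default built from the
#'   group names).
#' @return a `DifferentialResult` data.frame: `protein`, `contrast`,
#'   `estimate`, `p_value`, `p_adjusted`, `significant`.
#' @export
ttest_contrast <- function(m, groupA, groupB, cfg = analysis_config(),
                           contrast = NULL) {
  stopifnot(inherits(m, "IntensityMatrix"))
  groupA <- as.character(groupA); groupB <- as.character(groupB)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ",
         paste(intersect(groupA, groupB), collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 samples")
  bad <- setdiff(c(groupA, groupB), samples(m))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  x <- .log2_values(m)
  if (anyNA(x[, c(groupA, groupB)]))
    stop("matrix contains missing values; impute first")
  res <- .row_ttest(x[, groupA, drop = FALSE], x[, groupB, drop = FALSE],
                    welch = cfg$welch)
  if (is.null(contrast))
    contrast <- paste0(paste(groupA, collapse = "+"), " vs ",
                       paste(groupB, collapse = "+"))
  out <- data.frame(protein = proteins(m), contrast = contrast,
                    estimate = res$estimate, p_value = res$p,
                    p_adjusted = stats::p.adjust(res$p, cfg$p_adjust),
                    significant = res$p <= cfg$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' Per-protein one-way ANOVA across a partition of samples
#'
#' Fixed-effects one-way ANOVA per protein over all groups, plus a single
#' study-level *critical difference*: the Fisher least-significant
#' difference on the log2 scale,
#' `t(1 - lsd_alpha/2, df_within) * sqrt(2 * MS_within / n)`, computed from
#' the median within-group mean square across proteins and the harmonic
#' mean group size. It is the minimum absolute log2 difference between two
#' group means that the LSD rule declares significant, and is recomputed
#' from each dataset.
#'
#' @param m imputed log2 [intensity_matrix()].
#' @param groups named list of sample-identifier vectors (>= 2 groups,
#'   each >= 2 samples) partitioning the samples of interest.
#' @param cfg an [analysis_config()].
#' @return a `DifferentialResult` data.frame with columns `protein`,
#'   `contrast`, `estimate` (max minus min group mean), `p_value`,
#'   `p_adjusted`, `significant` and `critical_difference` (constant
#'   column; also attached as an attribute).
#' @export
anova_all_groups <- function(m, groups, cfg = analysis_config()) {
  stopifnot(inherits(m, "IntensityMatrix"), is.list(groups))
  if (length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 samples")
  all_s <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_s)) stop("groups overlap")
  bad <- setdiff(all_s, samples(m))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  x <- .log2_values(m)[, all_s, drop = FALSE]
  if (anyNA(x)) stop("matrix contains missing values; impute first")

  k <- length(groups)
  n_tot <- length(all_s)
  gmeans <- vapply(groups, function(s)
    rowMeans(x[, s, drop = FALSE]), numeric(nrow(x)))
  if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = 1)
  grand <- rowMeans(x)
  ss_between <- as.vector(gmeans^2 %*% sizes) - n_tot * grand^2
  ss_total <- rowSums(x^2) - n_tot * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  df_b <- k - 1
  df_w <- n_tot - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- ms_b / ms_w
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  zero <- ms_w == 0
  p[zero & ss_between <= .Machine$double.eps^0.5] <- 1
  p[zero & ss_between > .Machine$double.eps^0.5] <- 0

  n_harm <- k / sum(1 / sizes)
  crit <- stats::qt(1 - cfg$lsd_alpha / 2, df_w) *
    sqrt(2 * stats::median(ms_w) / n_harm)

  est <- apply(gmeans, 1, max) - apply(gmeans, 1, min)
  out <- data.frame(protein = proteins(m),
                    contrast = paste("ANOVA:",
                                     paste(names(groups), collapse = "|")),
                    estimate = est, p_value = p,
                    p_adjusted = stats::p.adjust(p, cfg$p_adjust),
                    significant = p <= cfg$alpha,
                    critical_difference = crit,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "critical_difference") <- crit
  attr(out, "F") <- unname(f)
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' Principal component analysis of the samples
#'
#' Samples are projected on the principal components of the protein-wise
#' mean-centred (not variance-scaled) log2 matrix.
#'
#' @param m imputed log2 [intensity_matrix()].
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components) and `explained` (variance fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_samples <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  x <- .log2_values(m)
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained = expl)
}

#' Hierarchical clustering of significant proteins
#'
#' Each selected protein profile is z-scored across samples, Euclidean
#' distances are computed and agglomerative clustering with the configured
#' linkage applied. The tree is returned together with its Newick
#' serialisation.
#'
#' @param m imputed log2 [intensity_matrix()].
#' @param significant character vector (>= 2) of protein accessions.
#' @param cfg an [analysis_config()] (linkage).
#' @return list with `hclust`, `newick` (string) and the z-scored matrix.
#' @export
cluster_significant <- function(m, significant, cfg = analysis_config()) {
  stopifnot(inherits(m, "IntensityMatrix"))
  significant <- as.character(significant)
  if (length(significant) < 2) stop("need >= 2 significant proteins")
  bad <- setdiff(significant, proteins(m))
  if (length(bad)) stop("unknown protein(s): ", paste(bad, collapse = ", "))
  x <- .log2_values(m)[significant, , drop = FALSE]
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1       # constant profiles stay at zero after centring
  z <- (x - mu) / sdv
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = cfg$linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = newick, z = z)
}
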
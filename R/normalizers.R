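#' Select housekeeping normalizer proteins from the discovery matrix
#'
#' Candidates are proteins (i) present (non-missing) in every sample,
#' (ii) measured with SR and TR coefficients of variation below `cv_max`,
#' and (iii) contained in the supplied housekeeping identifier list. They
#' are ranked by mean linear intensity (descending, "most abundant" first)
#' and the top `top_n` retained — fewer, with a warning, when fewer
#' qualify.
#'
#' @param m linear-scale [intensity_matrix()].
#' @param hk_list character vector of housekeeping identifiers, or a path
#'   to a plain-text file with one identifier per line.
#' @param cv `CvTable` from [compute_cv()].
#' @param cv_max CV gate in percent (default 20).
#' @param top_n number of normalizers to retain (default 17).
#' @return a `HousekeepingSelection`: list with `table` (ranked data.frame
#'   of `protein`, `mean_intensity`, `cv_sr`, `cv_tr`) and `factors`
#'   (per-sample geometric mean of the selected proteins' linear
#'   intensities, rescaled to geometric mean 1).
#' @export
select_housekeeping <- function(m, hk_list, cv, cv_max = 20, top_n = 17) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (length(hk_list) == 1 && file.exists(hk_list))
    hk_list <- readLines(hk_list)
  hk_list <- trimws(hk_list)
  hk_list <- hk_list[nzchar(hk_list)]
  if (!length(hk_list)) stop("housekeeping list is empty")
  x <- if (m$scale == "linear") m$intensity else 2^m$intensity
  present <- rowSums(is.na(x)) == 0
  idx <- match(proteins(m), cv$protein)
  low_cv <- !is.na(cv$cv_sr[idx]) & !is.na(cv$cv_tr[idx]) &
    cv$cv_sr[idx] < cv_max & cv$cv_tr[idx] < cv_max
  in_list <- proteins(m) %in% hk_list
  ok <- present & low_cv & in_list
  if (!any(ok))
    stop("no housekeeping candidate passes the filters; ",
         "consider relaxing cv_max or extending the identifier list")
  tab <- data.frame(protein = proteins(m)[ok],
                    mean_intensity = rowMeans(x[ok, , drop = FALSE]),
                    cv_sr = cv$cv_sr[idx][ok], cv_tr = cv$cv_tr[idx][ok],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_intensity, tab$protein), ]
  if (nrow(tab) < top_n)
    warning(sprintf("only %d housekeeping candidates qualify (top_n = %d)",
                    nrow(tab), top_n))
  tab <- utils::head(tab, top_n)
  rownames(tab) <- NULL
  f <- exp(colMeans(log(x[tab$protein, , drop = FALSE])))
  f <- f / exp(mean(log(f)))
  structure(list(table = tab, factors = f),
            class = "HousekeepingSelection")
}

#' @export
print.HousekeepingSelection <- function(x, ...) {
  cat(sprintf("HousekeepingSelection: %d normalizer proteins\n",
              nrow(x$table)))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Normalize a matrix by its housekeeping factors
#'
#' Each sample's linear intensities are divided by that sample's factor
#' (the geometric mean of the selected proteins, rescaled so the factors
#' themselves have geometric mean 1). After normalization the geometric
#' mean of the selected proteins is identical in every sample; purely
#' per-sample multiplicative distortions are removed exactly, and the
#' transform is idempotent.
#'
#' @param m linear-scale [intensity_matrix()].
#' @param sel a `HousekeepingSelection`, or `NULL` to reuse factors from
#'   `factors`.
#' @param factors optional explicit per-sample factors (named by sample).
#' @return the normalized `IntensityMatrix`.
#' @export
normalize_by_housekeeping <- function(m, sel = NULL, factors = NULL) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (is.null(factors)) {
    stopifnot(inherits(sel, "HousekeepingSelection"))
    x <- if (m$scale == "linear") m$intensity else 2^m$intensity
    miss <- setdiff(sel$table$protein, proteins(m))
    if (length(miss))
      stop("selected protein(s) absent from matrix: ",
           paste(miss, collapse = ", "))
    f <- exp(colMeans(log(x[sel$table$protein, , drop = FALSE])))
    f <- f / exp(mean(log(f)))
  } else {
    f <- factors[samples(m)]
  }
  if (any(!is.finite(f)) || any(f <= 0))
    stop("normalization factors must be finite and > 0")
  if (m$scale == "linear") {
    m$intensity <- sweep(m$intensity, 2, f, `/`)
  } else {
    m$intensity <- sweep(m$intensity, 2, log2(f), `-`)
  }
  attr(m, "norm_factors") <- f
  m
}
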
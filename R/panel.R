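#' Read an annotation-flag table
#'
#' @param path TSV with a `protein` column and the five 0/1 evidence
#'   columns `prior_evidence`, `biomarker_or_drug_target`, `secreted`,
#'   `exosome`, `database_match`.
#' @return data.frame with logical flag columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_annotation_records(ann$protein, ann)
}

.flag_cols <- c("prior_evidence", "biomarker_or_drug_target", "secreted",
                "exosome", "database_match")

#' Build per-protein annotation records
#'
#' Normalises an annotation table to one row per requested protein with
#' strictly logical evidence flags. Proteins absent from the table default
#' to all-FALSE flags. Membership in a literature marker list (for the
#' hypoxia panel: previously reported hypoxia biomarkers) is OR-ed into
#' `prior_evidence`.
#'
#' @param proteins character vector of accessions to cover.
#' @param annotations data.frame with a `protein` column and any subset of
#'   the five flag columns (0/1 or logical); may be `NULL`.
#' @param literature character vector of accessions whose membership sets
#'   `prior_evidence`.
#' @return `AnnotationRecord` data.frame: `protein` plus five logical
#'   flag columns.
#' @export
build_annotation_records <- function(proteins, annotations = NULL,
                                     literature = character()) {
  out <- data.frame(protein = as.character(proteins),
                    stringsAsFactors = FALSE)
  for (f in .flag_cols) out[[f]] <- FALSE
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!"protein" %in% names(annotations))
      stop("annotation table needs a `protein` column")
    idx <- match(out$protein, annotations$protein)
    for (f in intersect(.flag_cols, names(annotations))) {
      v <- as.logical(annotations[[f]])[idx]
      out[[f]] <- ifelse(is.na(v), FALSE, v)
    }
  }
  out$prior_evidence <- out$prior_evidence | out$protein %in% literature
  class(out) <- c("AnnotationRecord", "data.frame")
  out
}

#' Additive evidence score of annotation records
#'
#' The panel-prioritisation score: each of the five boolean evidence flags
#' (prior literature/study evidence, biomarker or drug-target association,
#' secreted classification, exosome-database membership, expression-database
#' match) contributes +1, giving an integer score 0-5.
#'
#' @param rec an `AnnotationRecord` data.frame (see
#'   [build_annotation_records()]).
#' @return integer vector of scores, one per row.
#' @export
score_candidate <- function(rec) {
  rec <- as.data.frame(rec)
  miss <- setdiff(.flag_cols, names(rec))
  if (length(miss))
    stop("annotation record lacks flag(s): ", paste(miss, collapse = ", "))
  as.integer(Reduce(`+`, lapply(rec[.flag_cols],
                                function(v) as.integer(as.logical(v)))))
}

#' Assemble CV-gated panel candidates from differential results
#'
#' Hypoxia (Hx) candidates are proteins significant in any per-cell-line
#' treated-vs-control t-test; androgen-sensitivity (AS) candidates are
#' proteins significant in the all-sample ANOVA separating
#' androgen-sensitive from androgen-independent lines. Both are gated to
#' `cv_sr < cv_max` and `cv_tr < cv_max`. Significant proteins lacking a
#' defined CV are excluded; their accessions are attached as attribute
#' `excluded_no_cv`.
#'
#' @param diff one `DifferentialResult` or a list of them (rows are pooled;
#'   a protein qualifies when significant in any contrast).
#' @param cv a `CvTable` from [compute_cv()].
#' @param panel_kind `"Hx"` or `"AS"`.
#' @param cv_max CV gate in percent (default 20).
#' @return `PanelCandidate` data.frame: `protein`, `panel_kind`, `cv_sr`,
#'   `cv_tr`, `contrast` (semicolon-joined provenance), `estimate` (from
#'   the most significant contrast).
#' @export
assemble_candidates <- function(diff, cv, panel_kind = c("Hx", "AS"),
                                cv_max = 20) {
  if (is.character(panel_kind) && !all(panel_kind %in% c("Hx", "AS")))
    stop("unknown panel_kind: ", paste(setdiff(panel_kind, c("Hx", "AS")),
                                       collapse = ", "))
  panel_kind <- match.arg(panel_kind)
  if (inherits(diff, "data.frame")) diff <- list(diff)
  all_diff <- do.call(rbind, lapply(diff, as.data.frame))
  sig <- all_diff[all_diff$significant, , drop = FALSE]
  if (!nrow(sig)) {
    out <- data.frame(protein = character(), panel_kind = character(),
                      cv_sr = numeric(), cv_tr = numeric(),
                      contrast = character(), estimate = numeric())
    class(out) <- c("PanelCandidate", "data.frame")
    return(out)
  }
  prov <- stats::aggregate(contrast ~ protein, sig,
                           function(v) paste(sort(unique(v)),
                                             collapse = "; "))
  best <- sig[order(sig$protein, sig$p_value), ]
  best <- best[!duplicated(best$protein), c("protein", "estimate")]
  cand <- merge(prov, best, by = "protein")
  idx <- match(cand$protein, cv$protein)
  cand$cv_sr <- cv$cv_sr[idx]
  cand$cv_tr <- cv$cv_tr[idx]
  no_cv <- cand$protein[is.na(cand$cv_sr) | is.na(cand$cv_tr)]
  keep <- !is.na(cand$cv_sr) & !is.na(cand$cv_tr) &
    cand$cv_sr < cv_max & cand$cv_tr < cv_max
  out <- data.frame(protein = cand$protein[keep], panel_kind = panel_kind,
                    cv_sr = cand$cv_sr[keep], cv_tr = cand$cv_tr[keep],
                    contrast = cand$contrast[keep],
                    estimate = cand$estimate[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein), ]
  rownames(out) <- NULL
  attr(out, "excluded_no_cv") <- no_cv
  class(out) <- c("PanelCandidate", "data.frame")
  out
}

#' Score candidates and select the panel
#'
#' Attaches the additive evidence score to each candidate and retains those
#' with `score >= threshold`, ordered by score (descending), TR CV
#' (ascending) and accession — a deterministic order.
#'
#' @param candidates `PanelCandidate` data.frame from
#'   [assemble_candidates()].
#' @param annotations annotation table (see [build_annotation_records()]);
#'   may be `NULL` (all flags false).
#' @param literature literature marker accessions OR-ed into
#'   `prior_evidence`.
#' @param threshold minimum score for selection (default 2).
#' @return the candidates with added `score` and `selected` columns,
#'   selected rows first in the deterministic order, unselected rows
#'   (ordered the same way) after them; attribute `panel` holds just the
#'   selected subset.
#' @export
select_panel <- function(candidates, annotations = NULL,
                         literature = character(), threshold = 2) {
  cand <- as.data.frame(candidates)
  if (is.null(cand$cv_tr)) cand$cv_tr <- NA_real_
  rec <- build_annotation_records(cand$protein, annotations, literature)
  cand$score <- score_candidate(rec)
  cand$selected <- cand$score >= threshold
  ord <- order(-cand$selected, -cand$score, cand$cv_tr, cand$protein)
  cand <- cand[ord, ]
  rownames(cand) <- NULL
  class(cand) <- c("PanelCandidate", "data.frame")
  attr(cand, "panel") <- cand[cand$selected, , drop = FALSE]
  cand
}
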
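## Monoisotopic constants (Da)
.PROTON <- 1.007276466
.WATER  <- 18.0105646863

## standard amino-acid residue monoisotopic masses (Da)
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.check_residues <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(.RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' MRM assay design rules
#'
#' The peptide-eligibility and transition filters of the assay design:
#' fully tryptic peptides of 7-25 residues, no missed cleavages, no ragged
#' ends (a peptide bordered by consecutive K/R residues), no cysteine or
#' methionine, proteotypic in the background proteome; doubly charged
#' precursors with singly charged y-ion products, product m/z capped at
#' 1000 Th and excluded within a symmetric window around the precursor m/z;
#' 2-3 peptides per protein with 4-5 transitions per peptide.
#'
#' @param min_len,max_len peptide length bounds (residues).
#' @param missed_cleavages allowed missed cleavages (default 0).
#' @param forbidden_residues residues that disqualify a peptide.
#' @param exclude_ragged_ends drop peptides at K/R-K/R junctions.
#' @param require_proteotypic drop peptides occurring in more than one
#'   background protein.
#' @param precursor_charge,product_charge ion charges (2 and 1).
#' @param product_mz_max maximum product m/z (Th).
#' @param precursor_exclusion_window half-width (Th) of the symmetric
#'   product-ion exclusion window around the precursor m/z.
#' @param min_fragment_index smallest y-ion index enumerated (default 2:
#'   y1 is low-specificity).
#' @param max_peptides peptides kept per protein (default 3).
#' @param transitions_min,transitions_max transition count bounds per
#'   peptide; a peptide with fewer than `transitions_min` surviving
#'   transitions is dropped.
#' @return list of class `DesignRules`.
#' @export
design_rules <- function(min_len = 7, max_len = 25, missed_cleavages = 0,
                         forbidden_residues = c("C", "M"),
                         exclude_ragged_ends = TRUE,
                         require_proteotypic = TRUE,
                         precursor_charge = 2, product_charge = 1,
                         product_mz_max = 1000,
                         precursor_exclusion_window = 5,
                         min_fragment_index = 2,
                         max_peptides = 3,
                         transitions_min = 4, transitions_max = 5) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (product_mz_max <= 0 || precursor_exclusion_window < 0)
    stop("m/z bounds must be positive")
  structure(list(min_len = min_len, max_len = max_len,
                 missed_cleavages = missed_cleavages,
                 forbidden_residues = forbidden_residues,
                 exclude_ragged_ends = exclude_ragged_ends,
                 require_proteotypic = require_proteotypic,
                 precursor_charge = precursor_charge,
                 product_charge = product_charge,
                 product_mz_max = product_mz_max,
                 precursor_exclusion_window = precursor_exclusion_window,
                 min_fragment_index = min_fragment_index,
                 max_peptides = max_peptides,
                 transitions_min = transitions_min,
                 transitions_max = transitions_max),
            class = "DesignRules")
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P. With
#' zero missed cleavages the peptides partition the sequence (their
#' concatenation reproduces the input); with `missed_cleavages = n`,
#' peptides spanning up to `n` internal cleavage sites are added.
#'
#' @param sequence protein sequence (standard 20 residues).
#' @param missed_cleavages allowed internal cleavage sites (default 0).
#' @return data.frame `peptide`, `start`, `end` (1-based inclusive),
#'   `prev`, `nxt` (flanking residues, `"-"` at the termini),
#'   `missed` (internal cleavage sites spanned).
#' @export
digest <- function(sequence, missed_cleavages = 0) {
  res <- .check_residues(sequence)
  n <- length(res)
  # cut after position i when res[i] is K/R and res[i+1] is not P
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[pmin(cuts + 1, n)] != "P" | cuts == n]
  bounds <- c(0, cuts[cuts < n], n)   # peptide i spans bounds[i]+1..bounds[i+1]
  starts <- utils::head(bounds, -1) + 1
  ends <- utils::tail(bounds, -1)
  base <- data.frame(start = starts, end = ends, missed = 0L)
  out <- base
  if (missed_cleavages > 0) {
    for (mc in seq_len(missed_cleavages)) {
      if (nrow(base) <= mc) break
      out <- rbind(out, data.frame(
        start = utils::head(base$start, -mc),
        end = utils::tail(base$end, -mc), missed = as.integer(mc)))
    }
  }
  out$peptide <- substr(rep(sequence, nrow(out)), out$start, out$end)
  out$prev <- ifelse(out$start == 1, "-", res[pmax(out$start - 1, 1)])
  out$nxt <- ifelse(out$end == n, "-", res[pmin(out$end + 1, n)])
  out[, c("peptide", "start", "end", "prev", "nxt", "missed")]
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of the residue monoisotopic masses plus one water. Additive:
#' `peptide_mass(paste0(a, b)) == peptide_mass(a) + peptide_mass(b) -
#' water`.
#'
#' @param sequence peptide sequence (empty string gives the mass of water).
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence) {
  if (!nchar(sequence)) return(.WATER)
  sum(.RESIDUE_MASS[.check_residues(sequence)]) + .WATER
}

#' Precursor m/z of a peptide
#'
#' @param sequence peptide sequence.
#' @param charge precursor charge state (default 2).
#' @return `(mass + charge * proton) / charge` in Th.
#' @export
precursor_mz <- function(sequence, charge = 2) {
  (peptide_mass(sequence) + charge * .PROTON) / charge
}

#' m/z of a singly protonated y ion
#'
#' The y_k fragment retains the C-terminal `k` residues plus water and a
#' proton.
#'
#' @param sequence peptide sequence.
#' @param k fragment index, `1 <= k <= nchar(sequence) - 1`.
#' @return m/z in Th (vectorised over `k`).
#' @export
y_ion_mz <- function(sequence, k) {
  len <- nchar(sequence)
  if (any(k < 1 | k > len - 1))
    stop("k must be in 1..len-1")
  res <- .check_residues(sequence)
  csum <- cumsum(rev(unname(.RESIDUE_MASS[res])))  # C-terminal k residues
  csum[k] + .WATER + .PROTON
}

# TRUE when the peptide sits at a K/R-K/R junction: its preceding residue
# is K/R with another K/R before it, or its C-terminal K/R is followed by K/R
.is_ragged <- function(sequence, start, prev, nxt, full_sequence) {
  kr <- c("K", "R")
  n_rag <- prev %in% kr & start >= 3 &
    substring(full_sequence, start - 2, start - 2) %in% kr
  last <- substring(sequence, nchar(sequence), nchar(sequence))
  c_rag <- last %in% kr & nxt %in% kr
  n_rag | c_rag
}

#' Filter digest peptides by the assay-design eligibility rules
#'
#' Applies the length, missed-cleavage, forbidden-residue and ragged-end
#' rules, determines proteotypicity against the background proteome (exact
#' substring occurrence in exactly one background protein) and flags
#' peptides observed in the discovery spectral library.
#'
#' @param peptides digest data.frame from [digest()] for one protein.
#' @param protein accession of the digested protein.
#' @param background named character vector of all background protein
#'   sequences (the FASTA), including `protein` itself.
#' @param library optional library data.frame with columns `peptide` and
#'   `observed` (0/1); peptides found there with `observed == 1` get
#'   `observed_in_discovery = TRUE`.
#' @param rules a [design_rules()].
#' @param sequence full sequence of `protein` (defaults to
#'   `background[[protein]]`).
#' @return `PeptideCandidate` data.frame: `protein`, `peptide`, `start`,
#'   `end`, `prev`, `nxt`, `mass`, `precursor_mz`, `proteotypic`,
#'   `observed_in_discovery`.
#' @export
filter_peptides <- function(peptides, protein, background, library = NULL,
                            rules = design_rules(),
                            sequence = background[[protein]]) {
  p <- peptides
  len <- nchar(p$peptide)
  keep <- len >= rules$min_len & len <= rules$max_len &
    p$missed <= rules$missed_cleavages
  if (length(rules$forbidden_residues))
    keep <- keep & !grepl(paste0("[", paste(rules$forbidden_residues,
                                            collapse = ""), "]"),
                          p$peptide)
  if (rules$exclude_ragged_ends)
    keep <- keep & !.is_ragged(p$peptide, p$start, p$prev, p$nxt, sequence)
  p <- p[keep, , drop = FALSE]
  if (!nrow(p)) {
    out <- data.frame(protein = character(), peptide = character(),
                      start = integer(), end = integer(),
                      prev = character(), nxt = character(),
                      mass = numeric(), precursor_mz = numeric(),
                      proteotypic = logical(),
                      observed_in_discovery = logical())
    class(out) <- c("PeptideCandidate", "data.frame")
    return(out)
  }
  hits <- vapply(p$peptide, function(pep)
    sum(vapply(background, function(s)
      grepl(pep, s, fixed = TRUE), logical(1))), numeric(1))
  p$proteotypic <- hits == 1
  if (rules$require_proteotypic) p <- p[p$proteotypic, , drop = FALSE]
  obs <- character(0)
  if (!is.null(library) && nrow(library)) {
    lib <- as.data.frame(library)
    obs_col <- if ("observed" %in% names(lib)) as.logical(lib$observed)
    else rep(TRUE, nrow(lib))
    obs <- lib$peptide[obs_col]
  }
  p$observed_in_discovery <- p$peptide %in% obs
  p$mass <- vapply(p$peptide, peptide_mass, numeric(1))
  p$precursor_mz <- (p$mass + rules$precursor_charge * .PROTON) /
    rules$precursor_charge
  out <- data.frame(protein = protein, p[, c("peptide", "start", "end",
                                             "prev", "nxt", "mass",
                                             "precursor_mz", "proteotypic",
                                             "observed_in_discovery")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("PeptideCandidate", "data.frame")
  out
}

#' Enumerate and filter the y-ion transitions of one peptide candidate
#'
#' y ions are enumerated for `k = min_fragment_index .. len - 1`, products
#' above `product_mz_max` or within the precursor exclusion window are
#' dropped, transitions are ranked by fragment length (descending - longer
#' y ions are more specific) and at most `transitions_max` kept. When fewer
#' than `transitions_min` survive the peptide is rejected: an empty table
#' with attribute `drop_reason` is returned.
#'
#' @param candidate one-row `PeptideCandidate` (or a list with `peptide`,
#'   `precursor_mz`, `protein`).
#' @param rules a [design_rules()].
#' @return `TransitionRow` data.frame: `Protein`, `Peptide`,
#'   `Precursor_mz`, `Precursor_charge`, `Product_mz`, `Product_charge`,
#'   `Fragment_ion`, `Rank`.
#' @export
build_transitions <- function(candidate, rules = design_rules()) {
  pep <- candidate$peptide[1]
  prot <- candidate$protein[1]
  pre_mz <- if (!is.null(candidate$precursor_mz))
    candidate$precursor_mz[1] else precursor_mz(pep, rules$precursor_charge)
  len <- nchar(pep)
  empty <- function(reason) {
    out <- data.frame(Protein = character(), Peptide = character(),
                      Precursor_mz = numeric(), Precursor_charge = integer(),
                      Product_mz = numeric(), Product_charge = integer(),
                      Fragment_ion = character(), Rank = integer())
    attr(out, "drop_reason") <- reason
    class(out) <- c("TransitionRow", "data.frame")
    out
  }
  ks <- seq.int(rules$min_fragment_index, len - 1)
  if (rules$min_fragment_index > len - 1) return(empty("peptide too short"))
  mz <- y_ion_mz(pep, ks)
  ok <- mz <= rules$product_mz_max &
    abs(mz - pre_mz) >= rules$precursor_exclusion_window
  ks <- ks[ok]; mz <- mz[ok]
  if (length(ks) < rules$transitions_min)
    return(empty("no valid transitions"))
  ord <- order(-ks)
  ks <- ks[ord][seq_len(min(length(ks), rules$transitions_max))]
  mz <- mz[ord][seq_len(length(ks))]
  out <- data.frame(Protein = prot, Peptide = pep, Precursor_mz = pre_mz,
                    Precursor_charge = as.integer(rules$precursor_charge),
                    Product_mz = mz,
                    Product_charge = as.integer(rules$product_charge),
                    Fragment_ion = paste0("y", ks),
                    Rank = seq_along(ks), stringsAsFactors = FALSE)
  class(out) <- c("TransitionRow", "data.frame")
  out
}

#' Read a FASTA file as a named character vector
#'
#' Headers are truncated to their first whitespace-delimited token (the
#' accession).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out
}

#' Design an MRM assay for a panel of proteins
#'
#' For each panel protein the tryptic digest is filtered by the eligibility
#' rules, candidate peptides are ranked (observed in discovery first, then
#' by surviving transition count, then alphabetically), the top
#' `max_peptides` kept, and their transitions emitted. Proteins absent from
#' the FASTA or yielding no eligible peptide/transitions are reported in a
#' design-failure table. Output order is deterministic.
#'
#' @param panel character vector of accessions, or a `PanelCandidate`
#'   data.frame (its `protein` column is used; when a `selected` column is
#'   present only selected rows are used).
#' @param fasta named character vector of background sequences or a FASTA
#'   path.
#' @param library optional library data.frame (`protein`, `peptide`,
#'   `observed`).
#' @param rules a [design_rules()].
#' @return list with `transitions` (`TransitionRow` data.frame) and
#'   `failures` (data.frame `protein`, `reason`).
#' @export
design_assay <- function(panel, fasta, library = NULL,
                         rules = design_rules()) {
  if (inherits(panel, "data.frame")) {
    panel <- if (!is.null(panel$selected))
      panel$protein[panel$selected] else panel$protein
  }
  panel <- unique(as.character(panel))
  if (!length(panel)) stop("empty panel")
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    fasta <- read_fasta(fasta)
  failures <- list()
  rows <- list()
  for (prot in panel) {
    if (!prot %in% names(fasta)) {
      failures[[prot]] <- "absent from FASTA"
      next
    }
    lib_p <- if (!is.null(library))
      library[library$protein == prot, , drop = FALSE] else NULL
    cand <- filter_peptides(digest(fasta[[prot]],
                                   rules$missed_cleavages),
                            prot, fasta, lib_p, rules)
    if (!nrow(cand)) {
      failures[[prot]] <- "no eligible peptides"
      next
    }
    tr_list <- lapply(seq_len(nrow(cand)), function(i)
      build_transitions(cand[i, ], rules))
    n_tr <- vapply(tr_list, nrow, integer(1))
    keep <- n_tr > 0
    if (!any(keep)) {
      failures[[prot]] <- "no valid transitions"
      next
    }
    ord <- order(-cand$observed_in_discovery[keep], -n_tr[keep],
                 cand$peptide[keep])
    sel <- which(keep)[ord][seq_len(min(sum(keep), rules$max_peptides))]
    rows[[prot]] <- do.call(rbind, tr_list[sel])
  }
  transitions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Protein = character(), Peptide = character(),
               Precursor_mz = numeric(), Precursor_charge = integer(),
               Product_mz = numeric(), Product_charge = integer(),
               Fragment_ion = character(), Rank = integer())
  rownames(transitions) <- NULL
  class(transitions) <- c("TransitionRow", "data.frame")
  fail_df <- data.frame(protein = names(failures),
                        reason = unlist(failures, use.names = FALSE),
                        stringsAsFactors = FALSE)
  list(transitions = transitions, failures = fail_df)
}

#' Write a transition list CSV
#'
#' @param transitions `TransitionRow` data.frame from [design_assay()].
#' @param path output CSV path.
#' @return (invisibly) `path`.
#' @export
write_transition_list <- function(transitions, path) {
  utils::write.csv(as.data.frame(transitions), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
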
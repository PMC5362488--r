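test_that("digest applies the K/R-not-before-P rule", {
  expect_identical(digest("AKRPTESTKGL")$peptide,
                   c("AK", "RPTESTK", "GL"))
  expect_identical(digest("ACDEFGHILM")$peptide, "ACDEFGHILM")  # no K/R
  expect_identical(digest("KKK")$peptide, c("K", "K", "K"))
  d <- digest("AKRPTESTKGL")
  expect_identical(d$prev, c("-", "K", "K"))
  expect_identical(d$nxt, c("R", "G", "-"))
  expect_error(digest("ABBA"), "position 2")
})

test_that("digest agrees with a brute-force scanner on random sequences", {
  set.seed(11)
  for (i in 1:300) {
    s <- rand_seq(sample(20:200, 1))
    d <- digest(s)
    # concatenation identity: zero missed cleavages partition the sequence
    expect_identical(paste(d$peptide, collapse = ""), s)
    expect_identical(d$peptide, brute_digest(s))
  }
})

test_that("missed cleavages add spanning peptides", {
  d1 <- digest("AKRPTESTKGL", missed_cleavages = 1)
  expect_setequal(d1$peptide,
                  c("AK", "RPTESTK", "GL", "AKRPTESTK", "RPTESTKGL"))
  expect_identical(sort(d1$missed), c(0L, 0L, 0L, 1L, 1L))
})

test_that("peptide_mass matches the reference value and is additive", {
  water <- peptide_mass("")
  expect_equal(water, 18.0105646863, tolerance = 1e-9)
  expect_equal(peptide_mass("G"), 57.02146 + water, tolerance = 1e-5)
  # widely used reference peptide, neutral monoisotopic mass
  expect_equal(peptide_mass("PEPTIDE"), 799.35996, tolerance = 1e-3)
  # additivity property on random pairs
  set.seed(21)
  for (i in 1:200) {
    a <- rand_seq(sample(1:30, 1)); b <- rand_seq(sample(1:30, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - water,
                 tolerance = 1e-9)
  }
})

test_that("y-ion and precursor m/z follow the mass relations", {
  expect_equal(y_ion_mz("TESTPEPK", 1), 147.113, tolerance = 1e-3)
  set.seed(31)
  for (i in 1:50) {
    s <- rand_seq(sample(7:25, 1))
    len <- nchar(s)
    ys <- y_ion_mz(s, seq_len(len - 1))
    expect_true(all(diff(ys) > 0))                    # strictly increasing
    expect_lt(ys[len - 1], peptide_mass(s) + 1.007276466)  # < [M+H]+
    # precursor m/z at charge 2 equals (mass + 2 proton)/2 to 1e-6 relative
    expect_equal(precursor_mz(s, 2),
                 (peptide_mass(s) + 2 * 1.007276466) / 2,
                 tolerance = 1e-6)
  }
})

test_that("filter_peptides applies eligibility and proteotypicity rules", {
  rules <- design_rules()
  # one protein containing a short peptide, an M peptide and a clean one
  seq1 <- "AAADDDK" # 7 clean
  seqA <- paste0("GGGGGK", "AMADEFGHK", seq1, "TTTTTTTTTK")
  bg <- c(A = seqA)
  cand <- filter_peptides(digest(seqA), "A", bg, rules = rules)
  expect_true(seq1 %in% cand$peptide)
  expect_false("GGGGGK" %in% cand$peptide)     # 6 residues: too short
  expect_false("AMADEFGHK" %in% cand$peptide)  # contains M
  expect_true(all(!grepl("[CM]", cand$peptide)))

  # shared peptide across two background proteins is not proteotypic
  shared <- "LLLDDDEEEK"
  bg2 <- c(A = paste0("GGGGGR", shared, "TTTTTTTK"),
           B = paste0("VVVVVR", shared, "SSSSSSSK"))
  c2 <- filter_peptides(digest(bg2[["A"]]), "A", bg2, rules = rules)
  expect_false(shared %in% c2$peptide)
  c2b <- filter_peptides(digest(bg2[["A"]]), "A", bg2,
                         rules = design_rules(require_proteotypic = FALSE))
  expect_true(shared %in% c2b$peptide)
  expect_false(c2b$proteotypic[c2b$peptide == shared])

  # ragged ends: peptides at K/R-K/R junctions are dropped
  seqr <- paste0("AAADDDKK", "EEEFFFGGGK", "HHHIIIK")
  bgr <- c(R1 = seqr)
  cr <- filter_peptides(digest(seqr), "R1", bgr, rules = rules)
  expect_false("EEEFFFGGGK" %in% cr$peptide)   # preceded by KK junction
  cr2 <- filter_peptides(digest(seqr), "R1", bgr,
                         rules = design_rules(exclude_ragged_ends = FALSE))
  expect_true("EEEFFFGGGK" %in% cr2$peptide)

  # library observations are keyed by peptide sequence
  lib <- data.frame(peptide = seq1, observed = 1)
  c3 <- filter_peptides(digest(seqA), "A", bg, library = lib, rules = rules)
  expect_true(c3$observed_in_discovery[c3$peptide == seq1])

  # precursor m/z stored at charge 2
  expect_equal(cand$precursor_mz,
               (cand$mass + 2 * 1.007276466) / 2, tolerance = 1e-9)
})

test_that("build_transitions enumerates, filters and ranks y ions", {
  rules <- design_rules()
  pep <- "AAADDDK"   # 7 residues: y2..y6 available
  cand <- data.frame(protein = "A", peptide = pep,
                     precursor_mz = precursor_mz(pep))
  tr <- build_transitions(cand, rules)
  expect_identical(tr$Fragment_ion, paste0("y", 6:2))
  expect_identical(tr$Rank, 1:5)
  expect_equal(tr$Product_mz, y_ion_mz(pep, 6:2), tolerance = 1e-9)

  # a product inside the precursor exclusion window is dropped
  win_rules <- design_rules(precursor_exclusion_window =
                              abs(y_ion_mz(pep, 4) - precursor_mz(pep)) + 1)
  tr2 <- build_transitions(cand, win_rules)
  expect_false("y4" %in% tr2$Fragment_ion)

  # all products above the m/z cap: peptide dropped with a reason
  tr3 <- build_transitions(cand, design_rules(product_mz_max = 100))
  expect_equal(nrow(tr3), 0)
  expect_identical(attr(tr3, "drop_reason"), "no valid transitions")

  # fewer than transitions_min survivors: dropped
  tr4 <- build_transitions(cand, design_rules(product_mz_max =
                                                y_ion_mz(pep, 3)))
  expect_equal(nrow(tr4), 0)
})

test_that("every emitted transition satisfies the design constraints", {
  rules <- design_rules()
  set.seed(41)
  truth <- simulate_catalog(simulation_config(n_proteins = 60, seed = 41))
  fasta <- truth$sequence
  names(fasta) <- truth$accession
  assay <- design_assay(truth$accession, fasta, rules = rules)
  tr <- assay$transitions
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$Product_mz <= rules$product_mz_max))
  expect_true(all(abs(tr$Product_mz - tr$Precursor_mz) >=
                    rules$precursor_exclusion_window))
  expect_true(all(tr$Precursor_charge == 2L))
  expect_true(all(tr$Product_charge == 1L))
  k <- as.integer(sub("^y", "", tr$Fragment_ion))
  expect_true(all(k >= rules$min_fragment_index))
  expect_true(all(k <= nchar(tr$Peptide) - 1))
  counts <- table(paste(tr$Protein, tr$Peptide))
  expect_true(all(counts >= rules$transitions_min &
                    counts <= rules$transitions_max))
  pep_per_prot <- tapply(tr$Peptide, tr$Protein,
                         function(p) length(unique(p)))
  expect_true(all(pep_per_prot <= rules$max_peptides))
  # precursor m/z invariant, 1e-6 relative
  mz <- vapply(unique(tr$Peptide), precursor_mz, numeric(1))
  expect_equal(tr$Precursor_mz, unname(mz[tr$Peptide]), tolerance = 1e-6)

  # byte-identical determinism
  assay2 <- design_assay(truth$accession, fasta, rules = rules)
  expect_identical(assay, assay2)
})

test_that("design_assay prioritises observed peptides and logs failures", {
  bg <- c(
    OBS = paste0("AAADDDEEEK", "FFFGGGHHHK", "IIILLLNNNK", "QQQSSSTTTK"),
    ALLM = paste0("MMMAAADDDK", "MEEEFFFGGGK"),
    GONE = "AAAAAAA")
  lib <- data.frame(protein = "OBS",
                    peptide = c("FFFGGGHHHK", "IIILLLNNNK"),
                    observed = c(1, 1))
  assay <- design_assay(c("OBS", "ALLM", "MISSING"), bg[c("OBS", "ALLM")],
                        library = lib)
  tr <- assay$transitions
  obs_peps <- unique(tr$Peptide[tr$Protein == "OBS"])
  expect_length(obs_peps, 3)       # top max_peptides of 4 eligible
  expect_true(all(c("FFFGGGHHHK", "IIILLLNNNK") %in% obs_peps[1:2]))
  expect_setequal(assay$failures$protein, c("ALLM", "MISSING"))
  expect_identical(
    assay$failures$reason[assay$failures$protein == "ALLM"],
    "no eligible peptides")
  expect_error(design_assay(character(0), bg), "empty panel")

  # eligible-peptide counts match a brute-force enumeration oracle
  rules <- design_rules(require_proteotypic = FALSE)
  set.seed(51)
  for (i in 1:20) {
    s <- rand_seq(150)
    peps <- brute_digest(s)
    ok <- vapply(seq_along(peps), function(j) {
      p <- peps[j]
      len <- nchar(p)
      if (len < 7 || len > 25) return(FALSE)
      if (grepl("[CM]", p)) return(FALSE)
      # ragged: junction of two consecutive K/R on either side
      start <- sum(nchar(peps[seq_len(j - 1)])) + 1
      before1 <- if (start > 1) substr(s, start - 1, start - 1) else "-"
      before2 <- if (start > 2) substr(s, start - 2, start - 2) else "-"
      after <- if (start + len - 1 < nchar(s))
        substr(s, start + len, start + len) else "-"
      last <- substr(p, len, len)
      nrag <- before1 %in% c("K", "R") && before2 %in% c("K", "R")
      crag <- last %in% c("K", "R") && after %in% c("K", "R")
      !(nrag || crag)
    }, logical(1))
    got <- filter_peptides(digest(s), "X", c(X = s), rules = rules)
    expect_setequal(got$peptide, unique(peps[ok]))
  }
})
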
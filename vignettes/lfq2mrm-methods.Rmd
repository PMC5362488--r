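---
title: "Methods: from label-free discovery to scored panels and MRM assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from label-free discovery to scored panels and MRM assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfq2mrm)
```

# Scope and model

`lfq2mrm` implements a discovery-to-verification workflow for label-free
quantitative (LFQ) proteomics studies of cultured cells under a factorial
design: cell line x treatment x timepoint, with three kinds of replicate
columns. A *biological replicate* (BR) is an independent culture; a *sample
replicate* (SR) is a split of the same lysate taken before enzymatic
digestion; a *technical replicate* (TR) is a repeated injection of the same
prepared digest. The motivating application is a prostate-cancer cell-line
model of progression: one androgen-sensitive line and two
androgen-independent sublines, treated with a hypoxia-mimetic
(a prolyl-hydroxylase inhibitor) or vehicle for 8 h and 24 h, three
biological replicates each.

The quantitative model throughout is additive on the log2 scale. For
protein $p$ in sample $j$,

$$\log_2 y_{pj} = \mu_p + \beta_{p,\mathrm{line}(j)}
  + \delta_p \, [\mathrm{treated}(j)] + b_{p,\mathrm{BR}(j)}
  + t_{p,\mathrm{prep}(j)} + e_{pj},$$

with baseline $\mu_p$, cell-line effect $\beta$, treatment effect
$\delta_p$, and three nested noise terms: biological
($b \sim N(0, \sigma_\mathrm{bio}^2)$, shared by a BR column and all of its
SR/TR injections), preparation ($t \sim N(0, \sigma_\mathrm{tech}^2)$,
shared by a BR and its TRs but redrawn for an SR, because an SR is split
before digestion) and injection ($e \sim N(0, \sigma_\mathrm{inj}^2)$,
independent per column). Values below a detection limit are censored to
missing (left-censored, missing-not-at-random); an optional
missing-completely-at-random component defaults to zero.

# The synthetic-data generator

`simulation_config()` / `simulate_catalog()` / `simulate_matrix()` /
`write_fixtures()` generate every input the pipeline reads, with ground
truth. Defaults were chosen once, as the stated world of the package, and
are not tuned against test outcomes:

* **Design**: 3 cell lines x {treated, control} x {8 h, 24 h} x 3 BR, with
  one SR and one TR attached to the first biological replicate of each
  condition (36 BR + 12 SR + 12 TR columns).
* **Baselines**: $\mu_p \sim N(25, 2^2)$ on the log2 scale, the typical
  magnitude of MaxQuant-style LFQ intensities.
* **Noise**: $\sigma_\mathrm{bio} = 0.5$, $\sigma_\mathrm{tech} = 0.1$,
  $\sigma_\mathrm{inj} = 0.05$ log2 units. These place TR coefficients of
  variation near 5%, SR CVs near 8-12% and parent-replicate Pearson
  correlations above 0.98 — the replicate behaviour a technically sound
  label-free experiment exhibits, and the regime in which a 20% CV gate is
  a meaningful but non-trivial filter.
* **Effects**: 5% of proteins carry a treatment (hypoxia) effect and 10% a
  cell-line (androgen-sensitivity) effect of ±1.5 log2 units; the first
  cell line is offset against the other two, mirroring a sensitive line
  versus independent sublines. Housekeeping-flagged proteins (5%) have all
  effects forced to zero.
* **Detection limit**: log2 intensity 20, i.e. roughly 1-2% censored
  values at the default baselines.
* **Sequences**: uniform random over the 20 residues with K and R boosted
  to 6% each (12% combined) so that tryptic peptides of assayable length
  are common; lengths 100-600.

What a green test on synthetic data does *not* establish: real LFQ data
have correlated peptide-level noise, intensity-dependent variance and
missingness, shared peptides between protein groups, and batch structure.
The generator emulates none of these; it validates the statistical and
combinatorial machinery, not instrument physics.

# Quality control

Identification filtering removes reverse-database hits, contaminants,
proteins only identified by a modification site, and proteins with fewer
than 2 peptides (all configurable); removal counts are logged per reason
and the operation is idempotent.

Replicate QC has three read-outs:

* `pearson_pairs()` — Pearson correlation of log2 intensities over
  pairwise-complete proteins, for SR/TR injections against their parent
  column or between biological replicates of a condition. No imputation is
  done at the QC stage; pairs sharing fewer than 3 proteins are undefined.
* `replicate_overlap()` — identification overlap of a replicate group as
  intersection-over-union (group Jaccard, in percent), with all pairwise
  Jaccard values alongside. Group Jaccard was chosen because a bare
  "percent overlap" is ambiguous for more than two sets.
* `compute_cv()` — per-protein CV% over a parent column plus its SR (or
  TR) injections, computed on **linear** intensities with the $n-1$
  standard deviation, since replicate scatter of measured LFQ intensity is
  what the downstream 20% gate refers to; a log2-scale CV is available via
  an argument. When several parents carry injections the per-group CVs are
  summarised by their median. A CV is undefined (NA, and the protein is
  excluded from gated selections) when fewer than 2 values remain.

# Differential analysis

Analysis runs on log2 intensities after constant imputation: every missing
cell is set to the global observed minimum minus a configurable offset
(default 1 log2 unit). This left-censored convention encodes
presence/absence: imputed values sit strictly below all observed values,
and the presence mask is retained. A per-sample variant is available
behind a flag.

* **t-tests** (`ttest_contrast()`): per-protein two-sided equal-variance
  Student's t-test (Welch behind a flag), estimate = difference of group
  means. Degenerate zero-variance rows use the documented convention
  p = 1 for equal means, p = 0 otherwise. Raw p-values at
  $\alpha = 0.05$ drive the significance flag, mirroring common practice
  in discovery-stage cell-line screens; Benjamini-Hochberg adjusted
  p-values are reported alongside for the reader.
* **ANOVA** (`anova_all_groups()`): per-protein fixed-effects one-way
  ANOVA. In addition a single study-level *critical difference* is
  reported: the Fisher least-significant difference
  $t_{1-\alpha/2,\,df_w}\sqrt{2\,\widetilde{MS}_w / \tilde n}$, using the
  median within-group mean square across proteins and the harmonic-mean
  group size. This operationalises the familiar practice of quoting one
  fold-change cutoff for a whole dataset ("changes beyond X are
  significant"); it is always recomputed from the data, never hard-coded.
  Whether such a published constant is an LSD, an HSD or a
  moderated-threshold quantity is generally not decidable from a study's
  methods text; the LSD is the most direct formalisation of a
  "least significant fold change" and is the documented default.
* **PCA** (`pca_samples()`): samples projected on components of the
  protein-wise mean-centred (not variance-scaled) log2 matrix —
  logarithmised values only, no standardisation, so abundant variable
  proteins dominate, as intended for a global structure check.
* **Clustering** (`cluster_significant()`): z-score per protein across
  samples, Euclidean distance, agglomerative clustering; average linkage
  by default (the linkage is a free choice; average linkage is robust to
  chaining and standard in expression work). The tree is exported as
  Newick via `ape`.

# Panel assembly and the additive evidence score

Hypoxia (Hx) candidates are proteins significant in any per cell line
treated-vs-control t-test; androgen-sensitivity (AS) candidates are
proteins significant in the cell-line ANOVA. Both are gated to SR CV < 20%
**and** TR CV < 20%; significant proteins lacking a defined CV are
excluded with a logged reason.

Each candidate is scored by five boolean evidence criteria, +1 each
(range 0-5):

1. prior evidence — membership in a literature marker list (hypoxia
   panel) or a shortlist from an earlier study (AS panel); always an
   input, never inferred;
2. previously reported biomarker or drug target;
3. classified as secreted (signal-peptide / transmembrane-topology
   prediction);
4. found in exosome proteome databases;
5. matched in tumour gene-expression databases.

All five criteria enter as offline boolean flags supplied by the user or
the simulator; the package never queries the underlying services. The
five-criterion form is used because it exactly reproduces the printed
score column of the published hypoxia panel bundled under
`inst/extdata/` (27 rows, scores 2-4), which the acceptance suite checks
row by row. Proteins with score >= 2 are selected, ordered by score
(descending), TR CV (ascending) and accession — a deterministic order.

A known inconsistency of the source material is deliberately not
replicated: a few published panel members carry a TR CV above 20%. The
stated gate is applied as stated; violations are visible in the logged
exclusions rather than silently reproduced.

# Housekeeping normalizer selection

Candidates for targeted-assay normalization must be present in every
sample, measured with SR and TR CV below 20%, and contained in a
user-supplied housekeeping identifier list (one identifier per line,
matched exactly). Candidates are ranked by mean linear intensity —
"most abundant" is read as largest mean LFQ intensity, the simplest
defensible ranking — and the top 17 retained, the conventional size for a
normalization sub-panel here.

Per-sample factors are the geometric mean of the selected proteins'
linear intensities, rescaled so the factors themselves have geometric
mean 1 (so normalization preserves the overall intensity scale). The
geometric mean is used rather than the arithmetic mean because
multiplicative noise is the natural error model on intensities.

One identifiability fact matters for testing: a distortion multiplying
*every* sample by the same constant cannot be detected from housekeeping
ratios under any scale-preserving normalization. Consequently the
round-trip guarantee is: any per-sample multiplicative distortion with
unit geometric mean is removed exactly (to numerical precision);
arbitrary distortions are removed up to their one global geometric-mean
constant. The test suite asserts both forms, including the predicted
constant itself.

# MRM assay design

For each panel protein:

1. **Digestion** — in-silico trypsin: cleave C-terminal to K/R except
   before proline. With zero missed cleavages the peptides partition the
   sequence (concatenation identity, property-tested against a
   brute-force scanner).
2. **Eligibility** — length 7-25, no missed cleavages, no C or M
   (reactive / oxidisable residues), no ragged ends. "Ragged end" is
   defined here as a K/R-K/R junction: the residue preceding the peptide
   is K/R and the one before it is also K/R, or the peptide's C-terminal
   K/R is immediately followed by K/R; such sites cleave variably.
3. **Proteotypicity** — the peptide occurs as an exact substring in
   exactly one protein of the supplied FASTA. I and L are treated as
   distinct (a configurable simplification).
4. **Masses** — neutral monoisotopic mass = sum of residue masses + one
   water (18.0105646863 Da); proton 1.007276466 Da; precursor at charge
   2+; products are singly charged y ions. The embedded residue table is
   unit-tested against an independent summation and the conventional
   reference peptide.
5. **Transitions** — y$_k$ for $k \ge 2$ (y$_1$ is excluded by default as
   low-specificity), products above 1000 Th or within ±5 Th of the
   precursor m/z discarded. The ±5 Th window is a conventional
   quadrupole-isolation vicinity; "close to the precursor" has no
   standard numeric definition, so the window is configurable. Surviving
   transitions are ranked by fragment length (longer y ions are more
   specific); peptides keeping fewer than 4 transitions are dropped with
   a reason.
6. **Selection** — peptides observed in the discovery library rank
   first, then by transition count, then alphabetically; up to 3 peptides
   per protein are kept, each with 4-5 transitions. The output is
   byte-identical across runs on identical inputs.

Out of scope by design: retention-time scheduling, collision-energy
optimisation, b ions and multiply charged fragments, spectrum-level
simulation.

# Numerical and degenerate-input conventions

* Zero intensity in the MaxQuant dialect reads as missing; a fully
  missing matrix cannot be imputed (error).
* Zero-variance t-test rows: p = 1 (equal means) / p = 0 (unequal).
* ANOVA with zero within-group variance follows the same convention.
* Constant profiles z-score to all-zero rather than dividing by zero.
* Unbalanced ANOVA group sizes enter the LSD through the harmonic mean.
* Ties in panel ordering are broken by accession; all outputs are
  deterministic given inputs and seed.

# Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_proteins = 500, seed = 1)
truth <- simulate_catalog(cfg)
m <- simulate_matrix(truth, cfg)
paths <- write_fixtures(truth, m, "study")
res <- run_pipeline(paths["protein_groups"], paths["design"],
                    paths["annotations"], paths["housekeeping"],
                    paths["fasta"], paths["library"], out_dir = "out")
head(res$panels$Hx)
head(res$assays$Hx$transitions)
```

# Known limitations

* Protein-level input only: peptide-to-protein inference, peptide-level
  ANOVA and spectrum-level modelling are out of scope.
* The simulator's independence assumptions (per-protein noise, flag
  independence) are idealisations.
* Annotation evidence is trusted as given; no live database access.
* The additive score weights all five evidence classes equally; that is
  the published convention being reproduced, not an optimised weighting.
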
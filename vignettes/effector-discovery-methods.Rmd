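---
title: "Methods: proteotranscriptomic effector discovery, expansion ranking and parasitism statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteotranscriptomic effector discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectorscan)
```

## The problem

Parasitoid wasps subdue and consume their hosts with two secreted arsenals:
venom proteins injected at oviposition, and digestive enzymes released by
teratocytes — cells shed from the egg's serosal membrane into the host.
Identifying these effector proteins from sequencing data is a two-evidence
problem. Expression alone over-calls: a transcript abundant in the venom
gland need not be translated and secreted into venom fluid. Proteomics
alone under-calls: peptide spectra must be anchored to the right gene
model. `effectorscan` implements the joint screen — transcriptome-wide
expression thresholding and tissue-specialization scoring, combined with
proteomic peptide-to-protein matching — together with the comparative
screen for gene-family expansions that often accompany venom innovation,
and the behavioral/parasitism assay statistics used to characterize the
wasp's ecology. Every stage runs on synthetic data with planted ground
truth, so the pipeline's operating characteristics are measurable without
any external download.

## Expression statistics

### The N99 expressed-gene threshold

Whether a gene counts as "expressed" in a sample group is decided by a
cumulative-abundance rule rather than a fixed TPM cutoff. Sort the group's
per-gene TPM values in descending order and accumulate; the threshold is
the TPM value at the first position where the running sum reaches 99% of
the total (the fraction is configurable via `n99_fraction`). Genes at or
above this value jointly account for 99% of the summarized transcripts:

```{r}
compute_n99(c(g1 = 50, g2 = 30, g3 = 15, g4 = 4, g5 = 1))[c("threshold", "n_expressed")]
```

The boundary rule deserves a word. Read literally, "expressed" could mean
strictly above the threshold, but then the gene that *defines* the
threshold — which by construction sits inside the 99% mass — would not
itself be expressed, an inconsistency. The default is therefore
`inclusive_ge` (TPM ≥ threshold counts as expressed), with `strict_gt`
available for users who want the literal reading; both are tested. An
all-zero group gets threshold 0 with nothing expressed. Whether the
threshold is computed per library or per replicate-averaged group is a
free choice in principle; the default here is group-level (replicates
averaged first), with `compute_n99` usable on any single sample's vector.

### Tissue-specialization index

A gene's specialization for a focal tissue (venom gland or teratocytes) is
the ratio of its mean TPM across the focal samples to the mean of the
*other group means* — each non-focal tissue/stage/sex group's replicates
are averaged first, and those group means are then averaged. Averaging
groups rather than raw samples prevents a heavily replicated group from
dominating the denominator. Degenerate ratios keep their mathematical
meaning: 0/positive is 0, positive/0 is `Inf`, 0/0 is `NaN`. A pseudocount
(`pseudocount` in `run_config()`) is available when a finite ranking of
genes with zero background is needed; the default of 0 preserves the plain
ratio. The index is scale-invariant: multiplying every TPM by a constant
changes no index, and scales every N99 threshold by exactly that constant
— an invariant the test suite checks bit-for-bit using dyadic factors (for
which floating-point multiplication is exact).

### The high-expression Z test

"Significantly highly expressed" genes within a candidate set are called
by standardizing log~2~(TPM + 1) with the sample mean and the n−1 standard
deviation and taking the one-sided upper standard-normal tail; a gene is
called at p < α (default 0.05). The log transform is used because TPM is
heavy-tailed; the one-sided tail because the question is directional.
Both, and α, are arguments, since neither choice is forced by the
definition of a Z test. With fewer than 3 candidates, or zero spread, the
test refuses to answer (a degenerate distribution supports no call).

A known property of this plug-in statistic: because each candidate's value
enters the mean and standard deviation it is standardized against, the
null call rate is slightly *below* α — approximately α − 0.09/n at α =
0.05 (about 0.0495 at n = 200, measured by direct simulation in the test
suite). The test is therefore mildly conservative at moderate candidate
counts; we document this rather than "correct" it, because the simple
plug-in form is the method's definition.

### Clustering and ordination

Expression-pattern clustering standardizes each gene's profile to z-scores
across samples and applies average-linkage agglomeration on the
1 − Pearson-correlation distance. No algorithm is canonical for ordering
heatmap leaves; this pair is the common default for expression patterns.
Genes are sorted lexicographically before clustering so ties resolve
deterministically and the result is invariant to input order;
zero-variance genes, which have no defined correlation, are appended after
the clustered leaves. Sample ordination is a PCA of samples on centered
log~2~(TPM + 1), with each axis's sign fixed by requiring its
largest-magnitude gene loading to be positive, so coordinates reproduce
across platforms.

### Relative qPCR quantification

`ddct_fold_change()` implements the 2^−ΔΔCt^ method: ΔCt = Ct~target~ −
Ct~reference~ per condition (reference e.g. tubulin), ΔΔCt = ΔCt~sample~ −
ΔCt~control~, fold change = 2^−ΔΔCt^.

## Effector calling

### Peptide matching

A proteomic peptide supports a protein when it can be *fully aligned* to
it, implemented as exact contiguous substring occurrence in the protein
sequence. This is the reproducible desk-scale surrogate for filtering
search-engine output, where reported peptides are exact subsequences of
their matched entries. Two policies are explicit:

* **I/L equivalence** is off by default (search engines assign I vs L from
  the database context, so reported peptides are already disambiguated),
  but can be switched on, in which case both peptide and protein are
  rewritten to a common residue before matching.
* **Distinct peptides, not spectra**, count toward evidence: "three
  peptides" means three peptide species; spectral counts are retained in
  the evidence trail but never substitute for distinctness.

A peptide matching several proteins supports each of them — no
parsimony/razor assignment is applied, since none is defined for this
screen. This inflates support for close paralogs (relevant where a venom
family has many similar copies); `peptide_support()` reports the number of
shared peptides per protein so the effect is visible.

### Venom proteins and teratocyte effectors

A gene is called a **venom protein** iff it is venom-gland-expressed (its
group TPM passes the venom-gland N99 threshold) AND at least
`min_peptides` (default 3, boundary inclusive) distinct peptides fully
align to its protein. The **highly expressed** subset applies the Z test
over the venom-protein set's venom-gland expression. **Teratocyte
effectors** are the teratocyte-expressed N99 set; its significantly high
subset comes from the same Z test, and each gene carries a functional
class from keyword matching against free-text annotation
(priority digestion > ribosome > immunity, then other/unknown). The
keyword taxonomy ships as an editable list
(`default_function_keywords()`) because "digestion-related" and similar
labels have no enumerated vocabulary; the shipped lists cover the common
protease/glycosidase/lipase, ribosomal-machinery and immune-effector
descriptions.

These definitions give three nested sets by construction — highly
expressed VPs ⊆ venom proteins ⊆ VG-expressed genes — and monotone
evidence behavior (adding a peptide observation can only add calls;
raising `min_peptides` can only remove them). Both properties are tested.

## Gene-family expansion ranking

The comparative screen asks which functional domains the focal genome has
amplified beyond *any* comparator genome. For each domain, the expansion
score is

> score = focal copy count − max(comparator copy counts)

Using the maximum, not the mean, of comparators matches the question "more
than any other species" and is robust to how many distant comparators are
included. Ties are broken by the shrunken ratio (focal+1)/(max_other+1)
descending, then accession ascending, making the ranking total and
deterministic; domains absent from the focal species are retained with
score ≤ 0 so contractions remain visible. Outliers are flagged by robust
z: (score − median)/(1.4826·MAD) > 5 by default. Median/MAD is used
because expansion scores are heavy-tailed by construction; when MAD
degenerates to zero (most scores identical) the dispersion falls back to
the mean absolute deviation about the median, and if that is also zero no
outlier exists. The cutoff 5 is deliberately conservative — the screen is
meant to surface *extreme* families — and is configurable
(`outlier_cutoff`).

## Ecology statistics

Rates follow the standard formulas on the 0–100 scale: parasitism rate =
(1 − emerged host adults / total hosts) × 100; emergence rate = emerged
wasps / total hosts × 100; oviposition preference index =
(N₁ − N~x~)/(N₁ + N~x~) × 100 for eggs laid in 1-day-old (N₁) vs X-day-old
(N~x~) hosts. Replicates with N₁ + N~x~ = 0 carry no preference
information and are excluded with a warning rather than imputed as 0.
Condition summaries report replicate-mean rates with SEM = sd/√n (sample
sd; undefined for one replicate), and superparasitism **fold recovery** is
the ratio of super to mono replicate-mean rates — means of replicate
rates, not pooled host counts, matching how replicate-level assays are
presented.

The two nonparametric tests are authored here with enumeration-exact
small-sample paths, because p-values near the α boundary should not
depend on an approximation:

* **Wilcoxon signed rank** (two-sided, against μ): zeros dropped before
  ranking (Wilcoxon's convention; Pratt's rank-then-drop method available
  by flag), midranks for ties, exact p from the full distribution of the
  signed-rank statistic over all 2^n^ sign assignments when n ≤ 25 (the
  distribution is built by convolution over doubled midranks, which equals
  full enumeration), and otherwise a normal approximation with tie
  correction (Var = Σr²/4) and continuity correction.
* **Mann-Whitney U** (two-sided): exact by enumerating all
  C(n~A~+n~B~, n~A~) labelings when n~A~+n~B~ ≤ 16 with no ties, otherwise
  the tie-corrected, continuity-corrected normal approximation.

Both report which path produced the p-value in a `method_detail` field.
Two-sided exact p is 2·min(lower tail, upper tail), capped at 1. The test
suite checks the exact paths against independent brute-force enumeration
oracles, and the approximation paths against `stats::wilcox.test`, which
serves only as a cross-check, never as the implementation.

## The synthetic-data generator

The generator emulates each input's *structure* and the planted effects
the pipeline must recover; its defaults are the study conditions used
throughout the tests.

* **Expression**: an 18-sample panel (venom gland, teratocytes,
  ovipositor, antenna, larval and adult whole body; 3 replicates each);
  TPM values i.i.d. 2^N(4, 1)^ per cell; 30 venom-gland-specialized and 10
  teratocyte-specialized genes at fold 8 applied to their focal-tissue
  samples. The i.i.d. log-normal baseline is deliberately simple: the
  pipeline consumes TPM, so simulating at TPM level (not read counts)
  suffices. What it does **not** emulate: per-gene baseline heterogeneity,
  replicate correlation, compositional coupling between genes, or
  library-size artifacts. Passing recovery tests therefore demonstrates
  correctness of the screening logic under the stated model, not
  performance on real libraries, where specialization rankings are noisier.
* **Proteins and peptides**: random sequences (residue frequencies with
  K+R ≈ 11%, so tryptic peptides average ~9 residues) for the 20 secreted
  genes plus 480 decoys — the proteomic search space of a venom experiment
  is the candidate secretome, and the decoys exercise matching
  specificity. Tryptic digestion cleaves after K/R except before P with
  zero missed cleavages, so peptides exactly partition the protein (the
  conservation invariant); missed-cleavage emission would break the
  partition and is left as a config extension. Peptides of ≥ 6 residues (a
  practical MS detectability floor that also avoids trivially shared short
  peptides) are each detected with probability 0.8, making the
  distinct-peptide count per secreted protein Binomial.
* **Domain counts**: 200 domains × (1 focal + 13 comparator) species,
  counts i.i.d. Poisson(2), with the planted family set to exactly 29
  focal copies.
* **Assays**: host ages 1–4 days × mono/superparasitism, 6 replicates × 20
  hosts. The 4-day-old cell plants mono (0.30, 0.20) vs super (0.66, 0.64)
  parasitism/emergence probabilities — true recoveries of 2.2× and 3.2×.
  Within a replicate the two outcome counts are coupled per host (a host
  is parasitized with p~par~; a parasitized host yields a wasp with
  p~em~/p~par~; an unparasitized host ecloses), which preserves the
  Binomial margins for both counts while guaranteeing adults + wasps ≤
  hosts. Choice assays draw per-side egg totals Poisson(30) with a
  side-preference multiplier (1 = no bias, the planted default, matching
  the observation that females do not discriminate host age); dissection
  assays use egg-presence probabilities 0.85 (unparasitized hosts) vs 0.15
  (previously parasitized hosts).

Each output table draws from its own random stream derived from the master
seed, so changing the assay design never perturbs the expression draw;
identical configurations emit byte-identical files. Planted effect sizes
without an external anchor (fold 8, sd 1, detection 0.8, the choice
intensity) are generator choices exposed in the config, not claims about
the biology.

## Validation sizes and numerical choices

The automated checks run at these problem sizes, chosen to give tight
Monte-Carlo error while keeping the whole suite in minutes on one core:
1,000 random vectors for the N99 oracle; 100 random matrices for scale
invariance; 10,000 replicates × 200 candidates for Z-test calibration;
10,000 random protein/peptide pairs for the matching oracle; 100 simulated
studies for venom-call precision/recall; 1,000 tables for expansion
recovery; 500 + 100 random inputs for the exact-test oracles; 500
simulated assay sets for fold recovery. Determinism is enforced
end-to-end: a fixed seed reproduces every output byte-identically, ties
break lexicographically, and all orderings are total.

## Known limitations

* Peptide matching is exact substring occurrence: it cannot model
  modified residues, semi-tryptic peptides, or isobaric ambiguity beyond
  the I/L switch.
* The expansion screen ranks copy-number excess only; it is not a model of
  gene gain/loss rates and performs no orthology inference.
* The Z test assumes approximate normality of log-transformed expression
  within the candidate set; for very small candidate sets its plug-in
  standardization is conservative (see above).
* The generator's independence assumptions (genes, replicates, peptides)
  make recovery estimates optimistic relative to real data.
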
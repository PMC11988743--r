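---
title: "Methods: quantitative RNA-editing analysis with editlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative RNA-editing analysis with editlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`editlens` analyzes RNA editing from bulk RNA-seq in a two-group design
(control vs treatment, e.g. an endotoxin-challenged liver versus untreated
controls, three biological replicates per group). It does not call variants:
it consumes a GATK-style VCF of variant candidates with site-level QC
annotations (QD, FS, MQRankSum, ReadPosRankSum, MQ, SOR) and per-sample
AD/DP depths, together with a reference FASTA, GFF3 gene models, an
expression count matrix with gene lengths, a pathway membership table and a
sample design table.

The analysis chain is: site discovery (two-stage filter cascade) ->
editing-type / region / consequence annotation -> gene-level aggregation of
editing-supporting reads -> negative-binomial Wald differential testing
(editing and expression) -> unsupervised summaries (PCA of editing
frequencies, sample correlation, shared-event counts, frequency histograms)
-> nine-quadrant integration with enzyme-expression correlation ->
hypergeometric pathway over-representation.

# Site discovery

**Hard filters.** A candidate survives iff QD >= 2, FS <= 60,
MQRankSum >= -12.5, ReadPosRankSum >= -8, MQ >= 40, SOR <= 3, and its mean
across-sample depth lies within [cohort_mean/3, 3 * cohort_mean]. All
boundaries are inclusive on the passing side. Removals are attributed to the
first failing rule in a fixed order (QD, FS, MQRankSum, ReadPosRankSum, MQ,
SOR, depth window) so attribution counts are reproducible; the survivor set
itself is order-independent because the rules are conjunctive. A non-finite
metric removes the candidate under a distinct `missing_qc` reason — never a
silent pass.

Two deliberate choices here:

* The depth-window rule is stated ambiguously in common pipeline
  descriptions ("less than 1/3x and more than 3x"); we exclude both
  extremes, the standard outlier-depth exclusion. The cohort mean used by
  the window is stored on the filter output and reused on re-application,
  which makes the stage idempotent (otherwise each pass would recompute the
  mean over a shrinking cohort and keep nibbling at the edges).

* Base quality is interpreted as a single site-level scalar (mean quality of
  alt-supporting bases), since per-read detail is not present in a VCF.

**Editing filters.** A surviving site is retained iff its mean alt base
quality is >= 25, it is strictly biallelic (ref + one alt), and it is not in
an optional known-SNP list. A per-sample measurement is *valid* iff total
depth >= 5, alt depth >= 3, and editing frequency (alt/total) lies in
[0.10, 1.00]; the site is kept if at least one sample measurement is valid,
and invalid measurements are treated as missing (NA frequency), not as zero.
Group-level analyses that need per-group data (Venn membership, MAF) use
only valid measurements.

The known-SNP exclusion matters: a homozygous germline SNP has frequency
~1.0 in every sample, which *passes* the 10–100% window, so the frequency
window alone cannot remove it. The synthetic generator plants exactly such
confounders, and the tests run discovery with the simulator's truth SNP
list.

# Annotation

Editing types are named in transcript orientation: the genomic pair is
complemented for minus-strand genes, then A>G is reported as A-to-I and C>T
as C-to-U; the other ten mismatch classes keep their X-to-Y names. For sites
outside genes (unknown strand) the genomic pair is collapsed under the
convention A>G/T>C => A-to-I, C>T/G>A => C-to-U. We treat the occasionally
printed "T>A" variant of the A-to-I pair as a typo for T>C: T>A cannot
arise from adenosine deamination, and the complement of A>G is T>C.

Region labels follow ANNOVAR-style precedence: splicing > exonic >
UTR5/UTR3 > intronic > ncRNA exonic > ncRNA intronic > upstream >
downstream > intergenic, with defaults upstream/downstream = 1000 bp and
splice window = 2 nt (configurable; no published values exist for this
pipeline, so the ANNOVAR conventions are used). "Exonic" means
CDS-overlapping; in the summary table the UTR labels are folded into
"exonic" to match the usual category list, but they are kept distinct
internally. Coding consequences translate the affected codon before and
after the edit with the standard genetic code (no initiator-codon special
case — an internal CTG is Leu): synonymous, nonsynonymous, stopgain,
stoploss.

Sites overlapping several genes are assigned to the gene with the longest
CDS, ties broken lexicographically — deterministic and biased toward the
transcript most likely to carry coding consequences.

# Differential testing

Both differential editing (gene-level sums of valid alt-read depths) and
differential expression run through the same count engine, a documented
approximation to the DESeq2 workflow:

* **Normalization** — median-of-ratios size factors over features with
  all-positive counts, rescaled to geometric mean 1; library-size fallback
  (with a warning) when no such feature exists.
* **Dispersion** — per-feature method-of-moments on normalized counts,
  pooled within groups, then shrunk toward the across-feature mean with
  weight 0.7 and floored at 1e-8. The strong default shrinkage was chosen
  from a null-calibration study across count regimes: at n = 3 per group a
  per-feature moment estimate has ~2 effective degrees of freedom, and with
  weak shrinkage the Wald test's type-I error inflates to ~0.08; with the
  true dispersion plugged in it is nominal, so shrinkage strength is the
  controlling knob. The cost is bias when true dispersions vary widely
  across features; the end-to-end false-discovery check in the acceptance
  suite guards that trade-off.
* **Testing** — per-feature NB GLM (log link, group indicator, log
  size-factor offsets, fixed dispersion) fit by IRLS; log2FC is the group
  coefficient / ln 2; two-sided p from the Wald normal approximation;
  Benjamini–Hochberg adjustment over tested features. All-zero features are
  excluded. When one group is all zero the GLM coefficient diverges, so the
  reported log2FC is recomputed from normalized group means with +0.5
  pseudocount and flagged; no pseudocount enters the GLM itself.

Significance rules differ by analysis, mirroring the usual practice:
differential editing uses adjusted p < 0.05 only (no fold-change cutoff);
differential expression additionally requires |log2FC| >= 1.

Two properties worth stating precisely. Swapping group labels negates every
log2FC and preserves p-values exactly. Scaling all samples' counts by a
constant is absorbed by normalization to first order — log2FC is invariant
up to IRLS tolerance, but exact p-invariance is impossible in a true NB
model because deeper counts genuinely carry more information; the tests
assert the first-order property.

This engine intentionally omits DESeq2's fold-change shrinkage, independent
filtering and outlier replacement: the claims it supports are structural
(which genes pass the threshold), and the acceptance surface is recovery of
synthetic truth, not byte-equality with DESeq2.

# Unsupervised summaries

TPM is computed as length-normalized rates scaled to one million per sample.
Sample–sample Pearson correlations use log2(TPM + 1) by default. PCA of the
site-by-sample editing-frequency matrix keeps sites observed in at least 2
samples, imputes remaining missing values with the per-site mean (zero
imputation would conflate missingness with low editing), centers, and
decomposes by SVD with a deterministic sign convention
(largest-magnitude loading positive). Shared-event (Venn) counts key sites
by (contig, pos, ref, alt); an event belongs to a group if any sample of
that group has a valid measurement — a definition the source analyses leave
implicit.

# Integration and enrichment

The nine-quadrant classification crosses the editing state (down/ns/up)
with the expression state (down/ns/up). A state is "up" iff log2FC exceeds
the axis threshold and the gene is BH-significant (both configurable;
defaults: editing axis threshold 0, expression axis 1). Quadrants are
indexed 1–9 row-major from the bottom-left (rows = editing, bottom to top);
candidates are quadrant 9, the coordinated up/up corner. "MAF" follows the
field's (mis)usage: the mean of a gene's valid per-site editing frequencies
in a sample, not population minor-allele frequency. Enzyme–target
correlation is plain Pearson over paired non-missing samples (>= 3), with
the two-sided t-based p-value; both groups are pooled, which is what gives
the correlation its dynamic range in an induction design.

Pathway enrichment uses the upper-tail hypergeometric probability
P = 1 − Σ_{i=0}^{m−1} C(M,i)·C(N−M,n−i)/C(N,n), evaluated in log space,
with N the annotated universe (union of pathway gene sets by default — an
`all_genes` mode accepts an explicit universe, since it is genuinely
ambiguous whether "annotated genes" should mean genome-wide or expressed),
n the candidates inside it, M the pathway's genes, m their intersection.
BH-adjusted; enriched iff FDR <= 0.05. m = 0 gives P = 1 exactly.

# The synthetic-data generator

The generator emits a complete study — reference FASTA, GFF3, VCF v4.2,
counts, lengths, pathways, design, truth tables — with the statistical
structure the analysis assumes:

* coverage and expression counts are negative-binomial (coverage dispersion
  0.15; expression follows the canonical mean–dispersion trend
  alpha(mu) = 0.01 + 3/mu, the shape every mainstream RNA-seq count
  simulator uses — a flat dispersion would make highly expressed genes
  unrealistically noisy);
* per-site editing frequencies are uniform on [0.10, 0.90] (no published
  distribution exists for real editing frequencies beyond the filter
  window, so the broad uniform is an explicit free choice, flagged in the
  config);
* 60% A-to-I / 20% C-to-U / 20% other mismatches among true editing sites,
  strand-adjusted — roughly the "~80% deamination" landscape;
* 10% of genes differentially edited at editing-count log2FC 2 and 10%
  differentially expressed at log2FC 2, directions random. Up-shifted
  editing frequencies are drawn from the feasible sub-range
  [0.10, clamp/2^lfc] so the stated effect is *realized exactly* rather
  than silently censored at the frequency ceiling;
* germline-SNP confounders at frequency 0.5 or 1.0 in every sample, at 10%
  of candidate sites;
* independent per-rule QC corruption at rate 0.02 (so each removal is
  attributable to exactly one rule in tests);
* one designated editing-enzyme gene, always induced, with a fixed high
  baseline mean (deaminases are robustly expressed in liver; this also
  keeps its TPM measurement error small), whose scaled per-sample
  expression determines target-gene editing frequencies linearly
  (intercept 0.10, slope 0.30, Gaussian noise sd 0.02).

What the generator does **not** emulate: read-level artifacts (alignment
error, splice-aware placement, strand bias that actually correlates with
FS), positional clustering of editing sites (Alu-like repeats), correlated
QC-metric failure, multi-factor designs, and any relationship between site
coverage and gene expression. A green end-to-end test therefore establishes
that the statistics are implemented correctly and recover truth under the
assumed model — not that the filters would behave identically on real
alignments.

# Numerical choices and degenerate inputs

* Editing frequency at zero depth is NA (undefined), never 0.
* IRLS: max 50 iterations, tolerance 1e-8, coefficients capped at ±30 on
  the natural-log scale; non-convergence is flagged, p left missing.
* Hypergeometric P in log space with log-sum-exp; agrees with direct
  evaluation to 1e-10 relative at N = 1000.
* PCA of identical samples returns all-zero variance percentages rather
  than 0/0.
* Empty candidate sets, empty pathway intersections and zero-gene
  simulations return empty structures, not errors.
* All pipeline randomness flows from the single config seed through fixed
  per-stage substreams; reruns are byte-identical, and the run manifest
  records input MD5 checksums (and no timestamps, so the manifest itself is
  reproducible).

# Known limitations

Site-level differential testing is deliberately out of scope (the
gene-level procedure is the specified one). The engine is a calibrated
approximation, not DESeq2. Strand for intergenic sites is unknown and the
collapsed editing class there relies on the stated convention. The
enrichment universe defaults to annotated-only and can materially change
results; use `all_genes` with an expressed-gene list when that is the
intended null.
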
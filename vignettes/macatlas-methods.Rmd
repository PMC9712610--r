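---
title: "Copy-number calibration and atlas analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calibration and atlas analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macatlas)
```

`macatlas` turns paired, arbitrary-scale proteome (MS intensity or iBAQ)
and transcriptome (FPKM) tables from a panel of sorted cell populations
into absolute copies per cell, and runs the comparative analyses that
follow: layer concordance, co-expression modules, transcription-factor
specificity and maintenance calls, tissue-to-cell crosstalk networks, and
differential expression. This vignette explains the models behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## Absolute quantification

**iBAQ.** MS intensity grows with both protein amount and protein size
(bigger proteins yield more peptides). Dividing the summed intensity by
the number of *theoretical* tryptic peptides — fully tryptic fragments,
cleavage C-terminal to K/R suppressed before proline, zero missed
cleavages, length 7–30 residues — gives a quantity proportional to molar
amount. The digestion convention is the canonical one for iBAQ; only the
length window is a biological constraint (peptides outside it are rarely
observed), the rest is the standard in-silico trypsin model.

**Proteomic ruler.** Absolute scaling needs an internal anchor. A
diploid cell carries a fixed DNA mass (`dna_mass_per_cell`, default
5.5 pg for mouse), and chromatin packages that DNA with an approximately
equal mass of histones. The summed histone signal therefore corresponds
to a known mass, which converts every protein's signal to mass and — via
molecular weight and Avogadro's number — to copies per cell:

* mole-proportional signal (iBAQ, the default):
  `copies_i = m_DNA · N_A · s_i / Σ_h (s_h · MW_h)`;
* mass-proportional signal (raw intensity):
  `mass_i = m_DNA · s_i / Σ_h s_h`, `copies_i = mass_i · N_A / MW_i`.

Both forms are invariant to any per-sample global rescaling of the
signal; the test suite asserts this under ten random scalings rather than
assuming it. The histone mass identity
`Σ_h copies_h · MW_h / N_A = m_DNA` holds by construction and is checked
to `1e-9` relative.

**RNA ruler.** Ribosomes pair rRNA and ribosomal protein roughly 1:1 by
mass, and rRNA is about 80% of total RNA. The ribosome count per cell is
estimated as the *median* ribosomal-protein copy number — the median, not
the sum, because paralog dropout otherwise deflates the estimate; the
1:1 stoichiometry makes any single ribosomal protein an estimator of the
ribosome count, and the median is the robust aggregate. From the
ribosome count: total RNA mass, then the mRNA mass fraction
(`mrna_mass_fraction_of_total_rna`, default 0.04) and mean mRNA molar
mass (default 340 g/mol × 1800 nt) give the total mRNA molecule count
`N_mRNA`. FPKM is length-normalized and hence molar-proportional, so
copies are FPKM shares of `N_mRNA`; the output sums to `N_mRNA` exactly
per sample. Whether the anchor is expressed in molecules or mass is a
modelling choice; the parameterization here is mass-based and every
constant is exposed in `ruler_params()`.

## Concordance between layers

Across-gene correlations use Spearman rank correlation of log10
replicate-mean copies over genes co-detected in a population. Gene-wise
correlations across populations are the harder case: at `n = 12`
populations the usual large-sample approximations to the null of
Spearman's rho are poor, so the package computes the *exact* permutation
null. Enumerating `12! ≈ 4.8e8` permutations directly is infeasible;
instead the distribution of `T = Σ i·π(i)` over permutations is built by
a bitmask dynamic program (counts fit exactly in doubles), from which the
rho null follows. The two-sided exact p-value of `|rho| = 0.57` at
`n = 12` is ≈ 0.056 — the reason an operating rule of `|r| > 0.57` with
`p < 0.05` is self-consistent at this panel size. The null is cached per
`n` (2–14); ties fall back to the asymptotic t approximation.

Never-detected features (genes seen in one layer, never in the other)
are classified into four regions by mean log10 expression in the *other*
layer and identification frequency, with automatic cutoffs at the median
expression and half the sample count. Ties count as "high" on both axes;
the partition is total and deterministic. Fixed cutoffs (for instance
1.6 log10 copies, or half the number of MS experiments) can be set
explicitly instead of the automatic ones.

## Co-expression modules

The network stage follows the weighted-correlation-network recipe:
adjacency `a_ij = |cor_ij|^β` (unsigned by default, a signed variant is
available), topological overlap
`t_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
average-linkage hierarchical clustering of `1 − TOM`, a static cut, and a
minimum module size of 30. `β` is chosen as the smallest candidate whose
binned log-log connectivity fit reaches R² = 0.85 (signed, negative-slope
convention), else the argmax with a warning.

Numerical choices that matter:

* Correlations are computed on log10 copies with **pairwise-complete**
  observations, and genes present in under 25% of samples are excluded.
  Zero-filling missing values before correlating would place log10 ≈ 7
  dropout outliers at 0 and let detection patterns, not expression,
  drive the network.
* The static cut sits at a fixed fraction (default 0.995) of the maximum
  merge height. A static cut alone leaves one failure mode: mutually
  uncorrelated background genes coalesce loosely just under the top of
  the tree and would form a single giant pseudo-module. A branch
  therefore only counts as a module if its *median internal dissimilarity
  is below the cut height* — real modules are far tighter than the cut,
  the diffuse background branch never is, and it stays unassigned (the
  analogue of the grey module in dynamic tree-cutting).
* Eigengenes are the first principal component of the module's
  standardized expression (missing values at the standardized mean),
  unit-norm, signed to correlate positively with members on average.

Module–trait statistics correlate each eigengene with one indicator
trait per population; each module is matched to its best population and
dropped below `cor_min = 0.5`. Gene significance (GS, correlation with
the matched trait) and module membership (MM, correlation with the
eigengene) filter members at GS ≥ 0.6 and MM ≥ 0.5.

## TF specificity and maintenance

CSPS is the relative entropy, in bits, of a gene's fractional expression
across the `P` populations against the uniform distribution: 0 when
uniform, `log2 P` (≈ 3.585 at `P = 12`) when confined to one population,
with `0·log 0 = 0`. Identical expression everywhere returns an exact 0
(the normalization's rounding residue is suppressed in that degenerate
case). A *specific* TF exceeds 5× the median of its expression over the
**other** populations. Two conventions are defensible here — the median
over the other populations or over all of them; the leave-one-out form
matches the specificity intent and is the default, and
`include_self = TRUE` provides the other.
Non-detections count as zero in the median; a TF positive against an
all-zero background is specific, zero against zero is not; the focal
mean requires detection in at least two replicates.

A *cell-type-maintenance* TF (ctmTF) additionally shows coordinated
regulon activity: per-gene z-scores of log10 population-mean copies
across populations, averaged over the TF's detected targets, must exceed
the maximum of `B = 1000` draws of equally many proteins sampled
uniformly from the quantified proteome (not from TFs only — the null is
"any random gene set of this size"). The exceedance rule makes the
nominal per-test call probability `1/(B+1)`; the empirical p-value
`(1 + #{null ≥ obs})/(B + 1)` is reported alongside. Calls are
deterministic given `(seed, B)`; sd-zero genes are dropped from scoring.

## Crosstalk networks

For one tissue–cell pair, the four tiers are assembled in order: ligands
at ≥ 1.5× their cross-tissue average (arithmetic mean including the
focal tissue, matching the "average level in the eight studied tissues"
wording; leave-one-out by flag) → receptors paired in the
ligand–receptor table and detected in the cell (≥ 2 replicates) →
pathways that contain such a receptor, contain a cell-type-specific TF
(1.5× the cross-population average), and are enriched for detected nodes
— hypergeometric upper tail over the cell's quantified proteome as
background, pathway members minus ligand-tier genes as the marked set,
raw p < 0.05 (no multiple-testing correction by default, a BH option
exists) → the specific TFs' regulon targets detected in the cell. Edges
carry their tier and, for receptor→TF edges, the pathway and its
p-value; the link count is the edge count. Every edge is reachable from
a ligand by construction, and an absent ligand tier yields an empty
network rather than an error.

## Differential expression, clustering, PCA, gene-set scores

The DEP caller is the dual rule: fold change ≥ 5 on linear group means
with a two-sided t-test p < 0.05 on log10 copies (variance-stabilized
scale for the test, linear scale for the fold change; the choice is
switchable), or — where a fold change cannot be formed — detection in
every replicate of one group at CV ≤ 0.6 and in none of the other. Raw
p-values gate the calls (the fold-change gate alone makes the caller
conservative under the null, which the suite verifies by simulation); a
BH column is emitted for transparency. Clustering and PCA use
`log10(x + 1)` with missing set to 0 — distances need complete vectors —
and this contract is *never* applied to testing. With heavy
abundance-dependent missingness the zero-filled distances are dominated
by detection patterns rather than expression; the replicate-co-clustering
checks therefore run at complete detection, and users clustering sparse
matrices should filter to well-detected genes first. Gene-set scores sum
copies over detected members per sample ("total expression"), with a
companion Pearson correlation of two sets' population means.

## The synthetic atlas

`generate_atlas()` draws the full input bundle plus ground truth. Its
defaults are the study conditions the pipeline targets: 12 populations ×
3 replicates per layer, 2000 genes, protein baselines uniform over 7
decades of log10 copies (the per-population abundance law is not
dictated by the data; uniform-in-log is this package's choice), mRNA
copies obtained by compressing the protein log-scale onto 5 decades and
shifting down by the 8000-fold mean protein/mRNA ratio plus lognormal
scatter, replicate noise at CV 0.2, and logistic detection in log10
abundance (protein midpoint 3.5, slope 1.2 — about 75–85% of
gene–population entries detected in ≥ 2 replicates, emulating the
roughly two-thirds per-population coverage typical of deep label-free
atlases; transcript midpoint 0). Planted structure: 8 modules of 60
genes (4× up-shift in a home population), one specific TF per population
(10×) with a 20-gene regulon (5×), histones carrying exactly
`dna_mass_per_cell` of mass (making the ruler invertible), 80 ribosomal
proteins at a fixed 3e6 copies, 8 tissues × 3 ligands (8× home-tissue
shift on a shared per-gene baseline) with paired receptors, and per
tissue one active pathway (its receptor, the paired population's TF, 40
well-detected intermediates — a typical signalling-pathway size, and
large enough that full detection is unambiguous enrichment against a
~80%-detected background) plus one decoy pathway without a specific TF.

Deliberate idealizations, and what they imply for the tests:

* Theoretical peptide counts are tied proportionally to molecular weight
  (2 kg/mol per peptide), so iBAQ is *exactly* molar and both ruler
  signal kinds invert exactly in the noiseless limit. Real proteins
  scatter around that proportionality; on real data the two signal
  kinds agree only approximately (the suite asserts log-log r > 0.9
  under noise, mirroring the strong but imperfect agreement seen in
  practice).
* Planted module/TF/regulon genes draw baselines from the upper
  abundance range ([4, 8] log10; receptors from [6, 8]): regulated,
  identity-defining proteins are detectable ones, and ground truth that
  dropout erases would be untestable. Consequently the recovery tests
  say nothing about modules of barely-detectable proteins.
* Module genes and the same population's TF + regulon targets share one
  planted profile and are genuinely co-expressed; the ground truth
  records this combined partition (`truth$coexpression`) alongside the
  raw module membership, and recovery is judged against it.
* Replicate noise is a single lognormal CV; there is no shared batch
  structure, no peptide-level variation, no isoform ambiguity, and
  missingness is independent across replicates given abundance. Passing
  recovery tests therefore demonstrate the *algorithms* under the
  stated generative model, not robustness to correlated artefacts of
  real MS data.

Scale of the shipped checks: the default fixture is 2000 genes ×
12 populations × 3 replicates, module detection runs in a few seconds,
and ctmTF calling uses B = 1000 draws; the full suite completes in well
under a minute on one core.

## Degenerate inputs and tie rules, in one place

Duplicate gene or sample identifiers, negative values, all-missing
columns, histone-free samples, missing molecular weights, sub-minimum
ribosomal detection, zero total FPKM, overlapping DEP groups, constant
matrices (PCA), and all-zero CSPS vectors are hard errors that name the
offender. Quadrant ties count as high; a gene exactly at 5× (or 1.5×)
the reference passes; TFs absent from the matrix and regulons below the
size floor are skipped with a message, not an error; an empty gene set
for quadrant classification returns an empty table.

## Known limitations

Gene identity is by symbol (no identifier mapping layer); species
ortholog mapping for cross-species ligand–receptor priors is out of
scope; the static tree cut is a documented simplification of dynamic
tree-cutting; the exact Spearman null covers `n ≤ 14`; and the
crosstalk tiers assume the priors (regulons, pathways, LR pairs) share
the expression tables' gene namespace.
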
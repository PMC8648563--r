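---
title: "Microenvironment-restricted cell-cell communication: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironment-restricted cell-cell communication: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clustered single-cell RNA-seq gives, for every cell type in a tissue, a
transcriptome-wide expression profile. Cell-cell communication inference asks
which curated ligand-receptor pairs could plausibly mediate signaling between
two cell types: the ligand must be made by the sender, the receptor by the
receiver. Two practical complications motivate this package's design.

First, **tissue context**. Two cell types that never share a location (or a
time window — for instance different phases of a hormonal cycle) cannot
signal through a contact- or gradient-limited pathway, no matter how well
their transcriptomes complement each other. `envcci` therefore takes a
user-declared set of *microenvironments* — named groups of cell types that
co-occur in space and time, such as the lumenal, functional and basal layers
of a glandular mucosa, optionally split per cycle phase — and only tests
cluster pairs that share one. Pairs shared by several microenvironments are
reported once per microenvironment, because downstream interpretation is
per-niche.

Second, **multimeric receptors and ligands**. Many receptors (WNT receptors
formed by a Frizzled and an LRP co-receptor, NOTCH, integrins, ...) are
functional only as heteromeric complexes. A complex is treated as a single
partner whose expression is limited by its least-expressed subunit: both the
mean expression and the fraction of cells expressing a complex are the
minimum over its subunits. This "min rule" is the standard convention in the
pipeline family this package belongs to; it encodes that the limiting
subunit governs complex availability, and it makes complex-level statistics
scale-consistent with gene-level ones.

# The relevance call

For an interaction with partners $A$ (placed on cluster $a$) and $B$ (placed
on cluster $b$), the interaction is *relevant* iff

1. **Expression**: every member gene of $A$ is expressed (raw count > 0) in
   at least a fraction `min_frac` of cluster $a$'s cells, and likewise $B$
   in cluster $b$. The threshold is inclusive ("at least 10%") and defaults
   to `min_frac = 0.10`.
2. **Differential support**: at least one member gene of either partner is a
   differentially expressed gene — with BH-adjusted $q <$ `max_fdr` and
   log2 fold change $>$ `min_log2_fc` in its one-vs-rest comparison — in at
   least one of the two clusters of the pair.

Both criteria are deterministic given the cluster summary and the DE table,
so the call itself carries no p-value; the statistical machinery sits in the
DE test. Two threshold presets are provided because both appear in practice:
the default (`min_log2_fc = 0.02`, `max_fdr = 0.005`) and a stricter-FDR
variant (`preset = "strict_fdr"`: any positive log fold change,
`max_fdr = 0.001`) that matches how binary interaction tables are often
published. Neither is silently preferred; the preset is an explicit argument
and is recorded in the run manifest. "Log fold change" is computed in base 2;
the threshold 0.02 is so close to zero that the base matters little (a
config-free choice we make explicit here rather than expose a switch for).

Every interaction is evaluated in both orientations (partner $A$ on cluster
$a$ and on cluster $b$) for every *ordered* eligible pair, since autocrine
and reciprocal signaling are distinct biological readouts. The binary
interaction-by-cluster-pair matrix collapses orientations: an entry is 1
when any orientation is relevant.

# Depth-stratified Wilcoxon DE

One-vs-rest rank tests on droplet data are confounded by sequencing depth:
a deeper cell detects more genes, so with per-cell normalization the zero
pattern — which dominates ranks for most genes — still tracks depth. A
cluster that happens to be sequenced deeper looks globally "upregulated",
inflating false positives by several fold (the package's own calibration
simulation shows naive false-positive rates of 0.3 at $\alpha = 0.05$ under
a 2x depth confound).

The implemented remedy: cells in the analysis set are ranked by total
counts and partitioned into four quartile strata (independent of donor;
ties broken by stable input order; block sizes differ by at most one). The
Wilcoxon rank-sum Z — normal approximation with tie-corrected variance, no
continuity correction — is computed within each stratum, and the strata are
combined with a weighted Stouffer statistic

$$Z = \frac{\sum_s w_s Z_s}{\sqrt{\sum_s w_s^2}}, \qquad w_s = \sqrt{n_s},$$

with $n_s$ the stratum size. The $\sqrt{n_s}$ weighting accounts for
unequal in/out splits across quartiles; an unweighted mode
(`weighting = "unweighted"`) is available since the combination rule is a
genuinely open choice. Two-sided p-values come from the standard normal and
are BH-adjusted across genes within each one-vs-rest comparison. The
positive-fold-change requirement is applied downstream at relevance
calling, not inside the test.

Degenerate cases are resolved conservatively: a stratum where either group
is empty, or where the gene is constant (zero rank variance), carries no
information and is dropped from the combination; a gene with no
contributing stratum gets $Z = 0$, $p = 1$. The log2 fold change uses a
$\varepsilon = 10^{-9}$ pseudocount on normalized means, small enough not
to distort any nonzero mean at the counts-per-10,000 scale.

The out-group of the one-vs-rest comparison defaults to all supplied cells;
a `universe` argument restricts the analysis set (and the quartile
computation) to a lineage subset when the comparison should be local.

# Normalization

Partner means are computed on library-normalized, non-log values (counts
per 10,000). Non-log means keep the min rule scale-consistent — the minimum
of log means is not the log of any meaningful quantity — and avoid an
arbitrary pseudocount. The "expressed" indicator at the cell level is raw
count > 0, the simplest reproducible definition. Both choices are open
conventions rather than derivable facts, which is why the normalization
scale is a parameter and both matrices (raw and normalized) flow through
the summary stage.

# Permutation null

An optional cluster-label permutation test scores each (interaction,
ordered pair) as the mean of the two partner-level mean expressions
(complexes via the min rule) and compares it with scores recomputed under
uniform reshuffling of all analyzed cells' cluster labels (sizes
preserved). The p-value is the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, bounded in
$[1/(n+1), 1]$, with $n = 1000$ permutations by default. Labels are
shuffled across all analyzed cells, not within microenvironments, mirroring
the convention of the pipeline family; a within-environment variant would
test a subtly different null and is deliberately not the default. The
restriction to microenvironment-eligible pairs applies to what is *scored*,
not to how the null is built. These p-values are diagnostics for the
magnitude of cluster-pair specificity; the relevance call does not consume
them, and no FDR is applied across them.

# The synthetic test bed

All validation runs on seeded synthetic data, because the method's inputs
(clustered counts, a curated database, membership declarations) are
exactly emulatable. Counts for gene $g$ in cell $c$ are negative binomial
with mean $s_c \mu_g f_{k(c),g}$ and dispersion $\phi$
($\mathrm{Var} = m + \phi m^2$), where $s_c$ is log-normal (sdlog
`libsize_sigma`) times a per-cluster depth multiplier, and $f$ carries the
planted signal: markers multiply one gene's mean in one cluster; planted
ligand-receptor pairs multiply ligand members in the sender and receptor
members in the receiver. Decoy interactions among untouched baseline genes
(5 per planted pair by default) make specificity measurable.

Default conditions are chosen to resemble droplet data: baseline mean 1
count per gene (so a 2,000-gene panel yields 2,000–4,000 total counts per
cell), dispersion 0.5, `libsize_sigma = 0.35`, planted effects 4-fold. The
calibration dataset uses two clusters of 300 cells, 2,000 genes and a 2x
depth ratio; marker recovery uses 200 cells per cluster over 20 replicates;
interaction recovery runs the full pipeline 10 times with three planted
pairs (one with a two-subunit receptor) against 15 decoys; the permutation
calibration uses 500 null interactions and 1,000 permutations. These sizes
are the package's study conditions, fixed in the acceptance tests and the
acceptance script.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: ambient RNA, doublets, donor or batch effects
(donor labels are assigned but carry no signal), gene-gene correlation,
zero inflation beyond the NB, and real spatial structure (microenvironment
declarations are taken as given, not derived from coordinates). On real
tissue the membership table is the analyst's responsibility, typically
derived from spatial deconvolution or histology.

# Numerical and design notes

- Database identity is exact string match against matrix gene names; no
  symbol aliasing. Aliasing would silently depend on an external resource;
  exactness is auditable and failures are loud (interactions with absent
  member genes are skipped with a warning, not errors).
- Curation records (add / replace / remove rows mirroring the complex and
  interaction schemas) apply in row order, later rows winning, and the
  result is re-validated — a patch-file semantic.
- Depth ties are broken by stable input order, making stratification and
  hence the whole DE table deterministic.
- Eligible pairs include self-pairs (autocrine signaling); nothing in the
  relevance criteria excludes them.
- The subunit count of a complex is unbounded below at 2; the CSV schema
  blank-pads `subunit_1..subunit_N`.
- All tabular outputs are TSV with doubles at 6 significant digits, so
  reruns with the same config and seed are byte-identical; the JSON
  manifest records thresholds, seed, database version and input MD5
  digests.

# Limitations

The relevance call is a screen, not a test of signaling activity: it says
an interaction is transcriptionally plausible in a niche, with differential
support on at least one side. It inherits the clustering (misassigned cells
blur fractions), the curation (an interaction absent from the database is
invisible), and the membership table (a wrong microenvironment declaration
silently removes or admits pairs). The stratified Wilcoxon controls the
depth confound between clusters but not other technical covariates, and
quartile stratification assumes four strata are enough to make depth
approximately constant within a stratum — reasonable at hundreds of cells,
coarse below that.
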
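---
title: "Methods: network-based miRNA biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based miRNA biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmark)
```

`netmark` screens candidate diagnostic miRNA biomarkers by combining
two-group differential expression with the structure of the miRNA–mRNA
regulatory network. This vignette explains the model behind each stage,
the tunable parameters, the synthetic-data generator used for
validation, and the numerical and design choices that were genuinely
open.

## Differential expression: the moderated t

Both assays are analysed on the log2 scale. Expression values are first
quantile-normalized (`quantile_normalize()`): every sample is forced onto
the common distribution given by the across-sample means of the per-rank
values, with ties receiving the mean over their rank span. Quantile
normalization is the default for single-channel microarray data and the
downstream structural statistics are invariant to any monotone common
rescaling, so the choice (`normalization = "quantile"` vs `"none"`)
matters only for the differential calls.

Per feature $g$, with group sizes $n_1, n_2$, the pooled variance
$s_g^2$ has residual df $d_g = n_1 + n_2 - 2$. Treating the true
variances as drawn from a scaled inverse-chisquare prior with df $d_0$
and scale $s_0^2$, the posterior (shrunken) variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic
$t_g = \widehat{\Delta}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ is
referred to a $t$ distribution on $d_0 + d_g$ df (normal when
$d_0 = \infty$). The hyperparameters are fitted by method of moments on
$z_g = \log s_g^2$: the excess of $\mathrm{var}(z)$ over the sampling
contribution $\psi'(d_g/2)$ identifies $\psi'(d_0/2)$, inverted by
Newton iteration (tolerance $10^{-8}$, at most 50 steps, $d_0$ treated
as infinite above $10^6$); $s_0^2$ follows from $\mathrm{mean}(z)$
corrected by the digamma terms. Degenerate inputs: variances are floored
at $10^{-12}$ before taking logs, and an exactly constant variance
vector returns $(d_0 = \infty,\ s_0^2 = s^2)$ directly. With $d_0 = 0$
the statistic reduces to the ordinary pooled two-sample t (a tested
identity), and as $d_0 \to \infty$ every $\tilde s_g^2 \to s_0^2$
monotonically.

Significance uses Benjamini–Hochberg adjustment with a strict
`p_adj < alpha` cut (default `alpha = 0.05`). Two notes: BH is *not*
idempotent — re-adjusting adjusted values can increase them (e.g.
$p = (0.05, 0.45)$ adjusts to $(0.10, 0.45)$, and re-adjusting gives
$(0.20, 0.45)$) — it is order-preserving and dominating, which is what
the tests assert. A `paired` option computes within-pair differences and
a one-sample moderated t; the default contrast is unpaired, the minimal
reading for data whose pairing structure is not recorded in the design
table.

## The condition-specific network and the structural indices

The reference interactome is a user-supplied two-column edge list, never
a bundled database; gene symbols are upper-cased and miRNA ids
normalized to "miR-" style with -3p/-5p arms preserved (arm identity is
biologically meaningful and is never stripped from data). The
*condition-specific network* keeps reference edges whose miRNA is
differentially expressed; by default (`restrict_genes = TRUE`) the gene
must be differentially expressed too, matching the dysregulated-network
framing in which both sides of an edge carry disease signal. Dropping
the gene restriction is a flag. Differential miRNAs whose edges are all
filtered away stay in the network with empty target sets and score 0 on
both indices — the empty-target convention is pinned by a published
panel entry with NOG 0 and TFP 0.

For each miRNA $m$ with target set $T(m)$ in the condition network:

- **NOG**: $|\{g \in T(m) : \deg_{in}(g) = 1\}|$ — targets no other
  miRNA of the same network reaches. Uniqueness is defined *within the
  condition network*, not the full reference: the index measures
  non-substitutability among the dysregulated regulators. Two exact
  identities make it cheap to verify: $\sum_m \mathrm{NOG}(m)$ equals the
  number of in-degree-1 genes, and removing a miRNA can only keep or
  raise the others' NOG.
- **TFP**: $|T(m) \cap \mathrm{TF}| / |T(m)|$, 0 for empty $T(m)$.
  Reported to 2 decimals, rounding halves away from zero — the
  convention forced by a published panel value of 0.13 for a 1/8
  fraction. TFP depends only on the miRNA's own edges.

## The signed-rank screen

Each miRNA's NOG (and, separately, TFP) is compared against the
background of the same index over the other network miRNAs
(leave-one-out by default; `background = "all"` includes the candidate)
with a one-sample Wilcoxon signed-rank test on the differences
(candidate − background), alternative "candidate greater". Zero
differences are dropped (classic Wilcoxon; a Pratt option keeps them in
the ranking), ties get average ranks. The p-value is exact — full
enumeration of the $2^n$ sign assignments via a dynamic program over
rank sums — for tie-free backgrounds of $n \le 12$, and otherwise uses
the normal approximation with tie-corrected variance and a continuity
correction. A candidate call requires *both* indices below `alpha`
(default 0.05, raw p, no correction across miRNAs).

This formulation depends only on the candidate's value and the fixed
background, so miRNAs with equal index values receive identical
p-values — a property the published candidate tables exhibit and that a
pairing-dependent formulation would violate. Its statistical character
should be understood clearly: because all $n$ differences share the one
candidate draw, they are strongly dependent, and under an exchangeable
null the per-index call rate is far above `alpha` (measured 0.28–0.43
for backgrounds of 10–99). The screen is therefore a *ranking/selection
device* — it asks how far a miRNA sits in the upper tail of the
network-wide distribution — not a calibrated hypothesis test; only
upper-tail candidates are ever called, and requiring both indices
tightens selection further. The extremely small p-values such screens
print on ~100-miRNA networks are a direct consequence.

Known-biomarker annotation matches a curated reported-miRNA list;
entries without an arm suffix match any arm (a reported "miR-145"
matches the candidate "miR-145-5p"), entries with an arm match exactly.

## Enrichment

Pooled targets of all candidate miRNAs form one query (per the pooled
phrasing of the validation analyses this stage replaces; per-miRNA
queries can be run by calling `enrich_gene_sets()` directly). Each gene
set is tested with the hypergeometric upper tail $P(X \ge k)$ —
over-representation convention, $k$ included — against a universe that
defaults to all genes of the reference network (a transparent,
reproducible choice; online annotation services use opaque universes,
which is why catalogue-specific enrichment tables are not reproduction
targets). BH adjustment runs across the collection; records sort by
adjusted p then set name, so top-k reports are deterministic under ties.

## The synthetic-data generator

The generator emulates the study conditions the pipeline is meant for:
a miRNA assay of 47 case / 47 control samples and an mRNA assay of
33 / 32 (typical tissue-microarray cohort sizes), feature universes of
150 miRNAs / 2000 genes with differential fractions 0.6 / 0.17 (so the
differential sets land near the ~90 miRNA / ~330 gene scale such
studies report), log2 effect size 2 with residual SD 0.5, baseline 8
log-units (arbitrary: every downstream statistic is shift-invariant),
Poisson out-degree with mean 8 (published candidate target lists span
1–15), and a 15% TF share (300/2000), the typical catalogue fraction.
Where the emulated studies state no value these are one-time
calibration choices, documented here, not facts about any dataset.

Planted biomarkers (the first `n_planted_biomarkers` miRNA ids, a
deterministic choice that keeps the artifact RNG streams independent)
receive `planted_unique_targets` genes reserved so no other miRNA can
draw them — in-degree 1 *by construction*, verifiable by exhaustive
tally — plus enough forced TF flags to put their target TF fraction at
or above `planted_tf_frac`. Exactly `n_tfs` genes carry TF flags; if
the planted requirements exceed `n_tfs` the configuration is rejected
as infeasible rather than silently adjusted. The differential ground
truth always contains the planted miRNAs, and on the gene side every
target of a planted miRNA: without the latter the default gene
restriction would sever planted miRNAs from the condition network and
end-to-end recovery would measure the gene-side filter, not the screen.
Each artifact (network, miRNA matrix, mRNA matrix, gene sets) draws
from its own sub-seed of the master seed, so regenerating one does not
perturb the others; identical configurations give byte-identical
outputs.

What the generator does *not* emulate: probe-level effects, batch
structure, paired-sample correlation, mRNA–miRNA expression coupling
(target mRNA levels are simulated independently of their regulators),
and realistic gene-set overlap structure. Passing tests therefore show
that the *procedure* recovers planted structure under clean two-group
Gaussian noise — not that any particular biological dataset would yield
the same candidates.

## Validation problem sizes

The test suite works at sizes chosen to make the Monte-Carlo checks
sharp but quick: the global-null type-I check pools 20 seeds of 2000
features at 10+10 samples; signed-rank exactness enumerates all sign
vectors up to $n = 10$; hypergeometric tails are checked against direct
pmf summation on 100 random parameterizations; NOG conservation on 100
random networks; and end-to-end planted-biomarker recovery runs 50
seeded studies on 100-miRNA / 1000-gene networks, requiring all planted
miRNAs to be called in at least 90% of runs.

## Known limitations

- The screen's p-values are selection scores, not calibrated error
  rates (above); comparing them across networks of different size is
  not meaningful.
- NOG depends on which miRNAs enter the condition network, so it is
  only comparable within one run's network.
- The TF catalogue and reference interactome are inputs; results are
  conditional on their coverage.
- Expression loading supports plain TSV and series-matrix-style text
  with `!`-prefixed comment lines; probe-to-gene collapsing and
  multi-factor designs are out of scope.
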
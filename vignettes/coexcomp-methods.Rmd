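---
title: "Methods: differential co-expression and comparative screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression and comparative screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcomp)
```

# Scope

`coexcomp` implements two screens of species-variable teratogen response
around a common question: which genes behave differently between organisms
(or conditions) that do and do not develop a teratogenic phenotype?

1. **Differential co-expression.** Given a genes-by-samples expression
   matrix split into control and exposed samples, find gene *pairs* whose
   Pearson correlation changes between conditions, classify how it changed,
   and score *driver* genes enriched for such changes. This targets
   deregulation invisible to per-gene differential expression: a pair can
   keep its mean levels while losing or inverting its coordination.
2. **Comparative genomics.** Given ortholog protein alignments and gene
   neighborhoods for species partitioned into a phenotype-sensitive and a
   phenotype-insensitive group, find substitutions, neighborhood genes, and
   paralog-count differences exclusive to one group.

Both arms run end to end on synthetic inputs with recorded truth, generated
by the package itself, so every stage is testable without any database
access.

# The differential co-expression model

For each unordered gene pair $(a, b)$ the screen computes the sample
Pearson correlation per condition, $r_{ab}^{\mathrm{ctrl}}$ and
$r_{ab}^{\mathrm{exp}}$, with the exact two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.

**Candidate filter.** Only pairs reaching $|r| \ge 0.5$ in *at least one*
condition enter testing (`r_threshold` in `coexp_config()`). A moderate
correlation in either state is what makes a change interpretable; pairs
weakly correlated in both states are noise-dominated at these sample sizes.

**Differential test.** The change is tested with the Fisher
variance-stabilising transform $z = \operatorname{atanh}(r)$:

$$Z = \frac{z_1 - z_2}{\sqrt{\tfrac{1}{n_1-3} + \tfrac{1}{n_2-3}}},$$

two-sided against the standard normal. The test is exact-variance under
bivariate normality and well calibrated at $n \gtrsim 10$; its null
uniformity is verified in the test suite by Kolmogorov–Smirnov on 2000
simulated null pairs. The interface (`diff_test` in the configuration)
admits alternatives such as a permutation test, but Fisher z is the only
implementation shipped: it has a closed form, known calibration, and no
tuning. Correlations at $|r| = 1$ are clamped to $1 - 10^{-7}$ with a
warning rather than propagating infinities.

**Multiplicity.** Benjamini–Hochberg is applied *within the candidate
family* — the pairs that passed the $|r| \ge 0.5$ filter — mirroring a
screen that first restricts to interpretable pairs and then adjusts.
Adjusting over all pairs instead would be more conservative and is easy to
obtain by setting `r_threshold = 0`. Significance is `q_diff < alpha`
(default 0.05).

**Edge classes.** A significant pair is classified by sign change and by
$\Delta r = |r^{\mathrm{ctrl}} - r^{\mathrm{exp}}|$:
*switched opposite* (sign flip with $\Delta r$ strictly $> 1$),
*differentially signed* (sign flip with $\Delta r \le 1$), and
*same signed* (no flip). Two conventions matter at the boundaries and are
fixed deliberately: $r = 0$ counts as non-negative, so $0 \to -0.6$ is a
sign flip; and a flip at exactly $\Delta r = 1$ falls to *differentially
signed* because the switched-opposite rule requires a strict exceedance.

**Driver scoring.** With $E$ significant edges among $C$ candidate pairs,
the global differential-link rate is $p_0 = E/C$. A gene with $m$ candidate
links, $k$ of them significant, gets the exact binomial tail
$P(X \ge k)$, $X \sim \mathrm{Binomial}(m, p_0)$, BH-adjusted across genes.
This is the link-enrichment idea used by differential-co-expression
packages in this field; a hypergeometric variant would condition on $E$
exactly, but the binomial form was chosen for its transparency and because
the two agree closely at these scales. A driver is only detectable when the
candidate family is larger than its own links — if every candidate pair is
differential, $p_0 \approx 1$ and no gene can be enriched — which is the
realistic regime: most co-expressed pairs in a screen are not disturbed.

**TF annotation.** Edges are annotated against a TRRUST-style regulator
table: the common regulators of both members, a flag for edges whose one
member itself regulates the other, and a ranking of regulators by edges
covered (ties lexicographic). Gene symbols match case-insensitively
throughout, since mouse (`Crbn`) and human (`CRBN`) conventions differ only
in case.

**Timepoints.** Samples collected over a time course are pooled within
condition by default, matching a single control-versus-exposed contrast.
The `per_timepoint` mode computes correlations within each timepoint and
combines them on the z scale weighted by $n_t - 3$, with the effective
sample size defined so the combined z variance is $1/\sum_t (n_t - 3)$.
Pooling treats timepoint-driven covariation as signal; the per-timepoint
mode removes it at the cost of power. Neither models temporal dynamics —
that is out of scope.

**Degenerate input.** A zero-variance gene in either condition cannot be
correlated; such genes are excluded pairwise with a message rather than
aborting the run, and requested genes absent from the matrix are reported
and skipped.

# The comparative screens

**Group-exclusive substitution calling.** An alignment column is called
when every insensitive species carries a non-gap, non-`X` residue that is
absent from all sensitive species at that column. `strict` mode (default)
additionally requires the insensitive residues to agree with each other,
which is the natural reading when the insensitive group is small (mouse and
rat); `loose` mode admits within-group disagreement so long as no
insensitive residue occurs in the sensitive group. Strict calls are a
subset of loose calls by construction, a property the suite checks. Three
disqualifiers are fixed choices:

* a gap in any sensitive species skips the column — a substitution and an
  indel are different event classes (an `count_indels` option reports
  group-splitting gap columns separately);
* `X` never supports a call: ambiguity is not evidence of difference, on
  either side of the partition;
* calls are reported in the ungapped coordinates of a reference species
  (human when present), as `P72A`-style labels, via a column-to-position
  map that is non-decreasing and surjective onto the reference length.

**Variant cross-reference.** A call matches a human variant row when gene,
protein position, reference residue, and the strict alternate residue all
agree; all matching variant identifiers are attached. `codon_diff()` gives
the codon-level view (which base positions differ between, say, human `CCC`
and rodent `GCA`).

**Neighborhoods.** Window gene sets per species are partitioned into a
shared core (in all species), group-exclusive genes, and species-exclusive
genes, plus a pairwise Jaccard matrix. Group-exclusive defaults to the
conservative "in *every* species of the group, in *none* of the other"
(`semantics = "all"`); the permissive `"any"` variant accommodates groups
whose members share the neighborhood only partially. The window size is a
required parameter of the comparison, not an assumption.

**Paralogs.** Percent identity is matches over columns where neither
sequence is gapped, excluding `X` columns from both counts — the standard
alignment identity; a family's paralog count is the number of non-reference
members at or above the threshold (default 70%).

# The synthetic-data generators

The generators define the study conditions; their defaults are fixed once
and are not tuned against test outcomes.

**Expression.** Each condition is drawn from a multivariate normal whose
correlation matrix carries the planted pair correlations (background 0
elsewhere), scaled to `noise_sd` and shifted to a microarray-like
log-intensity baseline of 8. Planted pairs are disjoint by default, which
keeps the truth exact; overlapping structures (hubs) must be supplied as a
full positive-semidefinite closure — e.g. a single-factor model in which a
hub's partners inherit the product correlations — or explicitly repaired by
eigenvalue clipping (`repair = TRUE`, off by default, documented as
distorting the truth). A non-PSD request without repair is rejected naming
the genes involved. Values are continuous intensities, not counts,
matching the microarray platform this emulates; probe-level artifacts,
normalisation effects, and batch structure are deliberately absent, so
passing tests demonstrate statistical correctness of the screen, not
robustness to platform noise.

**Alignments.** Background columns carry one residue across all 14 species;
shared polymorphic columns add a second residue to at least one species of
*each* group, so they can never be called exclusive; planted columns follow
the design exactly; gaps are placed only outside planted columns so the
recorded truth is unambiguous. Strict calling on a simulated alignment with
`gap_rate = 0` returns exactly the planted truth (round-trip identity).
There is no phylogeny-aware substitution model and no nucleotide level —
the generator emulates the *statistical shape* of a screen input, not
molecular evolution.

**Neighborhoods.** Planted content (shared core, group exclusives, species
exclusives) occupies the upstream window, shuffled deterministically by
seed and padded with namespaced `FILLER_<k>` symbols that are unique across
the table, so filler can never fake a group-exclusive gene (each filler
occurs in exactly one species).

# Problem sizes and numerical choices

The suite and the acceptance script run at desk scale, sized for tight
truth recovery rather than realism: 100 genes at 50 samples per condition
for pair recovery (10 planted sign flips, all with $\Delta r \ge 1.2$);
a 10-link hub in a single-factor closure for driver recovery; 20 null
simulations of 40 genes at 20 samples for type-I control; 2000 simulated
null pairs for the KS calibration check; 1200-column alignments over 14
species (12 sensitive, 2 insensitive) with up to 65 planted columns; and
40-gene neighborhood windows. At 50 samples per condition a planted flip
of $\Delta r \ge 1.2$ has essentially unit power under the Fisher z test,
so recovery failures would indicate implementation defects, not sampling
bad luck.

Numerical conventions collected in one place: correlations are clamped at
$1 - 10^{-7}$ only inside the z transform; $|r| = 1$ yields $p = 0$ in the
per-condition test; BH is `stats::p.adjust(method = "BH")` behind a
validating wrapper; binomial tails use `stats::pbinom` exactly; PSD is
declared at smallest eigenvalue $\ge -10^{-10}$ and repair clips at
$10^{-8}$ before rescaling to unit diagonal; all alignment columns, protein
positions, and codon positions are 1-based; pair identities are stored with
`gene_a < gene_b` lexicographically.

# Known limitations

* The differential test assumes approximate bivariate normality per
  condition; heavy-tailed expression would call for a rank-based or
  permutation variant behind the same interface.
* BH within the candidate family controls FDR over filtered pairs; the
  filter itself uses the same data, which is the field's standard practice
  but not a jointly-valid selective inference procedure.
* Driver attribution is correlational: a "driver" is a hub of changed
  links, not a demonstrated cause.
* The comparative callers treat the alignment as given; alignment error
  propagates directly into calls, and no attempt is made to model it.
* Group-exclusive calling with a two-species insensitive group cannot
  distinguish lineage effects (rodent-specific drift) from
  phenotype-linked substitution; it is a screen, not a test of
  association.
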
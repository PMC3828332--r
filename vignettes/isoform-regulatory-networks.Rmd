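---
title: "Inferring transcription-and-splicing networks from isoform expression"
author: "tsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription-and-splicing networks from isoform expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

`tsnet` treats the expression of an mRNA isoform as a linear readout of
two regulatory layers.  For isoform $g$ in a co-expressed group,

$$ E(g) \;=\; \alpha_0 + \sum_{j=1}^{J} \alpha_j\, T_j(g)
          + \sum_{k=1}^{K} \beta_k\, S_k(g) + \varepsilon, $$

where $T_j(g)$ is the interaction strength between transcription factor
$j$ and $g$'s promoter, $S_k(g)$ the strength between splicing factor $k$
and $g$'s pre-mRNA, and $\varepsilon$ additive noise.  The model is fit
once per co-expressed group, with one observation per isoform: the group,
not the sample, is the replication unit.  This presumes that

1. co-expressed isoforms share regulators (the rationale for clustering
   before fitting);
2. binding strength is a monotone proxy for regulatory input — summed
   site scores for TFs, conservation-averaged motif hits for SFs;
3. regulation is approximately linear in those strengths over the
   observed range, with a sparse set of active factors.

None of these is strictly true in cells; they are the standing
assumptions of strength-based regression models of expression, and the
sparsity assumption is what lets a group of 10–30 isoforms constrain a
panel of dozens of candidate factors.

# Interaction strengths

**TF strengths.**  The promoter-region dataset (PRD) holds the 2000 bp
upstream of each isoform's transcription start site (`promoter_len`,
default 2000 bp; promoters truncated by a contig edge are kept and
flagged).  Each position weight matrix is regularised with a probability
pseudocount of 0.01, converted to log$_2$ odds against the background
base frequencies, and slid over both strands; a window is a binding site
when it scores at least `threshold_fraction` (default 0.8) of the PWM's
maximum achievable score.  The TF–isoform strength is the *sum* of its
site scores, so both site quality and site number contribute; factors
with no sites on any promoter are removed.  Absolute strength values are
scanner-defined — downstream standardization makes the regression
scale-free, so only relative variation matters.

**SF strengths.**  Splicing-factor motifs are short literal sequences
with signed affinities (positive = enhancer-like, negative =
silencer-like).  Motifs with $|$score$| < 5$ or length $> 15$ nt are
discarded (`motif_abs_score_min`, `motif_len_max`; both boundaries
inclusive).  The exon–intron dataset (EID) consists of ±200 bp windows
(`splice_flank`) around every internal splice site, merged when they
overlap.  Motifs are matched exactly on the isoform's sense strand —
these are RNA elements read off the pre-mRNA, so the antisense genome
strand is not searched.  Because short motifs match constantly by
chance, each hit is scored by the mean per-base conservation
(phyloP-scale) over its span and deleted below `conservation_min = 2`
(a hit at exactly 2 survives).  The SF–isoform strength is the *mean*
conservation over retained hits — a mean rather than a sum so isoforms
with many exons are not automatically stronger targets — and 0 without
hits.  Paralogous hnRNP factors whose motif repertoires coincide
(A1/A2, H1/H2/H3, C/C1/C2, E1/E2) produce near-collinear columns; they
are merged by element-wise averaging into composite factors before
fitting.  The factor panel itself is input data, not package code.

# Preprocessing

Isoforms enter the analysis when (i) they were called differentially
expressed upstream (the package consumes a Cuffdiff-style flag; it does
not re-test), (ii) they have protein-level evidence, and (iii) every FPKM
value in their up-regulated condition exceeds `fpkm_min = 5` — strictly,
so a value of exactly 5 fails.  Retained isoforms are clustered on the
correlation distance $1 - r$ (signed Pearson, not $|r|$: co-expression
means moving together, not mirror-wise) with average linkage.  The
dendrogram is cut at height `h_cut = 0.3` ($r \ge 0.7$), after which any
cluster above `group_size_max = 30` is recursively re-cut at its own
merge heights (with a leaf-order chunking fallback when bisection shears
off a shard below the minimum), and clusters below `group_size_min = 10`
are dropped.  The height cut matters: size rules alone would accept any
small-enough set of mutually uncorrelated isoforms as a "co-expressed"
group.  Constant-expression rows have undefined correlation and are
removed first.

# Model selection

The response per isoform is, by default, its mean FPKM over the samples
of its up-regulated condition (`response = "condition_mean"`;
`all_mean` and `log2_condition_mean` are available).  One value per
isoform keeps the design at $N = $ group size, matching the model's
one-observation-per-isoform reading; stacking per-sample values would
pseudo-replicate correlated residuals.

Predictors are centered and scaled to unit Euclidean norm and the
response is centered — the LARS convention, under which correlations and
inner products coincide.  Constant columns are dropped.  Plain
least-angle regression (the active set only grows; no LASSO drop step)
then orders the factors: start from the predictor most correlated with
the response and advance along the direction equiangular to the active
set until an inactive predictor reaches the same absolute correlation.
Negative coefficients are allowed throughout and read as putative
inhibition.

**Choosing the model size.**  Mallows' $C_p = \mathrm{RSS}/\hat\sigma^2
- N + 2m$ needs a residual-variance estimate.  With more candidate
factors than isoforms ($P > N$), the largest model on the path fits the
data essentially perfectly, so estimating $\hat\sigma^2$ there collapses
the criterion and always picks the deepest model.  `tsnet` instead
estimates $\hat\sigma^2$ at the mid-path model ($m_0 = \lceil N/2
\rceil$), and treats an essentially perfect mid-path fit as the signal
to take the smallest step attaining that residual level.  A second,
structural issue remains: a greedy one-at-a-time path can interleave
spurious predictors before the last true ones and postpone true ones
past any fixed breakpoint, so *no* stopping rule on the raw path can be
simultaneously complete and parsimonious.  The chosen active set is
therefore refined by alternating backward elimination and forward
addition on ordinary-least-squares refits under the extended BIC
($n \log(\mathrm{RSS}/n) + |S|(\log n + 2\gamma\log P)$, $\gamma = 1$ —
the standard small-$n$-large-$P$ correction of BIC), until neither move
improves it.  The refinement is what the acceptance study measures: at
the standard conditions it recovers the full planted support in
essentially all replicates with about one spurious factor per group,
while a pure-noise response selects a median of zero factors.  The
fixed-$k$ criterion (`max_steps_k`), mirroring the run-until-$k$-enter
formulation of the algorithm, is kept without refinement for users who
want the raw path semantics.

Coefficients and the intercept are reported on the original strength
scale.  Groups are kept when the adjusted coefficient of determination
$1 - (1 - R^2)(N - 1)/(N - p - 1)$ reaches `r2_min = 0.5`; the threshold
is configurable because "did not fit well" is a judgement call, and 0.5
discards responses the factors explain no better than chance while
keeping anything with real structure.

# Networks and enrichment

A kept fit becomes a bipartite transcription-and-splicing network: an
edge runs from a selected factor to a member isoform exactly when the
factor's strength on that isoform is positive, weighted by the strength
and signed by the coefficient.  Target–target edges are out of scope
(they would come from external interaction databases, not from this
model).  Gene names are attached for display and the networks serialise
to TSV and GraphML.

Each network's gene list — target genes plus factor genes, deduplicated
— is tested for over-representation in gene-set collections with the
one-sided hypergeometric (Fisher exact) test; enrichment, not depletion,
is the question.  GO-style collections are first restricted to terms
with 10–100 genes (inclusive) against the universe: smaller terms cannot
overlap a network meaningfully, larger ones are uninformative.
Benjamini–Hochberg control is applied within each collection and pairs
with $q <$ `q_alpha` $= 0.05$ are flagged; a second flag records raw
$p < 10^{-4}$, the common reporting convention for GO scans.  The
universe defaults to all annotated genes of the run and is configurable
— enrichment p-values are only meaningful relative to an explicit
universe.

A single-factor genome-wide scan (`genome_scan_targets`) supports
follow-up of an individual splicing factor: all exact motif occurrences
in the genome are conservation-scored and the top third
(`keep_fraction = 1/3`, ties broken by coordinate) are mapped to
overlapping gene bodies.

# The synthetic-data generator

Real inputs for such a study (patient RNA-seq, licensed motif databases,
era-specific annotation and conservation tracks) cannot ship with a
package, so `tsnet` generates complete input bundles with known ground
truth and uses them as its study conditions.  The generator reads the
model forward: it draws group memberships, a support of
`true_support_per_group = 5` factors per group with coefficients of
magnitude 0.5–1.5 and random sign, plants the corresponding binding
evidence, and sets expression to intercept + strengths × coefficients +
Gaussian noise (`noise_sd = 0.1` FPKM).  Defaults mirror the conditions
used throughout the tests: groups of 25 isoforms against 40 TFs and 20
SFs.

Realisation details that make the bundle faithful to what the scanners
measure: TF sites are exact consensus matches of their PWM (a planted
site scores exactly the PWM maximum, and one mismatch falls below the
0.8 threshold); SF sites are motif occurrences within ±200 bp of a
splice site covered by a conservation peak of exactly the planted value
(2.5–4.5, above the filter floor of 2) on an untruncated
Normal(0.5, 0.5) background truncated at 0; isoforms are tiled on one
synthetic chromosome with ≥3 kb spacing so 2000-bp promoters never
collide; and accidental motif occurrences inside promoters and splice
windows are repaired by single-base edits (never touching planted
spans), so the measured strength matrices equal the planted ones
exactly.  Per-sample expression profiles are built from
mutually orthogonal group vectors, scaled so that the mean over the
up-regulated condition reproduces the model value exactly and
within-group correlations are ~0.999 while cross-group correlations stay
near 0; a small set of decoy isoforms is added that each fail exactly
one DEI filter.

What the generator does **not** emulate: read-level sequencing noise and
quantification uncertainty, phylogenetically realistic conservation,
degenerate or overlapping motifs, correlated factor activities, and
nonlinear or saturating regulation.  Passing tests therefore demonstrate
that the inference machinery is correct and calibrated under the model's
own assumptions — not that those assumptions hold in any particular
biological data set.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF is read and written
  1-based inclusive.  Promoter and window extraction are clipped at
  contig edges and flagged rather than erroring.
* PWM scanning skips windows containing `N`; the pseudocount keeps
  log-odds finite on zero counts.
* Ties: LARS tie-breaking is by column order; the genome scan breaks
  conservation ties by coordinate; clustering is order-invariant because
  rows are sorted by isoform id first.
* Rank-deficient active sets abort the path with a warning and return
  the breakpoints computed so far.
* Zero-variance responses (no expression spread) and all-constant
  designs are errors; a zero-hit factor yields strength 0 rather than
  missing data; a group with fewer than 3 members cannot be fit.
* The RSS floor in the refinement criterion ($10^{-12}\,\mathrm{TSS}$)
  makes model comparison well-defined for noiseless fits, where several
  supersets of the truth fit exactly.
* The persisted `report.json` omits wall-clock time so that repeated
  runs of the same configuration are byte-identical; timing is carried
  on the in-memory report object only.

# Problem sizes in the test-suite

The suite exercises the full pipeline on bundles of 2–3 groups (10–25
isoforms each, 8–60 factors, ~0.2–0.5 Mb synthetic chromosome), the
recovery study on 100 strength-level replicates at the standard
conditions, the LARS oracle on 50 random 20 × 10 designs against an
independent reference implementation, and the enrichment null on 200
label-shuffled replicates over a 200-gene universe.  These sizes keep a
full run in tens of seconds while leaving every claim at the scale the
method is designed for (tens of isoforms per group, tens of factors).

# Known limitations

* The log-odds PWM scanner is a deliberate, reproducible stand-in for
  profile-HMM scanners whose score semantics are tool-specific; absolute
  TF strengths are therefore not comparable across scanners (relative
  values, which the standardized regression uses, are).
* Exact string matching for SF motifs ignores degenerate positions and
  RNA secondary structure; conservation filtering compensates for, but
  does not eliminate, chance matches.
* With $P > N$ and correlated strength columns, selection is not
  information-theoretically guaranteed: chance collinearity between a
  support factor and other columns can make a sparser model genuinely
  indistinguishable; the acceptance study quantifies how often this
  occurs at the standard conditions.
* One regression per group cannot resolve regulator differences among
  isoforms *within* a group; the group size bounds (10–30) are the
  resolution limit.
* Enrichment treats gene sets as flat lists; ontology-graph propagation
  is out of scope.
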
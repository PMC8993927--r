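---
title: "Methods: designing and profiling minimal gut consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and profiling minimal gut consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimalgut)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where conventions in the field are
genuinely open.

## Core-microbiota screening

A taxon's *occupancy* at detection threshold $d$ is the fraction of
samples where its relative abundance is $\ge d$; the core is every taxon
with occupancy $\ge o_{min}$. Defaults are $d = 10^{-4}$ (a standard
detection limit for shotgun-derived relative abundances, below which
presence calls are dominated by classifier noise) and $o_{min} = 0.5$
("present in at least half the subjects"). Both comparisons are
**inclusive**: "at least 50%" and "a minimum relative abundance of $d$"
are lower bounds that include the bound itself, and the tests pin this at
the boundary (occupancy 0.6 vs threshold 0.5 is core; a KO in exactly 3 of
4 profiles passes a 0.75 prevalence rule). A consequence worth knowing:
at $d = 0$ every cell, including zeros, satisfies the inclusive rule, so
occupancy is 1 for all taxa — use a strictly positive detection threshold
for meaningful screens.

`occupancy_abundance()` summarises each taxon as (occupancy, mean
abundance over detected samples). A never-detected taxon is *flagged*
(`detected = FALSE`, `NA` mean) rather than letting `NaN` propagate.

## Probabilistic co-occurrence

For two taxa with $n_A$ and $n_B$ presences among $N$ samples, under
random placement the co-occurrence count $J$ is hypergeometric with
$P(j) = \binom{n_A}{j}\binom{N-n_A}{n_B-j}/\binom{N}{n_B}$. We report both
tails including the observed value, so $p_{lt} + p_{gt} \ge 1$ always.
Classification: *excluded* when the expected count $n_A n_B / N < 1$ (the
convention of the probabilistic co-occurrence model this follows —
low-expectation pairs cannot be informative), else *positive* / *negative*
at one-tailed $\alpha = 0.05$, else *random*. The significance level is
not dictated by any convention stronger than common practice, so it is a
logged, user-visible parameter. No multiple-testing correction is applied
by default, matching the cited model's convention; `p_adjust = TRUE`
applies Benjamini–Hochberg per tail for users who want it.

Because the denominator of "fraction of positively co-occurring pairs" is
ambiguous (do excluded pairs count?), `positive_pair_fraction()` reports
both: positive over non-excluded (primary) and positive over all pairs.

The implementation uses `stats::phyper`; the test suite checks it against
an independent enumeration of binomial-coefficient terms, exhaustively for
all margins with $N \le 12$ and at the closed-form worked case
($N=10, n_A=n_B=j=5 \Rightarrow p_{gt} = 1/252$), to $10^{-12}$.

## Functional (KO) coverage

Core KOs are those present at least once in $\ge 75\%$ of a panel of gut
metagenome KO profiles; "present" means abundance strictly $> 0$ (one
observation suffices). Consortium coverage is the fraction of core KOs in
the union of member genomes' KO sets — monotone non-decreasing as members
are added, which the tests assert on random instances.

## Quantitative (absolute) profiling

Amplicon reads count 16S rRNA gene copies, not cells, so a species with
$k$ ribosomal operons is over-represented $k$-fold. The pipeline follows
the bench method's stated order: (1) collapse ASVs to species (dropping
unclassified ASVs and *reporting* their read fraction so the user can
judge the bias); (2) divide each species' counts by its genomic 16S copy
number; (3) renormalise per sample and multiply by the qPCR-measured total
16S copies. Corrected counts are kept fractional — rounding before
renormalisation would bias small species. Samples with no classified reads
or zero corrected sum are excluded with a flag, never silently zeroed.
qPCR replicates are aggregated by arithmetic mean (measurements are made
in triplicate; the aggregator is not otherwise specified, and the mean is
the estimator qPCR standard curves assume).

Two invariants define correctness here and are tested: post-scaling column
sums equal the qPCR totals to $10^{-6}$ relative tolerance, and the output
is invariant to multiplying a sample's raw counts by any positive constant
(sequencing-depth invariance, asserted at ×7).

**Scale of the recovered profile.** Dividing by copy number yields
cell-scale proportions; scaling to total *copies* then yields
$\hat a_s = (a_s/\sum a) \cdot \sum_i a_i c_i$ for true cell abundances
$a$ and copy numbers $c$ — proportional to cell abundance with a known
community-level factor. The simulator therefore echoes this quantity
(`expected_absolute`) as the ground truth on the pipeline's own output
scale; the noiseless closed-loop test requires exact recovery against it
(relative error $< 10^{-9}$), and the stochastic regime (depth $10^5$,
qPCR CV 5%, 100 replicates) requires median absolute relative error
$< 10\%$ for species above 1% expected share.

## Reverse ecology

Each organism's KO set selects reactions from an explicit *reaction
universe* (reaction → KOs, substrates, products, reversibility). Reaction
inclusion uses OR semantics — any annotated ortholog suffices — which is
how composite networks are conventionally built from annotations. Each
included reaction adds all substrate→product edges; reversible reactions
add both directions; compounds never enter as isolated nodes. The universe
is an explicit input rather than an embedded KEGG snapshot: the exact
KO→reaction→compound mapping depends on the database version, so pinning
one inside the package would fake a precision the method does not have.

Seeds are computed on the condensation: strongly connected components
(via igraph) whose condensation in-degree is zero are *source components*;
their compounds are seeds with confidence $1/|\text{component}|$ (so
confidences within a source component sum to 1). The acceptance suite
proves this equivalent to the definitional brute force — $c$ is a seed iff
every vertex that reaches $c$ is mutually reachable from $c$ — on 1000
random digraphs of up to 12 nodes.

Indices default to **unweighted** set ratios; a `weighted` option uses
A's seed confidences instead. Which variant the original reverse-ecology
implementations used is not stated in the sources this package follows, so
both are exposed and the choice is recorded in output metadata. Degenerate
cases: an organism with no seeds has undefined indices (`NA`, flagged),
and an organism whose KOs hit no reaction gets a flagged-empty network and
flagged rows in `pairwise_matrix()`. For any organism with at least one
seed, `competition(A,A) = 1` and `complementarity(A,A) = 0` by
construction.

"Actively expressed" defaults to $\ge 1$ mapped read in the
replicate-summed transcript profile (`min_count = 1`), configurable
because no universal expression cutoff exists. With full expression the
expressed basis reduces exactly to the genome basis (tested).

An optional compound blacklist (currency metabolites such as ATP or
water, which otherwise connect everything to everything) is applied before
seed detection; it defaults to empty because the appropriate list depends
on the universe in use.

## Gut metabolic modules

The module grammar is the established GMM file convention: a header line
`ID<TAB>name`, one line per ordered step, commas separating alternative
KOs, `+` joining jointly required KOs (a complex), `///` terminating the
module. Scoring semantics, stated prominently because the source
conventions only fix the file format: a complex's abundance is the
**minimum** over its members (limiting subunit); a step's abundance is the
**sum** over its alternatives (parallel routes add); coverage is the
fraction of steps with nonzero abundance; the module score is the
**median** over covered steps (even counts average the middle two), zero
when nothing is covered. Input counts are CPM-normalised
($\mathrm{cpm}_k = 10^6 \, n_k / \sum n$).

Three reporting parameters mirror the conventional module-profiler knobs
and their interpretation here is a documented decision: the coverage
cutoff 0.5 ("contribute") is the inclusive fraction of steps that must be
covered; the KO minimum 2 is the number of distinct module KOs that must
be observed; and "no distribution" means a KO's abundance counts fully in
every module containing it, never split across modules.

The shipped module file is a clearly labelled **synthetic fixture**: its
six modules mirror the curation intent relevant to minimal-consortium
work — cellobiose degradation, lactate consumption via the
electron-bifurcating route, both 1,2-propanediol production routes,
propionate production via 1,2-propanediol, and acetyl-CoA → crotonyl-CoA
as a proxy for butyrate production — but the KO contents are placeholders,
because the real curated KO lists are external resources. Analyses of real
transcriptomes must supply their own curated definitions.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of (parameters, seed): repeat calls are
bit-identical, the caller's RNG state is restored, and ground truth is
returned alongside the data.

* `gen_abundance_table()` — per-taxon Bernoulli presence at a stated
  prevalence, lognormal nonzero abundances renormalised per sample.
  Default lognormal $\sigma = 1$ gives the heavy-tailed spread typical of
  species-level gut profiles. Emulates occupancy structure only: no
  compositional correlation, no overdispersion between cohorts.
* `gen_presence_absence()` — independent Bernoulli occupancy with planted
  pairs drawn from the 2×2 joint with both marginals preserved and
  co-presence shifted by ±strength; infeasible shifts error at generation
  time. Chosen over copulas as the simplest mechanism with analytically
  known pairwise probabilities.
* `gen_ko_profiles()` — core KOs at high prevalence (default 0.9),
  variable at low (default 0.3), straddling the 0.75 screening threshold
  realistically; no abundance structure, since the core screen only uses
  presence.
* `gen_amplicon_experiment()` — multinomial reads with expected share
  $\propto$ abundance × copy number, the minimal model consistent with
  proportional amplicon sampling (no chimera or error model: read-level
  processing is out of scope); qPCR total perturbed by mean-1 lognormal
  noise at a stated CV (default 5%, a typical inter-triplicate spread).
  Sequencing depth `Inf` yields expected counts for exact-recovery tests.
* `gen_reaction_universe()` / `gen_crossfeeding_pair()` — random small
  reactions with unique KOs per reaction; the cross-feeding planter picks
  reaction pairs sharing a compound that is, verifiably by construction, a
  pure source for the acceptor and a pure sink for the donor, and returns
  that certificate. The certificate check is combinatorial and independent
  of the seed-set machinery it is used to validate.
* `gen_expression_subset()` — uniform (optionally weighted) subsampling of
  a genome's KOs with Poisson-shifted counts. The optional weights exist
  so tests can state "non-shared KOs preferentially expressed" scenarios,
  under which expression-based competition falls below genome-based
  competition in the majority of draws — the qualitative behaviour
  expected when two close relatives partition their niches
  transcriptionally.

A green test on synthetic data establishes that the algorithms implement
their definitions and recover planted truth under the stated noise model —
not that real communities satisfy those models. In particular the
generators do not simulate reads, genome content, compositional coupling
between taxa, or growth dynamics.

## Numerical conventions

* Probability comparisons against enumeration use $10^{-12}$ absolute
  tolerance; conservation identities (CPM sums, qPCR column sums)
  $10^{-6}$ relative.
* Medians of even-length vectors average the two middle values
  (`stats::median`).
* All duplicated-identifier, negative-value, and missing-cell conditions
  are hard errors at construction; missing cells are never imputed as
  zeros.
* Identifiers are case-sensitive; whitespace is trimmed only at field
  edges when parsing.

## Known limitations

* The reaction universe abstracts away reaction stoichiometry and
  cofactor usage; seed sets are topological, not flux-based.
* Planted co-occurrence supports pairwise associations only (a taxon may
  appear in one planted pair), not higher-order structure.
* The CLI covers the standard file-based workflows; programmatic use is
  the primary interface.
* Headline numbers from real surveys (core species lists, co-occurrence
  percentages, coverage of real consortia, real competition/
  complementarity values) require external datasets and are intentionally
  out of scope; nothing in this package claims to reproduce them.
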
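---
title: "Consensus SV calling and precision-based quality calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV calling and precision-based quality calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svensemble)
library(dplyr)
```

## The problem

Short-read structural-variant (SV) callers are heuristic and heterogeneous:
a read-pair method, a split-read method and a read-depth method each see a
different slice of the evidence, so their error profiles differ sharply by
SV type and size. No single caller is best everywhere, and every caller's
raw output mixes high-confidence calls with a long tail of false
discoveries. An ensemble strategy exploits this heterogeneity twice over:
events reported independently by several methods are far more likely to be
real, and the *identity* of the supporting methods — together with the
event's type and size — is itself an informative predictor of whether a
call is true.

`svensemble` implements the computational core of such an ensemble:

1. **Merging.** Per-caller VCF call sets are clustered across callers into
   consensus candidates by breakpoint distance.
2. **Calibration.** Against a truth set, the empirical precision of every
   (supporting-caller combination, SV type, size class) category is
   measured and Phred-encoded into a quality value (QV).
3. **Evaluation.** Call sets are benchmarked with size-stratified
   precision/recall/F1, per-combination breakdowns, replicate concordance
   and cross-sample allele-frequency aggregation.
4. **Simulation.** A fully parameterised generator produces labeled
   multi-caller ensembles over a synthetic genome, so every stage above is
   testable end to end without external data.

Execution of the constituent callers themselves (alignment, read evidence,
re-genotyping) is out of scope: the package starts from their VCFs.

## The merge model

Two calls are *mergeable* when they lie on the same contig, share an SV
type, and both the start and the end breakpoints differ by at most
`max_dist` (default 1000 bp, the common default of SV merging tools; the
merge distance is a free parameter of any such pipeline and is exposed
everywhere). Consensus candidates are the **connected components** of the
mergeable-pair graph — single-linkage, transitive clustering, which is the
semantics of the standard SV merging tools this stage emulates. The
brute-force all-pairs + union-find oracle in the test suite pins exactly
this semantics.

Representative coordinates are the **lower medians** of the member
breakpoints, so representatives are always observed coordinates and the
representative always lies within the member range; the representative
size is recomputed from the representative breakpoints (for insertions,
the lower median of member sizes, since their `END` carries no size). A
caller contributing several calls to one component counts **once** in the
support set — intra-caller duplicate merging is subsumed by the
connected-components semantics. Breakends merge only with breakends, and
only when anchor and mate breakpoints each agree within `max_dist` on
matching contigs.

Coordinates are stored 1-based inclusive exactly as in VCF — every format
this package touches is VCF, so breakpoint distances are plain integer
differences and no off-by-one conversions exist anywhere.

## Quality calibration

For consensus calls labeled against a truth set, calls are grouped by
calibration key: the supporting-caller combination, the SV type, and the
size class — half-open strata [50, 300), [300, 1000) and [1000, Inf) bp.
The source convention writes the strata as "50–300, 300–1,000, >1 kb",
which books 300 and 1000 into two bins each; half-open intervals are the
unambiguous resolution and are used consistently by both calibration and
benchmarking. Insertions form a single collapsed bin: the size-stratified
ruleset applies to deletion-like events only, and insertion size is poorly
measured by short reads anyway. Events below 50 bp are not SVs under the
standard definition and are dropped at ingest (`min_size`, configurable).

Each category retained with at least `min_category_count = 3` calls (that
is, categories with more than two calls) receives

$$\mathrm{QV} = \min\!\big(40,\; -10 \log_{10}(1 - \text{precision})\big),$$

the Phred encoding of the category's empirical false-discovery rate,
capped at 40 — a category with observed precision 1 receives exactly the
cap, since a finite sample cannot support an unbounded quality claim. QVs
are reals rounded to two decimals, not integers: VCF QUAL permits floats,
and the conventional filtering threshold "QV > 3" (≈ precision 0.5)
requires finer granularity than integers provide. Whether the original
framework encodes QV exactly as this formula or as a binned lookup is not
stated by its description; the Phred formula is the stated encoding and is
adopted here, and the TSV table format lets users override any entry.

At assignment time a call's QV is looked up by its exact key; types
lacking truth data (inversions, duplications, breakends) fall back to the
deletion-trained entry with the same combination and size class — the
ruleset learned on deletions is applied unchanged to unbenchmarked types,
assuming the callers' relative reliability carries over. Keys absent from
both routes receive `default_qv` (0), so unknown combinations sort last.
Lookup never fails, and genotypes never influence merging or calibration —
they are annotations carried through from external genotypers.

## Benchmarking

Matching mirrors the standard SV benchmarking protocol: a candidate and a
truth record are compatible when they share contig and type, both
breakpoint displacements are at most `refdist` (2000 bp, the published
setting), and their size ratio `min/max` is at least `pctsize` (0.7, the
comparison tool's published default; only `refdist` and the disabled
sequence similarity are fixed by the protocol description, so `pctsize`
is exposed as a flag). Sequence similarity is disabled throughout
(`pctsim = 0` in the emulated protocol), hence no FASTA handling exists in
the package.

Assignment is greedy and one-to-one: candidates in coordinate order each
take their nearest compatible unmatched truth record, with distance
`|Δpos| + |Δend|` and ties broken toward the lower truth position. This is
deterministic and, on the test suite's random instances, within one pair
of the maximum bipartite matching (and exact when each candidate is
compatible with at most one truth record). The greedy TP count is the
reported metric. One-to-one matching means a duplicate candidate for an
already-claimed truth event counts as a false positive — the standard
convention, and occasionally different from the simulator's label
bookkeeping (below).

`passonly` (default on) restricts both sets to `PASS`/`.` records;
`include_bed` restricts both sets to records fully inside high-confidence
regions (BED, 0-based half-open); `size_min`/`size_max` implement
half-open size strata identical to the calibration bins, so stratified
truth counts tile the unstratified totals. Breakends are excluded from
precision/recall (the truth protocol covers sized events only) but flow
through merging and QV assignment.

Concordance between two call sets (replicates, platforms) is reported as
the Jaccard index over matched events, before and after quality
filtering; because greedy matching is not symmetric, the raw match counts
in both directions are also reported. Whether the original concordance
figure is Jaccard or an asymmetric overlap fraction is not stated; Jaccard
is implemented and labeled as such. Population aggregation merges
per-sample consensus sets with the same clustering (samples in the role of
callers) and reports carrier counts and allele frequencies — alternate
alleles over `2 * n_samples` when genotypes are present (non-carriers
counting as homozygous reference, unparseable genotypes contributing no
alternate alleles), otherwise carriers over `n_samples`.

## The simulator

The generator emulates the one thing the pipeline needs from real data:
heterogeneous per-caller error behaviour over a shared ground truth. Truth
events are placed uniformly over a fictitious genome (default five contigs
totalling 200 Mb), with types from a configurable mix (default 55% DEL,
15% DUP, 15% INS, 15% INV — deletion-dominated, as in real short-read call
sets), log-uniform sizes in [50, 100000] bp (SV size distributions are
heavy-tailed; log-uniform spreads events across all three size classes),
and an exclusion buffer of 2000 bp (= 2 × `max_dist`) so distinct truth
events can never fall into one merge window.

Each simulated caller detects each truth event independently with a
per-type (optionally per-size-class) sensitivity, perturbs both
breakpoints with independent rounded Gaussian jitter (callers err at the
two breakpoints independently), perturbs the size multiplicatively, and
adds false calls as a Poisson process per megabase with sizes and types
from the truth distribution. Perturbed sizes are clamped at the 50 bp
floor — real callers report SVs, not indels, under the same convention.
The five default profiles span the realistic range: sensitivities 0.35–0.9
by type, false-call rates 0.2–4 per Mb, jitter 10–150 bp, loosely shaped
on the published behaviour of read-depth, read-pair and assembly-informed
methods (a read-depth caller: deletion/duplication only, high false rate,
coarse breakpoints; an assembly-informed caller: high sensitivity, low
false rate, near-exact breakpoints).

Every call carries a label: the originating truth event, or none for false
calls. Labels give exact precision bookkeeping without a matcher, and the
agreement between label-based and matcher-based precision is itself a
test — they can differ for single events when a false call lies within
`refdist` of a truth event and claims it first, or when a co-clustered
false call corrupts a representative size past `pctsize`; the suite
asserts this disagreement affects well under 0.5% of calls and that every
retained calibration category recovers its label-derived precision within
three binomial standard errors (using the estimate's own standard error
for categories whose label precision is degenerate at 0 or 1, where the
sampling variance vanishes but assignment-convention effects do not).

Determinism: all randomness flows from the config seed; each caller's
stream derives from the master seed plus a stable polynomial hash of the
caller's name, so adding or removing a caller never perturbs the others'
outputs.

What the simulator does **not** model: read-level evidence, coverage and
mappability structure, reference bias, clustered/overlapping true events,
caller-correlated errors (real callers fail on the *same* hard regions;
simulated false calls are independent), and genotyping error. Passing
tests therefore demonstrate the correctness of the merging, calibration
and evaluation machinery under known conditions — not that any particular
QV table transfers to real data. Calibration against a real truth set
(e.g. the GIAB HG002 SV benchmark) is the intended production path; the
package ships no pre-trained table precisely because published figures
cannot be reproduced without those data.

## Numerical and degenerate-input choices

* Lower medians everywhere a representative is chosen (even-sized groups
  take the lower of the two middle values), so outputs are observed
  coordinates and permutation-invariant.
* Modal SV type for mixed-type components (only possible with
  `require_type_match = FALSE`), ties resolved alphabetically.
* `SVLEN` is preferred over `END` when a record carries both
  inconsistently; sign of `SVLEN` is ignored (deletions are conventionally
  negative).
* Empty inputs: merging returns an empty consensus set; an empty truth set
  makes every candidate a false positive; an empty consensus set yields an
  empty calibration table with a warning; empty VCFs are written as valid
  header-only files and read back as empty tables.
* Quality filtering is strictly greater-than (`QV > t`), matching the
  conventional "> 3" rule.
* Calibration tables serialize with `%.17g`, and are parsed back with base
  R's exact decimal conversion, so write–read round trips are bit-exact.
* `F1` is defined as 0 when precision and recall are both 0.

## Problem sizes in the test suite

The suite is sized for a single CPU: the merge oracle runs 1000 random
instances of up to 200 calls; the matcher bound runs 500 instances of up
to 30 calls against a maximum-bipartite-matching oracle plus 50
unique-compatibility instances; calibration recovery simulates a
five-caller ensemble over 2000 truth events; concordance uses two
replicate ensembles over 500 shared truth events; serialization round
trips cover 100 random consensus sets and 20 random tables. These sizes
give the property tests real coverage while keeping the default run to a
couple of minutes.

## Worked example

```{r example, eval = FALSE}
library(svensemble)

cfg <- sim_config(n_true = 500, seed = 7)
ens <- simulate_ensemble(cfg)

consensus <- merge_callsets(ens$calls)
table <- build_calibration_table(consensus, ens$truth,
                                 provenance = "simulated ensemble, seed 7")
consensus <- assign_qualities(consensus, table)

glance(match_calls(consensus, ens$truth))                  # raw accuracy
glance(match_calls(filter_by_quality(consensus, 3), ens$truth))  # QV > 3

autoplot(table)        # QV grid by combination and type/size
```

## Limitations

* The merge distance the original pipeline passes to its merging tool is
  not published; 1000 bp is a deliberate, documented default, not a
  reproduction.
* Greedy matching is a deterministic stand-in for the external comparison
  tool, bounded against the optimal matching rather than byte-compatible
  with any particular tool's report.
* The shipped workflow calibrates on simulated data unless the user
  supplies a truth set; simulated QVs quantify the machinery, not any
  sequencing platform.
* Inversion breakends are merged on type and distance only; no
  strand-awareness is modeled (the source gives no strand rule).
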
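# svensemble

Consensus structural-variant (SV) calling from multiple callers, with
Phred-scaled quality values calibrated from empirical precision.

Short-read SV callers disagree: read-pair, split-read and read-depth
methods have sharply different sensitivity and false-discovery profiles
across SV types (deletion, duplication, insertion, inversion, breakend)
and size regimes. `svensemble` is for anyone combining several callers'
VCFs on the same sample — it merges their calls into consensus events,
scores each event by how trustworthy its *supporting-caller combination*
has proven to be, and provides the benchmarking machinery to evaluate the
result.

## The model

**Merging.** Calls from different callers are clustered by breakpoint
distance: calls `a`, `b` are mergeable iff they share contig and SV type
and

```
|a.pos − b.pos| ≤ d   and   |a.end − b.end| ≤ d        (d = 1000 bp default)
```

Consensus events are the connected components (single-linkage) of the
mergeable-pair graph; representative breakpoints are lower medians of the
members, and the support set is the set of distinct contributing callers.

**Quality calibration.** Against a truth set, consensus calls are grouped
by key *(caller combination, SV type, size class)* with size classes
[50, 300), [300, 1000), [1000, ∞) bp (insertions: one collapsed bin). Each
key observed on ≥ 3 calls gets

```
QV = min(40, −10·log10(1 − precision)),   precision = TP / (TP + FP)
```

the Phred encoding of the key's false-discovery rate, capped at 40.
Assigned QVs land in the consensus VCF's QUAL column; filtering at
`QV > 3` (≈ precision 0.5) is the conventional cleanup step. Types without
truth data (e.g. inversions) fall back to the deletion-trained entry of
the same combination and size class.

**Benchmarking.** Truvari-style matching (breakpoint distance ≤ 2000 bp,
size ratio ≥ 0.7, sequence similarity disabled, PASS-only, optional
high-confidence BED, half-open size strata), greedy one-to-one assignment,
precision/recall/F1 overall and per size class, per-combination
breakdowns, Jaccard concordance between replicates, and cross-sample
population allele frequencies.

**Simulation.** A seeded generator produces a truth set over a synthetic
genome plus one labeled call set per configured caller (per-type
sensitivity, false calls per Mb, Gaussian breakpoint jitter, size error),
so the whole pipeline is testable without external data.

## Worked example

```r
library(svensemble)

cfg <- sim_config(n_true = 500, seed = 7)          # 5-caller ensemble
ens <- simulate_ensemble(cfg)

consensus <- merge_callsets(ens$calls)
table <- build_calibration_table(consensus, ens$truth,
                                 provenance = "simulated ensemble, seed 7")
consensus <- assign_qualities(consensus, table)

glance(match_calls(consensus, ens$truth))
#>      tp    fp    fn precision recall    f1
#> 1   474  1696    26     0.218  0.948 0.355

glance(match_calls(filter_by_quality(consensus, 3), ens$truth))
#>      tp    fp    fn precision recall    f1
#> 1   366    11   134     0.971  0.732 0.835
```

The raw consensus set is dominated by single-caller false calls
(precision 0.218). Filtering at `QV > 3` — i.e. keeping only events whose
supporting-caller combination has demonstrated better-than-even precision —
removes 1685 of 1696 false calls at the cost of about a fifth of the true
events, lifting F1 from 0.355 to 0.835. That trade-off dial is the point
of the calibration: `tidy(table)` shows the per-combination precision
behind every QV, and `autoplot(table)` draws the QV grid.

File-based workflows use the same operations through `read_sv_vcf()`,
`write_consensus_vcf()`, `write_calibration_table()` and the `cmd_*()`
wrappers, or the CLI:

```sh
Rscript inst/cli/svensemble.R merge --out consensus.vcf \
    manta=manta.vcf delly=delly.vcf lumpy=lumpy.vcf
Rscript inst/cli/svensemble.R calibrate --consensus consensus.vcf \
    --truth truth.vcf --out table.tsv
Rscript inst/cli/svensemble.R qualify --consensus consensus.vcf \
    --table table.tsv --threshold 3 --out filtered.vcf
```

Subcommands: `merge`, `calibrate`, `qualify`, `evaluate`, `combos`,
`concordance`, `simulate`, `popaf`.

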
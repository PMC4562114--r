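---
title: "Gene quantification in metagenomes: methods and design"
author: "metaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene quantification in metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaquant)
```

## The problem

Shotgun metagenomes are quantified by mapping sequence reads against a
reference (assembled contigs, a gene catalog, or genomes) and summarizing,
for every annotated region, how many reads aligned there and how deeply
its bases are covered. The datasets are large and the samples are
independent of one another, so the computation splits naturally into one
job per sample that can be distributed across machines. metaquant
implements this per-sample quantification pipeline and a dynamic
master-worker scheme to distribute it.

## The coverage model

Every reference sequence is represented by an integer array with one slot
per base. A retained alignment of a read to the half-open reference
interval $[s, e)$ contributes depth 1 to each slot in that interval. Per
annotated region $[a, b)$ on reference $r$ the pipeline reports:

* **count** — the number of retained alignments whose intersection with
  $[a, b)$ satisfies the overlap rule (at least `minOverlapBases` bases,
  optionally also at least `minOverlapFrac` of the alignment's own
  length). An alignment overlapping several regions counts in each of
  them; there is no fractional assignment.
* **median, mean, standard deviation of coverage** — computed over the
  depth values of exactly the slots in $[a, b)$.

### Difference-array accumulation

Naively incrementing every covered base costs $O(n + N \cdot M)$
elementary writes, for $n$ total reference bases, $N$ alignments, and
read length $M$. Instead, `buildCoverage()` adds $+1$ at slot $s$ and
$-1$ at slot $e$ (the slot just past the last covered base) and then
takes a cumulative sum per reference: $2N + n$ writes, independent of
$M$. Both routes are implemented — `naiveCoverage()` exists purely as an
independent oracle — and both carry an instrumented write counter, so the
complexity claim is asserted by the test suite on operation counts, never
on wall-clock time.

The decrement is placed at the *exclusive* end. Decrementing at the last
covered base itself would uncover every alignment's final base and break
the exact conservation law the tests assert (total coverage mass equals
the summed interval lengths of the retained alignments). The naive
oracle arbitrates this choice.

### Ambiguous reads

Mapper output may list several hits per read. Two policies are offered:
use all hits that pass the matching criteria (minimum percent identity
and minimum alignment length, the two columns every supported format
provides), or keep only the *best* hit, defined as the first hit listed
in the mapper output among those that pass. Criteria are applied before
best-hit selection, so a failing first hit does not shadow a passing
later one. `file_order`, assigned during parsing, is the arbiter of
"first listed".

### Statistics conventions

* Median of an even-length region is the mean of the two central order
  statistics (it changes the fourth decimal of the output, so it is
  worth stating).
* The standard deviation divides by the region length: the region's
  slots are the entire population being described, not a sample from it.
* Results are written with fixed 4-decimal formatting; coordinates in
  all files are 1-based inclusive (GFF convention), while every internal
  interval is 0-based half-open. Conversion happens only at file
  boundaries, which keeps the difference-array decrement position
  unambiguous.

## Formats

Reads stream from FASTA or FASTQ, plain or gzip (detected from magic
bytes), in bounded chunks, so memory use does not grow with file size.
Mapper output is accepted as 12-column BLAST tabular ("blast8", with
reverse-strand hits normalized by min/max since quantification is
strand-agnostic) or SAM (reference span from the M/D/N/=/X CIGAR
operations; identity from the NM tag as $100(1 - \mathrm{NM}/\mathrm{columns})$,
or 100 when absent). Malformed mapper lines are skipped and logged by
default because third-party mapper output is heterogeneous; a strict
mode aborts with the line number. Annotations use a minimal GFF-like
5-column table: ref id, start, end, strand, label.

## The master-worker scheme

The master holds a FIFO job queue; each job is only a set of file paths
(reads, reference, annotations, output, optionally a precomputed
mapping) plus options. Workers register over TCP whenever they come
online, pull one job at a time, execute the whole pipeline locally, and
report done or failed; a failed job is requeued until it has been
dispatched `retryLimit + 1` times (default retry limit 3), then
abandoned. The master never touches data files — workers fetch inputs
and write outputs themselves — and a done report is accepted at most
once per job and only from the currently assigned worker, giving
exactly-once completion. A job whose worker goes silent longer than a
heartbeat timeout (default 60 s) is requeued; the timeout is this
package's mechanism for hung (as opposed to failed) workers. Transport
is one line-delimited JSON request/reply per TCP connection; messages
are small control records (`register`, `poll`, `done`, `failed`,
`status`, and the replies `job`, `wait`, `shutdown`). `queryStatus()`
snapshots all job states from a running master. `runLocal()` forks
local worker processes for single-machine parallelism; cluster
schedulers are out of scope.

Disabling both counts and coverage (with `keepMapping`) turns the
framework into a pure parallel mapping harness: the quantification stage
performs zero array writes.

## The synthetic generator and what it emulates

`generateContigs()` draws uniform-random A/C/G/T contigs with lengths
uniform in a range, annotated whole-contig. `spikeReads()` reproduces
the spiking validation: among contigs of at least 2500 nt, 10% are
selected at random, and each selected contig of length $L$ is fragmented
into $\mathrm{round}(C L / 45)$ error-free reads of length 45 at start
positions uniform in $[0, L - 45]$ — reads lie fully inside the contig,
sampled with replacement, with constant Q40 qualities. The ground truth
is emitted as a blast8 file with the true coordinates, which the
pipeline's *precomputed* mapper adapter consumes, so no external aligner
is needed anywhere in the tests.

What this emulates is the placement statistics of mapped reads at a
known abundance; what it deliberately does not emulate is sequencing
error, paired ends, community abundance profiles, or mapper behaviour.
Passing tests therefore certify the quantification arithmetic and the
distribution machinery, not any particular aligner's accuracy.

### The validation study and its expected behaviour

`validationStudy()` runs the full pipeline per replicate and spiking
level and reports, per level $C$, the mean over spiked contigs of
$|\widehat{\mathrm{median}} - C| / C \times 100\,\%$ with its standard
error over contigs. Defaults: 100 contigs of 2500–10000 nt, 3
replicates, selection drawn once per replicate and shared across levels
(the same contigs are spiked at every level). These sizes were fixed up
front by a design-time power simulation of the median's sampling
distribution; they keep the whole four-level study under a minute on a
single core.

Two structural facts about this estimator are worth recording. First,
reads placed fully inside a contig make the *interior* expected depth
$\mu = n_{\mathrm{reads}} \cdot \ell/(L - \ell + 1) \approx C (1 + (\ell-1)/L)$,
slightly above $C$ — an edge-placement bias of order 0.5–2% for these
contig lengths ($\ell$ = read length). Second, depth is integer-valued,
so at small $C$ the sample median snaps exactly to $C$ and the reported
deviation is 0; as $C$ grows the discreteness stops masking the bias and
the deviation *rises* toward the bias. The deviation-versus-level curve
is therefore increasing, not decreasing — consistent with the bound
sequence the study is checked against. The law-of-large-numbers property
that *is* true, and is what the test suite asserts, is convergence of
the median to the interior expectation $\mu$: the relative deviation
from $\mu$ shrinks as $C$ grows.

```{r, eval = FALSE}
validationStudy(levels = c(1, 10, 100, 1000), seed = 1L)
#>   level mean_deviation_pct     se_pct n_contigs
#> 1     1          0.0000000 0.00000000        30
#> 2    10          0.0000000 0.00000000        30
#> 3   100          0.4166667 0.10743438        30
#> 4  1000          0.8200000 0.06787412        30
```

(Output shown from an actual run with the default conditions and seed 1;
`scripts/acceptance.R` recomputes exactly this table.)

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `minQuality` / `minPercent` | 20 / 90 | Phred / % | classic "90% of bases at Q20" read filter; a read is kept iff at least p% of bases reach Q >= q |
| quality offset | 33 | ASCII | Phred+33 is the modern default; configurable for legacy data |
| `minIdentityPct` / `minAlnLen` | 0 / 0 | % / columns | matching criteria off by default; the mapper's own thresholds often suffice |
| `bestHitOnly` | FALSE | — | all passing hits by default; best hit = first listed |
| `minOverlapBases` | 1 | bases | any overlap counts unless the user says otherwise |
| `retryLimit` | 3 | dispatches | bounded re-running of failed jobs |
| heartbeat timeout | 60 | s | requeue window for silent workers |
| spiking: read length / min contig / fraction | 45 / 2500 / 0.10 | nt / nt / — | the validation study's conditions |

## Degenerate inputs and numerical corners

Empty hit sets give all-zero coverage and zero counts; zero-length
intervals are dropped during accumulation; hits past a reference end are
clipped (and logged) rather than dropped, preserving mass from mappers
that soft-clip inconsistently; hits on unknown references follow a
skip-or-abort policy. Regions of length one have standard deviation 0 by
the population convention. Disabled counts or coverage are written as
literal `NA` fields. A failed job removes any partial output: results
are written to a temporary file and renamed only on success.

## Known limitations

No strand-aware counting (reverse-strand blast8 hits are normalized
away); no RPKM/TPM normalization; no per-base coverage export; no BAM
input (SAM text only); no bundled aligners — an adapter template invokes
external mappers, and all testing uses the precomputed adapter; no
cluster scheduler integration (local forked workers only); the jobs
master has no authentication and should be bound on trusted networks
only.
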
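---
title: "Error-tolerant demultiplexing of noisy reads: methods and design"
author: "editmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-tolerant demultiplexing of noisy reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editmux)
```

# The model

Each read is assumed to contain zero or more copies of a *structure*: fixed
flanking sequences (a primer, a polyT stretch) surrounding a variable region
made of a cell barcode and a UMI whose lengths — but not letters — are known.
Sequencing corrupts the read with substitutions, insertions and deletions;
some reads are chimeric concatenations of two molecules; either strand may
have been read.

Demultiplexing proceeds in two alignment stages, both under unit-cost edit
distance (Levenshtein), so that indels — the dominant long-read error mode —
are handled on the same footing as mismatches.

**Stage 1, flank search.** The structure is compiled into a single search
pattern: flanks contribute their letters, variable segments contribute one
wildcard `?` per base. The pattern is aligned *semi-globally* against the
read: the whole pattern must align, but both ends of the matching substring
are free. `?` substitutes against any base at zero cost, while indels
touching it cost one like any other column, which keeps the score a true
edit distance on the flanks and lets the variable region float in length by
exactly the indel count. The best hit within `flankMaxDist` (default 8)
edits is accepted. The wildcard columns of a global-alignment traceback of
the pattern against the hit then delimit the variable region; it is extracted
with `windowPad` (default 5) bases of context on each side, so that up to 5
unbalanced indels in the flanks cannot push the true barcode out of the
window.

**Stage 2, barcode assignment.** Every whitelist barcode is aligned
semi-globally inside the extracted window and the read is assigned to the
barcode with the lowest distance, provided it is at most `barcodeMaxDist`
(default 2) *and* unique — if two barcodes tie at the minimum the read is
left `AMBIGUOUS` rather than guessed. The UMI is read off the
strand-normalized read immediately adjacent to the barcode match (after it
when the structure places the UMI after the barcode, before it otherwise),
truncated and flagged when the read ends first.

**Chimeras and strands.** After each accepted hit the matched interval is
masked with a sentinel symbol `X` that mismatches everything, including
itself — so a masked region can never be matched again within any bound
smaller than the pattern length. The search repeats on the masked read (at
most 10 rounds) until no structure is found; the reverse complement is then
scanned identically, with the mirror images of all forward hits pre-masked.
Every assigned hit becomes a sub-read, trimmed from the end of its own
structure to the start of the next structure in its own 5'→3' orientation,
so chimeric reads are split and demultiplexed in one pass.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flankMaxDist` | 8 | edits allowed for the full flank pattern (22+9 fixed nt by default); ~25% of the fixed bases |
| `barcodeMaxDist` | 2 | edits allowed between window and whitelist barcode; with whitelists spaced ≥ 5 apart, 2 edits are always uniquely correctable *barcode-to-barcode* |
| `windowPad` | 5 | context around the variable region; bounds the flank-indel imbalance the extraction tolerates |
| `window` (knee) | 20 | rolling-derivative width, in collapsed curve points |
| `searchRange` (knee) | `[10, N − window]` | ranks searched for the inflection; the first 9 ranks are skipped to avoid overloaded-droplet artifacts |

Setting `barcodeMaxDist = 0` with a short "barcode" turns the second stage
into an exact-match filter: a structure of
`[flank][5-nt target][flank]` with `flankMaxDist = 2` requires a perfect
match at a variant position while tolerating errors around it. A structure
with no variable segments degrades to pure error-tolerant search, reporting
matching reads unmodified — useful as the first stage of a pipe.

# Knee-plot cell calling

Discovery mode tallies the barcode-length substring following the left
flank. Sorting barcodes by decreasing count gives the rank–frequency
("knee") curve; real cells sit on the high plateau, ambient/noise barcodes
in the tail, and the boundary is the inflection: the most negative
derivative of the log–log curve, estimated with a rolling window.

Two numerical choices here were genuinely open and deserve their rationale:

* **Tied counts are collapsed before the derivative.** With one rank per
  barcode, the slope between ranks $i$ and $i+w$ is
  $\Delta\log_{10}(\mathrm{count})/\Delta\log_{10}(\mathrm{rank})$, and the
  denominator shrinks like $1/\mathrm{rank}$. Any frequency table from real
  reads ends in thousands of count-1 and count-2 barcodes, so the single
  integer step 2→1 deep in the tail always produces the most negative raw
  slope — for every window width — and the "inflection" would land in the
  ambient tail rather than at the knee. Collapsing equal counts to one curve
  point carrying their average rank (the same convention
  `DropletUtils::barcodeRanks` uses for its fitted curve) restores the
  intended geometry: the tail becomes one wide, shallow step while the cliff
  stays steep. `rollingDerivative()` itself keeps the raw per-rank contract
  for transparency; the collapse happens inside `kneeFilter()`.
* **The cutoff is the steepest single step inside the winning window.** A
  width-$w$ slope only localizes the drop to $w$ ranks; cutting at the
  window start systematically under-calls by up to $w$ cells. `kneeFilter()`
  therefore places the reported inflection at the largest one-step drop of
  $\log_{10}(\mathrm{count})$ within the winning window — the top of the
  cliff — which is exact for sharp mixtures and central for smooth ones.

When the winning slope is not clearly separated from the background (less
than twice the median slope in range, assessed only when at least three
windows are eligible), the result is flagged low-confidence: the curve has
no pronounced knee and the cutoff should be inspected with `plotKnee()`.
On shallow or very noisy tables the detector prefers to over-call low-count
barcodes rather than truncate the cell population; over-called ambient
barcodes are diluted again at demultiplexing time.

# The simulator's stated world

`simulateReads()` emulates noisy single-cell long reads at desk scale. Each
molecule is `junk5 + primer + barcode + UMI + polyT + insert + junk3` with
uniform-random junk (0–50 nt a side, so the search is a true infix search),
a random insert (50–200 nt), barcodes drawn uniformly (or log-normally) from
a whitelist generated with minimum pairwise distance 5. Errors are applied
template-wide — flanks included — as independent per-base substitutions
(5%), insertions (2.5%) and deletions (2.5%), i.e. roughly the 10% aggregate
error of ONT cDNA reads. 3% of reads are two-part chimeras, matching the
chimera fraction reported for real ONT single-cell data, and each molecule
is strand-flipped with probability 0.5. Segment boundaries are tracked
through the error process, so the truth table carries exact post-error
coordinates; a special mode injects exactly *k* edits confined to the
barcode for controlled error-correction experiments.

What the generator does **not** model: homopolymer-dependent and
quality-correlated ONT errors, transcriptome-derived inserts, barcode
sharing between beads, and UMI collisions. A green test on simulated data
therefore establishes the correctness of the search/assignment/splitting
logic under the stated error process — not end-to-end accuracy on any
particular real library.

# Numerical choices and tie-breaks

* Among equal-distance flank hits: smallest start, then smallest end
  (leftmost, shortest). This mirrors scan order and makes chimera iteration
  and splitting reproducible. The same rule orders barcode matches inside
  the window.
* Barcode assignment is independent of whitelist order by construction
  (minimum and tie count are order-free); whitelists are deduplicated and
  uppercased on ingest.
* `N` in a read matches only `N` and `?` — an N-run cannot impersonate a
  flank; putative barcodes containing `N` are skipped in discovery.
* Hits that fail barcode assignment (ambiguous or no barcode within
  distance) still mask their interval, so one bad locus cannot deadlock the
  chimera iteration; the per-strand iteration is capped at 10 rounds.
* Reads with no assigned structure are emitted as a single failure record
  carrying the full read, and can be routed to a separate unassigned sink —
  the pipeline is lossless.
* The bounded distance uses a `2·maxDist + 1` band; its contract is defined
  by equality with the unbounded value whenever that is within the bound,
  and the test suite enforces this against an independently written
  recurrence.

# Known limitations

* **The 2k+1 spacing guarantee is barcode-to-barcode, not barcode-to-window.**
  Because assignment aligns whitelist barcodes semi-globally against a
  window that also contains the UMI and flank context, a decoy barcode can
  occasionally tie with — or in rare cases beat — the true barcode by
  aligning against that context (a T-rich decoy against the UMI tail plus
  polyT-side padding, for instance). With 200 spaced barcodes and 2 injected
  barcode edits this affects a fraction of a percent of reads, which are
  then left `AMBIGUOUS` by the uniqueness rule rather than silently
  misassigned. Shrinking the window would reduce the effect but also the
  robustness to flank indels; the window definition is kept as stated.
* At ~10% per-base error, more than two errors fall inside a 16 nt barcode
  in roughly 18% of reads; these are unassignable at `barcodeMaxDist = 2`
  by design, which bounds the assignment *rate* (not the accuracy) on
  ONT-like data.
* Structures may contain at most one barcode and one UMI segment, and when
  both are present they must be adjacent — the UMI is defined as the bases
  immediately adjacent to the barcode match.
* Search-only mode reports reads containing the *left* flank; multi-flank
  search chains instances instead.
* Thread-style parallelism is accepted at the interface as batching only;
  results are byte-identical for any chunking, which is enforced by test.
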
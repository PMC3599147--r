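---
title: "Methods: repeat detection, clone diffing and the PMM simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat detection, clone diffing and the PMM simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttr)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, the choices made
where the design was genuinely open, and what the tests do and do not
demonstrate.

## 1. Repeat detection on circular genomes

### Scoring

`score_tract()` computes the maximum global alignment score of a tract
against the *infinite cyclic repetition* of a motif (wraparound dynamic
programming). Every tract base must be aligned; the motif phase is free at
both ends, so a perfect tract of length $L$ scores $2L$ under the weights
used throughout: match $+2$, mismatch $-7$, indel $-7$. These heavy
penalties mean reportable tracts (score strictly above 50) are
near-perfect arrays of at least $\sim$26 matched bases; a single
substitution in a 32 bp array gives $31 \times 2 - 7 = 55$. `N` bases
mismatch everything, including `N`.

The same-row wrap in the DP (a gap consuming a motif column across the
motif origin) is resolved with two sweeps per row; because the gap penalty
is negative an optimal path never consumes a full motif period of gaps, so
two sweeps reach the fixed point. The kernel is in C++ (Rcpp), as is usual
for alignment inner loops.

### Candidate generation and refinement

`find_repeats()` is a deterministic, scoring-compatible detector rather
than a re-implementation of a probabilistic k-tuple finder. For every
period $p$ up to `max_period` (default 500, comfortably above the longest
motifs seen in mt surveys) it computes the lag-$p$ match vector, merges
runs of matches across gaps of up to 3 positions (a substitution breaks
the lag vector at two isolated positions), and keeps regions whose
match content could possibly clear the threshold. Each candidate is
extended greedily from its longest perfect run with an x-drop of 21
(three uncompensated mismatches), the consensus motif is taken as the
column majority over the copies, the consensus is reduced to its
primitive period, and the final span is re-scored exactly with the
wraparound DP. Circular genomes are scanned as a doubled sequence and
calls deduplicated back to genome coordinates; origin-spanning tracts are
reported with `start > end`.

Consequences of this design, verified by the test suite:

* detection agrees with a brute-force oracle (every start and period,
  scored over all ends with `score_tract`) on tract presence on seeded
  samples up to 200 bp and period 12, with boundary slack below one motif
  length;
* output is invariant under rotation of a circular genome;
* raising `min_score` never adds calls.

One known limitation: the seeding is substitution-oriented. A single-base
indel *inside* a tract shifts the lag register and can split one array
into two calls. Scoring itself handles indels exactly; only candidate
boundaries are affected. Motif indels in this package's domain are
modelled *between* clones, not within one tract's segmentation, so this
trade of generality for determinism is deliberate.

The strict inequality (`score > 50`) follows the survey convention of
reporting repeats whose scores *exceeded* 50; the inclusive variant is
available via `min_score = 49`.

## 2. Locating tracts

The vertebrate CR sits between tRNA-Pro and tRNA-Phe;
`orient_control_region()` takes the boundary adjacent to tRNA-Pro as the
5′ end (heavy-strand sense), falling back to an annotated TAS block —
which sits near the CR 5′ end, where nascent heavy strands arrest — when
the tRNAs are missing. The original survey located tracts manually;
`classify_tract()` operationalises that with a midpoint rule: a tract
wholly inside the CR is 5′ or 3′ when its midpoint falls within
`end_fraction` (default 0.5) of the respective boundary, and unresolved
otherwise — with the default band only an exact-midpoint tie is
unresolved, mirroring the survey's residue of unplaceable tracts.
Outside the CR the feature kind with the largest base overlap wins
(`partial = TRUE` when the overlap is incomplete; ties break
CDS > rRNA > tRNA), and `intergenic` otherwise. One category per tract,
always: the per-genome category counts sum to the number of tracts.

## 3. Survey statistics

`survey_table()` reproduces the survey's summary arithmetic from
per-class counts: `pct_cr` $= 100\,n_{CR}/n_{TR}$ and `pct_3_of_cr`
$= 100\,n_{3'}/(n_{3'}+n_{5'})$ — the denominator is the *resolved* CR
tracts only, which is the convention consistent with the published totals
(929/(929+591) = 61.12%). Percentages are rounded half-up at 2 decimals
(table style) or 1 decimal (prose style); half-up rounding is implemented
explicitly since base R rounds half to even. Degenerate inputs yield `NA`
percentages, never 0/0.

## 4. Clone tracts as motif strings

A `MotifAlphabet` is a canonical motif plus named variants within
`max_hamming` (default 1 — the "varied by a single base" convention) of
it. `decompose()` segments a tract greedily left-to-right into
motif-length windows, assigning each the nearest symbol within
`max_hamming`; the reading frame maximising the number of assigned
symbols wins, ties to the smallest offset. An unassignable window
*terminates* the encoding (remainder becomes `residual_suffix`) rather
than being skipped: chimeric encodings that splice across foreign
sequence would silently corrupt downstream diffs. Decoding an encoding
reproduces its input exactly, and the tests enforce that identity on
every fixture.

`diff_encodings()` explains one encoding as the other plus a single
contiguous run of inserted or deleted copies. The **ambiguity interval**
of a call is the maximal band of copy positions such that removing (or
inserting) the same symbol run at *any* placement inside the band gives
the identical result: a deletion of one copy inside a homogeneous run
spans the whole run; deleting six of ten identical copies yields the band
1–10; a deleted variant copy is pinned to a point. This matches how
clone-comparison ambiguity is reasoned about (a deletion "could have
occurred at any site from the *n*th to the *m*th copy"). When no single
event suffices, `max_events > 1` reports a minimal indel-only alignment
(LCS traceback grouped into runs), and otherwise a `complex` row carries
the symbol-level edit distance. Calls are verified against an exhaustive
enumerator, and interval maximality is checked by applying the indel at
every placement inside the band and at both flanking placements.

`detect_birth()` finds maximal exact tandem duplications (unit
$\ge$ `min_unit`, copies $\ge$ `min_copies`, harmonics of a smaller unit
suppressed) and reports the `prefix_overlap`: how many leading unit bases
recur immediately after the last copy. That overlap is the hallmark of a
newly born repeat — the duplication is anchored by a short sequence
present at both ends of the copied span — and on the two published
repeat-carrying flounder individuals it recovers unit lengths 58 (two
copies, overlap `TTTAA`) and 48 (four copies, overlap `AACACT`) from the
printed sequences.

## 5. The PMM simulator

The Pause-Melting Misalignment model is qualitative: no rates are
published. The simulator therefore aims to reproduce the mechanism's
*contrasts*, not calibrated magnitudes, and every rate is explicit
configuration in `pmm_params()`.

One replication pass (`replicate_once`) does:

1. **Pause.** A candidate position is drawn uniformly; a pause fires with
   the probability of its position class. Defaults: 0.3 at both CR ends
   (heavy-strand arrest at TAS blocks at the 5′ end; initiation/closure
   traffic at the 3′ end), 0.05 in CDS, 0.01 elsewhere — replication
   arrest is documented at many discrete positions genome-wide, so the
   floor is nonzero.
2. **Melt.** The nascent-strand tail melts over a geometric length
   (memoryless, hence geometric) with mean
   `melt_length_mean × competition_strength`. Defaults: means 40 (5′) and
   20 (3′/CDS/other); competition 1.0 except 0.5 at the CR 3′ end, where
   the displaced parental strand is largely gone and competes weakly —
   effective means 40 vs 10 at the two CR ends.
3. **Mispair.** The terminal anchor of the tail (geometric above
   `min_anchor = 4`, mean `anchor_length_mean = 8`, never longer than the
   melt) re-anneals at an out-of-register site with identity
   $\ge$ `mispair_min_identity` (0.9). The slip offset can reach at most
   `melt − anchor` back: the melted span must hold both the anchor and
   the looped-out bases. This cap is what converts the competition
   asymmetry into the observed positional contrast — shorter melts at the
   3′ end allow only shorter slips, hence shorter event motifs.
4. **Fold.** The unpaired span folds by length alone: bulge (< 6), loop
   (6–8), hairpin (> 8). No free-energy computation is attempted — the
   model's own conclusion is that stable secondary structure is not
   necessary — and bulges abort with `bulge_release_prob = 0.7` (a labile
   bulge can slip off the strand end). This release is what depletes
   sub-6 bp event motifs relative to 6–12 bp ones.
5. **Resolve.** Surviving events insert (protrusion on the nascent
   strand, probability `protrusion_side_prob_N = 0.5`) or delete
   (protrusion on the template) the slipped span. The span is reduced to
   its primitive period for reporting, so a 16-base slip in an 8 bp array
   is an event of `motif_count = 2` — multi-copy indels arise naturally.
   An insertion with no pre-existing exact adjacent copy is flagged
   `birth`.

Two deliberate deviations from a naive reading of the mechanism, both
load-bearing:

* **Register choice is sampled, not nearest-first.** The deterministic
  nearest-register primitive (`find_mispair_site()`, kept and tested as
  such) would *always* re-anneal a periodic tract at exactly one period,
  making multi-copy indels impossible — contradicting the model's own
  claim that one *or several* motifs indel per event. `replicate_once`
  therefore samples uniformly among all qualifying registers within
  reach.
* **A minimum anchor (4 bp).** Without it, one- and two-base "anneals"
  pass any identity threshold by chance and generate non-motif-multiple
  indels inside perfect arrays; a 1–2 bp pairing cannot anchor a
  mispair.

Randomness: a single seeded R RNG drives every draw; identical seeds give
byte-identical outputs (`evolve_lineages(..., seed = )`), and the event
log records position class, fold class, unpaired length, anchor length,
identity, outcome, primitive motif, copy count and the signed length
change, so every run is auditable — final lengths must equal the founder
length plus the summed signed changes.

### What the seeded simulations show — and what they cannot

The test suite runs, at fixed seeds and default parameters unless the
contrast under test dictates otherwise (pause probabilities are raised to
1.0 at the CR ends purely to collect enough events for distributional
comparisons; release, competition and identity always stay at defaults):

* zero pause probability ⇒ zero events, ever;
* all length changes are whole numbers of motifs; lengths conserve;
* protrusion always on the nascent strand ⇒ insertions only;
* fewer sub-6 bp event spans than 6–12 bp spans, absolutely and per
  qualifying attempt (the bulge-release effect);
* smaller mean event span at the CR 3′ end than at the 5′ end under the
  asymmetric competition defaults;
* at least one multi-copy indel, and at least two distinct tract
  copy-number classes across 50 lineages × 500 replications
  (length/organisation heteroplasmy emerges);
* birth insertions anchored by an exact short match re-create units whose
  prefix follows the tract — the same hallmark `detect_birth` looks for.

These are qualitative reproductions under invented rates on synthetic
founders; nothing here calibrates the model to real survey histograms,
and no quantitative agreement with observed motif-length distributions is
claimed.

### Study conditions of the simulation tests

The founder for the simulator checks emulates a flounder-like CR: a
16.5 kb annotated genome with a 26-copy 8 bp tract at the CR 3′ end and
its mirror at the 5′ end (26 copies are mid-range for the observed 4–51
copy panel), plus 12-copy 4 bp tracts at both ends so that short-slip
opportunity is matched where the short-vs-mid contrast is measured.
Problem sizes (50 × 500 replications for heteroplasmy, 20 000 single
passes for the distributional audits, 200 planted fixtures and 20 oracle
sequences for the detector properties) were chosen as the smallest runs
that make the contrasts unambiguous.

## 6. Synthetic data

`make_genome()` lays out a minimal but order-faithful genome (12S/16S,
the protein-coding genes through CytB, tRNA-Thr, tRNA-Pro, CR, tRNA-Phe,
wrapping back to 12S), rejection-samples the random background until no
unintended tandem scores above threshold (making negative tests exact),
plants the requested tracts by substitution, and hardens the three bases
flanking each plant against continuing the motif so detections recover
truth coordinates exactly. It emulates annotation geometry and base
composition only — no codon structure, no clade-specific composition, no
real CSB/TAS motifs (the CSB3 block in `make_pcornutus_cr()` is an
invented placeholder) — so passing tests demonstrate algorithmic
correctness on clean truth, not performance on messy real annotation.
Real GenBank records with inconsistent CR naming are handled by the
reader's synonym mapping (`D-loop`, `control region`, `CR`,
misc_features noting "control"), but genomes lacking any CR annotation
are reported unlocatable rather than delimited de novo.

`make_clone_set()` builds clone panels carrying specified motif indels
(plus unmodified controls) with fixed invented flanks and exact truth;
`make_pcornutus_cr()` assembles a flounder-style CR (CSB3 placeholder,
5′-TR tract, M-TR section in typical/DS-03/QD-07 modes, 3′-TR tract with
optional variant copies) from the published motifs with invented neutral
flanks, since the true flanking sequences are not printed.

## 7. Numerical conventions

* Coordinates are 1-based inclusive; `start > end` marks an
  origin-wrapping interval and is legal only on circular records.
* Copy numbers are reported to 1 decimal as span/period; reported tracts
  always have at least 2.0 copies.
* Detection ties break toward smaller period, then smaller start;
  equal-scoring overlapping calls keep the higher score; harmonic
  duplicates (period multiples of the same array) are collapsed via the
  primitive period of the consensus.
* Percentages: half-up rounding, 2 decimals in tables, 1 in prose-style
  figures.
* Degenerate inputs: empty detection results are empty tibbles, not
  errors; empty survey input yields a zero Total row with `NA`
  percentages; encodings shorter than one motif are all-residual.
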
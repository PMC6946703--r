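---
title: "Analysing CRISPR spacer-acquisition recordings of horizontal gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing CRISPR spacer-acquisition recordings of horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprec)
```

## The recording model

A recorder strain over-expressing Cas1/Cas2 (and lacking interference)
converts DNA uptake events into new spacers at the leader-proximal end of
its Type I-E CRISPR array. `crisprec` treats the sequenced array amplicons
as the primary data and makes three modelling assumptions:

* **Array grammar.** A read is `leader + (R + spacer)* + R` with a fixed
  direct repeat `R`. Only spacers *flanked by two repeat occurrences* are
  trusted; everything else (missing repeats, gaps outside the plausible
  spacer length range) is flagged rather than rescued.
* **Polarity.** New spacers integrate leader-proximally, so the new spacers
  of an array are exactly the prefix before the first parental spacer. An
  array whose parental anchor cannot be recognized (e.g. destroyed by a
  sequencing error) is excluded from expansion statistics entirely — a
  deliberate stringency bias: it deflates totals slightly but never
  inflates the expansion rate with mis-segmented arrays.
* **Homology dichotomy.** A new spacer is *endogenous* iff it matches the
  recorder genome or recording plasmid at ≥ 80% identity AND ≥ 80%
  coverage; otherwise it is *exogenous* and attributed to transferred DNA.
  The AND rule means a spacer passing one criterion but not the other
  stays exogenous.

## The matching primitive

Spacers are short (~25–45 nt), so the package uses a purpose-built
seed-and-extend matcher rather than wrapping an external aligner: exact
k-mer seeds define candidate diagonals; each diagonal is evaluated
gaplessly over the full query:

* coverage% = aligned query columns / query length × 100 (below 100 only
  when the query overhangs a reference end);
* identity% = matching columns / aligned query columns × 100.

These are the `-id` / `-query_cov` semantics of global-over-the-query
search tools, which matters because "80% identity and coverage" is
ambiguous without fixing the denominators. Gapless evaluation is an
approximation — at 33 nt an indel-containing alignment virtually never
reaches the 80% or 95% thresholds anyway — and is checked in the test
suite against an exhaustive diagonal-scan oracle on 500 planted instances
(exact agreement required).

The endogenous filter runs **two passes**: seed length 8 first, then seed
length 5 for every spacer without an accepted (≥ 80/80) first-pass hit.
The rescue pass costs more (a random 5-mer seeds roughly every 1 kb of
reference) but guarantees sensitivity down to the identity region around
the threshold: any diagonal with ≤ 3 mismatches over ≥ 25 columns
necessarily contains an exact 5-mer. "No pass-1 hit" is interpreted as "no
accepted hit": sub-threshold alignments are never materialized, matching
the behaviour of identity-thresholded search tools and keeping the filter
linear in the number of spacers.

## Threshold calibration with a scrambled null

Database matching (default ≥ 95% identity and coverage, every hit
reported on both strands) is calibrated per experiment:
`scramble_spacers()` permutes each exogenous spacer's characters
(composition- and length-preserving, seeded Fisher–Yates), and
`calibrate_threshold()` scans a grid (80–100%) for the smallest threshold
at which scrambled spacers produce **zero** hits while real spacers still
hit. The scrambled hit rate is monotonically non-increasing in the
threshold by construction, which the package asserts on every calibration.
On clean synthetic data even 80% silences the null — the conservative
95/95 default is kept because real databases are many orders of magnitude
larger than any synthetic donor set, and the published calibration against
a full RefSeq-scale database lands at 95.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_mismatch` (repeat match) | 2 | bases | ~7% of the 29-bp repeat; fixed-length Hamming keeps parsing deterministic and O(read) |
| `spacer_len_bounds` | [25, 45] | bases | Type I-E spacers cluster near 33 nt; outside values mark the array malformed instead of truncating |
| `id_threshold`, `cov_threshold` | 80, 80 | % | recorder-filter stringency (experimental value) |
| `min_identity`, `min_coverage` | 95, 95 | % | database-hit stringency (null-calibrated experimental value) |
| `control_percent` | 0.03 | % | no-donor control exogenous rate. Protocol dependent — published values differ between defined-donor (~0.5%) and fecal (0.03%) workflows — hence an explicit, documented input rather than a constant |
| `min_spacers`, `fold` | 10, 3 | — | sample-call gates; effective threshold `fold × control_percent` = 0.09% |
| `window` | 200 | bp | coverage-profile resolution |
| `seed_k` two-step | 8 then 5 | bases | word sizes of the two-pass recorder filter |
| `seed_k` database match | 10 | bases | short-query word size of nucleotide BLAST |

## The synthetic recording generator

`sim_config()` states a world and the generator realizes it exactly:

* `expansion_rate` (default 0.01, matching ~1% expanded arrays in a 6-h
  single-donor recording) is **enforced**, not sampled: exactly
  `round(n_reads × rate)` reads receive events, so expansion percentages
  on error-free data are exact and test failures are informative.
* `exogenous_fraction` (default 0.35, within the reported 30–40% band) is
  an independent Bernoulli per event; endogenous events favour the
  recording plasmid 10:1 over the genome, reflecting the observed
  preference for high-copy replicons.
* `pam_bias` (default 0.5, the reported AAG share) places the protospacer
  immediately 3′ of an AAG on the protospacer strand by rejection-free
  sampling from the precomputed AAG/CTT site lists; non-biased draws are
  uniform, so the realized AAG fraction is
  `pam_bias + (1 − pam_bias) × p_chance` with `p_chance ≈ 1/64` — the
  recovery tests compare against this exact expectation, computed from the
  donor sequence by an independent oracle.
* An optional `hotspot` multiplies the per-base acquisition rate inside an
  interval, emulating the elevated spacer density between oriV and oriT of
  a conjugative plasmid.
* Errors are i.i.d. substitutions (`error_rate`); amplicon sequencing is
  substitution-dominated, and indels are deliberately excluded from the
  default model.
* References are uniform random sequences; recorder and donor sets are
  regenerated until **no 16-mer is shared** (either strand), which makes
  ground-truth attribution unambiguous.

What the generator does **not** emulate: conjugation kinetics and
donor:recipient titration (collapsed into the scalar rates), phage burst
dynamics, array PCR/gel-enrichment biases, chimeric reads, quality-score
structure, and — importantly — the compositional non-uniformity of real
genomes. A green round-trip test therefore establishes that the pipeline's
bookkeeping (parsing, polarity, classification, attribution) is correct,
not that its thresholds are optimal for any particular real community.

One generator default is arbitrary and configurable: the parental array
carries 2 spacers (the recorder's true parental content is
strain-specific); the direct repeat defaults to the canonical 29-bp
*E. coli* K-12 Type I-E repeat, again configurable because amplicon
dialects vary. `multi_acquisition_prob` (default 0.05) gives an expanded
array exactly two new spacers instead of one — a minimal stand-in for the
rare multi-acquisition tail.

## Numerical and degenerate-input choices

* All internal and TSV coordinates are 0-based half-open; GFF3's 1-based
  closed convention is converted at the reading boundary.
* Repeat finding is a greedy left-to-right scan over Hamming matches;
  with fixed-length occurrences greedy is optimal, so the occurrence count
  is monotone in `max_mismatch` (property-tested).
* Best-hit ties break by (coverage, identity) then lowest reference id,
  then lowest start — fully deterministic outputs under `sort`-stable
  rules throughout; dereplication orders by descending abundance then
  sequence.
* "Minimal" covering set is **greedy** set cover (ties: more uncovered
  spacers, longer reference, lexicographic id); exact cover is NP-hard and
  the published analysis does not state its procedure, so greedy is this
  package's formalization, with an exhaustive `exact = TRUE` mode for
  ≤ 20 references. On 1000 random ≤ 12-reference instances greedy matches
  the brute-force optimum ≥ 95% of the time and always covers every
  coverable spacer (acceptance-tested).
* Zero-hit references are reported with value 0 and a `zero` flag, never
  dropped.
* Empty inputs return typed empty results (`dereplicate`,
  `minimal_covering_set`, `filter_multi_mapping`); unusable samples (no
  status-`ok` array) raise errors rather than returning fictitious zeros.
* The multi-mapping removal fraction is reported over unique spacers with
  ≥ 1 hit, with an abundance-weighted alternative alongside, because the
  published 26.0% figure does not say which denominator was used.
* `percent_exogenous` uses all sequenced spacers as denominator by
  default (`percent_denominator = "new_spacers"` selects the alternative)
  since published usage mixes both.

## Known limitations

* The matcher is gapless by default; genuinely indel-divergent homology
  near the 80% threshold can be under-called (flag-enabled tolerance is a
  possible extension, and the 95/95 database threshold is unaffected in
  practice).
* PAM statistics on *dereplicated* spacers are biased low when acquisition
  concentrates on few AAG sites (duplicates collapse); per-occurrence
  counting is used for PAM recovery and recommended for real data.
* Greedy set cover can exceed the optimum on adversarial instances (~1%
  of random ones); use `exact = TRUE` for small reference panels.
* The pipeline does not assemble or type plasmids; provenance and
  annotation operations consume user-supplied databases and GFF3.
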
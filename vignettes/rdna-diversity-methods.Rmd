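---
title: "Methods: simulating and measuring 45S rDNA diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring 45S rDNA diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnavar)
```

This vignette documents the models, parameter choices and numerical
conventions behind `rdnavar`, and what the package's validation on
synthetic data does and does not establish about real data.

## The unit model and the variant catalog

The 45S rDNA unit is modelled as a 10,500 bp sequence with 1-based
inclusive annotation: 5′ETS (1–1840), 18S (1841–3644), ITS1, 5.8S,
ITS2, 25S (4264–7639) and 3′ETS (7640–10500, including the intergenic
spacer). The 18S and 25S coordinates are the published reference
annotation; the 5.8S/ITS boundaries are not published for this
reference, so the default places a 164 bp 5.8S centered between the 18S
end and the 25S start, with ITS1/ITS2 filling the flanks. All of this is
configurable through `unit_annotation()`.

ETS length variants are described declaratively as ordered lists of
repeat elements. Element *lengths* for individual D and R repeats are
not published — only amplicon totals and orderings are — so the defaults
are chosen once such that every published total holds:

* VARA = 1260 bp (P1/P3 amplicon, primers included): 21 (P1) + 80 +
  D1a 150 + D1b 66 + D2a 55 + D12 55 + D2b 55 + C1 310 + C2 310 +
  C3 59 + 75 + 24 (P3).
* VARB = VARA − one 310 bp C repeat = 950 bp. The remaining C repeat
  ("C-like") realizes the same sequence as C1, reflecting its origin as
  a fusion of the two VARA C repeats; this also makes the VARA→VARB
  difference exactly one contiguous 310 bp block.
* The Brassica-type insertion-free variant is 200 bp, which fixes the
  insertion (five D repeats + C repeats) at 1060 bp; the often-quoted
  "1.1 kbp" is treated as a rounded figure.
* The *A. cebennensis*-like variant is VARB without D1a, which fixes
  D1a at 150 bp (950 − 800).
* Every C-class element begins with the 59 bp C3 repeat, and the first
  base after that prefix differs between C1 and C2, so the shared
  C-repeat prefix is exactly C3.

The 3′ETS variants use 90 bp R repeats, a 54 bp segment (`rdel`)
removed by the deletion shared by VAR3–5 and VAR7, and a 30 bp segment
(`post_r2b`) additionally deleted in VAR7. The resulting amplicons
(VAR1 484, VAR2 574, VAR3 520, VAR4 610, VAR5 580, VAR6 664, VAR7 490)
respect all published orderings: VAR6 is the longest, and VAR7 is
slightly shorter than VAR3 by exactly the post-R2b deletion. Absolute
3′ETS amplicon sizes are not published, so only the orderings and
differences are meaningful.

Element sequences are realized from a seeded uniform ACGT source, with
rejection sampling against accidental primer-site matches; repeated
elements share one realization per element name, and primer landing
sites carry the printed primer sequences verbatim. In-silico PCR uses
exact primer matching (the synthetic templates embed primers verbatim,
and no mismatch tolerance is published), pairing each forward site with
the nearest downstream reverse-complement site within `max_len`.

## Genotype definitions and the relation tiers

Genotypes are defined by a required variant set plus pairwise abundance
relations. The field describes relations qualitatively ("most
abundant", "equivalent", "rare"); gel-band dominance is never
quantified, so the package makes the tiers explicit and exclusive. For
the ratio r = high/low of a variant pair:

* r < `dominance_ratio` (default 2.0) — the variants are *equivalent*;
* `dominance_ratio` ≤ r < `rare_ratio` (default 10.0) — the larger one
  *dominates*;
* r ≥ `rare_ratio` — the smaller one is a *rare* (trace) component.

Exclusive tiers keep the matching unique: "VARB dominant" (5R3) and
"VARA rare" (5R10) are disjoint, so no pattern matches two definitions.
A pattern matches a genotype when the detected variant set and all
pairwise tiers agree; zero or multiple matches yield "unclassified"
with diagnostics, never a nearest-match guess. Both ratios are
arguments of `classify_3R()`/`classify_5R()`; the test suite exercises
dominance ratios of 1.5, 2 and 3.

The shipped catalog has 12 3R and 10 5R definitions. The compositions
of 3R6, 3R7 and 5R5–5R9 are not described in the source material beyond
"rare" or "intermediate or longer variants"; their defaults are
explicit placeholders (built around VAR6 and the intermediate-length
AC800-like variant) chosen to be mutually distinguishable, and they are
configurable. VAR4 is always removed before 3R matching (it is too
variable and rare to define genotypes), and the 5% detection threshold
mimics the PCR detection limit that renders VAR5 invisible.

Band patterns come from two sources. *Truth mode* reads copy fractions
from the simulator's per-copy table. *Depth mode* maps reads to a panel
of context-flanked variant templates, discards ambiguous placements,
and normalizes per-template unique read counts by the number of
read-length positions whose substring is unique within the panel. This
effective-length correction (familiar from transcript quantification)
is required because the indel variants are nested — most of their
sequence is shared, and the informative, junction-spanning territory
differs per variant. VAR5 is excluded from the default panel: its
structure has no junction unique to it, mirroring its undetectability
by PCR.

## The simulator

`make_genome()` draws a unit class (ETS variant combination plus SNP or
indel edits) for every copy multinomially from the configured mixture
and realizes the array head-to-tail next to a random single-copy
backbone. `simulate_reads()` draws fragments uniformly, with normal
insert lengths (mean 350, SD 35 — only the mean is published; the SD is
a typical short-insert library value) truncated below at the read
length, 2 × 150 bp pairs, i.i.d. substitution errors, and a configurable
fraction of exact duplicate fragments. Qualities are constant because
the pipeline never uses them. All randomness flows from one seed per
operation, so genomes, read sets and whole pipeline runs are exactly
reproducible; pipeline manifests carry no timestamps so reruns are
byte-identical.

The defaults mirror the study design this emulates: 2 × 150 bp pairs at
350 bp insert, ~800 copies for a Col-0-like genome, a 0.03–0.1%
substitution error scale. The backbone defaults to 1 Mb rather than the
10 Mb chromosome-3 baseline: the estimator only needs a depth-stable
single-copy interval, and 1 Mb keeps desk-scale runs fast; 10 Mb is a
configuration option.

What the simulator does **not** emulate: sequencer-specific error
profiles, indel sequencing errors, GC bias, coverage waviness, adapter
or quality artifacts, and genuinely divergent rDNA unit sequences
(copies differ only by the configured ETS variants and edits). Passing
tests therefore demonstrate that the estimators recover truth under
idealized sampling noise — not that they are robust to every real-data
artifact.

## Mapping and pileups

The mapper places each mate independently: exact-match k-mer seeding
(k = 31, seeds tried at offsets 0, k, 2k, …; the first seed with a
verified hit decides) followed by full-length verification allowing at
most 5 substitutions per 150 bp read — more than three times the
expected errors plus true SNP load. The rDNA unit reference is treated
as circular so that reads spanning the head-to-tail unit junction map
as legitimate unit reads; placements past the end wrap. Reads with
multiple equally good placements are discarded (ties would otherwise
break leftmost). Alignment is substitution-only: no gaps, no
realignment, no mapping qualities. Indel-edited copies therefore
register as local coverage dips rather than as deletion calls; the
pileup's deletion column exists for externally supplied counts.

Duplicate removal keys on exact (mate1, mate2) sequence identity,
keeping the lexicographically smallest read name. On a high-copy tandem
array this removes not only simulated duplicates but also occasional
genuine fragment collisions (two copies sampled at the same unit offset
and length), which depresses rDNA depth by a small margin — the ~2–4%
downward bias visible in the copy-number recovery runs. This is a
property of sequence-identity deduplication on collapsed repeats, not
of the simulator.

## Copy number, profiling and cohort statistics

`estimate_cnv()` is the plain depth ratio; 18S and 25S are always
reported separately and never averaged. A zero-coverage background is
an explicit error, not an infinite estimate. The distribution
comparisons delegate to `stats::wilcox.test` (rank-sum W with midranks,
exact for small tie-free samples, normal approximation with continuity
and tie correction otherwise) and `stats::shapiro.test`; quartiles are
type-7.

`alt_allele_freq()` needs at least `min_depth = 10` reads at a position
— below that a 5% frequency is not measurable, and the position is
reported missing rather than zero. The flagging rule is strict: exactly
0.05 is not flagged. Cohort proportions divide by the number of
non-missing individuals at each position. No error-model correction is
applied to the 5% rule: at the default error rate (0.1%) and unit depth
in the hundreds, false flags above 5% are vanishingly rare, matching
the direct-threshold practice this implements.

Frequency tables round percentages half-up to one decimal (154/320 →
48.1, 229/320 → 71.6); banker's rounding would disagree at some
boundaries. "Unclassified" calls appear in tables but are excluded from
distinct-genotype diversity counts. CNV reports are ordered along the
altitude gradient.

## Problem sizes used in validation

The test suite and acceptance script run entirely on synthetic data at
desk scale, chosen to keep the full suite around a minute while leaving
comfortable statistical margins: copy-number recovery at 800 copies on
a 1 Mb backbone at 5× depth (three seeds, median within ±10%),
monotonicity at 10/100/800 copies, mixture recovery at 10,000 copies in
truth mode and 1,000 copies in depth mode (VAR1 within ±5 percentage
points), and a 20-individual cohort for the polymorphism-proportion
check (within 3 binomial SDs). The real-data quantities from the
motivating study (e.g. a cohort rank-sum W on 173 individuals) require
the original sequencing archive and are deliberately out of scope.

## Known limitations

* Genotype definitions beyond the explicitly described ones are
  placeholders; real 3R6/3R7/5R5–9 individuals would need catalog
  updates from gel evidence.
* Depth-mode band patterns assume the panel covers the variants present;
  reads from an unmodelled variant are assigned to the nearest
  modelled one or discarded.
* The mapper is not a general-purpose aligner: no gapped alignment, no
  base-quality model, and no claim of equivalence with production
  aligners — only truth-recovery on simulations is validated.
* Copy-number estimates inherit the small negative bias from
  sequence-identity deduplication described above, and assume the
  background interval is genuinely single-copy.
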
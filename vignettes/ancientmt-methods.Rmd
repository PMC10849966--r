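---
title: "Models and methods behind ancientmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ancientmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ancientmt implements the mitochondrial DNA stage of an ancient-DNA
skeletal screening workflow: fragment filtering, deamination-based
authentication, contamination estimation, hominin lineage
classification from diagnostic positions, damage-masked consensus
calling, matriline grouping by zero pairwise differences, and
tip-calibrated strict-clock dating. This vignette explains the models,
the parameters that matter, the numerical choices, and what the
simulation-based tests do and do not demonstrate about real data.

## The data model

All aligned data live in a single observation-level tibble: one row per
aligned base, carrying the fragment's metadata (`fragment_id`,
`ref_start`, `strand`, `mapq`, `read_length`) alongside the observation
itself (`ref_pos`, 0-based and wrapped modulo the reference length;
`read_pos`, 0-based from the 5' end *in read orientation*; `base` in
*reference orientation*). Keeping both coordinate systems explicit is
what makes strand handling exact: a read-orientation C→T substitution
is reference C read T on the plus strand and reference G read A on the
minus strand. mtDNA is circular, so fragments may span the origin; SAM
output linearises them with a documented "rotated" convention (records
may extend past the reference end; positions are interpreted modulo the
length) which `read_sam()` undoes.

User-facing positions (pileups, consensus site tables, diagnostic
tables) are 1-based, following mtDNA community convention.

## The synthetic library generator

Every downstream estimator is validated against data from
`simulate_fragments()`, which records its every decision in a truth
table. The generator emulates:

* **Fragment lengths**: lognormal with median 55 bp and log-scale sd
  0.35, clamped to [20, 150] bp — a typical ancient-DNA length
  distribution. Published screening studies rarely report the full
  distribution, so these are stand-in defaults, not reconstructions.
* **Terminal deamination**: single-stranded-library chemistry, i.e.
  C→T at *both* read ends in read orientation. Per-position
  probabilities decay geometrically, `delta[i] = delta[1] * 0.5^(i-1)`
  over a 15-position window; the terminal default `delta[1] = 0.4`
  sits inside the 33–50% range typical of well-preserved Pleistocene
  material. A read position inside both windows (reads shorter than
  30 bp) combines the two rates independently,
  `p = 1 - (1-d5)(1-d3)`.
* **Sequencing error**: a single uniform per-base substitution rate
  (default 0.001), applied after damage. Quality scores are not
  modelled.
* **Contamination**: fragments are drawn from an undamaged present-day
  contaminant genome (the reference plus 20 substitutions by default)
  with probability `contamination_fraction`.
* **PCR duplicates**: `inject_duplicates()` gives each fragment one
  extra copy with probability `duplicate_rate`; copies share start,
  end and strand and are re-sequenced from the damaged template with
  fresh error. Duplicating a duplicate joins the original's set.

What the generator does **not** emulate: indels, local coverage biases,
fragmentation hotspots, quality-score structure, mapping error beyond
the MQ column, and joint nucleotide misincorporation patterns beyond
independent terminal C→T. Tests passing on this generator therefore
demonstrate algorithmic correctness under the stated model, not
robustness to every artefact of real libraries.

## Filtering and deduplication

Fragments shorter than 35 bp or with mapping quality below 25 are
removed (strict inequalities: a 35 bp, MQ 25 fragment survives — the
boundary is tested). Duplicates are collapsed on the
(start, end, strand) key, the standard key for merged single-end aDNA
fragments. The representative's base at each site is the majority base
among duplicates, with ties becoming N; majority-consensus was chosen
over "keep best quality" because the model carries no per-base
qualities, and it is deterministic. Filters run before deduplication;
the order is logged so it is auditable. Two independent fragments that
happen to share a key are genuinely indistinguishable from duplicates
and are collapsed — at 10,000 fragments on a 16.6 kb circle this
affects a handful of pairs.

## Damage profile and deaminated-fragment classification

`damage_profile()` reports, for each position within 15 bp of each read
end, the fraction of read-orientation C→T among reference-C
opportunities, with 95% Wilson intervals (chosen for small-count
behaviour). Zero-opportunity positions report NA, never 0. A fragment
is "deaminated" when it carries at least one terminal C→T within 3
positions of either end; the window is configurable because published
workflows do not state it.

## The conditional-damage contamination estimator

Present-day contamination is estimated from the damage signal itself
under two assumptions: (i) contaminant fragments are undamaged, and
(ii) terminal deamination is independent between the two ends of an
endogenous fragment. Writing `d` for the endogenous 5'-terminal C→T
rate per opportunity and `eps = error_rate/3` for the rate at which
sequencing error mimics C→T, the rate over all fragments is

    p_terminal = (1 - c) * d + eps,

while the same rate over fragments that carry at least one 3'-terminal
C→T — an almost purely endogenous subset — is

    p_conditional = d + eps,

so

    c_hat = 1 - (p_terminal - eps) / (p_conditional - eps),

clipped to [0, 1], with a bootstrap over fragments for the 95%
interval. When the conditional rate does not exceed the error floor the
estimate is undefined and the function raises an explicit error rather
than returning a number. This estimator is deliberately transparent —
a linear mixture inversion, not a hidden-Markov damage model — and its
assumptions are tested by parameter recovery across contamination
levels 0–0.5. Its single-seed standard deviation is about 0.013 at
20,000 fragments and about 0.02 at 50,000, so decisions near the 5%
mode threshold are genuinely uncertain for small libraries; the
estimate always ships with `n_conditioning` so low-power calls can be
flagged.

## Lineage classification

Diagnostic positions carry the base state of each hominin mtDNA type
(H. sapiens, Neanderthal, Denisovan). Each fragment observation at such
a position is tallied in the pairwise contrasts whose states differ
there. With `damage_aware = TRUE`, an observation is discarded when it
could be a deamination artefact: it reads T in read orientation, lies
within 7 positions of a read end (the same window the consensus caller
masks, one masking concept across the pipeline), and one of the lineage
states at the site is C in read orientation. The verdict is the lineage
that wins *every* contrast it participates in at a fraction of at least
0.8 with at least 10 informative observations; those thresholds are
explicit stand-ins — the screening literature states no numeric rule —
and are configurable. Disabling `damage_aware` never reduces the number
of informative observations; on heavily damaged sapiens-state data it
measurably degrades the support fraction, which the tests quantify.

## Consensus calling

A site is called when, after masking, at least 5 fragments cover it and
the top base reaches 80% support; everything else (including top-base
ties) is N. Two boundary conventions are deliberate and tested:
coverage 4 fails while 5 passes, and support *exactly* 0.80 passes
(the rule is stated as "80% support" without strictness; inclusive was
chosen). Masking removes read-orientation C→T observations within 7
positions of either read end, unconditionally — a genuine T allele at a
reference-C site near a fragment end is masked too, which matches the
rule as stated and costs only coverage, not accuracy, away from the
ends. Masking context is the *reference* base, not a provisional
consensus: a single deterministic pass, at the cost of slightly
mismasking sites where the true genome differs from the reference by a
C/T polymorphism. When estimated contamination reaches 5%, calling
switches to deaminated fragments only; exactly 5% — undefined by the
`<5%`/`>5%` convention — resolves to the conservative deaminated-only
branch.

## Matriline grouping

Pairwise differences are counted over positions that are A/C/G/T in
both genomes. Zero-difference groups are **maximal cliques** of the
zero-difference graph, not connected components: with differing
coverage, zero-difference is not transitive, and the claim "no pairwise
differences among them" is exactly the clique property. Pairs whose
joint coverage falls below `min_overlap` (default 1,000 positions) are
never linked — a zero over a few hundred positions is uninformative —
and are reported separately as low-overlap pairs.

## Strict-clock tip dating

Full Bayesian tip dating is out of scope; the package implements a
transparent least-squares stand-in that preserves the scientific
operation (tip calibration under a strict clock):

1. Jukes–Cantor distances, `d = -(3/4) ln(1 - (4/3) p)`, over non-N
   sites (undefined at `p >= 0.75`);
2. neighbour joining (ape), with negative branch lengths floored at 0;
3. rooting on the outgroup at the midpoint of the separating branch
   (pairwise path lengths are preserved; a non-monophyletic outgroup is
   an error);
4. ordinary least squares of root-to-tip distance on tip age over the
   calibration tips — under a clock, `y = intercept - rate * age`;
5. inversion of the regression at the query's root-to-tip distance.

Uncertainty comes from a bootstrap over alignment columns, re-running
the whole chain per replicate (95% percentile interval). Replicates
with saturated distances or a non-positive rate are dropped and
counted; a non-positive rate on the full alignment is a hard error —
the method refuses to date rather than extrapolate a broken clock.
The percentile interval is widened, if necessary, to include the point
estimate so that `ci_low <= point <= ci_high` always holds.

The clock simulator used to validate the chain evolves sequences under
the exact Jukes–Cantor transition kernel along a serially sampled
coalescent tree (`simulate_dated_tree()`). The validation conditions
are: substitution rate 2.5e-8 substitutions/site/year (a standard human
mtDNA whole-molecule rate), 16 kb alignments, a calibration panel of 15
genomes spanning 0–45,000 years BP (modern genomes anchor the recent
end, mirroring how published panels mix modern and directly dated
ancient genomes), two deep outgroup tips near 160,000 years BP for
rooting, and a coalescent time scale of 30,000 years. Under these
conditions the 95% bootstrap interval covers a 45,000-year truth in at
least 90% of seeds and the mean recovered rate is within 10% of truth.
Coverage and rate recovery degrade with shorter alignments, narrower
calibration spans, or fewer calibration tips — the regression simply
runs out of signal, since the whole 45,000-year span contributes only
`rate * span * L` (about 18) expected substitutions along a root-to-tip
path.

## Problem sizes in the test suite

The acceptance-style tests run at the scales the recovery properties
are stated at: 10,000 fragments for filter/dedup truth matching, 20,000
for damage recovery, 50,000 per contamination level, roughly 30-fold
coverage (and 80-fold for the contaminated-mode comparison) for
consensus accuracy, and 50 independent seeds for clock coverage. These
sizes were chosen so each property is a multi-sigma test under the
generator's noise model.

## Known limitations

* The contamination estimator assumes an undamaged contaminant; modern
  DNA with mild damage would be partially counted as endogenous.
* Damage masking against the reference (not an evolving consensus)
  slightly over-masks genuine C/T variation near fragment ends.
* The dating stand-in reports bootstrap intervals, not posteriors, and
  carries no coalescent prior; its intervals are wider and its point
  estimates noisier than a full Bayesian treatment at the same data
  size.
* No indel handling anywhere in the chain; alignments are taken as
  given.
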
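---
title: "Assessing splice-altering variants with data-driven heuristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing splice-altering variants with data-driven heuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heurosplice)
```

## The problem

Between 10% and 30% of disease-causing variants are thought to act by
disrupting pre-mRNA splicing, yet most of them fall outside the two
invariant dinucleotides where the effect is obvious. Deep-learning
predictors return a single delta score without exposing *why* a variant is
predicted damaging, and they fail to encode well-established spliceosome
constraints such as the AG-exclusion zone or branchpoint spacing.
`heurosplice` implements the complementary, transparent approach: a set of
rule-based heuristics derived from large collections of annotated exons and
experimentally validated splice-altering variants (SAVs), each rule
carrying a *spliceogenicity* — the empirical proportion of variants in that
sequence context that altered splicing, with a 95% confidence interval and
the number of supporting variants.

## Coordinate nomenclature

Every rule is anchored to a splice site using an HGVS-like relative scheme:
`+k` / `-k` count into an intron from its donor (5') and acceptor (3')
ends; `E+k` / `E-k` count into an exon from its start and end. So the first
exonic base is `E+1`, the penultimate one `E-2`, and the third intronic
base after a donor `+3`. `map_to_relative()` and `parse_relpos()` implement
the mapping and its round-trip.

## The splicing-requirements checklist

`evaluate_checklist()` tests whether a candidate exon (or a cryptic site
pair) satisfies the minimal requirements for U2-type splicing:

| item | requirement | default |
|---|---|---|
| donor motif | `AG\|GTRAG` consensus; GC donors accepted only with a near-consensus remainder | GT (or GC + 8/9 match) |
| acceptor motif | `YAG\|` at -3..-1 | exact |
| PPT | pyrimidines in -24..-5 | >= 9 |
| AGEZ | no AG with its A in -13..-6 (AG at -5 tolerated) | exact |
| branchpoint | `TNA` adenosine 17-50 nt upstream of the 3'SS | indeterminate if absent |
| intron length | each flanking intron | >= 80 nt |
| exon length | first / internal / last | 30 / 31 / 119 nt |

Two derived constants follow from the spacing rules alone: a branchpoint
needs at least 45 nt to the upstream donor and at least 17 nt to the
acceptor, so the smallest intron that can splice at all is **62 nt**, and
with the 60 nt low-mis-splicing-risk donor spacing, **77 nt**
(`theoretical_intron_minimum()`).

Branchpoint absence is reported `indeterminate`, never `fail`, and does not
gate the overall verdict: the TNA motif captures only a minority of true
branchpoints, and dedicated branchpoint predictors have low positive
predictive value. Additional PPT metrics (longest run, totals) are computed
and reported but never gate the checklist; empirically they are too
stringent as mandatory criteria. A "strong" PPT — >= 12 consecutive or
>= 17 total pyrimidines in -24..-4 — is used as a *contextual* feature by
the PPT heuristic. The two PPT windows (-24..-5 for the minimum, -24..-4
for strength) are deliberately retained verbatim despite the off-by-one
between them, because each bound is tied to its own empirical calibration.

The in-silico variant of the checklist replaces the motif items with score
thresholds. Because calibrated thresholds are published only in figure
form, the package defaults (3 bits for either site) are flagged
(`insilico_thresholds_default = TRUE`) and a message is emitted until the
user supplies calibrated values.

## Site strength models

The bundled scorer is a first-order position-weight log-odds model over the
9 nt donor window (`E-3..+6`) and 23 nt acceptor window (`-20..E+3`),
built from representative splice-site base-frequency tables shipped as
plain TSV, so the whole package works with zero downloads. Scores are
log2-odds bits against a uniform background; `model_max_score()` is exact
(per-position maximization). When a directory of standard maximum-entropy
score matrices is available, `load_maxent_models()` provides numerically
compatible `score_donor()`/`score_acceptor()` drop-ins; the model-wide
maximum is computed exactly by dynamic programming over the factorization,
never by sampling. "Maximum score" always means the model-wide theoretical
maximum — the stricter, deterministic reading — rather than a per-locus
maximum.

## The decision trees

Donor-disruption (DD1-DD12) and acceptor-disruption (DA1-DA9) rules are
shipped as a versioned JSON data file and interpreted by a small engine
with a fixed predicate vocabulary (reference/alternative base tests,
dinucleotide creation/destruction, base-cascade comparisons, contextual
base tests, PPT strength, branchpoint proximity, motif match counts). Three
*base cascades* encode per-position preference orders: `G>A>C>T` at `E-1`,
`A>G>C=T` at `+3`, `G>A=C>T` at `E+1`; ties are genuine (a `C>T` change at
`+3` is `equal`).

Each rule has up to three subgroups: **standard** (most likely
splice-altering), **context** (a surrounding-sequence feature shifts the
probability), **auxiliary** (usually not splice-altering). Published
subgroup annotations are stored verbatim (including their printed
confidence intervals, which are near-Wald but not exactly reproducible
from (p, n) — so they are never recomputed); every subgroup rests on at
least 10 validated variants, and `load_rule_table()` rejects tables
violating that rule. Branches whose published topology exists only in
figure or supplementary form are implemented with text-consistent
topologies and clearly labeled `source: "synthetic"` annotation stand-ins;
they are excluded from every numerical acceptance check.

Design choices worth knowing:

* **Evaluation order** within a routed position follows the flowchart:
  e.g. at `+5`, a non-G reference short-circuits to the auxiliary subgroup
  before the `E-1` context is consulted; the auxiliary subgroup
  deliberately has no further sub-classification (too few variants).
* **Dual-window variants** (short exons/introns) are classified once per
  site class; the nearer site is primary, donor wins ties, and the other
  assignment is kept as `secondary`.
* **U12 introns** are detected from a user-supplied interval list only
  (motif-based minor-spliceosome calling is out of scope) and flagged
  `U12_unsupported`, never classified.
* **Exonic variants away from splice sites** are flagged
  `SRE_not_covered`: splicing-regulatory-element effects have too few
  validated examples for rules.
* **N bases** make any touched predicate indeterminate — an indeterminate
  never passes, and classification carries an `indeterminate` flag.
* **Indels** are decomposed: the alternative sequence is rebuilt around
  each preserved splice boundary, every changed window position runs its
  decision path, and the summary is the maximum-spliceogenicity match with
  all matches retained.
* The branchpoint-proximity predicate of the AG-creation rule uses the
  permissive `YNA` motif (the checklist default is `TNA`), matching how
  the acceptor flowchart counts branchpoint sequences.

## Pseudoexons

For deep intronic variants, `attribute_mechanism()` assigns one of four
categories in precedence order: creation of a canonical GT/AG, a
strengthened pre-existing candidate site (present and viable in both Ref
and Alt, with a gain of at least 0.1 bits — an epsilon that guards against
float-noise promotions, since no gain threshold is published), a new
candidate appearing only in Alt (PPT strengthening, AGEZ removal), or
unresolved (which is where SRE-driven cases land, by design).
`find_partner_sites()` then pairs the new site with every complementary
dinucleotide such that the implied exon — measured acceptor boundary to
donor boundary, inclusive, a choice documented here because the published
window's endpoints are not fully specified — is 31-750 nt, applies the
checklist items computable in region space, and keeps partners reaching
75% of the model maximum score, relaxed to an absolute 3 bits within
200 nt of the new site (shorter pseudoexons are preferred in vivo). The
search is validated against a brute-force oracle that enumerates every
dinucleotide pair and re-applies all filters independently.

## Evidence re-estimation

`estimate_spliceogenicity()` recomputes per-subgroup proportions from any
labeled variant table (only binary high-confidence labels are kept; a
strict mode errors on unknown labels), with clamped Wald intervals
(z = 1.96); estimates are tagged `user_estimate` and never overwrite the
bundled values. `validate_subgroups()` flags subgroups under 10 variants
and context subgroups separated from their standard subgroup by fewer than
15 percentage points. `aggregate_outcomes()` computes multi-label outcome
profiles (percentages may sum past 100) per splicing region, gated at more
than 20 outcome-reporting SAVs; a variant with several outcomes counts
once in the denominator (the denominator is "variants with at least one
reported outcome", a documented choice).

## What the synthetic generator emulates — and what it does not

`generate_compliant_transcript()` states a world: introns of 100-300 nt,
internal exons of 80-200 nt, donor/acceptor motifs sampled from the same
frequency tables as the bundled scorer (canonical dinucleotides and the
acceptor YAG forced), a planted TNA branchpoint 20-40 nt upstream of each
acceptor, an 85% pyrimidine PPT, and a scrubbed AG-exclusion zone. Those
defaults make generated exons pass the manual checklist essentially
always, which is what the >= 95% acceptance property checks — it
establishes that the checklist and the generator agree about the stated
requirements, not that real GENCODE exons would pass at the published
rate (that number depends on the real annotation and genome, which this
package does not download). The generator does not emulate genome-wide
base composition, conservation, SRE landscapes, or U12 introns.

`generate_variant_panel()` is the inverse of the classifier: it plants the
context a requested subgroup needs and emits an SNV verified to classify
there. `generate_labeled_table()` draws Bernoulli labels at each
subgroup's true spliceogenicity and samples outcomes with weights
calibrated by fixed-point iteration so the realized outcome marginals
match the configured map (51.3% skipping, 36.3% truncation, 17.4%
retention, 16.2% extension, 19.1% multi-outcome rate) — a primary outcome
plus, with the multi-outcome probability, one extra. Everything is
deterministic under a seed.

## Numerical choices and known limitations

* Scores are reported in log2 bits; comparisons use a 1e-6 tolerance.
* Exonic positions equidistant from both exon ends report `E+k` as primary
  (both forms are always available); even-length intron midpoints belong
  to the donor side. Neither convention is published; any fixed rule works.
* Internal coordinates are 0-based half-open; VCF/GTF conversions happen
  only in readers and writers.
* **The Wald coverage criterion is honestly red.** The acceptance suite
  simulates subgroup tables at the bundled (p, n) and asks the clamped
  Wald interval to cover the truth 93-97% of the time. Measured coverage
  is about 91%, and that is a property of the interval, not a bug: at
  p = 99.2% with n = 124, the draw contains zero failures with
  probability 0.37, the interval degenerates to [100, 100], and the truth
  is missed. Wald is retained because the published intervals are
  near-Wald; switching to Wilson or Clopper-Pearson would change the
  bundled semantics to make a test pass, which this package refuses to do.
* The package takes one genome build per run and does not perform
  liftover; it assigns no pathogenicity classes — spliceogenicity is
  evidence, not a verdict.
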
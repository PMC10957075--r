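---
title: "Profiling chemical liability motifs in antibody variable domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chemical liability motifs in antibody variable domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abliab)
library(dplyr)
```

## The problem

Therapeutic antibodies degrade chemically: asparagines deamidate,
aspartates isomerize, methionines and tryptophans oxidize, Asp–Pro bonds
hydrolyse, stray cysteines scramble disulfides, and N-X-S/T sequons
acquire glycans. All of these risks are associated with short sequence
motifs, so annotating "sequence liabilities" is a staple early
developability screen. It is also notoriously over-predictive: nearly
every antibody — natural or marketed — carries several such motifs, most
of which never cause trouble. `abliab` implements both halves of a
practical protocol: (1) detect liability motifs in IMGT-numbered variable
domains against a codified reference, and (2) prioritize them with three
*low-risk flags* — germline, therapeutic, and surface — each of which
marks a detected motif as probably benign.

## The liability reference

`liability_reference()` ships 13 liability categories at three severity
levels (deamidation appears at three severities and fragmentation at two;
every other category has one). Motif patterns use a deliberately tiny
dialect — literal residues, bracketed classes, one-level negation
(`N[^P][ST]`), and top-level alternation — which keeps every pattern's
expansion finite (`expand_pattern()`), so a brute-force sliding-window
enumeration can serve as an exact test oracle for the scanner. Two
entries are positional rather than pattern-based: a missing conserved
cysteine at IMGT 23 or 104 (`mCys`) and a cysteine anywhere else
(`xCys`).

Users can extend the reference: it is a tab-separated text file (one
entry per line, `#` comments) validated on load, so in-house motif
catalogs can be dropped in without code changes.

## Numbering, regions, and scope

Numbering is consumed, not computed: the package parses the tabular
output of external IMGT numbering tools (an AIRR-style gapped TSV or a
wide per-position CSV) rather than re-implementing HMM-based numbering,
which is a known source of version drift. Regions follow the standard
IMGT delimitation (FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3
66–104, CDR3 105–117, FR4 118–128); insertion codes inherit the region of
their base number, and insertion order is taken from the input, never
re-sorted.

Two scope decisions matter and are configurable:

* **Motif adjacency is chain adjacency.** Chemistry acts on consecutive
  residues of the polypeptide; IMGT numbering gaps are notation. A motif
  spanning a numbering gap is still a motif.
* **CDR scope is "inclusive" by default**: a CDR-scoped motif is reported
  when at least one of its residues lies in a CDR. This captures
  boundary liabilities (one residue in the framework, one in the CDR),
  which region-attribution reports as `boundary`; a `strict` mode
  (all residues in a CDR) is available. The `fv` scope spans the whole
  numbered domain 1–128 including FR4, which is the plain reading of
  "variable fragment" for glycosylation and integrin-binding motifs.

Overlapping motifs are all reported independently (the string `NGS`
yields both a deamidation hit on `NG` and a glycosylation hit on `NGS`);
the reference defines independent liabilities and no de-duplication is
attempted, including double-motif regions such as `NGNT`, where each
match is counted.

## Quality control

`qc_filter()` applies, in order: length within [40, 1000]; standard
residues only; no `!`; numbering/germline assignment present; all three
CDRs present; for paired data one heavy and one light chain per unit; and
deduplication on the exact variable-domain string (concatenated H+L for
paired units). Each rejected record carries exactly one reason — the
first failing rule — so rejection ledgers are deterministic and testable,
and the filter is idempotent.

## The three low-risk flags

**Germline** (`flag_germline()`): a motif is flagged when every one of
its residues occurs at the identical IMGT position (number + insertion)
with the identical amino acid in a consulted human germline segment.
"Same position" is exact by design — the flag asserts the motif itself
exists in germline, not a homolog. Only V and J segments are consulted
(D-segment identification is unreliable), so most of CDR-H3 can never be
flagged. The default mode consults the chain's assigned top V and J; a
`mode = "any"` variant consults every segment in the reference and flags
a superset of the assigned mode.

**Therapeutic** (`flag_therapeutic()`): a motif is flagged when its
(chain class, motif, IMGT start) occurs in *strictly more than* 5% of
marketed-panel chains (`build_therapeutic_table()`); a frequency of
exactly 0.05 does not flag. Kappa and lambda chains are pooled into one
"light" class by default — IMGT positions are comparable across light
loci and marketed panels are small — with the heavy class separate. The
frequency table stores exact counts and denominators beside the float so
the rational arithmetic is auditable. The denominator is chains of the
panel (bispecific arms count as independent antibodies).

**Surface** (`flag_surface()`): residues with relative solvent-accessible
surface area strictly above 7.5% are `exposed`, otherwise `buried`; a
motif is `buried`/`exposed` when all its residues are, `partial` when
mixed, and `unknown` when any residue lacks structure coverage (or the
hit has no residues at all, as for a missing cysteine). The flag
requires a cognate heavy/light pair: on an isolated chain the interface
residues would be misclassified as exposed. By default `partial` is *not*
treated as benign (conservative).

SASA itself is computed by Shrake–Rupley sphere sampling over the heavy
atoms of the full H+L complex: a deterministic golden-spiral lattice of
960 points per atom (probe 1.4 Å, Bondi van der Waals radii), so results
are bit-stable; relative SASA normalizes by pinned theoretical maximum
ASA per residue type (Tien-style constants). The test suite checks the
integrator against an independently coded equal-area-grid integrator at
four times the point density (agreement within 2% of an atom's full
sphere area), and checks occlusion monotonicity, rotation invariance and
per-residue additivity.

A liability is *benign under a flag combination* when any applied flag in
the combination marks it low-risk (`benign_under()`); remaining-after-
combination accounting in `summarize_dataset()` is monotone over
combinations and conserves totals by construction, and both properties
are asserted on random synthetic datasets.

## Statistics

`summarize_dataset()` reports prevalence (share of units with ≥1
liability), totals, mean/sd/median per unit, per-type and per-region
counts (boundary hits keyed by their flanking regions), and the
remaining liabilities/units per flag combination. For benchmarking
against measured modification data, `benchmark_flags()` stratifies
percent-modification by flag status and, for oxidation data, forms 2×2
tables (oxidation × flagged, restricted to methionine-annotated
molecules; a molecule counts as flagged when at least one of its
methionines is) and applies `fisher_exact_2x2()` — an exact two-sided
test by hypergeometric enumeration, with the sample odds ratio
`ad/bc`. Welch's t-test (`welch_t_p()`, with a p = 1 convention for
degenerate identical zero-variance samples) and pairwise chi-squared
tests with Bonferroni correction over the number of pairs
(`chi2_pairwise_bonferroni()`, pooling count bins with expected value
below 1) round out the survey statistics.

## What the synthetic generators emulate — and what they do not

Everything the package tests against is generated in code
(`make_toy_germline_set()`, `generate_chains()`,
`generate_therapeutic_panel()`, `generate_toy_structure()`,
`generate_benchmark_records()`). The central trick is a *motif-free
scaffold alphabet* {E, F, I, L, Q, V}: no default-reference motif can be
formed from these residues, and every planted motif string is chosen so
that, with a two-residue separation margin, it cannot combine with its
neighbourhood into a second motif. Planted ledgers are therefore exact —
the generator verifies by re-scanning — and pipeline tests can demand
exact recovery of counts, tags, start positions and region attributions
rather than approximate agreement. Toy structures place one pseudo-atom
per residue on a widely spaced backbone and bury residues under a fully
occluding dummy shell, making expected exposure classes exact while
exercising the real SASA integrator.

The price of exactness is realism. Synthetic chains have no somatic
hypermutation, no clonal structure, no realistic residue composition, no
length variation in CDR3, and toy structures are not protein-like.
Passing tests therefore demonstrate the *correctness of the machinery* —
scanning, flag logic, accounting, integration — on controlled inputs;
they do not validate biological claims about real repertoires, which
require real corpora, real germline sets, and real structural models
supplied by the user.

## Numerical and design choices

* Problem sizes in the test-suite and acceptance script (1,000 random
  chains for the oracle equivalence check, 150 synthetic paired units
  for the corpus summary, 10 structurally modelled units, 50 seeded
  burial plans) were chosen to exercise every code path while keeping a
  full run in the minutes range on one core.
* Thresholds are strict inequalities at both published constants (5%
  therapeutic prevalence, 7.5% relative SASA), and the boundary cases
  are pinned in tests.
* Fisher's two-sided p sums hypergeometric outcome probabilities not
  exceeding the observed one, with the conventional `(1 + 1e-7)`
  relative tolerance for ties.
* Degenerate inputs are data, not crashes: QC rejections and unmatched
  benchmark records are returned as ledgers; empty reference patterns,
  all-zero contingency tables, infeasible panel frequencies and
  unsatisfiable planting plans raise named errors.
* The wide numbered-CSV writer orders insertion columns by first
  appearance, so parse → serialize → parse round-trips exactly.

## A worked miniature

```{r example}
germ <- make_toy_germline_set(seed = 1)
plan <- tibble::tibble(motif_tag = c("DeAmdH", "MetOx"),
                       region = c("CDR3", "CDR3"))
gen <- generate_paired_units(6, plan_h = plan, plan_l = plan,
                             seed = 42, germline = germ)
kept <- qc_filter(gen$chains, paired = TRUE)$kept

panel <- generate_therapeutic_panel(
  tibble::tibble(motif_tag = c("DeAmdH", "FragM"),
                 imgt_start = c("30", "58"),
                 frequency = 0.25),
  n = 20, seed = 7)
ttab <- build_therapeutic_table(panel$panel)

prof <- profile_antibody(kept, flags = c("germline", "therapeutic"),
                         germline = germ$segments,
                         therapeutic_table = ttab)
prof
summary <- summarize_dataset(prof)
tidy(summary)
```

Each unit carries its two planted motifs per chain plus the liabilities
inherited from its germline; the germline flag removes exactly the
inherited ones, which is what the remaining-liability accounting shows.

## Limitations

Numbering and structure prediction are out of scope by design; the
package consumes their outputs. The shipped reference is the published
13-category set, not the larger internal catalogs some organizations
maintain — the text format exists precisely so users can extend it. The
surface flag inherits all caveats of the structural model it is fed, and
the therapeutic flag is only as representative as the marketed panel
used to build the frequency table.
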
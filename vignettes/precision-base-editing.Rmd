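---
title: "Designing and quantifying high-precision cytosine base editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying high-precision cytosine base editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precisebe)
```

## The problem

Cytosine base editors (BEs) are fusions of a Cas9 nickase and a cytidine
deaminase that convert C to T without a double-strand break. Two practical
limits dominate their use. First, a conventional editor deaminates any C
inside a multi-nucleotide *activity window* upstream of the PAM, so a
target C flanked by *bystander* Cs is edited imprecisely. Second, editing
requires a PAM (NGG for wild-type SpCas9) at the right distance from the
target. Narrow-window editors built from C-terminally truncated deaminases
— CDA1 truncations that predominantly edit the C 18 nt 5' of the PAM
(written C-18), and APOBEC3A (A3A) truncations that prefer C-16 and C-15 —
together with Cas9 PAM variants (VQR: NGA, VRER: NGCG, xCas9: NG/GAA/GAT,
SpCas9-NG: NG) make precise single-C editing possible for most sequence
contexts.

`precisebe` packages the computational side of that workflow: guide/PAM
discovery, an editor knowledge base with a context-rule recommender, a
scanner for pathogenic T>C (A>G) variants, per-position C-to-T
quantification from amplicon reads, substitution-spectrum tallies of
off-target variant calls, and seed-deterministic simulators that provide
ground-truth-labelled inputs for every analysis step.

## Coordinate conventions

All genomic intervals are 0-based and half-open on the + strand. Positions
within a protospacer are expressed PAM-relative and negative: -1 is the
base immediately 5'-adjacent to the first PAM base, so in the default
20-mer protospacer C-18 is protospacer offset 2:

```{r}
pam_relative_index(2)    # offset 2 -> -18
protospacer_offset(-18)  # and back
```

The protospacer length is fixed at 20 by default (the SpCas9 standard) and
configurable in `find_guide_sites()`.

## Guide discovery and degenerate PAMs

PAM motifs use the degenerate codes the rule table needs — N (any base),
D (not C), R (A or G), Y (C or T) — and nothing else; unsupported codes are
rejected loudly rather than silently accepted. An ambiguous N in the
*subject* sequence matches pattern-N only, never a literal or D/R/Y: a
site is called only when the evidence supports it.

```{r}
s <- c(demo = paste0(strrep("C", 20), "TGG"))
find_guide_sites(s, builtin_pam_specs()["SpCas9"])
```

Overlapping and nested motifs are each reported under their own Cas9
variant, and a motif shared by two variants (NG for xCas9 and SpCas9-NG) is
reported once per variant, because downstream recommendations are
variant-specific.

## The editor catalog

`builtin_catalog()` holds a profile per editor: compatible PAMs, activity
window (an interval of PAM-relative positions), preferred positions
(most-preferred first) and an optional trinucleotide context preference
(TCR for eA3A). Windows carry a provenance flag:

* `paper-stated` — explicit range statements (the full-length CDA1 editor
  window spanning C-14..C-20; the nine-nucleotide A3A-BE3 window; the
  A3A d182 preference for C-15/C-16).
* `figure-informed-default` — defaults consistent with the polyC editing
  profiles and with the rule table itself. Two coherence arguments fix
  otherwise under-determined edges: an editor recommended for a
  no-bystander target at a distance must be active there (so the A3A-NL
  window reaches -20), and a bystander caveat at a position implies
  bystander risk there.
* `external-citation` — YEE-BE3 and BE-PAPAPAP are recommendable names
  from the wider literature and deliberately carry **no** window profile;
  asking `bystander_report()` about them is an error, not a guess.

The deletion-series naming uses ASCII `d` for the Greek capital delta:
`nCDA1d188-BE3` retains CDA1 residues 1..188. Since CDA1 is 208 residues
and A3A 199, `truncation_removed()` recovers the printed deletion sizes
(d188: 20 removed; A3A d182: 17 removed).

## The recommendation rules

The 19-row rule table maps a *distance bucket* (`<-19`, `-19` … `-14`,
`>-14`) plus either a `no-bystander` condition or an anchored IUPAC context
pattern to an ordered editor list. Three aspects of the encoding were
genuinely open and are resolved as follows:

* **Pattern anchoring.** The published table marks the target C
  typographically, which plain text loses. Anchors are reconstructed from
  the prose descriptions (e.g. CCDDD at -19 anchors its *second* C on the
  target: "a bystander C directly upstream") and stored explicitly as
  `target_offset`, overridable per rule.
* **Bystander requirement.** A pattern rule describes a bystander
  situation, so it additionally requires that at least one non-target
  position of the aligned pattern actually reads C. Without this, NCN
  (whose Ns match anything) would fire on bystander-free targets that the
  `no-bystander` rows already govern, and no row could be matched
  exactly.
* **Per-editor no-bystander.** "No bystander" means no other C within
  *that editor's own* window — a per-editor test, not a global one. A
  no-bystander row therefore recommends only the subset of its editors
  whose windows are clean.

Matched rules are ordered by specificity (count of non-N pattern
positions, descending) then table order; the final list is the
deduplicated concatenation, preserved in table order within a cell (the
paper does not rank within cells, and neither do we). When nothing
matches, `precise` is `FALSE` with an explicit warning — the YCC-15
context (Y = C or T) is the documented gap case, a direct consequence of
the A3A editors' C-16 >= C-15 preference:

```{r}
proto <- "AAAATCCAAAAAAAAAAAAA"  # T-17 C-16 C-15(target)
recommend(proto, -15)
```

## Scanning candidate pathogenic variants

`scan_variants()` emulates a ClinVar-style pass: each record carries >= 25
nt flanks around a focal base that reads C on at least one strand (a T>C
variant as reported, or an A>G variant via its complement). Both strand
representations are scanned with every PAM spec; every guide placing the
focal C inside any cataloged window is a candidate.

Candidate ranking had two open points, resolved as the package's own
design:

* **PAM deployability.** The rule table names editors in their NGG (BE3)
  form. CDA1-derived fusions were built for the whole Cas9 variant panel
  and tolerate Cas9 replacement, so they are treated as deployable behind
  every paneled PAM; A3A- and APOBEC1-based editors remain NGG-only. A
  candidate counts as `precise` only if a matched rule offers at least
  one editor deployable through the site's actual PAM. This matters
  because an NG PAM nests inside every NGG: the nested, frame-shifted
  "shadow" site can match a rule whose editors cannot actually be used
  there.
* **Precision before position.** Precisely-addressable candidates rank
  ahead of imprecise ones; among them the position priority ranking
  C-18 > C-17 > C-19 (extended by the A3A positions -16 then -15 as
  fallbacks, configurable) decides, then fewest high-risk bystanders,
  then smallest PAM distance, then the reported strand. Ranking position
  above precision would let an imprecise shadow placement at a
  higher-priority position displace a precise correction — the opposite
  of the scan's purpose.

Verdicts are `precisely-correctable` (best candidate matched a rule),
`bystander-prone` (candidates exist, none precise) or `not-targetable`.
Records with short flanks are skipped with a warning, never fatally.

```{r}
set.seed(1)
vt <- simulate_variant_table(6, fraction_targetable = 0.5, seed = 4)
scan_variants(vt$variants)[, c("id", "verdict", "best_position",
                               "recommended_bes")]
```

## Quantifying editing from amplicon reads

`anchor_reads()` implements deliberately strict, alignment-free anchoring:
a read is usable iff it contains exact matches to both 10-nt reference
flanks of the protospacer (either orientation) separated by exactly the
protospacer length. Anything else is tallied as `short`, `indel` (both
flanks present at the wrong spacing) or `unanchored`. There is no base
quality filtering by default — the data this emulates are high-coverage
yeast amplicons with exact flank anchoring — and reads are conserved:
usable + discarded = total, always.

`quantify_conversions()` reports, for every reference C of the
protospacer, `100 * (usable reads with T) / usable_reads`, with C>A/C>G
read separately as `c_to_other`. The denominator is *usable* reads: raw
totals are also carried so both can be reported.
`summarize_window()` thresholds the profile (default 10%), with
deterministic tie-breaks for the predominant position: nearest to -18
(the headline position of the CDA1 editors), then more PAM-distal; the
predominance ratio uses `Inf` as the sentinel when the runner-up is zero.

`canavanine_frequency()` is the companion plate-count statistic: induced
mutation frequency as resistant / total colonies, erroring on a zero
denominator and warning (but answering) when resistant exceeds total.

## What the simulators emulate — and what they do not

`simulate_reads()` generates full-length amplicon reads under the
measurement model behind per-position conversion percentages: independent
per-C conversion by default, a `linked` mode (off by default) in which a
read is edited with probability `p` and converted Cs concentrate in edited
reads — real BE outcomes co-edit processively within a window, but the
true correlation structure is not recoverable from printed figures, so
linked-mode parameters are user-set, not calibrated. Sequencing error is
uniform per base; FASTQ qualities are constant because the quantifier
ignores them. No platform-specific error profile, PCR duplicates or
chimeras are modelled — passing recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to every
artefact of real sequencing data.

One numerical subtlety: the quantifier estimates the *observed* T
fraction, whose expectation under the error model is
`rate * (1 - e) + (1 - rate) * e / 3`, marginally below the conversion
rate at high rates. Recovery checks compare against that expectation —
the exact binomial null for the statistic.

`simulate_variant_table()` builds records in an A/T-only background, so a
targetable record's embedded site is provably the only PAM-bearing one
and a non-targetable record provably has none (every paneled motif
requires a G). Truth labels carry the intended position; the scanner may
legitimately settle on a different (better-ranked) placement when a
nested alternative PAM creates one, so agreement is asserted on verdicts.

`simulate_variant_calls()` emits an exact requested composition over the
six complement-collapsed substitution classes plus 1-nt indels; its
round trip through `tally_variants()` is exact by construction. All
generators restore the caller's RNG state and are byte-reproducible from
their seed.

## Problem sizes and tolerances

The validation suite uses 300-nt sequences against a brute-force
every-offset oracle for guide discovery (100 seeded sequences), read sets
of 10^3–10^4 over conversion rates 0.05–0.9 for quantifier recovery
(within 3 binomial SEs in >= 99% of 100 replicates), and 200-record
variant tables for scanner/truth agreement — sizes at which every check
runs in seconds to a couple of minutes on a single CPU while keeping
binomial standard errors small relative to the effects asserted.

## Known limitations

* Window extents beyond the tested polyC targets are figure-informed
  defaults, flagged as such, not assertions.
* Editing efficiency magnitudes are not modelled — only windows,
  preferences and context rules.
* The scanner reports all candidate placements rather than deduplicating
  overlapping NG-derived candidates; the ranking chooses among them.
* Off-target guide specificity scores (MIT/CFD), read mapping, variant
  calling and significance testing of tally differences are out of scope;
  tallies surface counts and frequencies only.
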
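---
title: "Classifying plant Gγ subunits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant Ggamma subunits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammatype)
```

# The classification model

Plant heterotrimeric G-protein γ subunits share a conserved ~60-residue
central domain — the part that binds Gβ — flanked by a variable
N-terminus (roughly 10–75 aa) and a C-terminal region whose architecture
varies enormously. `gammatype` treats the C-terminal architecture as the
classifying signal and the central domain as the coordinate system.

Dissection starts at the **anchor**: the first match of `[DE]-P-L-[LI]`
(the "DPLL" block, template positions 51–54). Everything after the
anchor is the *tail*, and the decision procedure of `classify_gg()` runs
in a fixed order:

1. no anchor → `unclassified`;
2. tail at least `l_c` residues long **and** cysteine fraction at least
   `c_min` → **type C**;
3. otherwise a terminal CaaX box (cysteine exactly at −4, nothing after
   −1) → **type A**;
4. otherwise no cysteine in the last `window` residues → **type B**;
5. otherwise `unclassified`.

The C-before-A order is load-bearing: roughly half of the long
cysteine-rich tails also end in a CaaX-like motif, and a CaaX-first rule
would mislabel them. Every threshold comparison is kept as an evidence
column so a call can be re-derived from the sequence alone.

Positions near the C-terminus are reported as negative indices, −1 being
the last residue, matching the field's "−4 cysteine / −6 cysteine"
usage. `detect_caax()` reports the −4 cysteine as the prenylation site
and, when a second cysteine sits at −6 (the `C-x-C-a-a-X` arrangement of
tails like `...CGCSIL`), flags it as the S-acylation candidate.
`predict_transferase()` reads only the X residue: leucine/isoleucine
implicate geranylgeranyltransferase I, {M, Q, A, C, S} implicate
farnesyltransferase, anything else is ambiguous; the two sets are
disjoint by construction. The a₁/a₂ positions are deliberately
unconstrained — plant CaaX boxes often carry tryptophan at a₁, so
aliphatic-ness is an annotation, never a filter.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `l_c` | 50 aa | minimum tail length for type C; below the ~70-aa minimum extension seen in plants, leaving margin for shorter homologs |
| `c_min` | 0.15 | minimum tail cysteine fraction for type C; below the observed 19% lower bound, same margin logic |
| `window` | 25 aa | the C-terminal stretch that must be cysteine-free for type B; "proximity of the C-terminus" has no quantified value in the literature, so this is a package choice, exposed as a parameter |

The tail is measured **from the anchor end**, not from a hypothetical
CaaX position — the alternative convention would be undefined for the
CaaX-less types. The evidence columns record tail length and cysteine
fraction under this convention.

# Majority-rule consensus

`cterm_consensus()` right-anchors sequences (position −1 is every
sequence's last residue) instead of aligning them: C-termini of
different lengths have no meaningful alignment, and the terminal
residues are the biologically comparable ones. At each position the
residue whose frequency **strictly exceeds** 50% of contributing
sequences wins; otherwise the position is written `x`. Exact ties at 50%
are `x` — "over half" is read as a strict inequality, which also makes
the rule stable under duplication of the input. Sequences shorter than a
position, gaps, and `x` symbols do not contribute to that position's
denominator.

`hierarchical_consensus()` prevents an over-represented group from
dominating: per-group consensi are joined by a second majority pass in
which `x` does not vote, so each group weighs equally regardless of
size. `frequency_matrix()` exposes the data behind a sequence logo —
per-position residue frequencies over the 20 amino acids and information
content `log2(20) − H` in bits; gaps and `X` are excluded from the
denominator since they carry no residue identity.

# Gene structure projection

Exon boundaries live in CDS nucleotide space; the comparison of intron
positions across genes happens in protein space. For cumulative CDS
length *c* after an exon, `project_boundaries()` reports residue
`ceil(c/3)` with phase `c mod 3`. The codon-split convention is not
standardized in the literature we follow; ceil-plus-phase was chosen
because it marks the boundary on the single residue containing the
split and makes the projection exactly invertible
(`exon_lengths_from_projection()` is the inverse, and a property test
round-trips it). Only exon lengths matter — the projection is invariant
to shifting all genomic coordinates. `compare_boundaries()` then carries
each residue index through the gap structure of that gene's row in a
protein alignment; boundaries landing in one column across genes are the
shared intron positions. Gene models are taken on the coding strand,
1-based inclusive, with the stop codon included by default
(`includes_stop = TRUE`), so protein length is `cds/3 − 1`.

# Tandem repeats

`find_tandem_repeats()` scans every start and unit length (default 5–10
aa, the range typical of the cysteine-rich tails) and grows an array
copy by copy while the next unit's identity to the running consensus
stays at or above `min_identity` (default 0.7 — "sound identity" is not
quantified anywhere, so this is a configurable package choice). The
running consensus is the per-column majority with ties resolved to the
first copy's residue, which keeps the procedure deterministic.
Overlapping candidates are resolved greedily by span, then leftmost
start, then shorter unit. The whole procedure is simple enough that the
test suite holds it to exact agreement with an independent exhaustive
enumeration on regions up to 200 aa.

# Central-domain phylogeny

Only the central domain is informative for trees — the flanks do not
align. `extract_central_domain()` takes the column window
`[anchor_start − 45, anchor_end + 2]` (clipped to the alignment), enough
to cover all seven Gβ-contact positions; the window bounds are
configurable because no canonical domain boundary exists. Distances are
p-distances with pairwise deletion (`X` never matches anything,
including another `X`), optionally Poisson-corrected `−ln(1 − p)` with
`p` capped at 0.95 and capped pairs flagged as saturated.

`nj_tree()` is a standard Saitou–Nei agglomeration with two
determinism-motivated choices: Q-criterion ties break on the
lexicographically smallest pair of cluster representatives, and a
negative branch estimate is floored at zero with the deficit moved to
its sister branch so pairwise path lengths are preserved. The suite
checks exact recovery of additive matrices against an oracle that
enumerates every unrooted topology for up to six taxa, and cross-checks
topologies against an independent NJ implementation.

`bootstrap_support()` resamples columns with replacement, rebuilds the
tree per replicate, and scores each labeled group by the fraction of
replicates in which its taxa form one side of a bipartition — monophyly
as an unrooted-tree notion. One seeded generator drives all replicates
in order (replicate *r* consumes draw *r*), so supports reproduce bit
for bit. Groups with fewer than 2 or more than *n*−2 taxa have no
nontrivial bipartition; their support is reported as absent (`NA`), not
as zero. `majority_consensus()` keeps exactly the bipartitions occurring
in strictly more than the threshold fraction of trees (no greedy
addition of further compatible splits); the threshold must be ≥ 0.5 so
retained splits are mutually compatible, and two incompatible splits at
exactly 50% each are both dropped.

Parsimony and maximum-likelihood reconstruction are out of scope by
design: distance-based NJ is fully testable in-house, and the published
comparisons report closely agreeing topologies across algorithms for
this protein family.

# What the synthetic generator emulates

`make_cohort()` builds cohorts from a fixed 60-residue central-domain
template (`gg_template()`) that carries the seven Gβ contacts at their
template coordinates and the anchor at 51–54, is cysteine-free, and has
no proline outside position 52 (so no spurious anchor can precede the
real one). Two divergence levels shape the cohort:

- `type_divergence` (default 0.3): each type receives its own template
  variant, substituted at non-conserved positions — this is what gives
  the central domain a phylogenetic type signal;
- `divergence` (default 0.1): each record mutates its type template —
  within-type noise. Conserved contact positions are immune at both
  levels.

Tails follow the documented architectures: type A, a cysteine-free
linker (6–16 aa) plus a CaaX ending drawn from `CRCWIL` (0.4) /
`CGCSIL` / `CLIL` / `CSIL` (0.2 each) — the consensus plus the named
Arabidopsis variants; type B, 25–40 cysteine-free residues ending in the
eudicot `SRxxKRWI` or monocot `KGSDFS` consensus (the lower bound equals
the default cysteine-free window, so the window always lies wholly in
the tail); type C, 70–350 residues at a 19–38% cysteine fraction with
cysteines placed uniformly at random, optionally with a planted tandem
repeat. N-termini are uniform random sequences of 10–75 residues. If a
chance `[DE]PL[LI]` match would precede the planted anchor, the record
is redrawn, so the planted truth is exact by construction.

Because all records share template coordinates, the cohort is natively
aligned (N-termini left-padded, tails right-padded); de-gapping a row
recovers its sequence exactly. Gene models give type A/B genes four
exons and type C five, with boundaries at shared template-relative
positions (after template residues 10/30/50, plus the tail start for
type C) at phase 0, so projected boundaries land on identical alignment
columns across a cohort — the two middle exons come out identical in
length, mirroring the conserved central domain.

What the generator does **not** emulate: empirical residue composition
(background is uniform over the 20 amino acids — no composition is
claimed for the family), internal indels (gaps only pad variable-length
segments), evolution along a tree (records within a type are
conditionally independent given the type template), and sequencing or
assembly artifacts. Passing tests on generator output therefore
demonstrate the correctness of the algorithms under planted truth, not
classifier performance on real, noisy, manually curated collections.

# Numerical and degenerate-input choices

- Residue alphabet: the 20 standard letters plus `X`; `X` never matches
  in identity or distance computations and never votes in consensus
  columns. Gap characters never contribute to denominators.
- Absence is a value, not an error: a missing anchor, a missing CaaX, or
  an unclassifiable record flow through as `NA`/`unclassified`; errors
  are reserved for malformed inputs (ragged alignments, out-of-frame
  CDS, overlapping exons, empty regions, pairs with zero comparable
  columns).
- Branch lengths are written with 12 significant digits; Newick
  round-trips preserve topology and lengths to that precision.
- All randomness flows through explicit integer seeds; nothing samples
  from an unseeded stream.

# Problem sizes used in the checks

The bundled checks run on desk-scale cohorts chosen to exercise each
property sharply: 300 sequences (100 per type, within-type divergence
0.1) for classification-accuracy recovery; 24 taxa (8 per type,
`type_divergence` 0.4, `divergence` 0.05, 100 replicates) for the
bootstrap-support property; complete enumeration oracles at 4–6 taxa for
NJ, ≤ 200-aa regions for repeats, and all 20³ suffixes for
CaaX/transferase calls.

# Known limitations

- The classifier assumes one Gγ-like protein per record and does not
  decide whether a sequence *is* a Gγ candidate; homology search is out
  of scope.
- Type labels A/B/C are mutually exclusive by decision order; a type C
  protein's CaaX-like ending is visible in the evidence columns
  (`caax`, `prenyl_site`) but does not create a sub-label.
- Transferase prediction is a sequence rule, not a model of in-vivo
  prenylation efficiency.
- Gene models are accepted on the coding strand only; genome-scale GFF
  parsing and splice-site analysis are out of scope.
- Bootstrap support quantifies resampling stability of NJ under the
  chosen distance, which is not a posterior probability of monophyly.
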
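---
title: "Curating chicken MHC allele names from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating chicken MHC allele names from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfbl)
```

## The problem

The chicken BF-BL region contains two classical class I genes (BF1, BF2)
and two class II B genes (BLB1, BLB2). Until recently their alleles were
named after serological B haplotypes, so every gene in haplotype B12
carried the number 12 regardless of sequence. That convention breaks in
two ways: recombination within the region produces haplotypes whose genes
descend from different backgrounds, and most newly deposited sequences are
partial PCR amplicons with no haplotype context at all. `bfbl` implements
a sequence-first nomenclature: the unit that receives a name is an
*identity class* — all observed sequences identical over their provided
coding exons — and a haplotype is merely a string of allele names in
BLB1-BLB2-BF1-BF2 order.

This vignette records the procedure, the parameters that matter, and the
design decisions taken where the field's practice left the choice open.

## The procedure and its assumptions

**Comparison regions.** BLB sequences are compared over the β1 domain
(exon 2, 90 codons in the fixtures); BF sequences over the concatenated
α1+α2 domains (exons 2+3, intron removed; 90+92 codons). BF records
lacking either exon are rejected (`incomplete-BF`) rather than compared on
half a peptide-binding region. The procedure assumes **no indels** in
these exons — true of all known classical BF/BLB alleles — so comparison
is positional; a length mismatch is surfaced as `indel-or-truncation` and
excluded pending review, never silently aligned.

**Validation.** A class is *valid* with at least two evidence records
bearing distinct `(source_kind, source_key)` pairs. Independence is
deliberately flat: two birds within one study count, as do two studies.
Validation is monotone (more evidence can only promote). Provisional
classes within 2 nt of a valid class are flagged as probable PCR
mis-incorporation; the flag is advisory — rejection is a curator's call,
and flags never touch issued names.

**Locus assignment.** A specific locus claim in the metadata (ultimately
from between-gene PCR) anchors a class. Unanchored classes are assigned to
the locus of their nearest valid anchored reference by amino-acid count,
with the margin = d(nearest other-locus) − d(nearest same-locus). A margin
below `locus_margin_tau` (default 5 aa, i.e. narrower than one
variant-width) is ambiguous. A class anchored at *both* BLB loci is
ambiguous by definition and routed to the 101-series; such sharing between
the inverted BLB genes is an observed phenomenon, and no automatic
resolution is attempted — mechanism (inversion vs gene conversion) is not
an algorithm.

**Grouping.** Variant edges connect pairs within 4 aa per domain — and,
for BF, at most 8 aa in total. The rule is a conjunction (both per-domain
*and* total) because that is the stricter of the two possible readings of
the cutoff; the known seven-difference B15/B19 BF2 pair still groups under
it whenever its per-domain split is 4+3 or closer. Components are
single-linkage over variant edges: grouping by clade membership then
vetting pairs by matrix is the field's practice, and single linkage is its
graph equivalent. Its transitivity risk is not hidden — a component
containing any internal pair above the cutoff is marked `chained`. Pairs
with 5-9 differences per domain form *review edges*: recorded for
curators, never merged on their own. Exactly five differences falls in
the review zone, not the variant zone (the conservative reading, matching
the colour bins, whose yellow band starts at 5 for BF).

**Naming.** Within a locus, a group's first field is the lowest
standard-haplotype number among its members; equivalently, haplotypes are
processed in ascending numerical order and identical/close sequences are
named as encountered. The protein variant in the lowest-numbered haplotype
is `:01`; synonymous nucleotide variants order the third field the same
way. Groups with no standard-haplotype member draw the next free number at
or above 30; ambiguous class II B groups at or above 101. Fields with no
supporting data default to 01 and the name carries a completeness flag,
because most literature sequences are exon-only. An optional `parity_mode`
(odd numbers for BLB1, even for BLB2) exists behind a flag, off by
default — it is a proposal, not a rule.

**Registry.** Append-only, keyed by the class's full coding-exon
nucleotide sequence. Conflicts (one class, two proposed names; one group
spanning two registered first fields) are hard errors for the curator. The
audit log is ordered by a monotone event counter rather than timestamps so
a re-export after extending the input leaves previous rows byte-identical
— the property the tests assert.

**Haplotypes and Bfbl names.** Slots render as allele shorthand; `null`
only when curator-attested (absence of an amplicon is not evidence of
absence), `?` when unknown, and a parenthesized pair when one unlocated
BLB allele occupies both class II slots. The Bfbl name is the BF2
shorthand, suffixed `b`, `c`, ... in registration order (standard
haplotypes ascending, then other labels) when a distinct background shares
that BF2. Old-style recombinant names (`B2r1`) parse for backward
compatibility and are never emitted. Mosaic detection attributes each slot
to the other registered haplotypes carrying its group and reports a
minimal covering parent set, found by exhaustive search over parent
combinations (the candidate sets are tiny); resolution is gene-level only
— sub-gene breakpoints are out of scope.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `variant_max_per_domain` | 4 | aa | the curation cutoff for variants of one group |
| `bf_total_max` | 8 | aa | BF total across α1+α2, conjunction with the above |
| `review_lo`, `review_hi` | 5, 9 | aa/domain | too far to be variants, too close to ignore |
| `locus_margin_tau` | 5 | aa | near-ties in locus inference go to curators |
| suspect-singleton window | 2 | nt | one or two changes is PCR-error territory |
| `new_allele_base` | 30 | — | clear of the standard haplotype numbers |
| `ambiguous_blb_base` | 101 | — | interim series for unlocated BLB sequences |
| `bootstrap_reps` | 500 | replicates | conventional support depth |

## Trees: numerical choices

Distances entering neighbour joining are counts normalized by region
length (a Poisson correction `-log(1-p)` is available; clade structure at
these divergences does not depend on it, and grouping decisions rest on
raw counts anyway, so no substitution-model machinery is pulled in).
Labels are radix-sorted before agglomeration, making the result
deterministic and invariant to input row order; ties between equal
distances therefore resolve by label order. Negative NJ branch lengths are
clamped to zero with a message. Bootstrap resamples alignment columns with
replacement under a caller-supplied seed; supports attach to internal
nodes as integer percentages, the newick dialect most parsers accept.
Labels containing reserved characters are single-quoted on output.

## What the generator emulates — and what it does not

`synth_generate()` plants: allele-group founders separated by at least 20
aa (BF) / 12 aa (BLB) over the comparison region — the separations
observed among real alleles — implemented as disjoint substituted marker
sets, with the floor re-verified after generation; protein variants 1-4
substitutions from their founder (≤ 2 per domain, so all within-group
pairs respect the cutoff); occasional synonymous-only variants to exercise
the third field; haplotypes as draws of one allele per locus; recombinants
as single-slot swaps between two donors; cross-locus-shared BLB sequences
attested at both loci; and PCR-error singletons 1-2 nt from a valid
sequence with exactly one evidence record. Defaults are 3 groups per
locus, 2-3 variants per group, 6 haplotypes, one recombinant, one shared
sequence, and errors at 10% of classes.

The generator is *structural*, not population-genetic: no coalescent, no
selection, no rate heterogeneity, no chimeric reads, no partial exon
coverage. Passing its recovery tests therefore shows the engine is correct
on data satisfying the stated separations — it does not show robustness to
real data whose clades violate them (a documented failure mode of simple
sequence comparison as allele sets grow: groups can become wider within
than between; the `chained` flag and review edges exist to surface exactly
that).

`standard_fixture()` is the deterministic counterpart: synthetic sequences
realizing the published identity/variant relations among twelve standard
haplotypes (B6/B8 class II identities with B2 and B5, the B8=B11 BF
variants of B5, the B4=B13 relation with one exon-3 change in BLB2, the
B19 = B12-background + B15-derived-BF2 hybrid with its seven-difference
BF2 planted as a 4+3 split, the B14 BF1 null, the B8=B24 BLB2 identity).
Its bundled expectations are the frozen names and strings those relations
force.

## Degenerate inputs and edge policies

IUPAC-ambiguous codons translate to `X`; positions with `X` on either side
of a pair are excluded from counts and reported as masked, so ambiguity
can never inflate a difference past a cutoff. Internal stop codons flag
the record (`putative-null-or-artefact`) instead of dropping it. Records
whose class-level claim is `unknown` cannot enter a comparison and are
rejected by id. Identity classes are keyed on the full provided
coding-exon sequence, so records with different exon coverage form
separate classes — a curator-facing limitation, preferred over guessing
identity from partial overlap.

## Test problem sizes

The suite exercises: the twelve-haplotype fixture end-to-end; generated
sets of 3 groups × 2-3 variants across four loci (≈ 26 records); NJ
against an exhaustive-topology least-squares oracle on additive matrices
of 4-6 taxa; 500-replicate bootstraps on six 90-residue sequences; and
registry stability on subset→superset re-runs. These sizes keep every
property exact (recovery is asserted at 100%, not approximately) while the
whole suite stays desk-scale.

## Known limitations

- No gapped alignment: genuine indel alleles (none known in these exons)
  would be excluded, not accommodated.
- Locus inference needs anchored references at both candidate loci;
  without them classes stay unassigned for curators.
- The fourth name field (non-coding variants) is carried but never
  populated by the current input formats.
- Mosaic detection is gene-level; recombination breakpoints inside genes
  (e.g. mid-TAP events) are invisible to it.
- Names for provisional classes are intentionally withheld; there is no
  pathway from provisional to named without new evidence.
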
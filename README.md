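# bfbl — sequence-based allele nomenclature for the chicken MHC

The classical MHC of the chicken sits in the compact BF-BL region of the B
locus and carries just four polymorphic genes: two class I genes (**BF1**,
**BF2**) and two class II B genes (**BLB1**, **BLB2**). Alleles of these
genes were historically named after serologically defined B haplotypes
(B1-B29), but recombination within the region — the B19 haplotype, for
example, is a hybrid of the B12 and B15 haplotypes — and the flood of
partial PCR-derived sequences in public databases make haplotype-based
names untenable. `bfbl` implements the alternative: a curation engine in
which *sequences*, not haplotypes, own names, in the multi-field style of
the IPD databases.

The engine, in order of operation:

1. **Validation by replication.** A sequence identity class (the set of
   observed sequences identical over their coding exons) is *valid* only
   when attested by at least two independent amplifications — distinct
   `(source_kind, source_key)` evidence pairs: independent PCRs, birds,
   lines or studies. Once-observed sequences within 1-2 nt of a valid one
   are flagged as likely PCR errors and left unnamed.
2. **Distance matrices.** Amino-acid Hamming counts over the
   peptide-binding domains — the β1 domain (exon 2) for BLB, the α1+α2
   domains (exons 2+3, intron removed) for BF — with per-domain splits for
   BF and ambiguity-masked positions reported, never counted.
3. **Trees.** Neighbour-joining with column-resampled bootstrap support
   (500 replicates by default), exported as newick, for clade inspection
   and locus assignment; grouping decisions themselves rest on the
   matrices.
4. **Allele groups.** Single-linkage clustering under the curation cutoff:
   two sequences are variants of one allele group when they differ by at
   most **4 amino acids per domain** (totalled to **8** for BF). Pairs with
   5-9 differences per domain land in a review zone — recorded, never
   auto-merged. Components glued together only through intermediates are
   flagged `chained`.
5. **Names.** `<gene>*<group>:<protein variant>:<synonymous variant>` —
   e.g. `BF2*015:02:01` — assigned in ascending haplotype order, so the
   lowest-numbered standard haplotype anchors each group's first field.
   Groups outside the standard haplotypes number from **30**; class II B
   sequences attested in *both* BLB loci (a real phenomenon, driven by the
   genes' inverted orientation) get interim numbers from **101** and render
   in parentheses. Shorthand drops trailing `:01` fields: `BF1*002:01:01`
   is just `2`, `BF1*005:02:01` is `5:02`.
6. **Haplotype strings and Bfbl names.** A haplotype renders as
   `BLB1-BLB2-BF1-BF2` shorthand (tokens `null`, `?` and `(109-109)`
   allowed), and takes a *Bfbl* name from its BF2 allele, with letter
   suffixes when distinct backgrounds share one BF2.
7. **Registry.** Append-only: a name, once issued, is never altered;
   re-running on a superset of the input leaves old rows byte-identical.
   Gene-level mosaic detection attributes each slot of a haplotype to the
   registered haplotypes carrying that allele group.

## Worked example

The package ships a deterministic fixture realizing the identity/variant
relations among twelve standard haplotypes (synthetic sequences, real
relations):

```r
library(bfbl)
fx  <- standard_fixture()
cur <- curate(fx$records, fx$evidence, nulls = fx$nulls)
cur$registry$haplotypes[, c("haplotype", "string", "bfbl")]
#>    haplotype string               bfbl
#>  1 B2        2-2-2-2              2
#>  4 B6        2-5-6-6              6
#>  5 B8        2-8-5:02-5:02        5:02
#>  6 B11       11-11-5:02-5:02      5:02b
#>  8 B13       4-4:02-4-4           4b
#>  9 B14       14-14-null-14        14
#> 11 B19       12-12:02-12:02-15:02 15:02
#> 12 B24       24-8-4-24            24
```

Reading the B19 row: its class II genes and BF1 carry B12-group names
(`12`, `12:02`, `12:02`) while BF2 carries a variant of the B15 group
(`15:02`) — the recombinant ancestry is visible in the string itself, and

```r
detect_mosaic(cur, "B19")$parents
#> [1] "B12" "B15"
```

recovers the two parental haplotypes. The B14 row shows an attested BF1
null; B11, whose BF-BL content matches no earlier background but shares
B8's BF2 allele, gets the suffixed Bfbl name `5:02b`.

`tidy(cur)` returns the full allele table, `glance(cur)` one row of
pipeline counts, and `autoplot()` on a difference matrix or curation result
draws the colour-binned matrix / haplotype mosaic. A thin CLI over the same
functions lives at `inst/cli/bfbl.R` (subcommands `synth`, `validate`,
`distances`, `tree`, `assign`, `name`, `haplotypes`).

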
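test_that("FASTA + sidecar round-trips records byte-identically", {
  sx <- synth_generate(synth_config(seed = 11, n_haplotypes = 4,
                                    pcr_error_rate = 0))
  d <- withr::local_tempdir()
  write_records(sx$records, file.path(d, "a.fasta"), file.path(d, "a.tsv"))
  r2 <- read_records(file.path(d, "a.fasta"), file.path(d, "a.tsv"))
  expect_equal(nrow(r2), nrow(sx$records))
  expect_equal(r2$nt_seq, sx$records$nt_seq)
  expect_equal(r2$exon_map, sx$records$exon_map)
  expect_equal(r2$haplotype, sx$records$haplotype)
  write_records(r2, file.path(d, "b.fasta"), file.path(d, "b.tsv"))
  expect_identical(readLines(file.path(d, "a.fasta")),
                   readLines(file.path(d, "b.fasta")))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
})

test_that("identifier mismatches and malformed coordinates are hard errors", {
  sx <- synth_generate(synth_config(seed = 12, n_haplotypes = 3,
                                    pcr_error_rate = 0))
  d <- withr::local_tempdir()
  write_records(sx$records, file.path(d, "a.fasta"), file.path(d, "a.tsv"))
  side <- readr::read_tsv(file.path(d, "a.tsv"),
                          col_types = readr::cols(.default = "c"))
  readr::write_tsv(side[-1, ], file.path(d, "missing.tsv"))
  expect_error(read_records(file.path(d, "a.fasta"), file.path(d, "missing.tsv")),
               side$seq_id[1], fixed = TRUE)
  side2 <- side
  side2$exon_map[1] <- "exon2:zero-270"
  readr::write_tsv(side2, file.path(d, "bad.tsv"))
  expect_error(read_records(file.path(d, "a.fasta"), file.path(d, "bad.tsv")),
               "malformed")
  # extra sidecar rows are reported, not fatal
  side3 <- dplyr::bind_rows(side, side[1, ] |> dplyr::mutate(seq_id = "GHOST"))
  readr::write_tsv(side3, file.path(d, "extra.tsv"))
  expect_warning(read_records(file.path(d, "a.fasta"), file.path(d, "extra.tsv")),
                 "GHOST")
})

test_that("region extraction slices exons, trims post-translation, and rejects incomplete BF", {
  withr::local_seed(21)
  e2 <- paste(bfbl:::random_codons(90), collapse = "")
  e3 <- paste(bfbl:::random_codons(92), collapse = "")
  rec_bf <- manual_record("q1", paste0(e2, e3), "exon2:1-270;exon3:271-546", "BF2")
  # nucleotide beta-1-style slice for a BLB record is the exon-2 substring
  b2 <- paste(bfbl:::random_codons(90), collapse = "")
  b3 <- paste(bfbl:::random_codons(94), collapse = "")
  rec_blb <- manual_record("q2", paste0(b2, b3), "exon2:1-270;exon3:271-552", "BLB1")
  nt_out <- extract_region(rec_blb, region_spec("BLB", "beta1", "none", "nt"))
  expect_identical(nt_out$seq, b2)
  # BF alpha1+alpha2 with tree trimming: translated concatenation minus 7+7
  aa_out <- extract_region(rec_bf, region_spec("BF", "alpha1_2", "tree_trim", "aa"))
  expect_equal(nchar(aa_out$seq), (270 + 276) / 3 - 14)
  oracle <- paste(seqinr::translate(strsplit(paste0(e2, e3), "")[[1]]),
                  collapse = "")
  expect_identical(aa_out$seq, substr(oracle, 8, nchar(oracle) - 7))
  # amino-acid extraction equals translation of the nucleotide extraction
  nt_trim <- extract_region(rec_bf, region_spec("BF", "alpha1_2", "tree_trim", "nt"))
  expect_identical(aa_out$seq, as.character(translate_nt(nt_trim$seq)))
  # BLB tree trim removes the first two residues only
  blb_aa <- extract_region(rec_blb, region_spec("BLB", "beta1", "tree_trim", "aa"))
  expect_equal(nchar(blb_aa$seq), 88)
  # BF record lacking exon 3 is rejected as incomplete-BF
  rec_partial <- manual_record("q3", e2, "exon2:1-270", "BF1")
  out <- extract_region(rec_partial, region_spec("BF", "alpha1_2", "none", "aa"))
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")$reason, "incomplete-BF")
  # invalid locus_class/region combinations are rejected up front
  expect_error(region_spec("BF", "beta1"), "beta1")
  expect_error(region_spec("BLB", "alpha1_2"), "alpha1_2")
})

test_that("translation follows the standard code, masks ambiguity, flags internal stops", {
  expect_identical(as.character(translate_nt("ATGGCT")), "MA")
  amb <- translate_nt("ATGNCT")
  expect_identical(as.character(amb), "MX")
  expect_true(attr(amb, "ambiguous"))
  stopb <- translate_nt("ATGTAAGCT")
  expect_true(attr(stopb, "internal_stop"))
  expect_false(attr(translate_nt("ATGGCTTAA"), "internal_stop"))
  expect_error(translate_nt("ATGGC"), "multiple of 3")
  # frame offset drops leading nucleotides
  expect_identical(as.character(translate_nt("GATGGCT", frame = 1L)), "MA")
  # independent oracle on random coding sequences
  withr::local_seed(22)
  for (k in 1:10) {
    cds <- paste(bfbl:::random_codons(40), collapse = "")
    expect_identical(as.character(translate_nt(cds)),
                     paste(seqinr::translate(strsplit(cds, "")[[1]]),
                           collapse = ""))
  }
})
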
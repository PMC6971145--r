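test_that("count_diffs is a masked Hamming count with the expected symmetries", {
  withr::local_seed(41)
  s <- random_aa_string(60)
  expect_equal(as.integer(count_diffs(s, s)), 0)
  for (k in c(1, 3, 7, 20)) {
    pos <- sample(60, k)
    s2 <- substitute_aa(s, pos)
    expect_equal(as.integer(count_diffs(s, s2)), k)
    expect_equal(as.integer(count_diffs(s2, s)), as.integer(count_diffs(s, s2)))
  }
  expect_error(count_diffs(s, substr(s, 1, 10)), "equal length")
  # positions with X on either side are skipped and reported as masked
  a <- "AAXAA"
  b <- "ARAXK"
  d <- count_diffs(a, b)
  expect_equal(as.integer(d), 2)
  expect_equal(attr(d, "masked"), 2)
  # amino-acid distance never exceeds nucleotide distance over the same codons
  for (k in 1:8) {
    cds1 <- paste(bfbl:::random_codons(30), collapse = "")
    v <- strsplit(cds1, "")[[1]]
    pos <- sample(90, sample(1:10, 1))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    cds2 <- paste(v, collapse = "")
    d_nt <- as.integer(count_diffs(cds1, cds2, level = "nt"))
    d_aa <- as.integer(count_diffs(as.character(translate_nt(cds1)),
                                   as.character(translate_nt(cds2))))
    expect_lte(d_aa, d_nt)
  }
})

test_that("diff_matrix equals a brute-force double loop and splits BF domains", {
  withr::local_seed(42)
  seqs <- setNames(vapply(1:6, function(i) random_aa_string(50), character(1)),
                   paste0("q", 1:6))
  seqs[2] <- substitute_aa(seqs[1], 1:4)
  blk <- manual_block(seqs)
  dm <- diff_matrix(blk)
  expect_identical(dm$counts, oracle_matrix(seqs))
  expect_true(isSymmetric(dm$counts))
  expect_true(all(diag(dm$counts) == 0))
  # zero count iff identical strings
  expect_identical(dm$counts == 0L,
                   outer(seqs, seqs, Vectorize(function(a, b) a == b)))
  # BF per-domain split sums to the total when nothing is masked
  bf <- manual_block(seqs, locus_class = "BF", boundary = 25L)
  dmb <- diff_matrix(bf)
  expect_identical(dmb$per_domain$alpha1 + dmb$per_domain$alpha2, dmb$counts)
  # tidy() covers every unordered pair once
  td <- tidy(dmb)
  expect_equal(nrow(td), choose(6, 2))
  expect_true(all(td$alpha1 + td$alpha2 == td$count))
})

test_that("difference bins follow the BF and BLB highlight conventions", {
  expect_equal(as.character(diff_bin(c(0, 1, 4, 5, 8, 9), "BF")),
               c("green", "blue", "blue", "yellow", "yellow", "beyond"))
  expect_equal(as.character(diff_bin(c(0, 1, 2, 3, 4, 5), "BLB")),
               c("green", "blue", "blue", "yellow", "yellow", "beyond"))
})

test_that("blocks reject length mismatches by name and export round-trips", {
  withr::local_seed(43)
  good <- lapply(1:4, function(i) paste(bfbl:::random_codons(90), collapse = ""))
  recs <- dplyr::bind_rows(lapply(1:4, function(i)
    manual_record(paste0("r", i), good[[i]], "exon2:1-270", "BLB1")))
  short <- manual_record("r5", substr(good[[1]], 1, 267), "exon2:1-267", "BLB1")
  expect_error(build_block(dplyr::bind_rows(recs, short),
                           region_spec("BLB", "beta1", "none", "aa")),
               "indel-or-truncation\\(r5\\)")
  blk <- build_block(recs, region_spec("BLB", "beta1", "none", "aa"))
  expect_equal(nrow(blk), 4)
  dm <- diff_matrix(blk)
  d <- withr::local_tempdir()
  write_dm_phylip(dm, file.path(d, "m.phy"))
  back <- read_dm_phylip(file.path(d, "m.phy"))
  expect_equal(back, dm$counts + 0)  # numeric round trip
  write_dm_tsv(dm, file.path(d, "m.tsv"))
  tsv <- readr::read_tsv(file.path(d, "m.tsv"), col_types = readr::cols())
  expect_equal(as.matrix(tsv[, -1]), dm$counts, ignore_attr = TRUE)
})
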
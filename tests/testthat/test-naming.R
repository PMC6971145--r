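test_that("shorthand drops trailing first-variant fields and zero padding", {
  expect_equal(allele_shorthand("BF1*002:01:01"), "2")
  expect_equal(allele_shorthand("BF1*005:02:01"), "5:02")
  expect_equal(allele_shorthand("BF2*030:01:01"), "30")
  expect_equal(allele_shorthand("BLB2*012:02:01"), "12:02")
  expect_equal(allele_shorthand("BLB*109:01:01"), "109")
  expect_equal(allele_shorthand("BF1*030:01:02:01"), "30:01:02")
  expect_equal(allele_shorthand("null"), "null")
})

test_that("allele names render and parse as inverses", {
  withr::local_seed(71)
  for (k in 1:25) {
    f <- list(locus = sample(c("BLB1", "BLB2", "BF1", "BF2", "BLB"), 1),
              f1 = sample(c(1:29, 30:40, 101:110), 1),
              f2 = sample(1:4, 1), f3 = sample(1:3, 1),
              f4 = sample(c(NA_integer_, 1:2), 1))
    nm <- render_allele_name(f$locus, f$f1, f$f2, f$f3, f$f4)
    back <- parse_allele_name(nm)
    expect_equal(back$locus, f$locus)
    expect_equal(back$f1, f$f1)
    expect_equal(back$f2, f$f2)
    expect_equal(back$f3, f$f3)
    expect_equal(back$f4, f$f4)
  }
  expect_error(parse_allele_name("BF1-002"), "malformed")
  # old-style recombinant names parse but are never produced
  leg <- parse_legacy_recombinant("B2r1")
  expect_equal(leg$bf2_group, 2L)
  expect_equal(leg$r_index, 1L)
  expect_error(parse_legacy_recombinant("BF2*002"), "not an old-style")
})

test_that("haplotype strings render null, unknown and ambiguous-pair tokens", {
  le <- literature_examples()
  got <- vapply(le$haplotypes, haplotype_string, character(1))
  expect_equal(unname(got), le$expected$string)
  # canonical form keeps full names
  expect_equal(haplotype_string(le$haplotypes$bfbl33, "canonical"),
               "BLB1*009:01:01-BLB2*034:01:01-null-BF2*033:01:01")
  # strings re-parse to their slot tokens
  p <- parse_haplotype_string("(109-109)-23:02-38")
  expect_equal(p$blb_pair, "109")
  expect_equal(unname(p$tokens["BF2"]), "38")
  p2 <- parse_haplotype_string("?-?-9:02-9")
  expect_equal(unname(p2$tokens), c("?", "?", "9:02", "9"))
  expect_error(parse_haplotype_string("a-b-c"), "four tokens")
})

test_that("the standard-haplotype fixture reproduces every expected name and string", {
  fx <- standard_fixture()
  cur <- curate(fx$records, fx$evidence, nulls = fx$nulls)
  got_names <- cur$slot_table
  exp_names <- fx$expected$names[fx$expected$names$name != "null", ]
  merged <- dplyr::left_join(exp_names, got_names, by = c("haplotype", "locus"))
  expect_false(anyNA(merged$name.y))
  expect_equal(merged$name.y, merged$name.x)
  got_h <- cur$registry$haplotypes
  merged_s <- dplyr::left_join(fx$expected$strings, got_h, by = "haplotype")
  expect_equal(merged_s$string, merged_s$shorthand)
  expect_equal(merged_s$canonical.y, merged_s$canonical.x)
  merged_b <- dplyr::left_join(fx$expected$bfbl, got_h, by = "haplotype")
  expect_equal(merged_b$bfbl.y, merged_b$bfbl.x)
  # haplotype-independence: one name per identity class however often seen
  al <- tidy(cur)
  expect_equal(anyDuplicated(al$class_key), 0)
})

test_that("re-running and extending the registry preserves issued names bit-identically", {
  fx <- standard_fixture()
  subset_recs <- fx$records[!fx$records$haplotype %in% c("B5", "B24"), ]
  subset_ev <- fx$evidence[fx$evidence$seq_id %in% subset_recs$seq_id, ]
  cur1 <- curate(subset_recs, subset_ev, nulls = fx$nulls)
  d <- withr::local_tempdir()
  write_registry(cur1$registry, file.path(d, "r1"))
  # idempotence: same input against the populated registry allocates nothing
  cur_again <- curate(subset_recs, subset_ev, nulls = fx$nulls,
                      registry = cur1$registry)
  expect_identical(cur_again$registry$alleles, cur1$registry$alleles)
  expect_identical(cur_again$registry$audit, cur1$registry$audit)
  # superset: old rows must be a byte-identical prefix of the new export
  cur2 <- curate(fx$records, fx$evidence, nulls = fx$nulls,
                 registry = cur1$registry)
  write_registry(cur2$registry, file.path(d, "r2"))
  for (f in c("alleles.tsv", "haplotypes.tsv", "audit.tsv")) {
    old <- readLines(file.path(d, "r1", f))
    new <- readLines(file.path(d, "r2", f))
    expect_identical(new[seq_along(old)], old)
  }
  # the late-arriving B5 classes joined existing groups under registered f1
  al2 <- tidy(cur2)
  b5_bf1 <- al2[purrr::map_lgl(al2$haplotypes, ~"B5" %in% .x) &
                  al2$locus == "BF1", ]
  expect_equal(b5_bf1$f1, 8L)  # the group was first seen through B8
  # conflicting allocations are hard errors citing both names
  reg <- registry_new()
  reg <- registry_register(reg, tibble::tibble(
    class_key = "K", locus = "BF1", f1 = 2L, f2 = 1L, f3 = 1L,
    f4 = NA_integer_, ambiguous_locus = FALSE, complete = TRUE,
    name = "BF1*002:01:01", shorthand = "2"))
  expect_error(registry_register(reg, tibble::tibble(
    class_key = "K", locus = "BF1", f1 = 3L, f2 = 1L, f3 = 1L,
    f4 = NA_integer_, ambiguous_locus = FALSE, complete = TRUE,
    name = "BF1*003:01:01", shorthand = "3")),
    "BF1\\*002:01:01.*BF1\\*003:01:01")
  # registries survive the TSV round trip
  back <- read_registry(file.path(d, "r2"))
  expect_equal(back$alleles, cur2$registry$alleles)
  expect_equal(back$haplotypes, cur2$registry$haplotypes)
})

test_that("mosaic detection attributes slots and finds minimal parent sets", {
  fx <- standard_fixture()
  cur <- curate(fx$records, fx$evidence, nulls = fx$nulls)
  mo <- detect_mosaic(cur, "B19")
  expect_true(mo$is_mosaic)
  expect_equal(mo$parents, c("B12", "B15"))
  bf2 <- mo$attribution[mo$attribution$locus == "BF2", ]
  expect_equal(bf2$carriers[[1]], "B15")
  # a haplotype identical to another at every slot group needs one parent
  mo13 <- detect_mosaic(cur, "B13")
  expect_false(mo13$is_mosaic)
  expect_equal(mo13$parents, "B4")
})

test_that("parity mode allocates odd BLB1 and even BLB2 numbers above the base", {
  classes <- tibble::tibble(
    class_id = c("C1", "C2"),
    locus_class = "BLB",
    class_key = c("BLB:AAA", "BLB:CCC"),
    aa_key = c("K", "T"),
    seq_ids = list("s1", "s2"),
    haplotypes = list(character(), character()),
    claims = list("BLB1", "BLB2"),
    complete = FALSE, internal_stop = FALSE)
  groups <- tibble::tibble(locus = c("BLB1", "BLB2"), group_id = 1L,
                           members = list("C1", "C2"), chained = FALSE,
                           review_edges = list(NULL, NULL),
                           ambiguous = FALSE)
  reg <- assign_names(groups, classes, registry_new(),
                      naming_config(parity_mode = TRUE))
  expect_equal(reg$alleles$f1[reg$alleles$locus == "BLB1"], 31L)
  expect_equal(reg$alleles$f1[reg$alleles$locus == "BLB2"], 30L)
})
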
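test_that("generation is byte-reproducible for a fixed seed", {
  a <- synth_generate(synth_config(seed = 81))
  b <- synth_generate(synth_config(seed = 81))
  expect_identical(a$records, b$records)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$truth, b$truth)
  d <- withr::local_tempdir()
  write_synth(a, file.path(d, "x"))
  write_synth(b, file.path(d, "y"))
  for (f in list.files(file.path(d, "x"))) {
    expect_identical(readLines(file.path(d, "x", f)),
                     readLines(file.path(d, "y", f)))
  }
  c2 <- synth_generate(synth_config(seed = 82))
  expect_false(identical(a$records$nt_seq, c2$records$nt_seq))
})

test_that("planted between-group distances respect the configured floors", {
  sx <- synth_generate(synth_config(seed = 83, pcr_error_rate = 0))
  tr <- sx$truth
  for (lc in c("BLB", "BF")) {
    sel <- startsWith(tr$true_locus, lc)
    recs <- sx$records[match(tr$seq_id[sel], sx$records$seq_id), ]
    reg <- extract_region(recs, region_spec(
      lc, if (lc == "BLB") "beta1" else "alpha1_2", "none", "aa"))
    grp <- tr$true_group[sel][match(reg$seq_id, tr$seq_id[sel])]
    floor_lc <- synth_config()$between_floor[[lc]]
    # exhaustive pair check with an independent count
    for (i in seq_len(nrow(reg) - 1)) {
      for (j in (i + 1):nrow(reg)) {
        d <- sum(strsplit(reg$seq[i], "")[[1]] != strsplit(reg$seq[j], "")[[1]])
        if (grp[i] != grp[j]) {
          expect_gte(d, floor_lc)
        } else if (tr$true_variant[sel][match(reg$seq_id[c(i, j)],
                                              tr$seq_id[sel])] |>
                   (\(v) v[1] == v[2])()) {
          expect_equal(d, 0)  # same protein variant, synonymous at most
        } else {
          expect_lte(d, 8)
        }
      }
    }
  }
  # infeasible configurations fail before emission
  expect_error(synth_generate(synth_config(seed = 1, groups_per_locus = 8L)),
               "infeasible")
})

test_that("PCR-error singletons sit 1-2 nt from their parent with one evidence record", {
  sx <- synth_generate(synth_config(seed = 84, pcr_error_rate = 0.15))
  errs <- sx$truth[sx$truth$is_pcr_error, ]
  expect_gt(nrow(errs), 0)
  for (i in seq_len(nrow(errs))) {
    child <- sx$records$nt_seq[sx$records$seq_id == errs$seq_id[i]]
    parent <- sx$records$nt_seq[sx$records$seq_id == errs$parent_seq[i]]
    d <- sum(strsplit(child, "")[[1]] != strsplit(parent, "")[[1]])
    expect_true(d %in% 1:2)
    expect_equal(sum(sx$evidence$seq_id == errs$seq_id[i]), 1)
  }
})

test_that("end-to-end recovery on clean output is exact against the truth table", {
  sx <- synth_generate(synth_config(seed = 85, pcr_error_rate = 0))
  cur <- curate(sx$records, sx$evidence)
  cls <- tidyr::unnest(cur$classes[, c("class_id", "seq_ids", "status")],
                       cols = "seq_ids")
  tr <- dplyr::left_join(sx$truth, cls, by = c("seq_id" = "seq_ids"))
  tr <- dplyr::left_join(tr, cur$locus_assignments, by = "class_id")
  expect_true(all(tr$status == "valid"))
  plain <- tr[tr$true_locus %in% c("BLB1", "BLB2", "BF1", "BF2"), ]
  expect_true(all(plain$locus == plain$true_locus))
  shared <- tr[tr$true_locus == "BLB_ambiguous", ]
  expect_true(all(shared$ambiguous))
  # group/variant/synonymous indices in bijection with the planted structure
  al <- dplyr::left_join(
    cur$registry$alleles,
    cur$classes[, c("class_key", "class_id")], by = "class_key")
  tab <- dplyr::distinct(
    dplyr::left_join(plain, al, by = "class_id"),
    true_locus, true_group, true_variant, true_syn, f1, f2, f3)
  expect_equal(nrow(dplyr::distinct(tab, true_locus, true_group)),
               nrow(dplyr::distinct(tab, true_locus, f1)))
  expect_equal(nrow(dplyr::distinct(tab, true_locus, true_group, true_variant)),
               nrow(dplyr::distinct(tab, true_locus, f1, f2)))
  expect_equal(nrow(tab),
               nrow(dplyr::distinct(tab, true_locus, f1, f2, f3)))
  # shared classes went to the 101-series in parentheses
  shared_al <- al[al$ambiguous_locus, ]
  expect_true(all(shared_al$f1 >= 101L))
  hs <- cur$registry$haplotypes
  expect_true(any(grepl("^\\(10[0-9]-10[0-9]\\)-", hs$string)))
  # recombinant haplotype resolves to its two donors
  rec <- sx$hap_truth[sx$hap_truth$is_recombinant, ]
  if (nrow(rec) > 0 && rec$haplotype[1] %in% cur$slot_table$haplotype) {
    mo <- detect_mosaic(cur, rec$haplotype[1])
    expect_true(all(mo$parents %in% sx$hap_truth$haplotype))
  }
})

test_that("planted PCR errors are flagged, never named, and never taint valid classes", {
  sx <- synth_generate(synth_config(seed = 86, pcr_error_rate = 0.1))
  cur <- curate(sx$records, sx$evidence)
  cls <- tidyr::unnest(cur$classes[, c("class_id", "seq_ids", "status")],
                       cols = "seq_ids")
  tr <- dplyr::left_join(sx$truth, cls, by = c("seq_id" = "seq_ids"))
  errs <- tr[tr$is_pcr_error, ]
  expect_true(all(errs$status == "provisional"))
  expect_true(all(errs$class_id %in% cur$suspect_flags$class_id))
  valid_ids <- tr$class_id[!tr$is_pcr_error]
  expect_false(any(valid_ids %in% cur$suspect_flags$class_id))
  named_keys <- cur$registry$alleles$class_key
  err_keys <- cur$classes$class_key[cur$classes$class_id %in% errs$class_id]
  expect_false(any(err_keys %in% named_keys))
})
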
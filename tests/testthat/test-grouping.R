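test_that("locus assignment anchors claims, measures margins, flags ambiguity", {
  withr::local_seed(61)
  ref_bf1 <- random_aa_string(60)
  ref_bf2 <- substitute_aa(ref_bf1, 1:25)
  refs <- tibble::tibble(id = c("R1", "R2"), locus = c("BF1", "BF2"),
                         seq = c(ref_bf1, ref_bf2))
  # identical to a BF2 reference: unambiguous at full margin
  out <- assign_locus(tibble::tibble(id = "q", seq = ref_bf2), refs)
  expect_equal(out$locus, "BF2")
  expect_false(out$ambiguous)
  expect_equal(out$margin, 25L)
  # near-tie goes to curators: splice 12 BF2 residues onto the BF1 backbone
  v <- strsplit(ref_bf1, "")[[1]]
  v[1:12] <- strsplit(ref_bf2, "")[[1]][1:12]
  mid <- paste(v, collapse = "")  # 12 from BF1, 13 from BF2
  out2 <- assign_locus(tibble::tibble(id = "q", seq = mid), refs)
  expect_true(out2$ambiguous)
  expect_equal(out2$margin, 1L)
  # a sequence attested at both loci is ambiguous regardless of distances
  out3 <- assign_locus(tibble::tibble(id = "q", seq = ref_bf1,
                                      claims = list(c("BF1", "BF2"))), refs)
  expect_true(out3$ambiguous)
  expect_true(out3$anchored)
  # an anchored single claim overrides inference
  out4 <- assign_locus(tibble::tibble(id = "q", seq = ref_bf2,
                                      claims = list("BF1")), refs)
  expect_equal(out4$locus, "BF1")
  expect_true(out4$anchored)
  expect_error(assign_locus(tibble::tibble(id = "q", seq = mid), refs[0, ]),
               "no reference")
})

test_that("clustering merges within the cutoff, chains are surfaced, review edges kept", {
  lab <- c("a", "b", "c")
  dm_of <- function(ab, bc, ac) {
    counts <- matrix(0L, 3, 3, dimnames = list(lab, lab))
    counts["a", "b"] <- counts["b", "a"] <- ab
    counts["b", "c"] <- counts["c", "b"] <- bc
    counts["a", "c"] <- counts["c", "a"] <- ac
    manual_dm(counts, "BF",
              per_domain = list(alpha1 = counts %/% 2L,
                                alpha2 = counts - counts %/% 2L),
              len = 182L)
  }
  # 4-4-8 chain: all pairs satisfy the BF conjunction, one clean group
  g1 <- cluster_alleles(dm_of(4L, 4L, 8L))
  expect_equal(nrow(g1), 1)
  expect_false(g1$chained)
  # 4-4-12: single linkage still joins, but the far pair marks the chain
  g2 <- cluster_alleles(dm_of(4L, 4L, 12L))
  expect_equal(nrow(g2), 1)
  expect_true(g2$chained)
  expect_equal(nrow(g2$review_edges[[1]]), 1)  # 6+6 per domain: review zone
  # far-apart classes form separate groups
  g3 <- cluster_alleles(dm_of(25L, 25L, 25L))
  expect_equal(nrow(g3), 3)
  # BF conjunction: 5+4 per domain (total 9) is not a variant edge even
  # though a marginal reading of a per-domain-only rule might allow it
  counts <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  counts["a", "b"] <- counts["b", "a"] <- 9L
  dm_bf <- manual_dm(counts, "BF",
                     per_domain = list(alpha1 = counts * 0L + c(0L, 4L, 4L, 0L),
                                       alpha2 = counts * 0L + c(0L, 5L, 5L, 0L)),
                     len = 182L)
  g4 <- cluster_alleles(dm_bf)
  expect_equal(nrow(g4), 2)
  expect_equal(nrow(g4$review_edges[[1]]), 1)
  # exactly five differences (BLB) is review, not variant
  counts5 <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
                    dimnames = list(c("a", "b"), c("a", "b")))
  g5 <- cluster_alleles(manual_dm(counts5, "BLB"))
  expect_equal(nrow(g5), 2)
  expect_equal(g5$review_edges[[1]]$count, 5L)
})

test_that("clustering is order-invariant, idempotent, and exact on clean plants", {
  withr::local_seed(62)
  for (rep in 1:5) {
    base <- random_aa_string(90)
    founders <- list(base,
                     substitute_aa(base, 1:14),
                     substitute_aa(base, 20:33))
    seqs <- list()
    truth <- list()
    for (g in 1:3) {
      n_var <- sample(2:3, 1)
      for (v in seq_len(n_var)) {
        s <- if (v == 1) founders[[g]] else
          substitute_aa(founders[[g]], sample(60:90, sample(1:2, 1)))
        id <- sprintf("g%dv%d", g, v)
        seqs[[id]] <- s
        truth[[id]] <- g
      }
    }
    seqs <- unlist(seqs)
    groups <- cluster_alleles(diff_matrix(manual_block(seqs)))
    planted <- split(names(truth), unlist(truth))
    expect_true(same_partition(groups$members, unname(planted)))
    expect_true(all(!groups$chained))
    # permuting the input leaves the result identical
    perm <- sample(length(seqs))
    groups_p <- cluster_alleles(diff_matrix(manual_block(seqs[perm])))
    expect_identical(groups$members, groups_p$members)
    # idempotence: re-running on the same matrix changes nothing
    expect_identical(groups,
                     cluster_alleles(diff_matrix(manual_block(seqs))))
    # every within-group pair satisfies the cutoff; cross-group pairs do not
    dm <- diff_matrix(manual_block(seqs))
    for (gi in seq_len(nrow(groups))) {
      mem <- groups$members[[gi]]
      if (length(mem) > 1) {
        prs <- utils::combn(mem, 2)
        expect_true(all(dm$counts[t(prs)] <= 4))
      }
      other <- setdiff(unlist(groups$members), mem)
      if (length(other) > 0) {
        expect_true(all(dm$counts[mem, other] > 4))
      }
    }
  }
})
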
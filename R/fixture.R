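#' Deterministic fixture realizing the standard-haplotype relations
#'
#' Builds a synthetic sequence set (BLB exons 2+3, BF exons 2+3) that
#' realizes the identity and variant relations among the well-characterised
#' standard B haplotypes: the B6 and B8 BLB1 sequences identical to B2 and
#' the B6 BLB2 identical to B5; the B8 BLB2 shared with B24; the B8/B11 BF
#' genes as close variants of the B5 genes; all four B13 genes identical to
#' B4 in the peptide-binding exons with one amino-acid difference in BLB2
#' exon 3; the B19 haplotype as a B12 background carrying a close variant of
#' the B15 BF2 (seven amino-acid differences over alpha-1 + alpha-2, planted
#' as a 4+3 split); and the B14 haplotype with an attested BF1 null. The
#' sequences themselves are synthetic; the relations, and the expected names
#' and strings bundled alongside, are the fixture's ground truth.
#'
#' @return A list: `records`, `evidence`, `nulls`, and `expected` (tibbles
#'   `names` (haplotype, locus, name), `strings` (haplotype, shorthand,
#'   canonical), `bfbl` (haplotype, bfbl)).
#' @export
standard_fixture <- function() {
  withr::with_seed(190118L, standard_fixture_impl())
}

standard_fixture_impl <- function() {
  blb_exons <- c(270L, 282L); bf_exons <- c(270L, 276L)
  blb_b1 <- blb_exons[1] %/% 3L                 # 90 aa beta-1
  bf_a1 <- bf_exons[1] %/% 3L                   # 90 aa alpha-1
  bf_aa <- sum(bf_exons) %/% 3L                 # 182 aa alpha-1 + alpha-2
  blb_aa <- sum(blb_exons) %/% 3L
  base_blb <- random_codons(blb_aa)
  base_bf <- random_codons(bf_aa)

  founder <- function(base, positions) {
    for (p in positions) base <- apply_nonsyn(base, p)
    base
  }
  chunked_founders <- function(base, haps, pool, m) {
    out <- list()
    for (i in seq_along(haps)) {
      out[[haps[i]]] <- founder(base, pool[((i - 1) * m + 1):(i * m)])
    }
    out
  }
  variant <- function(codons, positions) {
    for (p in positions) codons <- apply_nonsyn(codons, p)
    codons
  }

  # disjoint 7-residue marker sets within beta-1 -> pairwise >= 14 aa (>= 12)
  blb1_f <- chunked_founders(base_blb,
                             c("B2", "B4", "B5", "B11", "B12", "B14", "B15", "B24"),
                             sample(seq_len(blb_b1)), 7L)
  blb2_pool <- sample(seq_len(blb_b1))
  blb2_haps <- c("B2", "B4", "B5", "B8", "B11", "B12", "B14", "B15")
  blb2_f <- chunked_founders(base_blb, blb2_haps, blb2_pool, 7L)
  blb2_free <- blb2_pool[-seq_len(7L * length(blb2_haps))]
  # disjoint 11-residue marker sets over alpha-1+alpha-2 -> pairwise >= 22 (>= 20)
  bf1_pool <- sample(seq_len(bf_aa))
  bf1_haps <- c("B2", "B4", "B5", "B6", "B12")
  bf1_f <- chunked_founders(base_bf, bf1_haps, bf1_pool, 11L)
  bf1_free <- bf1_pool[-seq_len(11L * length(bf1_haps))]
  bf2_pool <- sample(seq_len(bf_aa))
  bf2_haps <- c("B2", "B4", "B5", "B6", "B12", "B14", "B15", "B24")
  bf2_f <- chunked_founders(base_bf, bf2_haps, bf2_pool, 11L)
  bf2_free <- bf2_pool[-seq_len(11L * length(bf2_haps))]

  take_free <- function(free, n, lo, hi) {
    hit <- which(free >= lo & free <= hi)[seq_len(n)]
    free[hit]
  }
  drop_used <- function(free, used) setdiff(free, used)

  # planted variant relations
  blb2_v_b13 <- variant(blb2_f$B4, sample((blb_b1 + 1L):blb_aa, 1))  # exon-3 only
  p <- take_free(blb2_free, 1, 1, blb_b1)
  blb2_v_b19 <- variant(blb2_f$B12, p)

  p1 <- take_free(bf1_free, 2, 1, bf_a1); bf1_free <- drop_used(bf1_free, p1)
  p2 <- take_free(bf1_free, 1, bf_a1 + 1, bf_aa); bf1_free <- drop_used(bf1_free, p2)
  bf1_v_b8 <- variant(bf1_f$B5, c(p1, p2))                 # 2 + 1 split
  p <- take_free(bf1_free, 1, 1, bf_a1); bf1_free <- drop_used(bf1_free, p)
  bf1_v_b15 <- variant(bf1_f$B4, p)
  p <- take_free(bf1_free, 1, 1, bf_a1)
  bf1_v_b19 <- variant(bf1_f$B12, p)

  p1 <- take_free(bf2_free, 2, 1, bf_a1); bf2_free <- drop_used(bf2_free, p1)
  p2 <- take_free(bf2_free, 1, bf_a1 + 1, bf_aa); bf2_free <- drop_used(bf2_free, p2)
  bf2_v_b8 <- variant(bf2_f$B5, c(p1, p2))                 # 2 + 1 split
  p1 <- take_free(bf2_free, 4, 1, bf_a1); bf2_free <- drop_used(bf2_free, p1)
  p2 <- take_free(bf2_free, 3, bf_a1 + 1, bf_aa)
  bf2_v_b19 <- variant(bf2_f$B15, c(p1, p2))               # 4 + 3 split

  allele_of <- list(
    BLB1 = list(B2 = blb1_f$B2, B4 = blb1_f$B4, B5 = blb1_f$B5,
                B6 = blb1_f$B2, B8 = blb1_f$B2, B11 = blb1_f$B11,
                B12 = blb1_f$B12, B13 = blb1_f$B4, B14 = blb1_f$B14,
                B15 = blb1_f$B15, B19 = blb1_f$B12, B24 = blb1_f$B24),
    BLB2 = list(B2 = blb2_f$B2, B4 = blb2_f$B4, B5 = blb2_f$B5,
                B6 = blb2_f$B5, B8 = blb2_f$B8, B11 = blb2_f$B11,
                B12 = blb2_f$B12, B13 = blb2_v_b13, B14 = blb2_f$B14,
                B15 = blb2_f$B15, B19 = blb2_v_b19, B24 = blb2_f$B8),
    BF1 = list(B2 = bf1_f$B2, B4 = bf1_f$B4, B5 = bf1_f$B5, B6 = bf1_f$B6,
               B8 = bf1_v_b8, B11 = bf1_v_b8, B12 = bf1_f$B12,
               B13 = bf1_f$B4, B15 = bf1_v_b15, B19 = bf1_v_b19,
               B24 = bf1_f$B4),
    BF2 = list(B2 = bf2_f$B2, B4 = bf2_f$B4, B5 = bf2_f$B5, B6 = bf2_f$B6,
               B8 = bf2_v_b8, B11 = bf2_v_b8, B12 = bf2_f$B12,
               B13 = bf2_f$B4, B14 = bf2_f$B14, B15 = bf2_f$B15,
               B19 = bf2_v_b19, B24 = bf2_f$B24))

  haps <- c("B2", "B4", "B5", "B6", "B8", "B11", "B12", "B13", "B14", "B15",
            "B19", "B24")
  em <- c(BLB = sprintf("exon2:1-%d;exon3:%d-%d", blb_exons[1],
                        blb_exons[1] + 1L, sum(blb_exons)),
          BF = sprintf("exon2:1-%d;exon3:%d-%d", bf_exons[1],
                       bf_exons[1] + 1L, sum(bf_exons)))
  recs <- list(); ev <- list()
  for (h in haps) {
    for (loc in c("BLB1", "BLB2", "BF1", "BF2")) {
      codons <- allele_of[[loc]][[h]]
      if (is.null(codons)) next                  # B14 BF1: attested null
      id <- paste0(h, "_", loc)
      lc <- if (startsWith(loc, "BLB")) "BLB" else "BF"
      recs[[id]] <- tibble(
        seq_id = id, locus_claim = loc, haplotype = h,
        line = paste0("line-", h), study_id = "FIXTURE",
        pcr_id = paste0("P-", id), bird_id = paste0("bird-", h),
        nt_seq = paste(codons, collapse = ""),
        exon_map = list(parse_exon_map(em[[lc]], id)))
      ev[[paste0(id, "a")]] <- tibble(seq_id = id, source_kind = "study",
                                      source_key = paste0("labA-", h),
                                      citation = NA_character_)
      ev[[paste0(id, "b")]] <- tibble(seq_id = id, source_kind = "study",
                                      source_key = paste0("labB-", h),
                                      citation = NA_character_)
    }
  }

  nm <- function(locus, f1, f2 = 1L) render_allele_name(locus, f1, f2, 1L)
  expected_names <- bind_rows(
    tibble(haplotype = haps, locus = "BLB1",
           name = nm("BLB1", c(2, 4, 5, 2, 2, 11, 12, 4, 14, 15, 12, 24))),
    tibble(haplotype = haps, locus = "BLB2",
           name = nm("BLB2", c(2, 4, 5, 5, 8, 11, 12, 4, 14, 15, 12, 8),
                     c(1, 1, 1, 1, 1, 1, 1, 2, 1, 1, 2, 1))),
    tibble(haplotype = haps, locus = "BF1",
           name = c(nm("BF1", c(2, 4, 5, 6, 5, 5, 12, 4),
                       c(1, 1, 1, 1, 2, 2, 1, 1)), "null",
                    nm("BF1", c(4, 12, 4), c(2, 2, 1)))),
    tibble(haplotype = haps, locus = "BF2",
           name = nm("BF2", c(2, 4, 5, 6, 5, 5, 12, 4, 14, 15, 15, 24),
                     c(1, 1, 1, 1, 2, 2, 1, 1, 1, 1, 2, 1))))
  expected_strings <- tibble(
    haplotype = haps,
    shorthand = c("2-2-2-2", "4-4-4-4", "5-5-5-5", "2-5-6-6",
                  "2-8-5:02-5:02", "11-11-5:02-5:02", "12-12-12-12",
                  "4-4:02-4-4", "14-14-null-14", "15-15-4:02-15",
                  "12-12:02-12:02-15:02", "24-8-4-24"))
  expected_strings$canonical <- vapply(haps, function(h) {
    n <- expected_names$name[expected_names$haplotype == h]
    paste(n[match(c("BLB1", "BLB2", "BF1", "BF2"),
                  expected_names$locus[expected_names$haplotype == h])],
          collapse = "-")
  }, character(1), USE.NAMES = FALSE)
  expected_bfbl <- tibble(
    haplotype = haps,
    bfbl = c("2", "4", "5", "6", "5:02", "5:02b", "12", "4b", "14", "15",
             "15:02", "24"))

  list(records = bind_rows(recs), evidence = bind_rows(ev),
       nulls = tibble(haplotype = "B14", locus = "BF1"),
       expected = list(names = expected_names, strings = expected_strings,
                       bfbl = expected_bfbl))
}

#' Literature-style haplotype records exercising the string tokens
#'
#' Constructed haplotype records that render the tokens seen when naming
#' haplotypes assembled from the literature: an attested BF1 null
#' (`9-34-null-33`), a partial haplotype with unknown class II slots
#' (`?-?-9:02-9`), and an unlocated 101-series BLB allele occupying both
#' class II slots as a parenthesized pair (`(109-109)-23:02-38`).
#'
#' @return A list of `bfbl_haplotype` records with an `expected` tibble of
#'   their shorthand strings.
#' @export
literature_examples <- function() {
  haps <- list(
    bfbl33 = haplotype_record("Bfbl33", BLB1 = "BLB1*009:01:01",
                              BLB2 = "BLB2*034:01:01", BF1 = "null",
                              BF2 = "BF2*033:01:01"),
    bfbl9 = haplotype_record("Bfbl9", BF1 = "BF1*009:02:01",
                             BF2 = "BF2*009:01:01"),
    bfbl38 = haplotype_record("Bfbl38", blb_pair = "BLB*109:01:01",
                              BF1 = "BF1*023:02:01", BF2 = "BF2*038:01:01"))
  list(haplotypes = haps,
       expected = tibble(
         haplotype = c("Bfbl33", "Bfbl9", "Bfbl38"),
         string = c("9-34-null-33", "?-?-9:02-9", "(109-109)-23:02-38")))
}
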
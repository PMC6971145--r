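# --- codon-level helpers -----------------------------------------------------

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

random_codons <- function(n_aa) {
  sample(sense_codons(), n_aa, replace = TRUE)
}

# replace the codon at aa position `pos` with a codon for a different residue
apply_nonsyn <- function(codons, pos) {
  gc <- genetic_code()
  cur <- unname(gc[codons[pos]])
  aas <- setdiff(unique(gc), c("*", cur))
  target <- sample(aas, 1)
  codons[pos] <- sample(names(gc)[gc == target], 1)
  codons
}

# replace the codon at `pos` with a synonymous codon; NULL if non-degenerate
apply_syn <- function(codons, pos) {
  gc <- genetic_code()
  alt <- setdiff(names(gc)[gc == unname(gc[codons[pos]])], codons[pos])
  if (length(alt) == 0) return(NULL)
  codons[pos] <- sample(alt, 1)
  codons
}

# n random single-nucleotide changes, retried until no in-frame stop arises
apply_nt_errors <- function(cds, n, nt_range = c(1L, nchar(cds))) {
  gc <- genetic_code()
  repeat {
    s <- strsplit(cds, "", fixed = TRUE)[[1]]
    pos <- sample(seq(nt_range[1], nt_range[2]), n)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    out <- paste(s, collapse = "")
    codons <- substring(out, seq(1, nchar(out) - 2, 3), seq(3, nchar(out), 3))
    if (!any(gc[codons] == "*")) return(out)
  }
}

# --- generator ---------------------------------------------------------------

#' Configuration for the synthetic sequence generator
#'
#' Defaults encode the structure observed among real BF-BL sequences: allele
#' groups separated by at least 20 amino acids over the BF peptide-binding
#' domains (12 for BLB beta-1), variants within a group one to four
#' substitutions from each other, occasional synonymous-only variants,
#' rare recombinant haplotypes and class II B sequences shared between the
#' BLB loci, and once-observed PCR-error singletons one or two nucleotides
#' from a validated sequence.
#'
#' @param seed Integer seed; generation is byte-reproducible for a fixed seed.
#' @param groups_per_locus Allele groups per locus (default 3).
#' @param variants_per_group Range of protein variants per group (default 2:3).
#' @param between_floor Named minimum between-group amino-acid distances over
#'   the comparison region, `c(BF = 20, BLB = 12)`.
#' @param n_haplotypes Number of haplotypes (default 6).
#' @param n_recombinants Number of haplotypes built as single-slot swaps
#'   between two donor haplotypes (default 1).
#' @param cross_locus_shares Number of extra BLB sequences planted in both
#'   BLB1 and BLB2 loci (default 1).
#' @param pcr_error_rate PCR-error singletons per valid class (default 0.1).
#' @param syn_variant_prob Probability that a group also carries a
#'   synonymous-only nucleotide variant (default 0.25).
#' @param evidence_depth Range of independent evidence records per emitted
#'   sequence record (default 2:4; PCR-error singletons always get one).
#' @param blb_exons,bf_exons Exon 2 / exon 3 nucleotide lengths; conventional
#'   values, nothing downstream depends on them.
#' @return A `bfbl_synth_config` list.
#' @export
synth_config <- function(seed = 1L, groups_per_locus = 3L,
                         variants_per_group = 2:3,
                         between_floor = c(BF = 20L, BLB = 12L),
                         n_haplotypes = 6L, n_recombinants = 1L,
                         cross_locus_shares = 1L, pcr_error_rate = 0.1,
                         syn_variant_prob = 0.25, evidence_depth = 2:4,
                         blb_exons = c(270L, 282L), bf_exons = c(270L, 276L)) {
  structure(list(seed = as.integer(seed),
                 groups_per_locus = as.integer(groups_per_locus),
                 variants_per_group = as.integer(variants_per_group),
                 between_floor = between_floor,
                 n_haplotypes = as.integer(n_haplotypes),
                 n_recombinants = as.integer(n_recombinants),
                 cross_locus_shares = as.integer(cross_locus_shares),
                 pcr_error_rate = pcr_error_rate,
                 syn_variant_prob = syn_variant_prob,
                 evidence_depth = as.integer(evidence_depth),
                 blb_exons = as.integer(blb_exons),
                 bf_exons = as.integer(bf_exons)),
            class = "bfbl_synth_config")
}

# marker-set size per founder: disjoint sets of this size guarantee pairwise
# between-group distances of at least the floor (2 * ceiling(floor/2) + 2)
marker_size <- function(floor_aa) as.integer(ceiling(floor_aa / 2) + 1L)

#' Generate a synthetic sequence set with planted structure
#'
#' Each locus gets `groups_per_locus` allele-group founders built from a
#' shared base sequence by substituting disjoint marker positions inside the
#' comparison region, which guarantees every between-group distance exceeds
#' the configured floor (verified post-generation). Variants add one to four
#' nonsynonymous substitutions (at most two per domain, so all within-group
#' pairs respect the variant cutoff). Haplotypes draw one allele per locus;
#' recombinants copy one haplotype with a single slot from another;
#' cross-locus shares plant one BLB sequence in both class II slots of a
#' haplotype; PCR-error singletons sit one or two nucleotides from a valid
#' sequence and carry a single evidence record.
#'
#' @param config A [synth_config()].
#' @return A `bfbl_synth` list: `records`, `evidence`, `truth` (per-sequence
#'   true locus/group/variant), `hap_truth` (recombinant donors), `nulls`
#'   (empty), `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  region_aa <- c(BLB = config$blb_exons[1] %/% 3L,
                 BF = sum(config$bf_exons) %/% 3L)
  m <- c(BLB = marker_size(config$between_floor[["BLB"]]),
         BF = marker_size(config$between_floor[["BF"]]))
  n_founders <- c(BLB = 2L * config$groups_per_locus + config$cross_locus_shares,
                  BF = 2L * config$groups_per_locus)
  for (lc in c("BLB", "BF")) {
    need <- n_founders[[lc]] * m[[lc]] + 8L  # 8 positions reserved for variants
    if (need > region_aa[[lc]]) {
      abort(paste0("infeasible config: ", n_founders[[lc]], " founders x ",
                   m[[lc]], " marker positions exceed the ", region_aa[[lc]],
                   "-residue ", lc, " comparison region"))
    }
  }
  withr::with_seed(config$seed, synth_generate_impl(config, region_aa, m))
}

synth_generate_impl <- function(config, region_aa, m) {
  loci <- c("BLB1", "BLB2", "BF1", "BF2")
  n_aa <- c(BLB = sum(config$blb_exons) %/% 3L, BF = sum(config$bf_exons) %/% 3L)
  base <- list(BLB = random_codons(n_aa[["BLB"]]), BF = random_codons(n_aa[["BF"]]))
  # disjoint marker positions inside the comparison region, per locus class
  pool <- list(BLB = sample(seq_len(region_aa[["BLB"]])),
               BF = sample(seq_len(region_aa[["BF"]])))
  take <- function(lc, k) {
    got <- pool[[lc]][seq_len(k)]
    pool[[lc]] <<- pool[[lc]][-seq_len(k)]
    got
  }
  # first k pooled positions within [lo, hi]; keeps all draws disjoint
  take_range <- function(lc, k, lo, hi) {
    if (k == 0) return(integer())
    hit <- which(pool[[lc]] >= lo & pool[[lc]] <= hi)[seq_len(k)]
    got <- pool[[lc]][hit]
    pool[[lc]] <<- pool[[lc]][-hit]
    got
  }
  # alleles[[locus]][[group]] = list of list(codons, variant, syn, id)
  alleles <- list()
  for (loc in loci) {
    lc <- if (startsWith(loc, "BLB")) "BLB" else "BF"
    alleles[[loc]] <- purrr::map(seq_len(config$groups_per_locus), function(g) {
      codons <- base[[lc]]
      for (p in take(lc, m[[lc]])) codons <- apply_nonsyn(codons, p)
      boundary <- if (lc == "BF") config$bf_exons[1] %/% 3L else region_aa[["BLB"]]
      n_var <- sample(config$variants_per_group, 1)
      vars <- list(list(codons = codons, variant = 1L, syn = 1L))
      for (v in seq_len(n_var - 1L)) {
        vc <- codons
        if (lc == "BF") {
          n1 <- sample(0:2, 1); n2 <- sample(0:2, 1)
          if (n1 + n2 == 0) n1 <- 1L
          for (p in c(take_range("BF", n1, 1L, boundary),
                      take_range("BF", n2, boundary + 1L, region_aa[["BF"]])))
            vc <- apply_nonsyn(vc, p)
        } else {
          for (p in take("BLB", sample(1:2, 1))) vc <- apply_nonsyn(vc, p)
        }
        vars[[length(vars) + 1L]] <- list(codons = vc, variant = v + 1L, syn = 1L)
      }
      if (stats::runif(1) < config$syn_variant_prob) {
        src <- vars[[sample(length(vars), 1)]]
        degen <- which(vapply(seq_along(src$codons), function(p)
          !is.null(apply_syn(src$codons, p)), logical(1)))
        sc <- apply_syn(src$codons, sample(degen, 1))
        vars[[length(vars) + 1L]] <- list(codons = sc, variant = src$variant,
                                          syn = 2L)
      }
      vars
    })
  }
  # shared BLB founders attested at both loci
  shares <- purrr::map(seq_len(config$cross_locus_shares), function(s) {
    codons <- base[["BLB"]]
    for (p in take("BLB", m[["BLB"]])) codons <- apply_nonsyn(codons, p)
    codons
  })

  # haplotypes
  n_plain <- config$n_haplotypes - config$n_recombinants
  stopifnot(n_plain >= 2 || config$n_recombinants == 0)
  hap_ids <- sprintf("H%02d", seq_len(config$n_haplotypes))
  hap_alleles <- list()
  for (h in seq_len(n_plain)) {
    hap_alleles[[hap_ids[h]]] <- purrr::map(setNames(loci, loci), function(loc) {
      g <- sample(config$groups_per_locus, 1)
      v <- sample(length(alleles[[loc]][[g]]), 1)
      list(group = g, pick = v)
    })
  }
  hap_truth <- tibble(haplotype = hap_ids,
                      is_recombinant = FALSE, donor_a = NA_character_,
                      donor_b = NA_character_, swapped_slot = NA_character_)
  for (r in seq_len(config$n_recombinants)) {
    h <- hap_ids[n_plain + r]
    donors <- sample(hap_ids[seq_len(n_plain)], 2)
    slot <- sample(loci, 1)
    ha <- hap_alleles[[donors[1]]]
    ha[[slot]] <- hap_alleles[[donors[2]]][[slot]]
    hap_alleles[[h]] <- ha
    hap_truth[hap_truth$haplotype == h, c("is_recombinant", "donor_a",
                                          "donor_b", "swapped_slot")] <-
      list(TRUE, donors[1], donors[2], slot)
  }
  share_hap <- if (config$cross_locus_shares > 0)
    sample(hap_ids[seq_len(n_plain)], config$cross_locus_shares) else character()

  # emit records
  exon_map_str <- c(
    BLB = sprintf("exon2:1-%d;exon3:%d-%d", config$blb_exons[1],
                  config$blb_exons[1] + 1L, sum(config$blb_exons)),
    BF = sprintf("exon2:1-%d;exon3:%d-%d", config$bf_exons[1],
                 config$bf_exons[1] + 1L, sum(config$bf_exons)))
  recs <- list(); ev <- list(); truth <- list()
  counter <- 0L; ev_counter <- 0L
  seen_anchor <- character()
  emit <- function(cds, locus, claim, hap, t_locus, t_group, t_variant, t_syn,
                   is_err = FALSE, parent = NA_character_, depth = NULL) {
    counter <<- counter + 1L
    id <- sprintf("S%03d", counter)
    lc <- if (startsWith(locus, "BLB")) "BLB" else "BF"
    recs[[counter]] <<- tibble(
      seq_id = id, locus_claim = claim, haplotype = hap,
      line = paste0("line-", hap %||% "x"), study_id = "SYNTH",
      pcr_id = paste0("P", counter), bird_id = paste0("bird-", hap %||% "x"),
      nt_seq = cds, exon_map = list(parse_exon_map(exon_map_str[[lc]], id)))
    depth <- depth %||% sample(config$evidence_depth, 1)
    for (k in seq_len(depth)) {
      ev_counter <<- ev_counter + 1L
      kind <- sample(c("study", "bird", "line"), 1)
      ev[[ev_counter]] <<- tibble(seq_id = id, source_kind = kind,
                                  source_key = paste0(kind, "-", ev_counter),
                                  citation = NA_character_)
    }
    truth[[counter]] <<- tibble(seq_id = id, true_locus = t_locus,
                                true_group = t_group, true_variant = t_variant,
                                true_syn = t_syn, haplotype = hap %||% NA_character_,
                                is_pcr_error = is_err, parent_seq = parent)
    id
  }
  for (h in hap_ids) {
    for (loc in loci) {
      if (h %in% share_hap && loc %in% c("BLB1", "BLB2")) next
      al <- hap_alleles[[h]][[loc]]
      entry <- alleles[[loc]][[al$group]][[al$pick]]
      cds <- paste(entry$codons, collapse = "")
      key <- paste0(loc, ":", cds)
      claim <- if (key %in% seen_anchor && stats::runif(1) < 0.5)
        paste0(if (startsWith(loc, "BLB")) "BLB" else "BF", "_unassigned")
      else loc
      seen_anchor <- union(seen_anchor, key)
      emit(cds, loc, claim, h, loc, paste0(loc, ":G", al$group),
           entry$variant, entry$syn)
    }
  }
  for (s in seq_along(shares)) {
    cds <- paste(shares[[s]], collapse = "")
    h <- share_hap[s]
    for (loc in c("BLB1", "BLB2")) {
      emit(cds, loc, loc, h, "BLB_ambiguous", paste0("BLB_shared:G", s), 1L, 1L)
    }
  }
  # PCR-error singletons off valid sequences, inside the comparison region
  all_recs <- bind_rows(recs)
  all_truth <- bind_rows(truth)
  n_classes <- length(unique(all_recs$nt_seq))
  n_err <- round(config$pcr_error_rate * n_classes)
  if (config$pcr_error_rate > 0 && n_err == 0) n_err <- 1L
  existing <- unique(all_recs$nt_seq)
  for (e in seq_len(n_err)) {
    parent_i <- sample(nrow(all_recs), 1)
    lc <- if (startsWith(all_recs$locus_claim[parent_i], "BLB")) "BLB" else "BF"
    rng <- if (lc == "BLB") c(1L, config$blb_exons[1]) else
      c(1L, sum(config$bf_exons))
    repeat {
      mut <- apply_nt_errors(all_recs$nt_seq[parent_i], sample(1:2, 1), rng)
      if (!mut %in% existing) break
    }
    existing <- c(existing, mut)
    claim <- all_recs$locus_claim[parent_i]
    if (claim %in% c("BLB_unassigned", "BF_unassigned"))
      claim <- paste0(lc, "_unassigned")
    emit(mut, claim, claim, all_recs$haplotype[parent_i], "pcr_error",
         "pcr_error", NA_integer_, NA_integer_, is_err = TRUE,
         parent = all_recs$seq_id[parent_i], depth = 1L)
  }
  out <- list(records = bind_rows(recs), evidence = bind_rows(ev),
              truth = bind_rows(truth), hap_truth = hap_truth,
              nulls = tibble(haplotype = character(), locus = character()),
              config = config)
  class(out) <- "bfbl_synth"
  verify_planted_floors(out)
  out
}

# post-generation audit: every between-group distance respects the floor
verify_planted_floors <- function(x) {
  cfg <- x$config
  tr <- x$truth[!x$truth$is_pcr_error, ]
  recs <- x$records[match(tr$seq_id, x$records$seq_id), ]
  for (lc in c("BLB", "BF")) {
    sel <- startsWith(tr$true_locus, lc)
    if (sum(sel) < 2) next
    spec <- region_spec(lc, if (lc == "BLB") "beta1" else "alpha1_2", "none", "aa")
    reg <- extract_region(recs[sel, ], spec)
    grp <- tr$true_group[sel][match(reg$seq_id, tr$seq_id[sel])]
    n <- nrow(reg)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (grp[i] == grp[j]) next
        d <- as.integer(count_diffs(reg$seq[i], reg$seq[j]))
        if (d < cfg$between_floor[[lc]]) {
          abort(paste0("planted between-group distance ", d, " below the ",
                       lc, " floor of ", cfg$between_floor[[lc]]))
        }
      }
    }
  }
  invisible(x)
}

#' Write a synthetic set to disk
#'
#' Emits the same FASTA / sidecar / evidence dialects used by [read_records()]
#' and [read_evidence()], plus the truth tables. Byte-identical for a fixed
#' generator seed.
#'
#' @param x A `bfbl_synth`.
#' @param dir Output directory (created if needed).
#' @return `x`, invisibly.
#' @export
write_synth <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_records(x$records, file.path(dir, "records.fasta"),
                file.path(dir, "sidecar.tsv"))
  readr::write_tsv(x$evidence, file.path(dir, "evidence.tsv"), progress = FALSE)
  readr::write_tsv(x$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(x$hap_truth, file.path(dir, "hap_truth.tsv"), progress = FALSE)
  invisible(x)
}
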
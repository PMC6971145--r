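# independent brute-force difference matrix (nested loops over characters)
oracle_matrix <- function(seqs, mask = "X") {
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(seqs[[i]], "")[[1]]
      b <- strsplit(seqs[[j]], "")[[1]]
      keep <- !(a %in% mask) & !(b %in% mask)
      m[i, j] <- sum(a[keep] != b[keep])
    }
  }
  m
}

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_string <- function(len) {
  paste(sample(aa_alphabet, len, replace = TRUE), collapse = "")
}

# substitute the residues at `pos` with a residue different from the current
substitute_aa <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(aa_alphabet, v[p]), 1)
  paste(v, collapse = "")
}

# hand-assembled aligned block (bypasses record plumbing)
manual_block <- function(seqs, locus_class = "BLB", level = "aa",
                         boundary = NA_integer_) {
  blk <- tibble::tibble(seq_id = names(seqs), seq = unname(seqs))
  class(blk) <- c("bfbl_block", class(blk))
  attr(blk, "spec") <- structure(
    list(locus_class = locus_class,
         region = if (locus_class == "BLB") "beta1" else "alpha1_2",
         trim_policy = "none", level = level),
    class = "bfbl_region_spec")
  attr(blk, "domain_boundary") <- boundary
  blk
}

# hand-assembled difference matrix for grouping tests
manual_dm <- function(counts, locus_class = "BLB", per_domain = NULL,
                      len = 90L) {
  structure(list(labels = rownames(counts), counts = counts,
                 masked = counts * 0L, level = "aa", seq_length = len,
                 locus_class = locus_class, per_domain = per_domain),
            class = "bfbl_dm")
}

# minimal record tibble without file I/O
manual_record <- function(seq_id, nt_seq, exon_map, locus_claim,
                          haplotype = NA_character_) {
  tibble::tibble(seq_id = seq_id, locus_claim = locus_claim,
                 haplotype = haplotype, line = NA_character_,
                 study_id = NA_character_, pcr_id = NA_character_,
                 bird_id = NA_character_, nt_seq = nt_seq,
                 exon_map = list(bfbl:::parse_exon_map(exon_map, seq_id)))
}

# planted two-clade amino-acid block: >= `between` differences separating the
# clades, <= 2 within
two_clade_block <- function(len = 90, between = 20) {
  base <- paste(rep("A", len), collapse = "")
  sub_at <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  far <- sub_at(base, seq_len(between), "K")
  seqs <- c(S1 = base, S2 = sub_at(base, len, "R"), S3 = sub_at(base, len - 1, "R"),
            S4 = far, S5 = sub_at(far, len - 2, "R"), S6 = sub_at(far, len - 3, "R"))
  manual_block(seqs)
}

# exhaustive-topology oracle: best least-squares fit over all unrooted
# topologies of <= 6 taxa
exhaustive_nj_oracle <- function(dm) {
  tops <- phangorn::allTrees(nrow(dm), rooted = FALSE,
                             tip.label = rownames(dm))
  res <- vapply(tops, function(t) {
    f <- phangorn::nnls.tree(dm, t, method = "unrooted", trace = 0)
    sum((stats::cophenetic(f)[rownames(dm), colnames(dm)] - dm)^2)
  }, numeric(1))
  tops[[which.min(res)]]
}

# partition comparison: same grouping of labels regardless of group ids
same_partition <- function(members_a, members_b) {
  norm <- function(m) {
    s <- lapply(m, function(x) sort(x, method = "radix"))
    s[order(vapply(s, `[`, character(1), 1), method = "radix")]
  }
  identical(norm(members_a), norm(members_b))
}
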
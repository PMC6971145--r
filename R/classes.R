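#' Collapse records into identity classes
#'
#' The unit that receives a name is not an individual database entry but an
#' identity class: the set of observed sequences identical over their full
#' provided coding-exon nucleotide sequence. Records with different exon
#' coverage therefore form distinct classes and are left to curators to
#' reconcile. BF records lacking exon 2 or exon 3 are rejected with reason
#' `"incomplete-BF"`; records whose class-level claim is `unknown` cannot be
#' placed in a class-I or class-II comparison and are rejected with reason
#' `"unknown-locus-class"`.
#'
#' @param records A record tibble from [read_records()].
#' @return A tibble with one row per class: `class_id`, `locus_class`,
#'   `class_key`, `aa_key`, `seq_ids`, `haplotypes`, `claims` (specific
#'   locus claims attested among members), `complete`, `internal_stop`.
#'   Rejected records are reported in `attr(, "rejections")`.
#' @export
identity_classes <- function(records) {
  rej <- list()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    claim <- records$locus_claim[i]
    lc <- if (startsWith(claim, "BLB")) "BLB" else
      if (startsWith(claim, "BF")) "BF" else NA_character_
    if (is.na(lc)) {
      rej[[length(rej) + 1L]] <- tibble(seq_id = records$seq_id[i],
                                        reason = "unknown-locus-class")
      next
    }
    em <- records$exon_map[[i]][order(records$exon_map[[i]]$start), ]
    if (lc == "BF" && !all(c("exon2", "exon3") %in% em$exon)) {
      rej[[length(rej) + 1L]] <- tibble(seq_id = records$seq_id[i],
                                        reason = "incomplete-BF")
      next
    }
    segs <- substring(records$nt_seq[i], em$start + em$frame, em$end)
    cds <- paste(segs, collapse = "")
    aa <- translate_nt(cds)
    complete <- if (lc == "BLB") any(!em$exon %in% "exon2") else
      any(!em$exon %in% c("exon2", "exon3"))
    rows[[length(rows) + 1L]] <- tibble(
      seq_id = records$seq_id[i], locus_class = lc,
      class_key = paste0(lc, ":", cds), aa_key = as.character(aa),
      haplotype = records$haplotype[i],
      claim = if (claim %in% c("BLB1", "BLB2", "BF1", "BF2")) claim
              else NA_character_,
      complete = complete,
      internal_stop = attr(aa, "internal_stop"))
  }
  df <- bind_rows(rows)
  out <- df |>
    group_by(.data$locus_class, .data$class_key, .data$aa_key) |>
    summarise(seq_ids = list(sort(.data$seq_id, method = "radix")),
              haplotypes = list(sort(unique(.data$haplotype[!is.na(.data$haplotype)]),
                                     method = "radix")),
              claims = list(sort(unique(.data$claim[!is.na(.data$claim)]),
                                 method = "radix")),
              complete = any(.data$complete),
              internal_stop = any(.data$internal_stop),
              .groups = "drop")
  out <- out[order(purrr::map_chr(out$seq_ids, 1), method = "radix"), ]
  out$class_id <- sprintf("C%03d", seq_len(nrow(out)))
  out <- out[, c("class_id", "locus_class", "class_key", "aa_key", "seq_ids",
                 "haplotypes", "claims", "complete", "internal_stop")]
  attr(out, "rejections") <- if (length(rej)) bind_rows(rej) else
    tibble(seq_id = character(), reason = character())
  out
}

# one representative record per class, re-labelled by class_id
class_representatives <- function(records, classes) {
  rep_ids <- purrr::map_chr(classes$seq_ids, 1)
  reps <- records[match(rep_ids, records$seq_id), ]
  reps$seq_id <- classes$class_id
  reps
}
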
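#' Read sequence records from FASTA plus a metadata sidecar
#'
#' A record is one observed BLB or BF sequence (typically BLB exon 2 and BF
#' exons 2+3 amplified from genomic DNA) together with its curation metadata:
#' the claimed genetic locus, the serological haplotype label when known, the
#' chicken line, and provenance identifiers. The sidecar is tab-separated with
#' the fixed header `seq_id`, `locus_claim`, `haplotype`, `line`, `study_id`,
#' `pcr_id`, `bird_id`, `exon_map`.
#'
#' `exon_map` is serialized as `"exon2:1-270;exon3:271-546"` with 1-based
#' inclusive coordinates on the record's own sequence. An optional `/f` suffix
#' per exon (e.g. `"exon2:2-271/1"`) carries a reading-frame offset for
#' partial amplicons that start mid-codon; the default frame is 0.
#'
#' @param fasta_path Path to a FASTA file of nucleotide sequences.
#' @param sidecar_path Path to the tab-separated metadata sidecar.
#' @return A tibble with one row per record: `seq_id`, `locus_claim`,
#'   `haplotype`, `line`, `study_id`, `pcr_id`, `bird_id`, `nt_seq` and an
#'   `exon_map` list-column of tibbles (`exon`, `start`, `end`, `frame`).
#' @export
read_records <- function(fasta_path, sidecar_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated FASTA identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  side <- readr::read_tsv(sidecar_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  needed <- c("seq_id", "locus_claim", "haplotype", "line", "study_id",
              "pcr_id", "bird_id", "exon_map")
  missing_cols <- setdiff(needed, names(side))
  if (length(missing_cols) > 0) {
    abort(paste0("sidecar is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  orphans <- setdiff(ids, side$seq_id)
  if (length(orphans) > 0) {
    abort(paste0("FASTA identifier(s) absent from sidecar: ",
                 paste(orphans, collapse = ", ")))
  }
  unmatched <- setdiff(side$seq_id, ids)
  if (length(unmatched) > 0) {
    warn(paste0("sidecar row(s) with no FASTA sequence (ignored): ",
                paste(unmatched, collapse = ", ")))
  }
  side <- side[match(ids, side$seq_id), ]
  recs <- tibble(
    seq_id = ids,
    locus_claim = side$locus_claim,
    haplotype = side$haplotype,
    line = side$line,
    study_id = side$study_id,
    pcr_id = side$pcr_id,
    bird_id = side$bird_id,
    nt_seq = unname(as.character(seqs)),
    exon_map = purrr::map2(side$exon_map, ids, parse_exon_map)
  )
  purrr::pwalk(list(recs$exon_map, recs$nt_seq, recs$seq_id), check_exon_map)
  recs
}

#' Write sequence records back to FASTA plus sidecar
#'
#' Inverse of [read_records()]; reading the written pair reproduces the input
#' records (including coordinates and metadata) exactly.
#'
#' @param records A record tibble as returned by [read_records()].
#' @param fasta_path,sidecar_path Output paths.
#' @return `records`, invisibly.
#' @export
write_records <- function(records, fasta_path, sidecar_path) {
  x <- Biostrings::DNAStringSet(setNames(records$nt_seq, records$seq_id))
  Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  side <- tibble(
    seq_id = records$seq_id,
    locus_claim = records$locus_claim,
    haplotype = records$haplotype,
    line = records$line,
    study_id = records$study_id,
    pcr_id = records$pcr_id,
    bird_id = records$bird_id,
    exon_map = purrr::map_chr(records$exon_map, format_exon_map)
  )
  readr::write_tsv(side, sidecar_path, progress = FALSE)
  invisible(records)
}

parse_exon_map <- function(x, seq_id) {
  if (is.na(x) || !nzchar(x)) {
    abort(paste0("empty exon_map for record '", seq_id, "'"))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z0-9_]+):([0-9]+)-([0-9]+)(?:/([0-2]))?$", parts))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    abort(paste0("malformed exon_map component(s) for record '", seq_id, "': ",
                 paste(parts[bad], collapse = ", ")))
  }
  tibble(
    exon = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    frame = as.integer(ifelse(vapply(m, `[`, character(1), 5) == "",
                              "0", vapply(m, `[`, character(1), 5)))
  )
}

format_exon_map <- function(em) {
  paste0(em$exon, ":", em$start, "-", em$end,
         ifelse(em$frame > 0L, paste0("/", em$frame), ""),
         collapse = ";")
}

check_exon_map <- function(em, nt_seq, seq_id) {
  if (any(em$start < 1L) || any(em$end > nchar(nt_seq)) || any(em$end < em$start)) {
    abort(paste0("exon coordinates outside sequence for record '", seq_id, "'"))
  }
  em <- em[order(em$start), ]
  if (nrow(em) > 1 && any(em$start[-1] <= em$end[-nrow(em)])) {
    abort(paste0("overlapping exon intervals for record '", seq_id, "'"))
  }
  invisible(em)
}

#' Describe a peptide-binding (or CDS) region to extract
#'
#' The comparison regions follow field practice for the chicken classical MHC:
#' the beta-1 domain (exon 2) for class II B (BLB) sequences and the
#' alpha-1 plus alpha-2 domains (exons 2 and 3, intron removed) for class I
#' (BF) sequences. `trim_policy = "tree_trim"` reproduces the trimming used
#' for tree building: the first and last seven residues are removed from BF
#' regions and the first two residues from BLB regions (primer positions and
#' unequal amplicon ends).
#'
#' @param locus_class `"BF"` or `"BLB"`.
#' @param region One of `"beta1"` (BLB only), `"alpha1"`, `"alpha2"`,
#'   `"alpha1_2"` (BF only) or `"CDS"`.
#' @param trim_policy `"none"` (difference matrices) or `"tree_trim"` (trees).
#' @param level `"aa"` or `"nt"`.
#' @return A `bfbl_region_spec` list.
#' @export
region_spec <- function(locus_class = c("BLB", "BF"),
                        region = c("beta1", "alpha1", "alpha2", "alpha1_2", "CDS"),
                        trim_policy = c("none", "tree_trim"),
                        level = c("aa", "nt")) {
  locus_class <- match.arg(locus_class)
  region <- match.arg(region)
  trim_policy <- match.arg(trim_policy)
  level <- match.arg(level)
  if (region == "beta1" && locus_class != "BLB") {
    abort("region 'beta1' is only valid for locus_class 'BLB'")
  }
  if (region %in% c("alpha1", "alpha2", "alpha1_2") && locus_class != "BF") {
    abort(paste0("region '", region, "' is only valid for locus_class 'BF'"))
  }
  structure(list(locus_class = locus_class, region = region,
                 trim_policy = trim_policy, level = level),
            class = "bfbl_region_spec")
}

region_exons <- function(spec, em) {
  em <- em[order(em$start), ]
  want <- switch(spec$region,
                 beta1 = "exon2",
                 alpha1 = "exon2",
                 alpha2 = "exon3",
                 alpha1_2 = c("exon2", "exon3"),
                 CDS = em$exon)
  em[match(want, em$exon), , drop = FALSE]
}

# residues removed by tree_trim, as c(from_start, from_end)
trim_width <- function(spec) {
  if (spec$trim_policy != "tree_trim") return(c(0L, 0L))
  if (spec$locus_class == "BF") c(7L, 7L) else c(2L, 0L)
}

#' Extract a peptide-binding region from records
#'
#' For BF `alpha1_2`, exon 2 and exon 3 segments are concatenated with the
#' intervening intron removed; BF records lacking either exon are rejected
#' with reason `"incomplete-BF"` and reported in the `rejections` attribute
#' (such records are excluded from BF analyses). Trimming is applied after
#' translation at the amino-acid level (and over the corresponding codons at
#' the nucleotide level).
#'
#' @param records A record tibble.
#' @param spec A [region_spec()].
#' @return A tibble with columns `seq_id`, `seq`, `ambiguous` (any IUPAC
#'   ambiguity translated to `X`), `internal_stop`, and `domain_boundary`
#'   (for BF `alpha1_2`, the residue/nt index at which alpha-1 ends).
#'   Rejected records are listed in `attr(, "rejections")`.
#' @export
extract_region <- function(records, spec) {
  stopifnot(inherits(spec, "bfbl_region_spec"))
  out <- vector("list", nrow(records))
  rej <- list()
  for (i in seq_len(nrow(records))) {
    em <- records$exon_map[[i]]
    sel <- region_exons(spec, em)
    if (anyNA(sel$start)) {
      reason <- if (spec$locus_class == "BF") "incomplete-BF" else "missing-exon"
      rej[[length(rej) + 1L]] <- tibble(seq_id = records$seq_id[i], reason = reason)
      next
    }
    segs <- substring(records$nt_seq[i], sel$start + sel$frame, sel$end)
    if (any(nchar(segs) %% 3L != 0L)) {
      abort(paste0("exon segment length not a multiple of 3 after frame offset for '",
                   records$seq_id[i], "'"))
    }
    nt <- paste(segs, collapse = "")
    boundary_nt <- if (spec$region == "alpha1_2") nchar(segs[1]) else NA_integer_
    if (spec$level == "aa") {
      aa <- translate_nt(nt)
      amb <- attr(aa, "ambiguous")
      stp <- attr(aa, "internal_stop")
      attributes(aa) <- NULL
      tw <- trim_width(spec)
      seq_out <- substr(aa, 1L + tw[1], nchar(aa) - tw[2])
      boundary <- if (!is.na(boundary_nt)) boundary_nt %/% 3L - tw[1] else NA_integer_
      out[[i]] <- tibble(seq_id = records$seq_id[i], seq = seq_out,
                         ambiguous = amb, internal_stop = stp,
                         domain_boundary = boundary)
    } else {
      tw <- trim_width(spec) * 3L
      seq_out <- substr(nt, 1L + tw[1], nchar(nt) - tw[2])
      boundary <- if (!is.na(boundary_nt)) boundary_nt - tw[1] else NA_integer_
      out[[i]] <- tibble(seq_id = records$seq_id[i], seq = seq_out,
                         ambiguous = grepl("[^ACGT]", seq_out),
                         internal_stop = NA,
                         domain_boundary = boundary)
    }
  }
  res <- bind_rows(out)
  attr(res, "rejections") <- if (length(rej)) bind_rows(rej) else
    tibble(seq_id = character(), reason = character())
  attr(res, "spec") <- spec
  res
}

#' Translate nucleotides with the standard genetic code
#'
#' Codons containing IUPAC ambiguity codes translate to `X` (the sequence is
#' kept rather than rejected; replication evidence is relied upon to weed out
#' errors). An internal stop codon does not drop the sequence but is flagged
#' so the record can be marked as a putative null allele or artefact.
#'
#' @param nt A character vector of nucleotide strings.
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return A character vector of amino-acid strings with logical attributes
#'   `ambiguous` and `internal_stop` (per element).
#' @export
translate_nt <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  nt <- substring(nt, frame + 1L)
  if (any((nchar(nt)) %% 3L != 0L)) {
    abort("nucleotide length minus frame offset must be a multiple of 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           if.fuzzy.codon = "X"))
  aa <- unname(aa)
  structure(aa,
            ambiguous = grepl("X", aa, fixed = TRUE),
            internal_stop = grepl("\\*.", aa))
}
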
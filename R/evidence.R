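#' Read an evidence table
#'
#' Each row records one independent isolation of a sequence: an independent
#' PCR from the same bird, a different bird, a different line or a different
#' study/laboratory. Columns: `seq_id`, `source_kind` (one of
#' `pcr_replicate`, `bird`, `line`, `study`), `source_key`, `citation`.
#'
#' @param path Path to a tab-separated evidence file.
#' @return A tibble.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("seq_id", "source_kind", "source_key")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- !ev$source_kind %in% c("pcr_replicate", "bird", "line", "study")
  if (any(bad)) {
    abort(paste0("unknown source_kind value(s): ",
                 paste(unique(ev$source_kind[bad]), collapse = ", ")))
  }
  if (!"citation" %in% names(ev)) ev$citation <- NA_character_
  ev
}

#' Validate identity classes by replication evidence
#'
#' The first requirement for a sequence to be considered valid is replication:
#' it must have been found in at least two independent amplifications.
#' Independence means distinct `(source_kind, source_key)` pairs at any level,
#' so two birds from one study count as independent, as do two studies. A
#' class with evidence from only one source is `provisional` (reason
#' `"singleton"`); a class with no evidence at all is `provisional` with
#' reason `"no-evidence"`. Validation is monotone: adding evidence can only
#' promote, never demote.
#'
#' @param classes A tibble with `class_id` and a `seq_ids` list-column of the
#'   member sequence identifiers (as from [identity_classes()]).
#' @param evidence An evidence tibble (see [read_evidence()]).
#' @return `classes` with added columns `n_independent`, `status`
#'   (`"valid"`/`"provisional"`) and `reason`.
#' @export
validate_classes <- function(classes, evidence) {
  n_ind <- purrr::map_int(classes$seq_ids, function(ids) {
    ev <- evidence[evidence$seq_id %in% ids, c("source_kind", "source_key")]
    nrow(distinct(ev))
  })
  classes$n_independent <- n_ind
  classes$status <- ifelse(n_ind >= 2L, "valid", "provisional")
  classes$reason <- dplyr::case_when(
    n_ind >= 2L ~ NA_character_,
    n_ind == 1L ~ "singleton",
    TRUE ~ "no-evidence"
  )
  classes
}

#' Flag provisional singletons likely to be PCR errors
#'
#' Once-observed sequences that differ from a validated sequence by only one
#' or two nucleotides are most likely the result of nucleotide
#' mis-incorporation during PCR. Any provisional class within `window`
#' nucleotides of a valid class is flagged `"likely-PCR-error(nearest=<id>)"`.
#' Flags are advisory: they never change names already in the registry, and
#' rejection is a curator decision.
#'
#' @param classes A validated class tibble (with `class_id`, `status`).
#' @param nt_dm A nucleotide-level difference matrix ([diff_matrix()]) whose
#'   labels are class ids covering `classes`.
#' @param window Maximum nucleotide distance to a valid class (default 2).
#' @return A tibble `class_id`, `flag`, `nearest_valid`, `nt_distance` with
#'   one row per flagged class.
#' @export
flag_suspect_singletons <- function(classes, nt_dm, window = 2L) {
  counts <- if (inherits(nt_dm, "bfbl_dm")) nt_dm$counts else as.matrix(nt_dm)
  valid_ids <- classes$class_id[classes$status == "valid"]
  prov_ids <- classes$class_id[classes$status == "provisional"]
  valid_ids <- intersect(valid_ids, rownames(counts))
  out <- list()
  for (id in intersect(prov_ids, rownames(counts))) {
    if (length(valid_ids) == 0) break
    d <- counts[id, valid_ids, drop = TRUE]
    j <- which.min(d)
    if (d[j] >= 1L && d[j] <= window) {
      out[[length(out) + 1L]] <- tibble(
        class_id = id,
        flag = paste0("likely-PCR-error(nearest=", valid_ids[j], ")"),
        nearest_valid = valid_ids[j],
        nt_distance = as.integer(d[j])
      )
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(class_id = character(), flag = character(),
           nearest_valid = character(), nt_distance = integer())
}
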
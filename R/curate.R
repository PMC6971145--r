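#' Run the full nomenclature pipeline
#'
#' Orchestrates the curation engine end to end: collapse records into
#' identity classes, validate by replication evidence, flag likely PCR-error
#' singletons, infer or anchor the genetic locus of each class, cluster
#' validated classes into allele groups with the per-domain difference
#' cutoffs, assign multi-field names in haplotype order, and assemble
#' haplotype strings and Bfbl names into the registry. Only valid classes
#' receive names; provisional classes are reported with their reasons and
#' flags.
#'
#' @param records A record tibble from [read_records()].
#' @param evidence An evidence tibble from [read_evidence()].
#' @param nulls Optional tibble `haplotype`, `locus` of attested null
#'   alleles (absence of a gene is curator knowledge, not inferable from a
#'   missing amplicon).
#' @param registry A `bfbl_registry` to extend (default empty).
#' @param grouping A [grouping_config()].
#' @param naming A [naming_config()].
#' @return A `bfbl_curation` list: `classes`, `locus_assignments`,
#'   `suspect_flags`, `groups`, `registry`, `haplotypes`, `slot_table`,
#'   `rejections`.
#' @export
curate <- function(records, evidence, nulls = NULL,
                   registry = registry_new(),
                   grouping = grouping_config(),
                   naming = naming_config()) {
  classes <- identity_classes(records)
  rejections <- attr(classes, "rejections")
  classes <- validate_classes(classes, evidence)

  reps <- class_representatives(records, classes)
  blocks <- list()
  suspect <- list()
  region_seq <- setNames(rep(NA_character_, nrow(classes)), classes$class_id)
  for (lc in intersect(c("BLB", "BF"), classes$locus_class)) {
    sel <- classes$locus_class == lc
    reg <- if (lc == "BLB") "beta1" else "alpha1_2"
    spec_aa <- region_spec(lc, reg, "none", "aa")
    spec_nt <- region_spec(lc, reg, "none", "nt")
    blk <- build_block(reps[sel, ], spec_aa, on_length_mismatch = "exclude")
    blocks[[lc]] <- blk
    region_seq[blk$seq_id] <- blk$seq
    blk_nt <- build_block(reps[sel, ], spec_nt, on_length_mismatch = "exclude")
    suspect[[lc]] <- flag_suspect_singletons(classes[sel, ], diff_matrix(blk_nt))
  }
  suspect_flags <- bind_rows(suspect)

  # locus assignment: anchored claims first, sequence inference for the rest
  loci_of <- list(BLB = c("BLB1", "BLB2"), BF = c("BF1", "BF2"))
  assign_rows <- list()
  for (i in seq_len(nrow(classes))) {
    cl <- classes$claims[[i]]
    id <- classes$class_id[i]
    if (length(cl) >= 2) {
      assign_rows[[length(assign_rows) + 1L]] <-
        tibble(class_id = id, locus = NA_character_, margin = 0L,
               ambiguous = TRUE, anchored = TRUE)
    } else if (length(cl) == 1) {
      assign_rows[[length(assign_rows) + 1L]] <-
        tibble(class_id = id, locus = cl, margin = NA_integer_,
               ambiguous = FALSE, anchored = TRUE)
    }
  }
  anchored <- bind_rows(assign_rows)
  need <- classes[!classes$class_id %in% anchored$class_id, ]
  for (lc in unique(need$locus_class)) {
    q <- need[need$locus_class == lc & !is.na(region_seq[need$class_id]), ]
    refs <- anchored[!anchored$ambiguous &
                       anchored$locus %in% loci_of[[lc]], ]
    refs <- refs[refs$class_id %in%
                   classes$class_id[classes$status == "valid"], ]
    ref_tbl <- tibble(id = refs$class_id, locus = refs$locus,
                      seq = region_seq[refs$class_id])
    ref_tbl <- ref_tbl[!is.na(ref_tbl$seq), ]
    if (nrow(q) == 0) next
    if (length(unique(ref_tbl$locus)) < 2) {
      assign_rows[[length(assign_rows) + 1L]] <-
        tibble(class_id = q$class_id, locus = NA_character_,
               margin = NA_integer_, ambiguous = TRUE, anchored = FALSE)
      next
    }
    inferred <- assign_locus(
      tibble(id = q$class_id, seq = region_seq[q$class_id]),
      ref_tbl, grouping)
    assign_rows[[length(assign_rows) + 1L]] <-
      tibble(class_id = inferred$id, locus = inferred$locus,
             margin = inferred$margin, ambiguous = inferred$ambiguous,
             anchored = FALSE)
  }
  locus_assignments <- bind_rows(assign_rows)
  locus_assignments <- locus_assignments[
    order(locus_assignments$class_id, method = "radix"), ]

  # grouping per locus over valid, unambiguous classes
  classes2 <- left_join(classes, locus_assignments, by = "class_id")
  groups_all <- list()
  for (loc in c("BLB1", "BLB2", "BF1", "BF2")) {
    ids <- classes2$class_id[classes2$status == "valid" &
                               !classes2$ambiguous %in% TRUE &
                               classes2$locus %in% loc]
    if (length(ids) == 0) next
    lc <- if (startsWith(loc, "BLB")) "BLB" else "BF"
    dm <- diff_matrix(subset_block(blocks[[lc]], ids))
    g <- cluster_alleles(dm, grouping)
    g$locus <- loc
    g$ambiguous <- FALSE
    groups_all[[loc]] <- g
  }
  # unlocated class II B sequences: 101-series route
  amb_ids <- classes2$class_id[classes2$status == "valid" &
                                 classes2$ambiguous %in% TRUE &
                                 classes2$locus_class == "BLB"]
  amb_ids <- intersect(amb_ids, blocks[["BLB"]]$seq_id %||% character())
  if (length(amb_ids) > 0) {
    g <- cluster_alleles(diff_matrix(subset_block(blocks[["BLB"]], amb_ids)),
                         grouping)
    g$locus <- "BLB"
    g$ambiguous <- TRUE
    groups_all[["BLB"]] <- g
  }
  groups <- bind_rows(groups_all)
  groups$members <- purrr::map(groups$members, identity)

  registry <- assign_names(groups, classes, registry, naming)
  asm <- assemble_haplotypes(registry, classes, nulls)

  structure(list(classes = classes2, locus_assignments = locus_assignments,
                 suspect_flags = suspect_flags, groups = groups,
                 registry = asm$registry, haplotypes = asm$haplotypes,
                 slot_table = asm$slot_table, rejections = rejections),
            class = "bfbl_curation")
}

subset_block <- function(block, ids) {
  out <- block[match(ids, block$seq_id), ]
  class(out) <- class(block)
  attr(out, "spec") <- attr(block, "spec")
  attr(out, "domain_boundary") <- attr(block, "domain_boundary")
  out
}

#' @export
print.bfbl_curation <- function(x, ...) {
  cat("<bfbl_curation>\n",
      "  classes: ", nrow(x$classes), " (",
      sum(x$classes$status == "valid"), " valid)\n",
      "  allele groups: ", nrow(x$groups), "\n",
      "  names issued: ", nrow(x$registry$alleles), "\n",
      "  haplotypes: ", nrow(x$registry$haplotypes), "\n", sep = "")
  invisible(x)
}

#' Tidy the allele names of a curation result
#'
#' @param x A `bfbl_curation`.
#' @param ... Unused.
#' @return A tibble with one row per issued name, joined to class
#'   membership (haplotypes, member sequence ids, validation status).
#' @export
tidy.bfbl_curation <- function(x, ...) {
  left_join(x$registry$alleles,
            x$classes[, c("class_key", "class_id", "haplotypes", "seq_ids",
                          "status")],
            by = "class_key")
}

#' One-row summary of a curation result
#'
#' @param x A `bfbl_curation`.
#' @param ... Unused.
#' @return A one-row tibble of pipeline counts.
#' @export
glance.bfbl_curation <- function(x, ...) {
  tibble(n_classes = nrow(x$classes),
         n_valid = sum(x$classes$status == "valid"),
         n_provisional = sum(x$classes$status == "provisional"),
         n_suspect = nrow(x$suspect_flags),
         n_groups = nrow(x$groups),
         n_chained = sum(x$groups$chained),
         n_names = nrow(x$registry$alleles),
         n_haplotypes = nrow(x$registry$haplotypes))
}

#' Mosaic-style overview of named haplotypes
#'
#' Tiles haplotypes by locus, filled by allele group (first field) and
#' labelled with the allele shorthand — the at-a-glance view in which
#' recombinant haplotypes show up as rows mixing colours that belong to
#' different backgrounds.
#'
#' @param object A `bfbl_curation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfbl_curation <- function(object, ...) {
  st <- object$slot_table
  st$shorthand <- allele_shorthand(st$name)
  st$locus <- factor(st$locus, levels = c("BLB1", "BLB2", "BF1", "BF2", "BLB"))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$locus, y = .data$haplotype,
                                   fill = factor(.data$f1))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$shorthand), size = 3) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
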
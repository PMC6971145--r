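#' Configuration for name assignment
#'
#' @param new_allele_base First-field numbers for allele groups with no
#'   standard-haplotype member start here (default 30, well above the
#'   standard haplotypes for which sequences are available).
#' @param ambiguous_blb_base First-field numbers for class II B sequences
#'   without a clear genetic location start here (default 101); such alleles
#'   are rendered in parentheses in haplotype strings.
#' @param parity_mode When `TRUE`, newly allocated numbers are odd for BLB1
#'   and even for BLB2 (a proposed convention, off by default).
#' @return A `bfbl_naming_config` list.
#' @export
naming_config <- function(new_allele_base = 30L, ambiguous_blb_base = 101L,
                          parity_mode = FALSE) {
  structure(list(new_allele_base = as.integer(new_allele_base),
                 ambiguous_blb_base = as.integer(ambiguous_blb_base),
                 parity_mode = isTRUE(parity_mode)),
            class = "bfbl_naming_config")
}

#' Standard-haplotype number of a haplotype label
#'
#' `"B12"` gives 12; labels that are not standard `B<number>` haplotypes
#' give `NA`.
#'
#' @param x Character vector of haplotype labels.
#' @return Integer vector.
#' @export
hap_number <- function(x) {
  m <- regexec("^B([0-9]+)$", x)
  parts <- regmatches(x, m)
  vapply(parts, function(p) if (length(p)) as.integer(p[2]) else NA_integer_,
         integer(1))
}

next_free <- function(used, base, parity = NA) {
  k <- base
  repeat {
    ok <- !(k %in% used)
    if (ok && !is.na(parity)) ok <- (k %% 2L) == parity
    if (ok) return(k)
    k <- k + 1L
  }
}

# deterministic ordering key for classes: lowest standard-haplotype number
# first (Inf when none), then lowest seq_id
class_order_key <- function(classes) {
  hmin <- purrr::map_dbl(classes$haplotypes, function(h) {
    n <- hap_number(h)
    if (all(is.na(n))) Inf else min(n, na.rm = TRUE)
  })
  smin <- purrr::map_chr(classes$seq_ids, function(s) sort(s, method = "radix")[1])
  list(hmin = hmin, smin = smin)
}

#' Assign multi-field allele names to clustered identity classes
#'
#' Names are assigned so that the lowest-numbered standard haplotype in a
#' group anchors the first field, and the variant present in the
#' lowest-numbered haplotype takes `:01` — equivalent to working through the
#' haplotypes in ascending numerical order and naming identical and closely
#' related sequences as they are encountered. Groups with no
#' standard-haplotype member receive the next free number at or above
#' `new_allele_base` (at or above `ambiguous_blb_base` for class II B
#' sequences without a clear genetic location). Within a group, protein
#' (nonsynonymous) variants order the second field; synonymous nucleotide
#' variants within a protein variant order the third field; the fourth field
#' defaults to 01 with a completeness flag since most literature sequences
#' are exon-only. Names already in the registry are never changed:
#' re-running on a superset of the input only appends.
#'
#' @param groups A tibble of allele groups with columns `locus`, `group_id`,
#'   `members` (list of class ids), `chained`, plus logical `ambiguous`
#'   (unlocated BLB groups, locus `"BLB"`).
#' @param classes The identity-class tibble ([identity_classes()]) with
#'   `class_id`, `class_key`, `aa_key`, `haplotypes`, `seq_ids`, `complete`.
#' @param registry A `bfbl_registry` (may be empty or populated).
#' @param config A [naming_config()].
#' @return The updated registry.
#' @export
assign_names <- function(groups, classes, registry = registry_new(),
                         config = naming_config()) {
  stopifnot(inherits(registry, "bfbl_registry"))
  key <- class_order_key(classes)
  classes$.hmin <- key$hmin
  classes$.smin <- key$smin
  locus_order <- c("BLB1", "BLB2", "BF1", "BF2", "BLB")
  for (loc in intersect(locus_order, unique(groups$locus))) {
    gl <- groups[groups$locus == loc, ]
    ambiguous <- loc == "BLB"
    base <- if (ambiguous) config$ambiguous_blb_base else config$new_allele_base
    parity <- NA
    if (config$parity_mode && loc %in% c("BLB1", "BLB2")) {
      parity <- if (loc == "BLB1") 1L else 0L
    }
    used <- registry$alleles$f1[registry$alleles$locus == loc]
    # resolve f1 per group: registry first, then lowest standard haplotype
    info <- purrr::map(seq_len(nrow(gl)), function(g) {
      mem <- classes[classes$class_id %in% gl$members[[g]], ]
      reg <- registry$alleles[registry$alleles$class_key %in% mem$class_key, ]
      if (nrow(reg) > 0 && any(reg$locus != loc)) {
        abort(paste0("class registered at locus ", unique(reg$locus)[1],
                     " reappears at locus ", loc, " — curator action required"))
      }
      f1 <- NA_integer_
      if (nrow(reg) > 0) {
        f1s <- unique(reg$f1)
        if (length(f1s) > 1) {
          abort(paste0("allele-group merge would join registered names ",
                       paste(unique(reg$name), collapse = " and "),
                       " — curator action required"))
        }
        f1 <- f1s
      } else {
        hmin <- min(mem$.hmin)
        if (is.finite(hmin) && !ambiguous) f1 <- as.integer(hmin)
      }
      list(mem = mem, f1 = f1, order_key = c(min(mem$.hmin), min(mem$.smin)))
    })
    fixed <- vapply(info, function(x) x$f1, integer(1))
    clash <- fixed[!is.na(fixed)][duplicated(fixed[!is.na(fixed)])]
    if (length(clash) > 0) {
      abort(paste0("two allele groups at ", loc,
                   " claim first-field number(s) ",
                   paste(unique(clash), collapse = ", "),
                   " — curator action required"))
    }
    used <- c(used, fixed[!is.na(fixed)])
    # allocate remaining groups deterministically
    pending <- which(is.na(fixed))
    pending <- pending[order(vapply(info[pending], function(x)
      as.numeric(x$order_key[1]), numeric(1)),
      vapply(info[pending], function(x) x$order_key[2], character(1)),
      method = "radix")]
    for (g in pending) {
      f1 <- next_free(used, base, parity)
      info[[g]]$f1 <- f1
      used <- c(used, f1)
    }
    # second/third fields within each group
    for (g in seq_along(info)) {
      mem <- info[[g]]$mem
      f1 <- info[[g]]$f1
      reg <- registry$alleles[registry$alleles$class_key %in% mem$class_key, ]
      aa_keys <- unique(mem$aa_key)
      # existing f2 per protein variant
      f2_of <- setNames(rep(NA_integer_, length(aa_keys)), aa_keys)
      for (ak in aa_keys) {
        keys <- mem$class_key[mem$aa_key == ak]
        hit <- reg[reg$class_key %in% keys, ]
        if (nrow(hit) > 0) f2_of[ak] <- hit$f2[1]
      }
      ord <- order(purrr::map_dbl(aa_keys, function(ak)
        min(mem$.hmin[mem$aa_key == ak])),
        purrr::map_chr(aa_keys, function(ak)
          min(mem$.smin[mem$aa_key == ak])),
        method = "radix")
      for (ak in aa_keys[ord]) {
        if (is.na(f2_of[ak])) {
          f2_of[ak] <- next_free(f2_of[!is.na(f2_of)], 1L)
        }
      }
      alloc <- list()
      for (ak in aa_keys) {
        sub <- mem[mem$aa_key == ak, ]
        sub <- sub[order(sub$.hmin, sub$.smin, method = "radix"), ]
        f3_used <- reg$f3[reg$class_key %in% sub$class_key]
        for (i in seq_len(nrow(sub))) {
          if (sub$class_key[i] %in% reg$class_key) next
          f3 <- next_free(f3_used, 1L)
          f3_used <- c(f3_used, f3)
          nm <- render_allele_name(loc, info[[g]]$f1, f2_of[[ak]], f3)
          alloc[[length(alloc) + 1L]] <- tibble(
            class_key = sub$class_key[i], locus = loc,
            f1 = info[[g]]$f1, f2 = unname(f2_of[[ak]]), f3 = f3,
            f4 = NA_integer_, ambiguous_locus = ambiguous,
            complete = sub$complete[i], name = nm,
            shorthand = allele_shorthand(nm))
        }
      }
      if (length(alloc) > 0) {
        registry <- registry_register(registry, bind_rows(alloc))
      }
    }
  }
  registry
}

#' Assemble haplotype records and register haplotype strings
#'
#' Groups named identity classes by haplotype label and fills the four slots
#' in BLB1-BLB2-BF1-BF2 order. Attested null alleles come from `nulls`;
#' missing slots render `"?"`; a locus-ambiguous BLB class occupies both
#' class II slots as a parenthesized pair. Bfbl names are allocated in
#' registration order — standard haplotypes in ascending numerical order,
#' then other labels — with letter suffixes (`b`, `c`, ...) when a distinct
#' background shares an already-used BF2 shorthand.
#'
#' @param registry A registry populated by [assign_names()].
#' @param classes The identity-class tibble.
#' @param nulls Optional tibble `haplotype`, `locus` of attested nulls.
#' @return A list: updated `registry`, `haplotypes` (list of
#'   `bfbl_haplotype`), and `slot_table` (tibble `haplotype`, `locus`,
#'   `class_id`, `name`, `f1`).
#' @export
assemble_haplotypes <- function(registry, classes, nulls = NULL) {
  named <- left_join(
    tidyr::unnest(classes[, c("class_id", "class_key", "haplotypes")],
                  "haplotypes"),
    registry$alleles[, c("class_key", "locus", "f1", "name", "ambiguous_locus")],
    by = "class_key")
  named <- named[!is.na(named$name) & !is.na(named$haplotypes), ]
  haps <- unique(named$haplotypes)
  hn <- hap_number(haps)
  haps <- haps[order(is.na(hn), hn, haps, method = "radix")]
  slot_rows <- list()
  records <- list()
  bfbl_seen <- list()  # base -> tibble(string, suffix)
  for (h in haps) {
    hh <- named[named$haplotypes == h, ]
    slots <- list(BLB1 = NA_character_, BLB2 = NA_character_,
                  BF1 = NA_character_, BF2 = NA_character_)
    pair <- NA_character_
    for (loc in c("BLB1", "BLB2", "BF1", "BF2")) {
      cand <- hh[hh$locus == loc, ]
      if (nrow(cand) > 0) {
        cand <- cand[order(cand$name, method = "radix"), ]
        slots[[loc]] <- cand$name[1]
        slot_rows[[length(slot_rows) + 1L]] <-
          tibble(haplotype = h, locus = loc, class_id = cand$class_id[1],
                 name = cand$name[1], f1 = cand$f1[1])
      }
    }
    amb <- hh[hh$ambiguous_locus, ]
    if (nrow(amb) > 0) {
      pair <- amb$name[1]
      slot_rows[[length(slot_rows) + 1L]] <-
        tibble(haplotype = h, locus = "BLB", class_id = amb$class_id[1],
               name = amb$name[1], f1 = amb$f1[1])
    }
    if (!is.null(nulls)) {
      nl <- nulls[nulls$haplotype == h, ]
      for (loc in nl$locus) slots[[loc]] <- "null"
    }
    rec <- haplotype_record(h, BLB1 = slots$BLB1, BLB2 = slots$BLB2,
                            BF1 = slots$BF1, BF2 = slots$BF2, blb_pair = pair)
    # provisional suffix allocation on the BF2 shorthand
    base <- slot_token(rec$slots$BF2, "shorthand")
    str_now <- haplotype_string(rec)
    if (!base %in% c("?", "null")) {
      prev <- registry$haplotypes[!is.na(registry$haplotypes$bfbl), ]
      prev_base <- sub("[a-z]+$", "", prev$bfbl)
      seen <- prev[prev_base == base, ]
      if (h %in% registry$haplotypes$haplotype) {
        rec$provisional_suffix <- registry$haplotypes$suffix[
          registry$haplotypes$haplotype == h]
        if (is.na(rec$provisional_suffix) ||
            rec$provisional_suffix == "") rec$provisional_suffix <- NA_character_
      } else if (nrow(seen) > 0 && any(seen$string == str_now)) {
        sfx <- seen$suffix[seen$string == str_now][1]
        rec$provisional_suffix <- if (is.na(sfx) || sfx == "") NA_character_ else sfx
      } else if (nrow(seen) > 0) {
        n_distinct_strings <- length(unique(seen$string))
        rec$provisional_suffix <- letters[n_distinct_strings + 1L]
      }
    }
    registry <- registry_register_haplotype(
      registry, h, str_now, haplotype_string(rec, "canonical"),
      bfbl_name(rec), rec$provisional_suffix %||% NA_character_)
    records[[h]] <- rec
  }
  list(registry = registry, haplotypes = records,
       slot_table = if (length(slot_rows)) bind_rows(slot_rows) else
         tibble(haplotype = character(), locus = character(),
                class_id = character(), name = character(), f1 = integer()))
}

#' Detect gene-level mosaic (recombinant) haplotypes
#'
#' Attributes each slot's allele group to the other registered haplotypes
#' carrying that group and reports a minimal set of parent haplotypes
#' covering all attributable slots — e.g. a B19-style haplotype resolves to
#' the B12 background for the first three slots and the B15 group for BF2.
#' Resolution is at the gene level only.
#'
#' @param slot_table The `slot_table` from [assemble_haplotypes()] (or a
#'   `bfbl_curation`'s `$slot_table`).
#' @param haplotype The haplotype to analyse.
#' @return A list: `attribution` tibble (`locus`, `f1`, `carriers`
#'   list-column) and `parents`, the minimal covering set (the queried
#'   haplotype itself excluded); `is_mosaic` is `TRUE` when more than one
#'   parent is needed.
#' @export
detect_mosaic <- function(slot_table, haplotype) {
  if (inherits(slot_table, "bfbl_curation")) slot_table <- slot_table$slot_table
  mine <- slot_table[slot_table$haplotype == haplotype, ]
  if (nrow(mine) == 0) abort(paste0("haplotype not in catalogue: ", haplotype))
  attribution <- purrr::map(seq_len(nrow(mine)), function(i) {
    carriers <- unique(slot_table$haplotype[
      slot_table$locus == mine$locus[i] & slot_table$f1 == mine$f1[i] &
        slot_table$haplotype != haplotype])
    tibble(locus = mine$locus[i], f1 = mine$f1[i],
           carriers = list(sort(carriers, method = "radix")))
  })
  attribution <- bind_rows(attribution)
  covered <- vapply(attribution$carriers, length, integer(1)) > 0
  candidates <- sort(unique(unlist(attribution$carriers)), method = "radix")
  parents <- character()
  if (any(covered) && length(candidates) > 0) {
    target <- which(covered)
    for (k in seq_along(candidates)) {
      combos <- combn(candidates, k, simplify = FALSE)
      hit <- purrr::detect(combos, function(cs) {
        all(vapply(target, function(t)
          length(intersect(attribution$carriers[[t]], cs)) > 0, logical(1)))
      })
      if (!is.null(hit)) { parents <- hit; break }
    }
  }
  list(attribution = attribution, parents = parents,
       uncovered = attribution[!covered, c("locus", "f1")],
       is_mosaic = length(parents) > 1)
}
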
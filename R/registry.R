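#' Create an empty allele registry
#'
#' The registry is the persistent catalogue of issued names. It is
#' append-only: a name, once issued, is never reassigned or altered, and the
#' same identity class (keyed by its full coding-exon nucleotide sequence)
#' always maps to one name regardless of haplotype. Every allocation and
#' override is recorded in an audit log ordered by a monotone event counter.
#'
#' @return A `bfbl_registry` object.
#' @export
registry_new <- function() {
  structure(list(
    alleles = tibble(class_key = character(), locus = character(),
                     f1 = integer(), f2 = integer(), f3 = integer(),
                     f4 = integer(), ambiguous_locus = logical(),
                     complete = logical(), name = character(),
                     shorthand = character(), event = integer()),
    haplotypes = tibble(haplotype = character(), string = character(),
                        canonical = character(), bfbl = character(),
                        suffix = character(), event = integer()),
    audit = tibble(event = integer(), action = character(),
                   detail = character()),
    next_event = 1L
  ), class = "bfbl_registry")
}

#' @export
print.bfbl_registry <- function(x, ...) {
  cat("<bfbl_registry> ", nrow(x$alleles), " allele name(s), ",
      nrow(x$haplotypes), " haplotype(s), ", nrow(x$audit),
      " audit event(s)\n", sep = "")
  invisible(x)
}

registry_log <- function(registry, action, detail) {
  registry$audit <- bind_rows(registry$audit,
                              tibble(event = registry$next_event,
                                     action = action, detail = detail))
  registry$next_event <- registry$next_event + 1L
  registry
}

#' Register new allele-name allocations
#'
#' Appends allocations to the registry. Re-registering an identical
#' allocation is a no-op; a conflicting allocation (same identity class,
#' different proposed name) is a hard error citing both names and requires
#' curator action.
#'
#' @param registry A `bfbl_registry`.
#' @param allocations A tibble with the columns of `registry$alleles`
#'   (except `event`).
#' @return The updated registry.
#' @export
registry_register <- function(registry, allocations) {
  stopifnot(inherits(registry, "bfbl_registry"))
  for (i in seq_len(nrow(allocations))) {
    key <- allocations$class_key[i]
    hit <- registry$alleles[registry$alleles$class_key == key, ]
    if (nrow(hit) > 0) {
      if (hit$name[1] != allocations$name[i]) {
        abort(paste0("conflicting allocation for one identity class: ",
                     "registered name ", hit$name[1],
                     " vs proposed name ", allocations$name[i],
                     " — curator action required"))
      }
      next
    }
    row <- allocations[i, ]
    row$event <- registry$next_event
    registry$alleles <- bind_rows(registry$alleles, row)
    registry <- registry_log(registry, "name-issued",
                             paste0(row$name, " <- class ",
                                    substr(key, 1, 24), "..."))
  }
  registry
}

registry_register_haplotype <- function(registry, haplotype, string,
                                        canonical, bfbl, suffix) {
  hit <- registry$haplotypes[registry$haplotypes$haplotype == haplotype, ]
  if (nrow(hit) > 0) {
    if (hit$string[1] != string) {
      abort(paste0("haplotype ", haplotype, " already registered with string ",
                   hit$string[1], "; conflicting string ", string,
                   " — curator action required"))
    }
    return(registry)
  }
  registry$haplotypes <- bind_rows(
    registry$haplotypes,
    tibble(haplotype = haplotype, string = string, canonical = canonical,
           bfbl = bfbl, suffix = suffix, event = registry$next_event))
  registry_log(registry, "haplotype-registered",
               paste0(haplotype, " = ", string))
}

#' Persist / load a registry as TSV files
#'
#' Writes `alleles.tsv`, `haplotypes.tsv` and `audit.tsv` under `dir`.
#' Because allocation is deterministic and the audit log uses an event
#' counter rather than timestamps, re-exporting after a re-run on a superset
#' of the input leaves previously issued rows byte-identical.
#'
#' @param registry A `bfbl_registry`.
#' @param dir Directory (created if needed).
#' @return The registry (readers return the loaded registry), invisibly.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(registry$alleles, file.path(dir, "alleles.tsv"),
                   progress = FALSE)
  readr::write_tsv(registry$haplotypes, file.path(dir, "haplotypes.tsv"),
                   progress = FALSE)
  readr::write_tsv(registry$audit, file.path(dir, "audit.tsv"),
                   progress = FALSE)
  invisible(registry)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  al <- readr::read_tsv(file.path(dir, "alleles.tsv"),
                        col_types = "cciiiillcci", progress = FALSE)
  hp <- readr::read_tsv(file.path(dir, "haplotypes.tsv"),
                        col_types = "ccccci", progress = FALSE)
  au <- readr::read_tsv(file.path(dir, "audit.tsv"),
                        col_types = "icc", progress = FALSE)
  structure(list(alleles = al, haplotypes = hp, audit = au,
                 next_event = max(0L, al$event, hp$event, au$event) + 1L),
            class = "bfbl_registry")
}

#' Tidy the allele table of a registry
#'
#' @param x A `bfbl_registry`.
#' @param ... Unused.
#' @return The allele tibble.
#' @export
tidy.bfbl_registry <- function(x, ...) x$alleles

#' One-row summary of a registry
#'
#' @param x A `bfbl_registry`.
#' @param ... Unused.
#' @return A one-row tibble with allele, group and haplotype counts.
#' @export
glance.bfbl_registry <- function(x, ...) {
  tibble(n_alleles = nrow(x$alleles),
         n_groups = nrow(distinct(x$alleles, .data$locus, .data$f1)),
         n_haplotypes = nrow(x$haplotypes),
         n_ambiguous = sum(x$alleles$ambiguous_locus))
}
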
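#' Configuration for locus assignment and allele grouping
#'
#' The variant cutoff follows curation practice for these genes: up to four
#' amino-acid differences per peptide-binding domain, totalled to eight for
#' BF sequences (beta-1 only for BLB), qualify two sequences as variants of
#' one allele group. Pairs with five to nine differences per domain/exon are
#' too far apart to be variants but close enough to warrant curator review.
#'
#' @param variant_max_per_domain Maximum amino-acid differences per domain
#'   for two sequences to be variants of one group (default 4).
#' @param bf_total_max Maximum total differences over alpha-1 + alpha-2 for
#'   BF (default 8).
#' @param review_lo,review_hi Inclusive per-domain review zone (default 5-9).
#' @param locus_margin_tau Minimum margin, in amino acids, between the
#'   nearest other-locus and nearest same-locus reference for an unambiguous
#'   locus call (default 5, below one variant-width: near-ties go to
#'   curators).
#' @return A `bfbl_grouping_config` list.
#' @export
grouping_config <- function(variant_max_per_domain = 4L, bf_total_max = 8L,
                            review_lo = 5L, review_hi = 9L,
                            locus_margin_tau = 5L) {
  stopifnot(review_lo > variant_max_per_domain, review_hi < 10L)
  structure(list(variant_max_per_domain = as.integer(variant_max_per_domain),
                 bf_total_max = as.integer(bf_total_max),
                 review_lo = as.integer(review_lo),
                 review_hi = as.integer(review_hi),
                 locus_margin_tau = as.integer(locus_margin_tau)),
            class = "bfbl_grouping_config")
}

#' Infer the genetic locus of query sequences
#'
#' Each query is compared (amino-acid differences over the comparison region)
#' to labelled reference sequences from both candidate loci of its class
#' (BLB1/BLB2 or BF1/BF2). The locus of the nearest reference is assigned;
#' the margin is the distance to the nearest other-locus reference minus the
#' distance to the nearest same-locus reference. A call is flagged ambiguous
#' when the margin is below `locus_margin_tau`, or when the identical
#' sequence is attested at both loci. A specific locus claim backed by
#' between-gene PCR evidence overrides sequence inference and is recorded as
#' anchored; a query claimed at both loci is ambiguous regardless of
#' distances (for BLB, such sequences are routed to the 101-series).
#'
#' @param queries Tibble with `id`, `seq` and optionally a `claims`
#'   list-column of specific locus claims attested for that sequence.
#' @param references Tibble with `id`, `locus`, `seq`; must cover at least
#'   two loci.
#' @param config A [grouping_config()].
#' @return A tibble `id`, `locus`, `nearest_reference`, `margin`,
#'   `ambiguous`, `anchored`.
#' @export
assign_locus <- function(queries, references, config = grouping_config()) {
  if (nrow(references) == 0) abort("no reference sequences supplied")
  loci <- sort(unique(references$locus))
  if (length(loci) < 2) abort("references must cover both candidate loci")
  claims <- if ("claims" %in% names(queries)) queries$claims else
    rep(list(character()), nrow(queries))
  out <- purrr::map(seq_len(nrow(queries)), function(i) {
    cl <- intersect(claims[[i]], loci)
    d <- vapply(references$seq, function(r)
      as.integer(count_diffs(queries$seq[i], r)), integer(1))
    d_by_locus <- vapply(loci, function(l) min(d[references$locus == l]),
                         numeric(1))
    if (length(cl) >= 2) {
      return(tibble(id = queries$id[i], locus = NA_character_,
                    nearest_reference = NA_character_, margin = 0L,
                    ambiguous = TRUE, anchored = TRUE))
    }
    if (length(cl) == 1) {
      same <- d_by_locus[cl]
      other <- min(d_by_locus[setdiff(loci, cl)])
      return(tibble(id = queries$id[i], locus = cl,
                    nearest_reference = references$id[which.min(d)],
                    margin = as.integer(other - same),
                    ambiguous = FALSE, anchored = TRUE))
    }
    best <- loci[which.min(d_by_locus)]
    same <- d_by_locus[best]
    other <- min(d_by_locus[setdiff(loci, best)])
    margin <- as.integer(other - same)
    tibble(id = queries$id[i], locus = best,
           nearest_reference = references$id[which.min(d)],
           margin = margin,
           ambiguous = margin < config$locus_margin_tau,
           anchored = FALSE)
  })
  bind_rows(out)
}

variant_edge <- function(dm, i, j, config) {
  if (!is.null(dm$per_domain)) {
    a1 <- dm$per_domain$alpha1[i, j]
    a2 <- dm$per_domain$alpha2[i, j]
    a1 <= config$variant_max_per_domain &&
      a2 <= config$variant_max_per_domain &&
      (a1 + a2) <= config$bf_total_max
  } else {
    dm$counts[i, j] <= config$variant_max_per_domain
  }
}

review_edge <- function(dm, i, j, config) {
  in_zone <- function(x) x >= config$review_lo & x <= config$review_hi
  if (!is.null(dm$per_domain)) {
    a1 <- dm$per_domain$alpha1[i, j]
    a2 <- dm$per_domain$alpha2[i, j]
    max(a1, a2) <= config$review_hi && (in_zone(a1) || in_zone(a2))
  } else {
    in_zone(dm$counts[i, j])
  }
}

#' Cluster validated sequences at one locus into allele groups
#'
#' Single-linkage components over variant edges: for BLB, pairs within
#' `variant_max_per_domain` beta-1 differences; for BF, pairs within the
#' per-domain cutoff in each of alpha-1 and alpha-2 *and* within
#' `bf_total_max` in total (the conjunction is the stricter reading of the
#' cutoff and the safer curation rule). Pairs in the 5-9 per-domain review
#' zone are recorded as review edges but never merge groups on their own.
#' A component containing an internal pair above the cutoff is marked
#' `chained` — single linkage can chain through intermediates, a transitivity
#' risk surfaced rather than resolved. Output is deterministic and invariant
#' to input order.
#'
#' @param dm A `bfbl_dm` (amino-acid level, `trim_policy = "none"`) covering
#'   the identity classes at one locus; BF matrices must carry the
#'   per-domain split.
#' @param config A [grouping_config()].
#' @return A tibble `group_id`, `members` (list of labels, ordered),
#'   `chained`, `review_edges` (list of tibbles `a`, `b`, `count`).
#' @export
cluster_alleles <- function(dm, config = grouping_config()) {
  stopifnot(inherits(dm, "bfbl_dm"))
  if (dm$level != "aa") abort("allele grouping uses amino-acid differences")
  labels <- sort(dm$labels, method = "radix")
  n <- length(labels)
  idx <- match(labels, dm$labels)
  # adjacency over variant edges
  adj <- matrix(FALSE, n, n)
  review <- list()
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        i <- idx[a]; j <- idx[b]
        if (variant_edge(dm, i, j, config)) {
          adj[a, b] <- adj[b, a] <- TRUE
        } else if (review_edge(dm, i, j, config)) {
          review[[length(review) + 1L]] <-
            tibble(a = labels[a], b = labels[b],
                   count = dm$counts[i, j])
        }
      }
    }
  }
  # connected components by breadth-first search
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  review_tbl <- if (length(review)) bind_rows(review) else
    tibble(a = character(), b = character(), count = integer())
  out <- purrr::map(seq_len(k), function(g) {
    mem <- labels[comp == g]
    chained <- FALSE
    if (length(mem) > 1) {
      prs <- combn(match(mem, dm$labels), 2)
      chained <- !all(vapply(seq_len(ncol(prs)), function(p)
        variant_edge(dm, prs[1, p], prs[2, p], config), logical(1)))
    }
    rv <- review_tbl[review_tbl$a %in% mem | review_tbl$b %in% mem, ]
    tibble(group_id = g, members = list(mem), chained = chained,
           review_edges = list(rv))
  })
  bind_rows(out)
}
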
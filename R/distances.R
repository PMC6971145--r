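#' Build an aligned block of region strings
#'
#' The peptide-binding exons of chicken classical class I and class II B
#' sequences contain no indels, so equal-length region strings align
#' position-for-position without a gapped alignment step. A record whose
#' region string differs in length from the majority indicates an indel or a
#' truncated amplicon and is reported by id.
#'
#' @param records A record tibble.
#' @param spec A [region_spec()].
#' @param on_length_mismatch `"error"` (default) aborts naming the offending
#'   records; `"exclude"` drops them (pending curator review) with a warning.
#' @return A `bfbl_block`: a tibble (`seq_id`, `seq`) with attributes `spec`,
#'   `domain_boundary` and `rejections`.
#' @export
build_block <- function(records, spec,
                        on_length_mismatch = c("error", "exclude")) {
  on_length_mismatch <- match.arg(on_length_mismatch)
  reg <- extract_region(records, spec)
  if (nrow(reg) == 0) abort("no records yield a region string")
  lens <- nchar(reg$seq)
  mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  offenders <- reg$seq_id[lens != mode_len]
  if (length(offenders) > 0) {
    msg <- paste0("indel-or-truncation(", paste(offenders, collapse = ", "), ")")
    if (on_length_mismatch == "error") abort(msg)
    warn(paste0(msg, " — excluded pending curator review"))
    reg <- reg[lens == mode_len, ]
  }
  out <- reg[, c("seq_id", "seq")]
  class(out) <- c("bfbl_block", class(out))
  attr(out, "spec") <- spec
  attr(out, "domain_boundary") <-
    if (all(is.na(reg$domain_boundary))) NA_integer_ else reg$domain_boundary[1]
  attr(out, "rejections") <- attr(reg, "rejections")
  out
}

block_char_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$seq, "", fixed = TRUE))
  rownames(m) <- block$seq_id
  m
}

masked_symbol <- function(level) if (level == "aa") "X" else c("A", "C", "G", "T")

#' Count pairwise differences between two equal-length residue strings
#'
#' A plain Hamming count. Positions where either residue is ambiguous (`X` at
#' the amino-acid level; any non-ACGT symbol at the nucleotide level) are
#' skipped and the number of skipped positions is reported in the `masked`
#' attribute, so sequencing ambiguity never inflates a difference count.
#'
#' @param a,b Equal-length residue strings.
#' @param level `"aa"` or `"nt"`.
#' @return An integer count with attribute `masked`.
#' @export
count_diffs <- function(a, b, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- if (level == "aa") av != "X" & bv != "X" else
    av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  structure(sum(av[ok] != bv[ok]), masked = sum(!ok))
}

#' Pairwise difference matrix over an aligned block
#'
#' Symmetric matrix of Hamming counts (zero diagonal). For BF alpha-1 +
#' alpha-2 blocks a per-domain breakdown is carried alongside, since the
#' allele-group cutoff is applied per domain as well as in total.
#'
#' @param block A `bfbl_block` from [build_block()].
#' @return A `bfbl_dm` list: `labels`, `counts`, `masked`, `level`,
#'   `seq_length`, `locus_class` and (for BF alpha1_2) `per_domain`, a list
#'   of `alpha1`/`alpha2` count matrices.
#' @export
diff_matrix <- function(block) {
  stopifnot(inherits(block, "bfbl_block"))
  spec <- attr(block, "spec")
  m <- block_char_matrix(block)
  boundary <- attr(block, "domain_boundary")
  ok <- if (spec$level == "aa") m != "X" else
    matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  counts <- masked <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  dom <- NULL
  if (!is.na(boundary)) {
    dom <- list(alpha1 = counts, alpha2 = counts)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        use <- ok[i, ] & ok[j, ]
        d <- m[i, ] != m[j, ] & use
        counts[i, j] <- counts[j, i] <- sum(d)
        masked[i, j] <- masked[j, i] <- sum(!use)
        if (!is.null(dom)) {
          a1 <- sum(d[seq_len(boundary)])
          dom$alpha1[i, j] <- dom$alpha1[j, i] <- a1
          dom$alpha2[i, j] <- dom$alpha2[j, i] <- sum(d) - a1
        }
      }
    }
  }
  structure(list(labels = rownames(m), counts = counts, masked = masked,
                 level = spec$level, seq_length = ncol(m),
                 locus_class = spec$locus_class, per_domain = dom),
            class = "bfbl_dm")
}

#' @export
print.bfbl_dm <- function(x, ...) {
  cat("<bfbl_dm> ", length(x$labels), " sequences, ", x$level,
      " level, length ", x$seq_length,
      if (!is.null(x$per_domain)) ", with per-domain split" else "", "\n", sep = "")
  invisible(x)
}

#' Classify a difference count into the curation colour bins
#'
#' The bins mirror the highlighting convention used when inspecting the
#' matrices: `green` = identical; `blue` = 1-4 differences for BF (1-2 for
#' BLB); `yellow` = 5-8 for BF (3-4 for BLB), the zone close to the variant
#' cutoff; `beyond` = more than that.
#'
#' @param count Non-negative integer vector of difference counts.
#' @param locus_class `"BF"` or `"BLB"`.
#' @return A factor with levels `green`, `blue`, `yellow`, `beyond`.
#' @export
diff_bin <- function(count, locus_class = c("BF", "BLB")) {
  locus_class <- match.arg(locus_class)
  stopifnot(all(count >= 0))
  breaks <- if (locus_class == "BF") c(-Inf, 0, 4, 8, Inf) else c(-Inf, 0, 2, 4, Inf)
  cut(count, breaks = breaks, labels = c("green", "blue", "yellow", "beyond"))
}

#' Tidy a difference matrix into long form
#'
#' @param x A `bfbl_dm`.
#' @param ... Unused.
#' @return A tibble `label_a`, `label_b`, `count`, `masked`, `bin` over the
#'   upper triangle (one row per unordered pair).
#' @export
tidy.bfbl_dm <- function(x, ...) {
  n <- length(x$labels)
  if (n < 2) {
    return(tibble(label_a = character(), label_b = character(),
                  count = integer(), masked = integer(), bin = factor()))
  }
  idx <- which(upper.tri(x$counts), arr.ind = TRUE)
  out <- tibble(
    label_a = x$labels[idx[, 1]],
    label_b = x$labels[idx[, 2]],
    count = x$counts[idx],
    masked = x$masked[idx],
    bin = diff_bin(x$counts[idx], x$locus_class)
  )
  if (!is.null(x$per_domain)) {
    out$alpha1 <- x$per_domain$alpha1[idx]
    out$alpha2 <- x$per_domain$alpha2[idx]
  }
  out
}

#' Heatmap of a difference matrix with curation colour bins
#'
#' @param object A `bfbl_dm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfbl_dm <- function(object, ...) {
  long <- tidyr::expand_grid(label_a = object$labels, label_b = object$labels)
  long$count <- object$counts[cbind(long$label_a, long$label_b)]
  long$bin <- diff_bin(long$count, object$locus_class)
  long$bin[long$label_a == long$label_b] <- NA
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label_b, y = .data$label_a,
                                     fill = .data$bin)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.6) +
    ggplot2::scale_fill_manual(
      values = c(green = "#7fbf7f", blue = "#9fc5e8", yellow = "#ffe599",
                 beyond = "white"),
      na.value = "grey85", name = "differences") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export / import difference matrices
#'
#' `write_dm_tsv()` writes a labels-by-labels table; `write_dm_phylip()` and
#' `read_dm_phylip()` exchange square PHYLIP distance matrices (relaxed
#' names, whitespace-separated) for interoperability with tree programs.
#'
#' @param dm A `bfbl_dm` or a square numeric matrix with dimnames.
#' @param path Output (or input) path.
#' @return The matrix, invisibly (readers return the matrix).
#' @export
write_dm_tsv <- function(dm, path) {
  counts <- if (inherits(dm, "bfbl_dm")) dm$counts else as.matrix(dm)
  df <- as_tibble(counts, rownames = "label")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(counts)
}

#' @rdname write_dm_tsv
#' @export
write_dm_phylip <- function(dm, path) {
  counts <- if (inherits(dm, "bfbl_dm")) dm$counts else as.matrix(dm)
  lines <- c(sprintf("%5d", nrow(counts)),
             vapply(seq_len(nrow(counts)), function(i) {
               paste(c(rownames(counts)[i],
                       format(counts[i, ], trim = TRUE)), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(counts)
}

#' @rdname write_dm_tsv
#' @export
read_dm_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  m
}
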
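#' Configuration for tree building
#'
#' @param bootstrap_reps Number of bootstrap replicates (default 500, the
#'   conventional depth for reporting clade support in this literature).
#' @param seed Integer seed controlling bootstrap resampling.
#' @param outgroup Labels to root on (empty = unrooted).
#' @param distance_model `"count"` (differences divided by region length) or
#'   `"poisson_corrected"` (`-log(1 - p)`); group decisions rest on raw
#'   counts, so the tree metric is advisory.
#' @return A `bfbl_tree_config` list.
#' @export
tree_config <- function(bootstrap_reps = 500L, seed = 1L,
                        outgroup = character(),
                        distance_model = c("count", "poisson_corrected")) {
  stopifnot(bootstrap_reps >= 0)
  structure(list(bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), outgroup = outgroup,
                 distance_model = match.arg(distance_model)),
            class = "bfbl_tree_config")
}

dm_to_dist <- function(dm, model) {
  if (inherits(dm, "bfbl_dm")) {
    p <- dm$counts / dm$seq_length
  } else {
    p <- as.matrix(dm)
  }
  if (model == "poisson_corrected") {
    p <- pmin(p, 1 - 1e-6)
    p <- -log(1 - p)
  }
  p
}

#' Neighbour-joining tree from a difference matrix
#'
#' Standard Saitou-Nei agglomeration on normalized distances. Labels are
#' sorted into a locale-independent order before agglomeration, so the result
#' is deterministic and invariant to the input row order (ties between equal
#' distances resolve by label order). Negative branch lengths are clamped to
#' zero, with a message when this happens.
#'
#' @param dm A `bfbl_dm` (counts normalized by region length) or a square
#'   numeric distance matrix with dimnames (used as-is).
#' @param config A [tree_config()]; `outgroup` and `distance_model` are used.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm, config = tree_config()) {
  d <- dm_to_dist(dm, config$distance_model)
  if (nrow(d) < 3) abort("neighbour joining needs at least 3 sequences")
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord]
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  if (length(config$outgroup) > 0) {
    missing_og <- setdiff(config$outgroup, tree$tip.label)
    if (length(missing_og) > 0) {
      abort(paste0("outgroup label(s) not in matrix: ",
                   paste(missing_og, collapse = ", ")))
    }
    tree <- ape::root(tree, outgroup = config$outgroup, resolve.root = TRUE)
  }
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement, the tree is rebuilt per
#' replicate, and the percentage of replicates containing each bipartition of
#' the point-estimate tree is attached as integer internal-node labels.
#' Reproducible for a fixed seed; `bootstrap_reps = 0` returns the tree
#' without support values.
#'
#' @param block A `bfbl_block` from [build_block()].
#' @param config A [tree_config()].
#' @return An `ape::phylo` tree; `node.label` holds support percentages.
#' @export
bootstrap_tree <- function(block, config = tree_config()) {
  dm <- diff_matrix(block)
  point <- nj_tree(dm, config)
  if (config$bootstrap_reps == 0) return(point)
  m <- block_char_matrix(block)
  spec <- attr(block, "spec")
  level <- spec$level
  reps <- withr::with_seed(config$seed, {
    purrr::map(seq_len(config$bootstrap_reps), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      cb <- resampled_counts(mb, level)
      db <- cb / ncol(mb)
      ord <- order(rownames(db), method = "radix")
      t <- ape::nj(as.dist(db[ord, ord]))
      t$edge.length[t$edge.length < 0] <- 0
      if (length(config$outgroup) > 0) {
        t <- ape::root(t, outgroup = config$outgroup, resolve.root = TRUE)
      }
      t
    })
  })
  cl <- ape::prop.clades(point, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  point$node.label <- as.character(round(100 * cl / config$bootstrap_reps))
  point
}

resampled_counts <- function(m, level) {
  ok <- if (level == "aa") m != "X" else
    matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  counts <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      counts[i, j] <- counts[j, i] <- sum(m[i, use] != m[j, use])
    }
  }
  counts
}

newick_quote <- function(x) {
  needs <- grepl("[]['(),:; \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs], fixed = TRUE), "'")
  x
}

#' Serialize a tree to newick
#'
#' Branch lengths are written with `digits` significant digits and bootstrap
#' supports (when present) as internal-node labels. Labels containing
#' newick-reserved characters are single-quoted, so the string re-parses to
#' an isomorphic tree with [parse_newick()].
#'
#' @param tree An `ape::phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A single newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  blen <- tree$edge.length
  node_lab <- tree$node.label %||% rep("", tree$Nnode)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- newick_quote(tree$tip.label[node])
    } else {
      ch <- kids[[as.character(node)]]
      inner <- paste(vapply(ch, function(e) rec(tree$edge[e, 2], e),
                            character(1)), collapse = ",")
      lab <- node_lab[node - ntip]
      s <- paste0("(", inner, ")",
                  if (!is.na(lab) && nzchar(lab)) newick_quote(lab) else "")
    }
    if (!is.null(edge_idx) && !is.null(blen)) {
      s <- paste0(s, ":", fmt(blen[edge_idx]))
    }
    s
  }
  root <- ntip + 1L
  paste0(rec(root, NULL), ";")
}

#' Parse a newick string
#'
#' Thin wrapper around [ape::read.tree()] that also strips the single-quote
#' wrapping produced by [to_newick()] for labels with reserved characters.
#'
#' @param text A newick string.
#' @return An `ape::phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- ape::read.tree(text = text)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]), fixed = TRUE)
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}
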
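#' Pairwise p-distance with pairwise deletion of gaps
#'
#' For each pair of aligned sequences the distance is the proportion of
#' mismatching positions among columns that are ungapped in *both*
#' sequences (pairwise deletion). Works for protein or nucleotide
#' alignments; the gap symbol is `-` (`.`, `?`, `X`/`N` are treated as
#' ordinary characters and count as mismatches unless identical).
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (at least two).
#' @return A symmetric numeric matrix of p-distances with dimnames equal
#'   to the sequence ids.
#' @export
p_distance <- function(alignment) {
  check_alignment(alignment)
  n <- length(alignment)
  ids <- names(alignment)
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  gap <- mat == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        rlang::abort(paste0("no shared ungapped columns between '",
                            ids[i], "' and '", ids[j], "'"))
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / nc
    }
  }
  d
}

check_alignment <- function(alignment) {
  if (length(alignment) < 2L) rlang::abort("alignment needs >= 2 sequences")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    rlang::abort("alignment sequences must have unique names")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    rlang::abort("aligned sequences must all have the same length")
  }
  invisible(alignment)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); negative estimated
#' branch lengths are clamped to zero. The result is unrooted.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) rlang::abort("neighbor-joining needs >= 3 taxa")
  if (is.null(rownames(dm))) rlang::abort("distance matrix needs dimnames")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Builds the NJ p-distance tree on the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree on
#' each replicate, and records for every internal bipartition of the full
#' tree the percentage of replicates containing it (0-100, integer).
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical supports.
#' @return The full-data NJ tree with `node.label` set to integer support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  check_alignment(alignment)
  stopifnot(n_reps >= 1L)
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  full <- nj_tree(p_distance(alignment))
  L <- ncol(mat)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      nj_tree(p_distance(sub))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_reps))
  # first internal node is the (arbitrary) basal node of the unrooted tree
  support[1L] <- NA_integer_
  full$node.label <- ifelse(is.na(support), "", as.character(support))
  full
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. The
#' input must be unrooted; the output is strictly bifurcating.
#'
#' @param tree An unrooted [ape::phylo] tree with branch lengths.
#' @return A rooted, bifurcating [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 2L) {
    # a two-leaf tree is a single path; place the root halfway along it
    if (is.null(tree$edge.length)) rlang::abort("branch lengths required")
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, nrow(tree$edge))
    return(tree)
  }
  if (ape::is.rooted(tree)) {
    rlang::abort("tree is already rooted; unroot it first (ape::unroot)")
  }
  if (is.null(tree$edge.length)) rlang::abort("branch lengths required")
  if (all(tree$edge.length == 0)) {
    rlang::warn("all branch lengths zero; rooting on an arbitrary edge")
  }
  rooted <- phangorn::midpoint(tree)
  rooted <- ape::multi2di(rooted)
  rooted
}

#' Assign family groups from anchor leaves
#'
#' Each group is defined as the smallest clade (MRCA clade) containing all
#' of its anchor leaves in a rooted tree; every leaf falling inside exactly
#' one group clade receives that label, leaves in none are `"unassigned"`,
#' and overlapping (including nested) group clades are an error.
#'
#' @param tree A rooted [ape::phylo].
#' @param anchors Named list: group label -> character vector of leaf
#'   labels anchoring the group.
#' @return A tibble with columns `leaf` and `group`.
#' @export
assign_groups <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) rlang::abort("assign_groups needs a rooted tree")
  if (is.null(names(anchors)) || anyDuplicated(names(anchors))) {
    rlang::abort("anchors must be a uniquely named list")
  }
  missing <- setdiff(unlist(anchors), tree$tip.label)
  if (length(missing) > 0L) {
    rlang::abort(paste0("anchor leaves not in tree: ",
                        paste(missing, collapse = ", ")))
  }
  clades <- lapply(anchors, function(tips) {
    if (length(tips) == 1L) return(tips)
    node <- ape::getMRCA(tree, tips)
    ape::extract.clade(tree, node)$tip.label
  })
  for (i in seq_along(clades)) {
    for (j in seq_along(clades)) {
      if (i < j && length(intersect(clades[[i]], clades[[j]])) > 0L) {
        rlang::abort(paste0("group clades overlap: '", names(clades)[i],
                            "' and '", names(clades)[j],
                            "' share leaves (nested or conflicting anchors)"))
      }
    }
  }
  label <- setNames(rep("unassigned", length(tree$tip.label)), tree$tip.label)
  for (g in names(clades)) label[clades[[g]]] <- g
  tibble::tibble(leaf = names(label), group = unname(label))
}
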
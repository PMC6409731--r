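#' Duplication-loss reconciliation of a gene tree against a species tree
#'
#' Standard most-parsimonious LCA reconciliation with equal unit costs for
#' duplications and losses. Every gene-tree node is mapped to the LCA of
#' the species of its descendant genes; a node is a duplication iff its
#' image equals the image of at least one child. Losses are read off the
#' species-tree path skipped between a node's image and each child's image
#' and assigned to the species branch (identified by its child node) whose
#' subtree lost the copy. Ancestral copy numbers follow the recurrence
#' `count(child) = count(parent) + gains(child branch) - losses(child
#' branch)`, anchored at `count(root) = 1 + duplications mapped to the
#' species root`.
#'
#' @param gene_tree Rooted, bifurcating [ape::phylo] whose tips are genes.
#' @param species_tree Rooted, bifurcating [ape::phylo] whose tips are
#'   species.
#' @param species_map Named character vector mapping every gene-tree tip
#'   label to a species-tree tip label.
#' @return An object of class `reconciliation`: a list with `lca_map`
#'   (gene node -> species node, by internal indices and labels),
#'   `duplication_nodes`, `events` (tibble per species branch: gains,
#'   losses), `ancestral_count` (tibble per species node), and the input
#'   trees.
#' @export
lca_reconcile <- function(gene_tree, species_tree, species_map) {
  check_rooted_binary(gene_tree, "gene tree")
  check_rooted_binary(species_tree, "species tree")
  unmapped <- setdiff(gene_tree$tip.label, names(species_map))
  if (length(unmapped) > 0L) {
    rlang::abort(paste0("gene(s) missing from species map: ",
                        paste(unmapped, collapse = ", ")))
  }
  bad <- setdiff(unname(species_map[gene_tree$tip.label]),
                 species_tree$tip.label)
  if (length(bad) > 0L) {
    rlang::abort(paste0("species not in species tree: ",
                        paste(bad, collapse = ", ")))
  }

  st <- species_tree_index(species_tree)
  ng_tip <- length(gene_tree$tip.label)
  ng_all <- ng_tip + gene_tree$Nnode
  g_children <- children_list(gene_tree)

  # postorder LCA mapping: image of a tip is its species; image of an
  # internal node is the species-tree LCA of its children's images
  m <- integer(ng_all)
  for (i in seq_len(ng_tip)) {
    m[i] <- match(species_map[[gene_tree$tip.label[i]]],
                  species_tree$tip.label)
  }
  is_dup <- logical(ng_all)
  gains <- integer(st$n_all)   # per species node: dups mapped there
  losses <- integer(st$n_all)  # per species branch (child node id)

  for (v in postorder_nodes(gene_tree)) {
    if (v <= ng_tip) next
    ch <- g_children[[v]]
    m[v] <- st$lca(m[ch[1]], m[ch[2]])
    is_dup[v] <- m[v] == m[ch[1]] || m[v] == m[ch[2]]
    gains[m[v]] <- gains[m[v]] + as.integer(is_dup[v])
    for (c in ch) {
      # walk the species path from image(c) up toward image(v); every
      # pass-through species node implies a loss in its other child
      top <- if (is_dup[v]) m[v] else NA_integer_
      x <- m[c]
      repeat {
        p <- st$parent[x]
        if (is.na(p)) break
        if (!is_dup[v] && p == m[v]) break
        if (is_dup[v] && x == m[v]) break
        # lineage passed through p and continued into x: sibling lost
        sib <- setdiff(st$children[[p]], x)
        losses[sib] <- losses[sib] + 1L
        x <- p
      }
      if (is_dup[v] && m[c] != m[v]) {
        # the walk above stops when x reaches m(v); nothing extra needed
      }
    }
  }

  anc <- integer(st$n_all)
  root_s <- st$root
  anc[root_s] <- 1L + gains[root_s]
  for (s in st$preorder) {
    p <- st$parent[s]
    if (is.na(p)) next
    anc[s] <- anc[p] + gains[s] - losses[s]
  }

  s_label <- node_labels(species_tree)
  g_label <- node_labels(gene_tree)
  events <- tibble::tibble(
    species_node = s_label,
    node_id = seq_len(st$n_all),
    is_leaf = seq_len(st$n_all) <= length(species_tree$tip.label),
    gains = gains,
    losses = losses,
    copies = anc
  )
  structure(list(
    lca_map = tibble::tibble(
      gene_node = g_label,
      gene_node_id = seq_len(ng_all),
      species_node = s_label[m],
      species_node_id = m,
      is_duplication = is_dup
    ),
    duplication_nodes = which(is_dup),
    events = events,
    n_duplications = sum(is_dup),
    n_losses = sum(losses),
    gene_tree = gene_tree,
    species_tree = species_tree,
    species_map = species_map
  ), class = "reconciliation")
}

check_rooted_binary <- function(tree, what) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    rlang::abort(paste0(what, " must be rooted"))
  }
  if (!ape::is.binary(tree)) {
    rlang::abort(paste0(what, " contains multifurcations; resolve them ",
                        "(e.g. ape::multi2di) before reconciling"))
  }
  invisible(tree)
}

# indexing helpers shared by reconciliation and the simulators ------------

children_list <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

parent_vec <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n_all)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# tips (any order) followed by internal nodes child-before-parent
postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  # a node's last appearance as a parent comes after every edge in its
  # subtree, so ordering internals by last appearance is a postorder
  pos <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  for (e in seq_len(nrow(tr$edge))) pos[tr$edge[e, 1]] <- e
  internals <- which(!is.na(pos))
  c(seq_len(length(tree$tip.label)), internals[order(pos[internals])])
}

node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  lab <- c(tree$tip.label,
           if (!is.null(tree$node.label) &&
               length(tree$node.label) == tree$Nnode &&
               all(nzchar(tree$node.label))) tree$node.label
           else paste0("node", ntip + seq_len(tree$Nnode)))
  lab
}

species_tree_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  n_all <- ntip + species_tree$Nnode
  par <- parent_vec(species_tree)
  ch <- children_list(species_tree)
  root <- which(is.na(par))
  depth <- integer(n_all)
  # preorder: root first, then children
  pre <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    x <- stack[[1L]]
    stack <- stack[-1L]
    pre <- c(pre, x)
    depth[ch[[x]]] <- depth[x] + 1L
    stack <- c(ch[[x]], stack)
  }
  anc_of <- function(x) {
    out <- x
    while (!is.na(par[x])) { x <- par[x]; out <- c(out, x) }
    out
  }
  lca <- function(a, b) {
    aa <- anc_of(a)
    bb <- anc_of(b)
    hit <- aa[aa %in% bb]
    hit[1L]
  }
  list(parent = par, children = ch, root = root, depth = depth,
       preorder = pre, lca = lca, n_all = n_all)
}

#' Per-branch census of gains, losses and copy numbers
#'
#' @param recon A `reconciliation` object from [lca_reconcile()].
#' @return Tibble with one row per species-tree branch/node: `species_node`,
#'   `gains`, `losses`, `copies` (copy number after events on the branch),
#'   plus the parent's copy number for bookkeeping.
#' @export
family_census <- function(recon) {
  stopifnot(inherits(recon, "reconciliation"))
  ev <- recon$events
  par <- parent_vec(recon$species_tree)
  ev$parent_copies <- ifelse(is.na(par[ev$node_id]), NA_integer_,
                             ev$copies[match(par[ev$node_id], ev$node_id)])
  ev
}

#' @export
tidy.reconciliation <- function(x, ...) family_census(x)

#' @export
glance.reconciliation <- function(x, ...) {
  tibble::tibble(
    n_duplications = x$n_duplications,
    n_losses = x$n_losses,
    total_cost = x$n_duplications + x$n_losses,
    root_copies = x$events$copies[x$events$node_id ==
                                    species_tree_index(x$species_tree)$root],
    n_genes = length(x$gene_tree$tip.label)
  )
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Duplication-loss reconciliation\n")
  cat("  genes:", length(x$gene_tree$tip.label),
      " species:", length(x$species_tree$tip.label), "\n")
  cat("  duplications:", x$n_duplications,
      " losses:", x$n_losses, "\n")
  invisible(x)
}
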
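# Repeatable simulation studies quantifying how well each stage of the
# pipeline recovers known ground truth. These back the package's
# validation claims; each is a pure function of its seed.

#' NJ topology recovery on additive distance matrices
#'
#' Neighbor-joining is consistent on additive matrices; this study draws
#' random trees, computes their exact patristic matrices, and checks that
#' [nj_tree()] returns the generating unrooted topology.
#'
#' @param n_reps Number of random matrices.
#' @param leaf_range Candidate leaf counts.
#' @param seed Integer seed.
#' @return Tibble with one row per replicate (`n_leaves`, `recovered`).
#' @export
nj_recovery_study <- function(n_reps = 200L, leaf_range = 5:8, seed = 1L) {
  sizes <- withr::with_seed(stream_seed(seed, "nj_study"),
                            sample(leaf_range, n_reps, replace = TRUE))
  purrr::map_dfr(seq_len(n_reps), function(i) {
    s <- simulate_additive_distances(sizes[i], seed = seed * 1000L + i)
    tr <- nj_tree(s$dm)
    tibble::tibble(rep = i, n_leaves = sizes[i],
                   recovered = ape::dist.topo(ape::unroot(tr),
                                              s$tree)[1] == 0)
  })
}

#' Duplication-type recovery on planted genome layouts
#'
#' @param n_reps Number of planted layouts.
#' @param seed Integer seed.
#' @return Tibble with one row per planted pair (`rep`, `true_type`,
#'   `called_type`, `correct`).
#' @export
layout_recovery_study <- function(n_reps = 50L, seed = 1L) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    lay <- simulate_genome_layout(seed * 1000L + i)
    called <- vapply(seq_len(nrow(lay$truth)), function(j) {
      classify_pair(lay$truth$gene_a[j], lay$truth$gene_b[j],
                    lay$gene_table, lay$blocks)
    }, character(1))
    tibble::tibble(rep = i, gene_a = lay$truth$gene_a,
                   true_type = lay$truth$true_type, called_type = called,
                   correct = called == lay$truth$true_type,
                   boundary = lay$truth$gene_a == "famB1")
  })
}

#' Reconciliation recovery against simulated birth-death histories
#'
#' Simulates families at the given rates, reconciles the pruned gene tree
#' against the species tree, and compares inferred gains/losses with the
#' simulator's observable event log restricted to the species subtree
#' spanned by the surviving genes (events outside that subtree are not
#' recoverable from the gene tree alone). Families that went extinct or
#' survive as a single gene carry no reconciliation signal and are
#' reported with `informative = FALSE`.
#'
#' @param n_reps Number of simulated families.
#' @param species_tree Rooted species tree (default: 4 balanced species
#'   with unit branches).
#' @param birth_rate,death_rate Birth-death rates per unit branch length.
#' @param seed Integer seed.
#' @return Tibble per replicate: observed and inferred gain/loss counts,
#'   `match` (both counts equal) and `parsimony_gap` (observable cost
#'   minus inferred minimum cost; > 0 means the true history was not most
#'   parsimonious, so exact recovery is impossible in principle).
#' @export
reconciliation_recovery_study <- function(n_reps = 100L,
                                          species_tree = NULL,
                                          birth_rate = 0.1,
                                          death_rate = 0.05,
                                          seed = 1L) {
  species_tree <- species_tree %||%
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st <- species_tree_index(species_tree)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    fam <- simulate_family(species_tree, birth_rate, death_rate,
                           seed = seed * 1000L + i)
    if (fam$extinct || isTRUE(fam$single_copy)) {
      return(tibble::tibble(rep = i, informative = FALSE,
                            obs_gains = NA_integer_,
                            obs_losses = NA_integer_,
                            inf_gains = NA_integer_,
                            inf_losses = NA_integer_,
                            match = NA, parsimony_gap = NA_real_))
    }
    recon <- lca_reconcile(fam$gene_tree, species_tree, fam$species_map)
    ntipg <- length(fam$gene_tree$tip.label)
    root_img <- recon$lca_map$species_node_id[
      recon$lca_map$gene_node_id == ntipg + 1L]
    # species branches at/below the gene-root image are recoverable
    below <- which(vapply(seq_len(st$n_all), function(x) {
      while (!is.na(st$parent[x])) {
        if (x == root_img) return(TRUE)
        x <- st$parent[x]
      }
      x == root_img
    }, logical(1)))
    obs <- fam$observable[fam$observable$branch %in%
                            node_labels(species_tree)[below], ]
    strict <- setdiff(below, root_img)
    obs_l <- fam$observable[fam$observable$branch %in%
                              node_labels(species_tree)[strict], ]
    obs_gains <- sum(obs$gains)
    obs_losses <- sum(obs_l$losses)
    inf_gains <- recon$n_duplications
    inf_losses <- recon$n_losses
    tibble::tibble(rep = i, informative = TRUE,
                   obs_gains = obs_gains, obs_losses = obs_losses,
                   inf_gains = inf_gains, inf_losses = inf_losses,
                   match = obs_gains == inf_gains &&
                     obs_losses == inf_losses,
                   parsimony_gap = (obs_gains + obs_losses) -
                     (inf_gains + inf_losses))
  })
}

#' Positive-site recovery under the M8 site model
#'
#' Simulates codon alignments under a discretized M8 mixture (beta part
#' p0 at beta(p, q), point mass 1 - p0 at `ws`), fits M8, and reports the
#' fraction of truly positively selected sites (`omega = ws`) whose
#' posterior mean exceeds 1, together with the fitted `ws` and `p0`.
#'
#' @param n_reps Replicates (one tree + alignment + fit each).
#' @param n_taxa Taxa per replicate tree.
#' @param n_codons Alignment length in codons.
#' @param p0,p,q,ws True M8 parameters of the generator.
#' @param K Discrete classes.
#' @param seed Integer seed.
#' @return Tibble per replicate: `recall` (called fraction of true
#'   positive sites), `n_true_positive`, fitted `ws`, `p0`, `logL`.
#' @export
selection_recovery_study <- function(n_reps = 20L, n_taxa = 12L,
                                     n_codons = 300L, p0 = 0.9, p = 0.5,
                                     q = 1.5, ws = 4, K = 8L, seed = 1L) {
  cats <- discretize_omega("M8", list(p0 = p0, p = p, q = q, ws = ws), K)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    tr <- withr::with_seed(stream_seed(seed * 1000L + i, "sel_tree"),
                           ape::rtree(n_taxa,
                                      br = function(n) runif(n, 0.1, 0.5)))
    sim <- simulate_codon_alignment(tr, cats, n_codons,
                                    seed = seed * 1000L + i)
    fit <- fit_site_model(sim$alignment, tr, model = "M8", K = K,
                          codon_freqs = "uniform")
    post <- posterior_site_omega(fit)
    pos <- which(sim$site_omega == ws)
    tibble::tibble(rep = i,
                   recall = mean(post$called[pos]),
                   n_true_positive = length(pos),
                   false_call_rate = mean(post$called[sim$site_omega < 1]),
                   ws_hat = fit$params$ws, p0_hat = fit$params$p0,
                   logL = fit$logL, convergence = fit$convergence)
  })
}

#' Fold-change recovery from noisy qPCR tables
#'
#' @param n_reps Number of simulated CT tables.
#' @param fold_changes Planted fold changes.
#' @param sigma Gaussian CT noise.
#' @param seed Integer seed.
#' @return Tibble per replicate and gene: planted and estimated fold.
#' @export
ddct_recovery_study <- function(n_reps = 50L,
                                fold_changes = c(0.25, 1, 4),
                                sigma = 0.1, seed = 1L) {
  genes <- paste0("g", seq_along(fold_changes))
  purrr::map_dfr(seq_len(n_reps), function(i) {
    sim <- simulate_expression(seed * 1000L + i, genes = genes,
                               fold_changes = fold_changes, sigma = sigma)
    dd <- ddct_table(sim$ct, reference_gene = "actin", control = "control")
    tibble::tibble(rep = i, gene = genes,
                   fold_true = fold_changes,
                   fold_est = dd$rel_expr[match(genes, dd$gene)])
  })
}
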
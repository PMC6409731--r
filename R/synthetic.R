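# Synthetic-data generators with recorded ground truth. Every generator
# is a pure function of (parameters, seed); each draws from its own
# stream derived from (seed, stream name) so adding one generator never
# perturbs another.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate a gene family by birth-death along a species tree
#'
#' A single ancestral gene enters the root of the species tree; along
#' every species branch each gene lineage duplicates at rate `birth_rate`
#' and is lost at rate `death_rate` (exponential waiting times, exact
#' event log); at speciation nodes every lineage splits into both
#' daughter species. Extinct lineages are pruned from the returned gene
#' tree. Besides the full event log the generator records the *observable*
#' history: duplications with surviving descendants on both sides, and
#' one loss per maximal extinct subtree hanging off a surviving
#' speciation (exactly what duplication-loss reconciliation of the pruned
#' tree can recover).
#'
#' @param species_tree Rooted bifurcating [ape::phylo] with branch
#'   lengths.
#' @param birth_rate,death_rate Events per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return List: `gene_tree` ([ape::phylo] or `NULL` if the family went
#'   extinct), `species_map` (named vector tip -> species), `extinct`
#'   (flag), `events` (full log tibble), `observable` (tibble of
#'   observable gains/losses per species branch), `n_observable_gains`,
#'   `n_observable_losses`, `extant_counts` (per species).
#' @export
simulate_family <- function(species_tree, birth_rate, death_rate, seed) {
  stopifnot(birth_rate >= 0, death_rate >= 0)
  check_rooted_binary(species_tree, "species tree")
  par <- parent_vec(species_tree)
  ch <- children_list(species_tree)
  ntip <- length(species_tree$tip.label)
  root <- which(is.na(par))
  # absolute time of each species node (root = 0)
  node_time <- numeric(ntip + species_tree$Nnode)
  elen <- numeric(ntip + species_tree$Nnode)
  elen[species_tree$edge[, 2]] <- species_tree$edge.length
  for (s in species_tree_index(species_tree)$preorder) {
    if (!is.na(par[s])) node_time[s] <- node_time[par[s]] + elen[s]
  }
  s_label <- node_labels(species_tree)

  withr::with_seed(stream_seed(seed, "family"), {
    counter <- new.env()
    counter$n <- setNames(rep(0L, ntip), species_tree$tip.label)
    events <- list()
    total <- birth_rate + death_rate
    evolve <- local({
      function(sb, t_now) {
        t_end <- node_time[sb]
        wait <- if (total > 0) rexp(1, total) else Inf
        if (t_now + wait < t_end) {
          te <- t_now + wait
          if (runif(1) < birth_rate / total) {
            events[[length(events) + 1L]] <<- list(type = "duplication",
                                                   branch = s_label[sb],
                                                   branch_id = sb, time = te)
            kids <- list(evolve(sb, te), evolve(sb, te))
            list(kind = "dup", sp_branch = sb, time = te, children = kids)
          } else {
            events[[length(events) + 1L]] <<- list(type = "loss",
                                                   branch = s_label[sb],
                                                   branch_id = sb, time = te)
            list(kind = "dead", sp_branch = sb, time = te, children = list())
          }
        } else if (sb <= ntip) {
          sp <- species_tree$tip.label[sb]
          counter$n[sp] <- counter$n[sp] + 1L
          list(kind = "extant", sp_branch = sb, time = t_end,
               name = paste0(sp, "_g", counter$n[sp]), species = sp,
               children = list())
        } else {
          kids <- lapply(ch[[sb]], evolve, t_now = t_end)
          list(kind = "spec", sp_branch = sb, time = t_end, children = kids)
        }
      }
    })
    root_node <- list(kind = "spec", sp_branch = root, time = 0,
                      children = lapply(ch[[root]], evolve, t_now = 0))
    finish_family(root_node, events, s_label, species_tree, counter$n)
  })
}

finish_family <- function(root_node, events, s_label, species_tree, counts) {
  mark <- function(node) {
    if (node$kind == "extant") { node$alive <- TRUE; return(node) }
    if (node$kind == "dead") { node$alive <- FALSE; return(node) }
    node$children <- lapply(node$children, mark)
    node$alive <- any(vapply(node$children, `[[`, logical(1), "alive"))
    node
  }
  root_node <- mark(root_node)

  gains <- losses <- integer(length(s_label))
  walk <- function(node) {
    if (node$kind == "extant") return(invisible())
    alive_kids <- vapply(node$children, `[[`, logical(1), "alive")
    if (node$kind == "dup" && all(alive_kids)) {
      gains[node$sp_branch] <<- gains[node$sp_branch] + 1L
    }
    if (node$kind == "spec") {
      for (k in which(!alive_kids)) {
        dead_branch <- node$children[[k]]$sp_branch
        losses[dead_branch] <<- losses[dead_branch] + 1L
      }
    }
    for (k in which(alive_kids)) walk(node$children[[k]])
    invisible()
  }

  events_tb <- if (length(events) > 0L) {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  } else {
    tibble::tibble(type = character(), branch = character(),
                   branch_id = integer(), time = numeric())
  }

  if (!root_node$alive) {
    return(list(gene_tree = NULL, species_map = character(0),
                extinct = TRUE, events = events_tb,
                observable = tibble::tibble(branch = s_label,
                                            gains = 0L, losses = 0L),
                n_observable_gains = 0L, n_observable_losses = 0L,
                extant_counts = counts))
  }
  walk(root_node)

  to_newick <- function(node, parent_time) {
    if (node$kind == "extant") {
      return(paste0(node$name, ":", format(node$time - parent_time,
                                           digits = 10)))
    }
    alive_kids <- Filter(function(k) k$alive, node$children)
    if (length(alive_kids) == 1L) {
      return(to_newick(alive_kids[[1L]], parent_time))
    }
    inner <- vapply(alive_kids, to_newick, character(1),
                    parent_time = node$time)
    paste0("(", paste(inner, collapse = ","), "):",
           format(node$time - parent_time, digits = 10))
  }
  # root: strip the trailing branch length
  nwk <- to_newick(root_node, 0)
  nwk <- sub(":[0-9.eE+-]+$", ";", nwk)
  if (!grepl(";$", nwk)) nwk <- paste0(nwk, ";")
  single <- !grepl("^\\(", nwk)
  gene_tree <- if (single) NULL else ape::read.tree(text = nwk)
  tips <- if (single) sub(":.*", "", sub(";$", "", nwk)) else gene_tree$tip.label
  species_map <- setNames(sub("_g[0-9]+$", "", tips), tips)
  list(gene_tree = gene_tree, species_map = species_map,
       extinct = FALSE,
       single_copy = single,
       events = events_tb,
       observable = tibble::tibble(branch = s_label, gains = gains,
                                   losses = losses),
       n_observable_gains = sum(gains), n_observable_losses = sum(losses),
       extant_counts = counts)
}

#' Simulate a codon alignment with site-specific omega
#'
#' Each codon site draws its omega from a finite mixture and evolves along
#' the tree under the GY94-style process (the same rate convention the
#' fitter uses: classes jointly rescaled to unit mean rate), starting from
#' a root codon drawn from the equilibrium frequencies.
#'
#' @param tree [ape::phylo] with branch lengths in expected substitutions
#'   per codon.
#' @param mixture Tibble/data frame with columns `omega` and `weight`
#'   (weights sum to 1).
#' @param L Number of codon sites.
#' @param seed Integer seed.
#' @param kappa Transition/transversion ratio.
#' @param codon_freqs Equilibrium codon frequencies (default uniform over
#'   the 61 sense codons).
#' @return List: `alignment` (named character vector), `site_class`
#'   (integer vector of true mixture classes), `site_omega` (true omega
#'   per site).
#' @export
simulate_codon_alignment <- function(tree, mixture, L, seed, kappa = 2,
                                     codon_freqs = NULL) {
  stopifnot(L >= 1)
  if (abs(sum(mixture$weight) - 1) > 1e-8) {
    rlang::abort("mixture weights must sum to 1")
  }
  pi <- codon_freqs %||% uniform_codon_freqs()
  cm <- codon_machinery()
  Qs <- lapply(mixture$omega, function(w) gy94_Q(kappa, w, pi))
  mean_rate <- sum(mixture$weight * vapply(Qs, `[[`, numeric(1), "rate"))
  ess <- lapply(Qs, function(q) eigen_system(q$Q / mean_rate, pi))
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  ntip <- length(tr$tip.label)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]

  withr::with_seed(stream_seed(seed, "codon_alignment"), {
    cls <- sample.int(nrow(mixture), L, replace = TRUE,
                      prob = mixture$weight)
    state <- matrix(NA_integer_, ntip + tr$Nnode, L)
    state[root, ] <- sample.int(cm$n, L, replace = TRUE, prob = pi)
    P_cache <- vector("list", nrow(mixture))
    for (k in seq_len(nrow(mixture))) {
      P_cache[[k]] <- lapply(tr$edge.length, function(t) {
        P <- prob_matrix(ess[[k]], max(t, 0))
        P / rowSums(P)
      })
    }
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
      for (k in unique(cls)) {
        sites <- which(cls == k)
        P <- P_cache[[k]][[e]]
        for (s in sites) {
          state[c, s] <- sample.int(cm$n, 1L, prob = P[state[p, s], ])
        }
      }
    }
    aln <- vapply(seq_len(ntip), function(i) {
      paste(cm$codons[state[i, ]], collapse = "")
    }, character(1))
    names(aln) <- tr$tip.label
    list(alignment = aln, site_class = cls,
         site_omega = mixture$omega[cls])
  })
}

#' Simulate a genome layout with planted duplication types
#'
#' Chromosomes are populated with background genes; a tandem array of
#' family genes (consecutive members separated by 0-4 intervening genes)
#' is planted on one chromosome; a segmental block containing family
#' genes is copied to a second chromosome and registered in the synteny
#' block table; one family gene is relocated to a third chromosome with
#' no block record (transposition); optionally a same-chromosome pair
#' separated by exactly five intervening genes is planted as a boundary
#' case (truth: not tandem).
#'
#' @param seed Integer seed.
#' @param n_background Background genes per chromosome.
#' @param tandem_size Number of genes in the tandem array (>= 2).
#' @param block_genes Family genes inside the segmental block (>= 1).
#' @param boundary_pair Plant the exactly-five-intervening boundary pair?
#' @param species Species label.
#' @return List: `gene_table`, `blocks`, `truth` (tibble `gene_a, gene_b,
#'   true_type`).
#' @export
simulate_genome_layout <- function(seed, n_background = 60L,
                                   tandem_size = 4L, block_genes = 2L,
                                   boundary_pair = TRUE,
                                   species = "synsp") {
  stopifnot(tandem_size >= 2L, block_genes >= 1L, n_background >= 30L)
  withr::with_seed(stream_seed(seed, "genome_layout"), {
    chr_genes <- list(
      chr1 = paste0("bg1_", seq_len(n_background)),
      chr2 = paste0("bg2_", seq_len(n_background)),
      chr3 = paste0("bg3_", seq_len(n_background))
    )
    truth <- list()
    # tandem array on chr1: successive members 0-4 intervening genes apart
    fam_tandem <- paste0("famT", seq_len(tandem_size))
    pos <- 5L
    g <- chr_genes$chr1
    for (i in seq_along(fam_tandem)) {
      g <- append(g, fam_tandem[i], after = pos)
      if (i < length(fam_tandem)) {
        gap <- sample(0:4, 1L)
        pos <- pos + 1L + gap
      }
    }
    for (i in seq_len(tandem_size - 1L)) {
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_a = fam_tandem[i], gene_b = fam_tandem[i + 1L],
        true_type = "tandem")
    }
    chr_genes$chr1 <- g
    # segmental block: a run on chr1 (family genes inside) copied to chr2
    fam_block <- paste0("famS", seq_len(block_genes))
    start <- length(chr_genes$chr1) - 15L
    run <- c(fam_block,
             chr_genes$chr1[start:(start + 5L)])
    chr_genes$chr1 <- append(chr_genes$chr1, fam_block, after = start - 1L)
    copies <- paste0(run, "_cp")
    insert_at <- 10L
    chr_genes$chr2 <- append(chr_genes$chr2, copies, after = insert_at)
    blocks <- tibble::tibble(
      block_id = "blk1",
      species_a = species, gene_a = run,
      species_b = species, gene_b = copies)
    for (fg in fam_block) {
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_a = fg, gene_b = paste0(fg, "_cp"), true_type = "segmental")
    }
    # transposition: family gene on chr1 with a copy on chr3, no block
    chr_genes$chr1 <- append(chr_genes$chr1, "famX1", after = 2L)
    chr_genes$chr3 <- append(chr_genes$chr3, "famX1_cp", after = 20L)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      gene_a = "famX1", gene_b = "famX1_cp", true_type = "transposition")
    # boundary case: exactly 5 intervening genes on chr3, no block
    if (boundary_pair) {
      n3 <- length(chr_genes$chr3)
      chr_genes$chr3 <- append(chr_genes$chr3, "famB1", after = n3 - 10L)
      chr_genes$chr3 <- append(chr_genes$chr3, "famB2", after = n3 - 10L + 6L)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_a = "famB1", gene_b = "famB2", true_type = "transposition")
    }
    gene_table <- dplyr::bind_rows(lapply(names(chr_genes), function(cn) {
      ids <- chr_genes[[cn]]
      starts <- seq_along(ids) * 1000L
      tibble::tibble(gene_id = ids, species = species, chromosome = cn,
                     strand = sample(c("+", "-"), length(ids),
                                     replace = TRUE),
                     start = starts, end = starts + 500L)
    }))
    list(gene_table = assign_order_index(gene_table), blocks = blocks,
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate FPKM and qPCR CT tables with known fold changes
#'
#' CT values follow `baseline - log2(expression) + N(0, sigma)`; the
#' reference gene's expression is constant across conditions, so the
#' Livak 2^-ddCT estimate recovers the planted fold change exactly when
#' `sigma = 0`.
#'
#' @param seed Integer seed.
#' @param genes Gene ids (fold changes planted per gene).
#' @param fold_changes Positive per-gene treatment/control fold changes.
#' @param n_replicates CT replicates per (gene, condition).
#' @param sigma Gaussian CT noise standard deviation.
#' @param reference_gene Name of the endogenous control.
#' @param tissues Column names of the FPKM table.
#' @return List: `ct` (tibble gene/condition/replicate/ct), `fpkm`
#'   (genes x tissues matrix), `truth` (tibble gene, fold_change).
#' @export
simulate_expression <- function(seed, genes = paste0("gene", 1:6),
                                fold_changes = c(1, 0.25, 0.5, 2, 4, 8),
                                n_replicates = 3L, sigma = 0.1,
                                reference_gene = "actin",
                                tissues = c("root", "stem", "leaf",
                                            "flower", "nodule")) {
  stopifnot(length(genes) == length(fold_changes), all(fold_changes > 0))
  withr::with_seed(stream_seed(seed, "expression"), {
    base_expr <- setNames(2^runif(length(genes), 2, 8), genes)
    ct_rows <- list()
    add_ct <- function(gene, cond, expr) {
      ct_rows[[length(ct_rows) + 1L]] <<- tibble::tibble(
        gene = gene, condition = cond,
        replicate = seq_len(n_replicates),
        ct = 30 - log2(expr) + rnorm(n_replicates, 0, sigma))
    }
    for (i in seq_along(genes)) {
      add_ct(genes[i], "control", base_expr[i])
      add_ct(genes[i], "treatment", base_expr[i] * fold_changes[i])
    }
    add_ct(reference_gene, "control", 2^6)
    add_ct(reference_gene, "treatment", 2^6)
    fpkm <- matrix(stats::rlnorm(length(genes) * length(tissues),
                                 meanlog = 2, sdlog = 1.2),
                   nrow = length(genes),
                   dimnames = list(genes, tissues))
    list(ct = dplyr::bind_rows(ct_rows), fpkm = fpkm,
         truth = tibble::tibble(gene = genes, fold_change = fold_changes))
  })
}

#' Simulate a paralog pair with a planted retained intron
#'
#' Gene A carries `n_introns` phase-0 introns; gene B is an identical
#' paralog except that one of A's introns (random sense codons, in frame)
#' is retained in B's mature transcript. Returns the two gene models, the
#' protein sequences, the (trivially constructed) protein alignment, and
#' the planted event coordinates.
#'
#' @param seed Integer seed.
#' @param n_codons Protein length of the spliced form.
#' @param n_introns Number of introns in gene A (>= 1).
#' @param retained_codons Length of the retained segment in codons.
#' @return List: `model_a`, `model_b`, `alignment`, `truth` (tibble with
#'   the retained intron index and alignment coordinates).
#' @export
simulate_retention_pair <- function(seed, n_codons = 120L, n_introns = 2L,
                                    retained_codons = 15L) {
  stopifnot(n_introns >= 1L, retained_codons >= 2L, n_codons >= 30L)
  cm <- codon_machinery()
  withr::with_seed(stream_seed(seed, "retention"), {
    no_met_stop <- setdiff(cm$codons, c("ATG"))
    cds_codons <- c("ATG", sample(no_met_stop, n_codons - 1L, replace = TRUE))
    ins_codons <- sample(no_met_stop, retained_codons, replace = TRUE)
    # intron boundaries at codon multiples (phase 0), spread evenly
    cut_after <- round(seq_len(n_introns) * n_codons / (n_introns + 1L)) * 3L
    retained_idx <- sample.int(n_introns, 1L)
    # genomic layout of gene A (+ strand): exon pieces split by introns
    intron_len <- retained_codons * 3L
    seg_bounds <- c(0L, cut_after, n_codons * 3L)
    pos <- 1000L
    cds_a <- list(); introns_a <- list()
    for (i in seq_len(length(seg_bounds) - 1L)) {
      seg_len <- seg_bounds[i + 1L] - seg_bounds[i]
      cds_a[[i]] <- data.frame(start = pos, end = pos + seg_len - 1L)
      pos <- pos + seg_len
      if (i < length(seg_bounds) - 1L) {
        introns_a[[i]] <- data.frame(start = pos, end = pos + intron_len - 1L)
        pos <- pos + intron_len
      }
    }
    cds_a <- do.call(rbind, cds_a)
    model_a <- gene_model("geneA", "+", exons = cds_a, cds = cds_a)
    # gene B: same structure but the retained intron is part of the CDS
    cds_b <- list()
    for (i in seq_len(nrow(cds_a))) {
      seg <- cds_a[i, ]
      if (i == retained_idx) {
        # merge this CDS piece with the following intron and next piece
        nxt <- cds_a[i + 1L, ]
        cds_b[[length(cds_b) + 1L]] <- data.frame(start = seg$start,
                                                  end = nxt$end)
      } else if (i != retained_idx + 1L) {
        cds_b[[length(cds_b) + 1L]] <- seg
      }
    }
    model_b <- gene_model("geneB", "+", exons = do.call(rbind, cds_b),
                          cds = do.call(rbind, cds_b))
    translate1 <- function(codons) {
      paste(codon_machinery()$aa[match(codons, cm$codons)], collapse = "")
    }
    prot_a <- translate1(cds_codons)
    cut_codon <- cut_after[retained_idx] / 3L
    prot_b <- translate1(c(cds_codons[seq_len(cut_codon)], ins_codons,
                           cds_codons[(cut_codon + 1L):n_codons]))
    aln_a <- paste0(substr(prot_a, 1, cut_codon),
                    strrep("-", retained_codons),
                    substr(prot_a, cut_codon + 1L, n_codons))
    alignment <- c(geneA = aln_a, geneB = prot_b)
    list(model_a = model_a, model_b = model_b, alignment = alignment,
         truth = tibble::tibble(retained_in = "geneB",
                                intron_index = retained_idx,
                                aln_start = cut_codon + 1L,
                                aln_end = cut_codon + retained_codons,
                                codons_retained = retained_codons))
  })
}

#' Random additive distance matrix from a random tree
#'
#' Draws a random bifurcating tree with strictly positive branch lengths
#' and returns its exact patristic distance matrix (which is additive by
#' construction) together with the generating topology.
#'
#' @param n_leaves Number of leaves (>= 4).
#' @param seed Integer seed.
#' @return List: `tree` (the generating tree, unrooted) and `dm` (the
#'   additive distance matrix).
#' @export
simulate_additive_distances <- function(n_leaves, seed) {
  stopifnot(n_leaves >= 4L)
  withr::with_seed(stream_seed(seed, "additive"), {
    tr <- ape::rtree(n_leaves, br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(tr)
    list(tree = ape::unroot(tr), dm = dm)
  })
}
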
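# Independent oracles used by the unit and acceptance tests. These are
# deliberately separate implementations (brute force / dynamic programs
# over all mappings) from the package code paths they check.

# --- exhaustive duplication-loss reconciliation ------------------------

# Minimum (duplications + losses) over ALL valid gene->species mappings,
# by dynamic programming over every candidate image of every node
# (equivalent to enumerating all mappings). Ties broken toward fewer
# duplications. Returns list(total, dups, losses).
recon_oracle <- function(gene_tree, species_tree, species_map) {
  st <- famevol:::species_tree_index(species_tree)
  n_s <- st$n_all
  par <- st$parent
  depth <- st$depth
  anc_of <- function(s) {
    out <- s
    while (!is.na(par[s])) { s <- par[s]; out <- c(out, s) }
    out
  }
  is_anc <- matrix(FALSE, n_s, n_s)
  for (d in seq_len(n_s)) is_anc[anc_of(d), d] <- TRUE
  ntip <- length(gene_tree$tip.label)
  ch <- famevol:::children_list(gene_tree)
  post <- famevol:::postorder_nodes(gene_tree)
  INF <- 1e9
  n_g <- ntip + gene_tree$Nnode
  cost <- matrix(INF, n_g, n_s)
  dcnt <- matrix(INF, n_g, n_s)
  for (v in post) {
    if (v <= ntip) {
      s0 <- match(species_map[[gene_tree$tip.label[v]]],
                  species_tree$tip.label)
      cost[v, s0] <- 0
      dcnt[v, s0] <- 0
      next
    }
    c1 <- ch[[v]][1]; c2 <- ch[[v]][2]
    for (s in seq_len(n_s)) {
      best <- INF; bestd <- INF
      for (s1 in which(cost[c1, ] < INF & is_anc[s, ])) {
        if (!is_anc[s, s1]) next
        for (s2 in which(cost[c2, ] < INF)) {
          if (!is_anc[s, s2]) next
          l12 <- st$lca(s1, s2)
          dup <- (s != l12) || (s1 == s) || (s2 == s)
          loss <- (depth[s1] - depth[s]) + (depth[s2] - depth[s]) -
            (if (dup) 0L else 2L)
          tot <- as.numeric(dup) + loss + cost[c1, s1] + cost[c2, s2]
          dd <- as.numeric(dup) + dcnt[c1, s1] + dcnt[c2, s2]
          if (tot < best || (tot == best && dd < bestd)) {
            best <- tot; bestd <- dd
          }
        }
      }
      cost[v, s] <- best
      dcnt[v, s] <- bestd
    }
  }
  root <- post[length(post)]
  s_star <- which.min(cost[root, ])
  list(total = cost[root, s_star], dups = dcnt[root, s_star],
       losses = cost[root, s_star] - dcnt[root, s_star])
}

# literal enumeration over every mapping combination (tiny trees only);
# used to validate the DP oracle itself
recon_oracle_literal <- function(gene_tree, species_tree, species_map) {
  st <- famevol:::species_tree_index(species_tree)
  n_s <- st$n_all
  par <- st$parent
  depth <- st$depth
  anc_of <- function(s) {
    out <- s
    while (!is.na(par[s])) { s <- par[s]; out <- c(out, s) }
    out
  }
  ntip <- length(gene_tree$tip.label)
  ch <- famevol:::children_list(gene_tree)
  post <- famevol:::postorder_nodes(gene_tree)
  internals <- post[post > ntip]
  leaf_img <- vapply(seq_len(ntip), function(v) {
    match(species_map[[gene_tree$tip.label[v]]], species_tree$tip.label)
  }, integer(1))
  combos <- expand.grid(rep(list(seq_len(n_s)), length(internals)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    m <- integer(ntip + gene_tree$Nnode)
    m[seq_len(ntip)] <- leaf_img
    m[internals] <- as.integer(combos[r, ])
    ok <- TRUE
    total <- 0
    for (v in internals) {
      s <- m[v]; s1 <- m[ch[[v]][1]]; s2 <- m[ch[[v]][2]]
      if (!(s %in% anc_of(s1)) || !(s %in% anc_of(s2))) { ok <- FALSE; break }
      l12 <- st$lca(s1, s2)
      dup <- (s != l12) || (s1 == s) || (s2 == s)
      loss <- (depth[s1] - depth[s]) + (depth[s2] - depth[s]) -
        (if (dup) 0L else 2L)
      total <- total + as.numeric(dup) + loss
    }
    if (ok && total < best) best <- total
  }
  best
}

# --- all rooted binary leaf-labeled topologies -------------------------

# trees represented as nested lists; leaf = character scalar
all_rooted_topologies <- function(labels) {
  grow <- function(trees, lab) {
    out <- list()
    for (tr in trees) {
      spots <- insert_everywhere(tr, lab)
      out <- c(out, spots)
    }
    out
  }
  insert_everywhere <- function(tr, lab) {
    res <- list(list(tr, lab)) # above the current root
    if (!is.character(tr)) {
      for (side in 1:2) {
        sub <- insert_everywhere(tr[[side]], lab)
        for (s in sub) {
          cp <- tr
          cp[[side]] <- s
          res <- c(res, list(cp))
        }
      }
    }
    res
  }
  trees <- list(labels[1])
  for (lab in labels[-1]) trees <- grow(trees, lab)
  trees
}

topology_to_phylo <- function(tr) {
  nwk <- function(t) {
    if (is.character(t)) return(t)
    paste0("(", nwk(t[[1]]), ",", nwk(t[[2]]), ")")
  }
  ape::read.tree(text = paste0(nwk(tr), ";"))
}

# --- Nei-Gojobori pathway-enumeration oracle ---------------------------

ng_oracle_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

ng_oracle_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = max(1L, length(v) > 0)))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- ng_oracle_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# per-codon synonymous site fraction (to-stop changes nonsynonymous)
ng_oracle_sites <- function(codon, code) {
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (nt in c("A", "C", "G", "T")) {
      if (nt == ref) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1
    }
  }
  s / 3
}

# explicit enumeration of every mutational pathway between two codons
ng_oracle_diffs <- function(c1, c2, code) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0L) return(c(Sd = 0, Nd = 0))
  P <- ng_oracle_perms(dpos)
  run <- function(drop_stop_paths) {
    tot_s <- tot_n <- 0; n_ok <- 0L
    for (r in seq_len(nrow(P))) {
      cur <- c1; ssteps <- nsteps <- 0; ok <- TRUE
      for (pos in P[r, ]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (drop_stop_paths && code[[nxt]] == "*") { ok <- FALSE; break }
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) {
          ssteps <- ssteps + 1
        } else nsteps <- nsteps + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + ssteps; tot_n <- tot_n + nsteps
                n_ok <- n_ok + 1L }
    }
    if (n_ok == 0L) return(NULL)
    c(Sd = tot_s / n_ok, Nd = tot_n / n_ok)
  }
  run(TRUE) %||% run(FALSE)
}

ng_oracle <- function(a, b) {
  code <- ng_oracle_code()
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (ng_oracle_sites(ca[i], code) + ng_oracle_sites(cb[i], code)) / 2
    N <- N + 3 - (ng_oracle_sites(ca[i], code) + ng_oracle_sites(cb[i], code)) / 2
    d <- ng_oracle_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random sense-codon sequence
random_cds <- function(n_codons, exclude_stops = TRUE) {
  cm <- famevol:::codon_machinery()
  paste(sample(cm$codons, n_codons, replace = TRUE), collapse = "")
}
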
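sp4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("a rate-free birth-death run returns the species tree itself", {
  fam <- simulate_family(sp4, birth_rate = 0, death_rate = 0, seed = 1)
  expect_false(fam$extinct)
  expect_equal(sort(unname(fam$species_map)), c("A", "B", "C", "D"))
  r <- lca_reconcile(fam$gene_tree, sp4, fam$species_map)
  expect_equal(r$n_duplications + r$n_losses, 0L)
  expect_equal(nrow(fam$events), 0L)
})

test_that("generators are pure functions of their seed", {
  f1 <- simulate_family(sp4, 0.4, 0.2, seed = 77)
  f2 <- simulate_family(sp4, 0.4, 0.2, seed = 77)
  expect_identical(ape::write.tree(f1$gene_tree),
                   ape::write.tree(f2$gene_tree))
  expect_identical(f1$events, f2$events)

  l1 <- simulate_genome_layout(5)
  l2 <- simulate_genome_layout(5)
  expect_identical(l1, l2)

  e1 <- simulate_expression(9)
  e2 <- simulate_expression(9)
  expect_identical(e1, e2)

  tr <- withr::with_seed(1, ape::rtree(5))
  mix <- tibble::tibble(omega = c(0.5, 2), weight = c(0.8, 0.2))
  a1 <- simulate_codon_alignment(tr, mix, 30, seed = 3)
  a2 <- simulate_codon_alignment(tr, mix, 30, seed = 3)
  expect_identical(a1, a2)
})

test_that("extant copy numbers match the branching-process expectation", {
  # E[copies per species] = exp((birth - death) * root-to-leaf length)
  b <- 0.5; d <- 0.2
  sp2 <- ape::read.tree(text = "(A:1,B:1);")
  nrep <- 2000
  counts <- vapply(seq_len(nrep), function(s) {
    fam <- simulate_family(sp2, b, d, seed = s)
    as.numeric(fam$extant_counts[["A"]])
  }, numeric(1))
  expected <- exp((b - d) * 1)
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("zero-scale codon simulation copies the root everywhere", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  mix <- tibble::tibble(omega = 1, weight = 1)
  sim <- simulate_codon_alignment(tr, mix, 25, seed = 2)
  expect_equal(length(unique(sim$alignment)), 1L)
})

test_that("omega = 0 sites never change the protein", {
  tr <- withr::with_seed(5, ape::rtree(6, br = function(n) runif(n, 0.2, 0.6)))
  mix <- tibble::tibble(omega = c(0, 1), weight = c(0.5, 0.5))
  sim <- simulate_codon_alignment(tr, mix, 60, seed = 11)
  cm <- famevol:::codon_machinery()
  aa_mat <- sapply(sim$alignment, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cm$aa[match(cods, cm$codons)]
  })
  zero_sites <- which(sim$site_omega == 0)
  for (s in zero_sites) {
    expect_equal(length(unique(aa_mat[s, ])), 1L)
  }
})

test_that("higher true omega classes show more protein-level divergence", {
  tr <- withr::with_seed(15, ape::rtree(8, br = function(n) runif(n, 0.2, 0.5)))
  mix <- tibble::tibble(omega = c(0.1, 3), weight = c(0.5, 0.5))
  sim <- simulate_codon_alignment(tr, mix, 150, seed = 21)
  cm <- famevol:::codon_machinery()
  aa_mat <- sapply(sim$alignment, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cm$aa[match(cods, cm$codons)]
  })
  div <- apply(aa_mat, 1, function(r) length(unique(r)))
  expect_gt(mean(div[sim$site_omega == 3]), mean(div[sim$site_omega == 0.1]))
})

test_that("planted genome layouts are classified back perfectly", {
  lay <- simulate_genome_layout(42)
  got <- vapply(seq_len(nrow(lay$truth)), function(i) {
    classify_pair(lay$truth$gene_a[i], lay$truth$gene_b[i],
                  lay$gene_table, lay$blocks)
  }, character(1))
  expect_equal(got, lay$truth$true_type)
  # the boundary pair is present and non-tandem
  expect_true("famB1" %in% lay$truth$gene_a)
})

test_that("noise-free expression tables recover fold changes exactly", {
  sim <- simulate_expression(3, genes = c("g1", "g2"),
                             fold_changes = c(1, 4), sigma = 0)
  dd <- ddct_table(sim$ct, reference_gene = "actin", control = "control")
  expect_equal(dd$rel_expr[dd$gene == "g1"], 1, tolerance = 1e-12)
  expect_equal(dd$rel_expr[dd$gene == "g2"], 4, tolerance = 1e-12)
})

test_that("additive matrices are additive (NJ least-squares fit is exact)", {
  s <- simulate_additive_distances(6, 9)
  tr <- nj_tree(s$dm)
  fitted <- ape::cophenetic.phylo(tr)[rownames(s$dm), colnames(s$dm)]
  expect_equal(fitted, s$dm, tolerance = 1e-8)
})
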
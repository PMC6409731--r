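test_that("omega discretization uses class medians and proper weights", {
  d <- discretize_omega("M7", list(p = 1, q = 1), K = 1)
  expect_equal(d$omega, 0.5)
  expect_equal(d$weight, 1)

  # M8 with p0 = 1 degenerates to M7
  m7 <- discretize_omega("M7", list(p = 0.4, q = 1.2), K = 8)
  m8 <- discretize_omega("M8", list(p0 = 1, p = 0.4, q = 1.2, ws = 3), K = 8)
  expect_equal(m8$omega[1:8], m7$omega)
  expect_equal(m8$weight[1:8], m7$weight)
  expect_equal(m8$weight[9], 0)

  # gamma class values equal the quantile oracle
  g <- discretize_omega("M5", list(alpha = 1, beta = 1), K = 8)
  expect_equal(g$omega, qgamma((1:8 - 0.5) / 8, shape = 1, scale = 1),
               tolerance = 1e-10)
  expect_equal(sum(g$weight), 1)
  expect_error(discretize_omega("M7", list(p = -1, q = 1)), "positive")
})

test_that("discretized means approach the analytic mean as K grows", {
  d <- discretize_omega("M5", list(alpha = 2, beta = 0.3), K = 1024)
  expect_equal(sum(d$omega * d$weight), 2 * 0.3, tolerance = 1e-3)
  b <- discretize_omega("M7", list(p = 2, q = 5), K = 1024)
  expect_equal(sum(b$omega * b$weight), 2 / 7, tolerance = 1e-4)
})

test_that("pruning likelihood equals the exhaustive 61-state sum on 3 taxa", {
  cm <- famevol:::codon_machinery()
  pi <- uniform_codon_freqs()
  tr <- ape::read.tree(text = "(x:0.2,y:0.3,z:0.1);")
  withr::with_seed(51, {
    for (rep in 1:5) {
      cods <- sample(cm$codons, 3, replace = TRUE)
      aln <- setNames(cods, c("x", "y", "z"))
      Q <- famevol:::gy94_Q(2.3, 0.7, pi)
      es <- famevol:::eigen_system(Q$Q / Q$rate, pi)
      ti <- famevol:::tree_info(tr)
      pat <- famevol:::codon_patterns(aln, tr)
      Pm <- lapply(ti$edge.length, function(t) famevol:::prob_matrix(es, t))
      ll <- famevol:::prune_patterns(ti, pat$tip_index, Pm, pi)
      obs <- match(cods, cm$codons)
      oracle <- 0
      for (r in 1:61) {
        term <- pi[r]
        for (e in seq_len(nrow(ti$edge))) {
          tip <- tr$tip.label[ti$edge[e, 2]]
          term <- term * Pm[[e]][r, obs[match(tip, names(aln))]]
        }
        oracle <- oracle + term
      }
      expect_equal(unname(ll), log(unname(oracle)), tolerance = 1e-10)
    }
  })
})

test_that("near-zero branches give the equilibrium frequency of a shared codon", {
  pi <- uniform_codon_freqs()
  tr <- ape::read.tree(text = "(x:1e-9,y:1e-9);")
  aln <- c(x = "AAA", y = "AAA")
  Q <- famevol:::gy94_Q(2, 0.5, pi)
  es <- famevol:::eigen_system(Q$Q / Q$rate, pi)
  ti <- famevol:::tree_info(tr)
  pat <- famevol:::codon_patterns(aln, tr)
  ll <- famevol:::prune_patterns(
    ti, pat$tip_index,
    lapply(ti$edge.length, function(t) famevol:::prob_matrix(es, t)), pi)
  expect_equal(exp(ll), 1 / 61, tolerance = 1e-6)
})

test_that("the likelihood is invariant to leaf order", {
  tr <- withr::with_seed(61, ape::rtree(6, br = function(n) runif(n, 0.1, 0.4)))
  mix <- tibble::tibble(omega = c(0.2, 1.5), weight = c(0.7, 0.3))
  sim <- simulate_codon_alignment(tr, mix, L = 40, seed = 6)
  pi <- uniform_codon_freqs()
  ll_for <- function(aln) {
    ti <- famevol:::tree_info(tr)
    pat <- famevol:::codon_patterns(aln, tr)
    famevol:::mixture_loglik(
      famevol:::category_loglik(ti, pat$tip_index, mix, 2, 1, pi),
      mix$weight, pat$pattern_weight)
  }
  base <- ll_for(sim$alignment)
  perm <- sample(names(sim$alignment))
  expect_equal(ll_for(sim$alignment[perm]), base, tolerance = 1e-8)
})

test_that("identical alignments are flagged as degenerate fits", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  aln <- setNames(rep(strrep("ATG", 20), 4), c("a", "b", "c", "d"))
  fit <- fit_site_model(aln, tr, model = "M5", K = 4)
  expect_equal(fit$convergence, "degenerate")
  expect_true(fit$degenerate)
})

test_that("M8 contains M7: likelihood never drops when adding the point mass", {
  tr <- withr::with_seed(71, ape::rtree(6, br = function(n) runif(n, 0.1, 0.4)))
  m7cats <- discretize_omega("M7", list(p = 0.3, q = 1.2), 8)
  sim <- simulate_codon_alignment(tr, m7cats, L = 80, seed = 17)
  f7 <- fit_site_model(sim$alignment, tr, model = "M7", K = 8,
                       codon_freqs = "uniform")
  f8 <- fit_site_model(sim$alignment, tr, model = "M8", K = 8,
                       codon_freqs = "uniform",
                       extra_starts = list(list(
                         params = c(f7$params, list(p0 = 1 - 1e-6, ws = 1)),
                         kappa = f7$kappa, scale = f7$scale)))
  expect_gte(f8$logL, f7$logL - 1e-4)
  lrt <- m7_m8_lrt(f7, f8)
  expect_gte(lrt$statistic, -2e-4)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
})

test_that("posterior site omegas are normalized expectations of the classes", {
  tr <- withr::with_seed(81, ape::rtree(8, br = function(n) runif(n, 0.1, 0.4)))
  mix <- discretize_omega("M8", list(p0 = 0.85, p = 0.5, q = 1.5, ws = 3), 8)
  sim <- simulate_codon_alignment(tr, mix, L = 60, seed = 9)
  fit <- fit_site_model(sim$alignment, tr, model = "M8", K = 8,
                        codon_freqs = "uniform")
  post <- posterior_site_omega(fit)
  expect_equal(nrow(post), 60)
  expect_true(all(post$e_omega >= min(fit$categories$omega) - 1e-9))
  expect_true(all(post$e_omega <= max(fit$categories$omega) + 1e-9))
  expect_true(all(post$p_positive_class >= 0 & post$p_positive_class <= 1))
  expect_equal(post$called, post$e_omega > 1)
  # tidy/glance accessors
  expect_equal(tidy(fit), post)
  g <- glance(fit)
  expect_equal(g$model, "M8")
  expect_true(is.finite(g$AIC))
})

test_that("single-class fits give every site the same omega", {
  tr <- withr::with_seed(91, ape::rtree(5, br = function(n) runif(n, 0.1, 0.3)))
  mix <- tibble::tibble(omega = 0.5, weight = 1)
  sim <- simulate_codon_alignment(tr, mix, L = 30, seed = 4)
  fit <- fit_site_model(sim$alignment, tr, model = "M5", K = 1,
                        codon_freqs = "uniform")
  post <- posterior_site_omega(fit)
  expect_equal(length(unique(round(post$e_omega, 10))), 1)
})

test_that("called sites are mapped onto protein regions that must partition", {
  calls <- tibble::tibble(site = c(3, 10, 25, 40), called = TRUE)
  regions <- tibble::tibble(region = c("N-terminal", "loop"),
                            start = c(1, 21), end = c(20, 35))
  out <- map_sites_to_topology(calls, regions)
  expect_equal(out$n_sites[out$region == "N-terminal"], 2L)
  expect_equal(out$n_sites[out$region == "loop"], 1L)
  expect_equal(out$n_sites[out$region == "unannotated"], 1L)
  expect_equal(sum(out$n_sites), 4L)
  expect_equal(nrow(map_sites_to_topology(integer(0), regions)), 2)
  bad <- tibble::tibble(region = c("a", "b"), start = c(1, 10), end = c(15, 20))
  expect_error(map_sites_to_topology(calls, bad), "overlap")
})
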
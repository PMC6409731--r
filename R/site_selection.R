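#' Discretize an omega distribution into equal-probability categories
#'
#' The continuous distribution of omega (= Ka/Ks) across sites is
#' approximated by `K` equal-weight classes whose omega value is the class
#' median (quantile at `(k - 0.5)/K`). Models: `M5` gamma(shape `alpha`,
#' scale `beta`); `M7` beta(`p`, `q`) on (0,1); `M8` beta(`p`, `q`) with
#' total weight `p0` plus a point mass `1 - p0` at `ws >= 1` appended as
#' an extra category.
#'
#' @param model `"M5"`, `"M7"` or `"M8"`.
#' @param params Named list of distribution parameters (see above).
#' @param K Number of discrete classes for the continuous part.
#' @return Tibble with columns `omega` and `weight` (weights sum to 1).
#' @export
discretize_omega <- function(model, params, K = 8L) {
  stopifnot(K >= 1L)
  model <- match.arg(model, c("M5", "M7", "M8"))
  qs <- (seq_len(K) - 0.5) / K
  if (model == "M5") {
    if (params$alpha <= 0 || params$beta <= 0) {
      rlang::abort("gamma parameters must be positive")
    }
    omega <- qgamma(qs, shape = params$alpha, scale = params$beta)
    weight <- rep(1 / K, K)
  } else {
    if (params$p <= 0 || params$q <= 0) {
      rlang::abort("beta parameters must be positive")
    }
    omega <- qbeta(qs, params$p, params$q)
    weight <- rep(1 / K, K)
    if (model == "M8") {
      p0 <- params$p0
      if (p0 < 0 || p0 > 1) rlang::abort("p0 must lie in [0, 1]")
      if (params$ws < 1) rlang::abort("ws must be >= 1")
      omega <- c(omega, params$ws)
      weight <- c(weight * p0, 1 - p0)
    }
  }
  tibble::tibble(omega = omega, weight = weight)
}

# --- alignment preparation ----------------------------------------------

codon_patterns <- function(alignment, tree) {
  check_alignment(alignment)
  if (!setequal(names(alignment), tree$tip.label)) {
    rlang::abort("alignment ids and tree tip labels must match")
  }
  L <- unique(nchar(alignment))
  if (L %% 3 != 0) rlang::abort("alignment length not divisible by 3")
  cm <- codon_machinery()
  ntip <- length(tree$tip.label)
  nsite <- L / 3
  idx <- matrix(NA_integer_, ntip, nsite)
  for (i in seq_len(ntip)) {
    s <- toupper(alignment[[tree$tip.label[i]]])
    cods <- substring(s, seq(1, L, 3), seq(3, L, 3))
    j <- match(cods, cm$codons)
    if (any(is.na(j) & !grepl("[-N]", cods))) {
      bad <- which(is.na(j) & !grepl("[-N]", cods))[1]
      rlang::abort(paste0("stop or invalid codon '", cods[bad], "' at codon ",
                          bad, " in ", tree$tip.label[i]))
    }
    idx[i, ] <- j
  }
  key <- apply(idx, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  list(tip_index = idx[, upat, drop = FALSE],
       pattern_of_site = match(key, key[upat]),
       pattern_weight = as.vector(table(factor(match(key, key[upat]),
                                               levels = seq_len(sum(upat))))),
       n_sites = nsite)
}

tree_info <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) rlang::abort("tree needs branch lengths")
  list(edge = tr$edge, edge.length = tr$edge.length,
       ntip = length(tr$tip.label),
       root = tr$edge[nrow(tr$edge), 1])
}

# per-pattern log-likelihood under one omega category (Felsenstein pruning
# with per-node rescaling)
prune_patterns <- function(ti, tip_index, P_edges, pi) {
  npat <- ncol(tip_index)
  n61 <- length(pi)
  partial <- vector("list", max(ti$edge))
  logscale <- numeric(npat)
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    child <- ti$edge[e, 2]
    P <- P_edges[[e]]
    if (child <= ti$ntip) {
      cols <- tip_index[child, ]
      ok <- which(!is.na(cols))
      if (length(ok) == npat) {
        contrib <- P[, cols, drop = FALSE]
      } else {
        contrib <- matrix(1, n61, npat)
        contrib[, ok] <- P[, cols[ok], drop = FALSE]
      }
    } else {
      # rescale the child partial (column sums to 1) before propagating,
      # which keeps everything in floating range on deep trees
      L <- partial[[child]]
      cs <- .colSums(L, n61, npat)
      cs[cs == 0] <- .Machine$double.xmin
      logscale <- logscale + log(cs)
      contrib <- P %*% (L * rep(1 / cs, each = n61))
    }
    partial[[par]] <- if (is.null(partial[[par]])) contrib
                      else partial[[par]] * contrib
  }
  log(.colSums(partial[[ti$root]] * pi, n61, npat)) + logscale
}

# npat x ncat matrix of per-pattern log likelihoods
category_loglik <- function(ti, tip_index, cats, kappa, scale, pi) {
  Qs <- lapply(cats$omega, function(w) gy94_Q(kappa, w, pi))
  mean_rate <- sum(cats$weight * vapply(Qs, `[[`, numeric(1), "rate"))
  if (!is.finite(mean_rate) || mean_rate <= 0) {
    rlang::abort("degenerate rate matrix (mean rate <= 0)")
  }
  npat <- ncol(tip_index)
  out <- matrix(NA_real_, npat, nrow(cats))
  for (k in seq_len(nrow(cats))) {
    es <- eigen_system(Qs[[k]]$Q / mean_rate, pi)
    P_edges <- lapply(ti$edge.length, function(t) {
      prob_matrix(es, max(t, 0) * scale)
    })
    out[, k] <- prune_patterns(ti, tip_index, P_edges, pi)
  }
  out
}

mixture_loglik <- function(cat_ll, weights, pattern_weight) {
  lw <- log(weights)
  m <- sweep(cat_ll, 2, lw, `+`)
  mmax <- apply(m, 1, max)
  site_ll <- mmax + log(rowSums(exp(m - mmax)))
  sum(site_ll * pattern_weight)
}

# --- model fitting ------------------------------------------------------

par_pack <- function(model, params, kappa, scale) {
  base <- c(log_kappa = log(kappa), log_scale = log(scale))
  rest <- switch(model,
    M5 = c(log_alpha = log(params$alpha), log_beta = log(params$beta)),
    M7 = c(log_p = log(params$p), log_q = log(params$q)),
    M8 = c(logit_p0 = stats::qlogis(min(max(params$p0, 1e-6), 1 - 1e-6)),
           log_p = log(params$p), log_q = log(params$q),
           log_wsm1 = log(max(params$ws - 1, 1e-6))))
  c(base, rest)
}

par_unpack <- function(model, x) {
  kappa <- exp(x[["log_kappa"]])
  scale <- exp(x[["log_scale"]])
  params <- switch(model,
    M5 = list(alpha = exp(x[["log_alpha"]]), beta = exp(x[["log_beta"]])),
    M7 = list(p = exp(x[["log_p"]]), q = exp(x[["log_q"]])),
    M8 = list(p0 = stats::plogis(x[["logit_p0"]]),
              p = exp(x[["log_p"]]), q = exp(x[["log_q"]]),
              ws = 1 + exp(x[["log_wsm1"]])))
  list(kappa = kappa, scale = scale, params = params)
}

#' Fit a discretized omega-distribution codon site model
#'
#' Maximizes the log-likelihood of a codon alignment on a fixed tree
#' topology under a mixture of omega classes obtained by discretizing the
#' model's omega distribution ([discretize_omega()]): per site the
#' likelihood is the weighted sum over classes of the Felsenstein pruning
#' likelihood under a GY94-style codon process with transition/transversion
#' ratio `kappa`. Free parameters are the distribution parameters, `kappa`,
#' and one global branch-length scale (the supplied tree may be in any
#' units, e.g. protein p-distance); optimization is bounded quasi-Newton on
#' log/logit-transformed parameters with multiple starts.
#'
#' @param alignment Named character vector of aligned CDS sequences.
#' @param tree Rooted or unrooted [ape::phylo] with branch lengths whose
#'   tips match the alignment ids.
#' @param model `"M5"`, `"M7"` or `"M8"`.
#' @param K Number of discrete omega classes (default 8).
#' @param codon_freqs `"F3x4"` (default, estimated from the alignment) or
#'   `"uniform"`, or a numeric vector over the 61 sense codons.
#' @param extra_starts Optional list of extra start points, each a list
#'   with `params`, `kappa`, `scale` (used e.g. to start M8 from an M7
#'   optimum when checking model nesting).
#' @param max_iter Iteration cap per start.
#' @return An object of class `site_model_fit`.
#' @export
fit_site_model <- function(alignment, tree, model = c("M8", "M7", "M5"),
                           K = 8L, codon_freqs = "F3x4",
                           extra_starts = NULL, max_iter = 300L) {
  model <- match.arg(model)
  pi <- resolve_codon_freqs(codon_freqs, alignment)
  ti <- tree_info(tree)
  pat <- codon_patterns(alignment, tree)

  degenerate <- length(unique(toupper(alignment))) == 1L

  objective <- function(x) {
    up <- par_unpack(model, x)
    cats <- try(discretize_omega(model, up$params, K), silent = TRUE)
    if (inherits(cats, "try-error")) return(1e10)
    ll <- try(category_loglik(ti, pat$tip_index, cats, up$kappa, up$scale, pi),
              silent = TRUE)
    if (inherits(ll, "try-error") || any(!is.finite(ll))) return(1e10)
    -mixture_loglik(ll, cats$weight, pat$pattern_weight)
  }

  starts <- list(
    switch(model,
      M5 = list(params = list(alpha = 1, beta = 0.5), kappa = 2, scale = 1),
      M7 = list(params = list(p = 0.5, q = 1.5), kappa = 2, scale = 1),
      M8 = list(params = list(p0 = 0.9, p = 0.5, q = 1.5, ws = 2),
                kappa = 2, scale = 1)),
    switch(model,
      M5 = list(params = list(alpha = 0.5, beta = 1), kappa = 3, scale = 0.5),
      M7 = list(params = list(p = 1.5, q = 0.5), kappa = 3, scale = 0.5),
      M8 = list(params = list(p0 = 0.6, p = 1, q = 1, ws = 3),
                kappa = 3, scale = 0.5))
  )
  starts <- c(starts, extra_starts %||% list())

  best <- NULL
  convergence <- "failed"
  if (degenerate) {
    st <- starts[[1]]
    x0 <- par_pack(model, st$params, st$kappa, st$scale)
    best <- list(par = x0, objective = objective(x0))
    convergence <- "degenerate"
  } else {
    for (st in starts) {
      x0 <- par_pack(model, st$params, st$kappa, st$scale)
      fit <- try(nlminb(x0, objective,
                        control = list(iter.max = max_iter,
                                       rel.tol = 1e-7)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$objective < best$objective) {
        best <- fit
        convergence <- if (fit$convergence == 0) "converged"
                       else "not_converged"
      }
    }
    if (is.null(best)) rlang::abort("optimization failed from every start")
  }

  up <- par_unpack(model, best$par)
  cats <- discretize_omega(model, up$params, K)
  cat_ll <- category_loglik(ti, pat$tip_index, cats, up$kappa, up$scale, pi)
  logL <- mixture_loglik(cat_ll, cats$weight, pat$pattern_weight)
  npar <- length(best$par)
  structure(list(
    model = model, K = K, params = up$params, kappa = up$kappa,
    scale = up$scale, categories = cats, logL = logL,
    aic = 2 * npar - 2 * logL, npar = npar,
    convergence = convergence, degenerate = degenerate,
    codon_freqs = pi,
    pattern_loglik = cat_ll, pattern_of_site = pat$pattern_of_site,
    n_sites = pat$n_sites
  ), class = "site_model_fit")
}

resolve_codon_freqs <- function(codon_freqs, alignment) {
  if (is.numeric(codon_freqs)) {
    stopifnot(length(codon_freqs) == 61, all(codon_freqs >= 0))
    return(codon_freqs / sum(codon_freqs))
  }
  switch(match.arg(codon_freqs, c("F3x4", "uniform")),
         F3x4 = codon_freqs_f3x4(alignment),
         uniform = uniform_codon_freqs())
}

#' Per-site posterior selection pressure (empirical Bayes)
#'
#' Posterior weight of omega class k at site i is proportional to
#' `weight_k * L_i(omega_k)`; the posterior mean `E[omega | site]` is the
#' reported site-specific Ka/Ks. Under M8 the posterior probability of the
#' positive-selection class (`omega = ws`) is reported, and a site is
#' called positively selected when `E[omega | site] > 1` (no
#' multiple-testing adjustment).
#'
#' @param fit A `site_model_fit`.
#' @return Tibble: `site, e_omega, p_positive_class, called`.
#' @export
posterior_site_omega <- function(fit) {
  stopifnot(inherits(fit, "site_model_fit"))
  lw <- log(fit$categories$weight)
  m <- sweep(fit$pattern_loglik, 2, lw, `+`)
  mmax <- apply(m, 1, max)
  post <- exp(m - mmax)
  post <- post / rowSums(post)
  e_omega_pat <- as.vector(post %*% fit$categories$omega)
  p_pos_pat <- if (fit$model == "M8") post[, ncol(post)] else NA_real_
  i <- fit$pattern_of_site
  tibble::tibble(
    site = seq_len(fit$n_sites),
    e_omega = e_omega_pat[i],
    p_positive_class = if (fit$model == "M8") p_pos_pat[i] else NA_real_,
    called = e_omega_pat[i] > 1
  )
}

#' Likelihood-ratio comparison of M7 vs M8
#'
#' Conventional chi-squared test with 2 degrees of freedom.
#'
#' @param fit_m7,fit_m8 Fits from [fit_site_model()].
#' @return Tibble with the statistic, df and p-value.
#' @export
m7_m8_lrt <- function(fit_m7, fit_m8) {
  stopifnot(fit_m7$model == "M7", fit_m8$model == "M8")
  lr <- 2 * (fit_m8$logL - fit_m7$logL)
  tibble::tibble(statistic = lr, df = 2,
                 p_value = stats::pchisq(max(lr, 0), df = 2,
                                         lower.tail = FALSE))
}

#' Count called sites per protein region
#'
#' Joins positively selected sites to a region annotation (protein
#' coordinates, 1-based inclusive). Regions must not overlap; sites
#' outside every region are counted as `"unannotated"`.
#'
#' @param calls Either the tibble from [posterior_site_omega()] (rows with
#'   `called == TRUE` are used) or an integer vector of site positions.
#' @param regions Tibble with columns `region`, `start`, `end`.
#' @return Tibble `region, n_sites` (region order preserved;
#'   `unannotated` appended when needed).
#' @export
map_sites_to_topology <- function(calls, regions) {
  if (is.data.frame(calls)) calls <- calls$site[calls$called]
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (nrow(regions) > 1L) {
    r <- regions[order(regions$start), ]
    if (any(r$start[-1] <= r$end[-nrow(r)])) {
      rlang::abort("region annotation must not overlap")
    }
  }
  assign_one <- function(s) {
    hit <- which(regions$start <= s & s <= regions$end)
    if (length(hit) == 0L) "unannotated" else regions$region[hit]
  }
  lab <- vapply(as.integer(calls), assign_one, character(1))
  out <- tibble::tibble(region = regions$region)
  out$n_sites <- vapply(out$region, function(g) sum(lab == g), integer(1),
                        USE.NAMES = FALSE)
  if (any(lab == "unannotated")) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = "unannotated", n_sites = sum(lab == "unannotated")))
  }
  out
}

#' @export
tidy.site_model_fit <- function(x, ...) posterior_site_omega(x)

#' @export
glance.site_model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, K = x$K, logL = x$logL, AIC = x$aic,
    npar = x$npar, kappa = x$kappa, branch_scale = x$scale,
    convergence = x$convergence,
    !!!setNames(as.list(unlist(x$params)), paste0("par_", names(unlist(x$params))))
  )
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Codon site model", x$model, "(", x$K, "classes )\n")
  cat("  logL:", format(x$logL, digits = 8), " AIC:",
      format(x$aic, digits = 8), "\n")
  cat("  kappa:", signif(x$kappa, 4), " branch scale:",
      signif(x$scale, 4), "\n")
  cat("  params:", paste(names(unlist(x$params)),
                         signif(unlist(x$params), 4),
                         sep = "=", collapse = " "), "\n")
  cat("  convergence:", x$convergence, "\n")
  invisible(x)
}

#' Plot per-site posterior omega
#'
#' @param object A `site_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_model_fit <- function(object, ...) {
  d <- posterior_site_omega(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$e_omega,
                                  fill = .data$called)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "codon site", y = expression(E[omega ~ "|" ~ site]),
                  title = paste0("Site-specific selection (", object$model,
                                 ")")) +
    ggplot2::theme_minimal()
}
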
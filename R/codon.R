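# GY94-style codon substitution machinery shared by the site-selection
# fitter and the alignment simulator. Rates: zero for multi-nucleotide
# changes, pi_j * kappa^[transition] * omega^[nonsynonymous] otherwise.

codon_machinery <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    codons <- names(gc_tab)[gc_tab != "*"]
    aa <- unname(gc_tab[codons])
    n <- length(codons) # 61
    cmat <- do.call(rbind, strsplit(codons, ""))
    purine <- c("A", "G")
    # pair type: 0 = not single-nt, 1 = syn ts, 2 = syn tv, 3 = nonsyn ts,
    # 4 = nonsyn tv
    type <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        diffs <- which(cmat[i, ] != cmat[j, ])
        if (length(diffs) != 1L) next
        a <- cmat[i, diffs]; b <- cmat[j, diffs]
        ts <- (a %in% purine) == (b %in% purine)
        syn <- aa[i] == aa[j]
        t <- if (syn && ts) 1L else if (syn) 2L else if (ts) 3L else 4L
        type[i, j] <- type[j, i] <- t
      }
    }
    cache <<- list(codons = codons, aa = aa, n = n, type = type)
    cache
  }
})

#' Uniform codon equilibrium frequencies
#' @return Named numeric vector over the 61 sense codons summing to 1.
#' @export
uniform_codon_freqs <- function() {
  cm <- codon_machinery()
  setNames(rep(1 / cm$n, cm$n), cm$codons)
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Empirical nucleotide frequencies at each codon position, multiplied and
#' renormalized over the 61 sense codons.
#'
#' @param alignment Named character vector of aligned CDS sequences.
#' @return Named numeric vector over the sense codons summing to 1.
#' @export
codon_freqs_f3x4 <- function(alignment) {
  cm <- codon_machinery()
  nts <- c("A", "C", "G", "T")
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, nts))
  for (s in alignment) {
    ch <- strsplit(toupper(s), "")[[1]]
    pos <- ((seq_along(ch) - 1L) %% 3L) + 1L
    for (p in 1:3) {
      chp <- ch[pos == p]
      chp <- chp[chp %in% nts]
      pos_freq[p, ] <- pos_freq[p, ] + as.numeric(table(factor(chp, levels = nts)))
    }
  }
  pos_freq <- pos_freq / rowSums(pos_freq)
  f <- vapply(cm$codons, function(cd) {
    prod(pos_freq[cbind(1:3, match(strsplit(cd, "")[[1]], nts))])
  }, numeric(1))
  # floor so unobserved codons keep a tiny positive frequency (keeps the
  # rate matrix irreducible on low-diversity alignments)
  f <- pmax(f, 1e-8)
  f / sum(f)
}

# unscaled GY94 rate matrix and its mean rate under pi
gy94_Q <- function(kappa, omega, pi) {
  cm <- codon_machinery()
  type <- cm$type
  R <- matrix(0, cm$n, cm$n)
  R[type == 1L] <- kappa
  R[type == 2L] <- 1
  R[type == 3L] <- kappa * omega
  R[type == 4L] <- omega
  Q <- R * rep(pi, each = cm$n)     # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

# eigendecomposition of a reversible Q for fast matrix exponentials
eigen_system <- function(Q, pi) {
  sq <- sqrt(pi)
  # similarity transform diag(sq) Q diag(1/sq) is symmetric for
  # reversible Q; symmetrize to absorb rounding
  A <- sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors * (1 / sq),   # diag(1/sq) %*% V
       left = t(e$vectors * sq))       # t(V) %*% diag(sq)
}

# P(t) = diag(1/sq) V exp(Lt) V' diag(sq)
prob_matrix <- function(es, t) {
  P <- es$right %*% (exp(es$values * t) * es$left)
  P[P < 0] <- 0
  P
}
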
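#' Log-transform an FPKM expression matrix
#'
#' Elementwise `log10(x + pseudocount)`; optionally per-gene (row) z-score
#' normalization for heatmap display. Constant rows are left at 0 under
#' z-scoring.
#'
#' @param mat Numeric matrix (genes x conditions) of FPKM values (>= 0),
#'   or a data frame whose first column holds gene ids.
#' @param pseudocount Added before the log (default 1, so FPKM 0 maps
#'   to 0).
#' @param normalize `"none"` (default), `"zscore"` (per-gene) or
#'   `"minmax"` (per-gene 0-1 range).
#' @return An object of class `expression_matrix`: a list with the raw
#'   `fpkm` matrix and the `transformed` matrix.
#' @export
log_transform <- function(mat, pseudocount = 1,
                          normalize = c("none", "zscore", "minmax")) {
  normalize <- match.arg(normalize)
  if (is.data.frame(mat)) {
    rn <- mat[[1]]
    mat <- as.matrix(mat[-1])
    rownames(mat) <- rn
  }
  if (any(mat < 0)) rlang::abort("FPKM values must be non-negative")
  tr <- log10(mat + pseudocount)
  if (normalize == "zscore") {
    tr <- t(apply(tr, 1, function(r) {
      s <- sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    colnames(tr) <- colnames(mat)
  } else if (normalize == "minmax") {
    tr <- t(apply(tr, 1, function(r) {
      rg <- diff(range(r))
      if (rg == 0) rep(0, length(r)) else (r - min(r)) / rg
    }))
    colnames(tr) <- colnames(mat)
  }
  structure(list(fpkm = mat, transformed = tr, pseudocount = pseudocount,
                 normalize = normalize),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$fpkm), "genes x", ncol(x$fpkm),
      "conditions (log10, pseudocount", x$pseudocount, ", normalize",
      x$normalize, ")\n")
  invisible(x)
}

#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$transformed, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "condition",
                        values_to = "log10_fpkm")
}

#' Heatmap of a transformed expression matrix
#'
#' @param object An `expression_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$gene,
                                  fill = .data$log10_fpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = mean(d$log10_fpkm)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "expr") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Relative expression by the 2^-ddCT (Livak) method
#'
#' CT replicates are averaged per (gene, condition); `dCT = CT_target -
#' CT_reference` within each condition; `ddCT = dCT_treatment -
#' dCT_control`; relative expression is `2^-ddCT`. The replicate standard
#' deviations of the four CT means are propagated in quadrature to a
#' standard deviation of ddCT, and to the fold-change scale by the delta
#' method.
#'
#' @param ct Tibble with columns `gene, condition, replicate, ct`.
#' @param target_gene Gene of interest.
#' @param reference_gene Endogenous control gene measured in the same
#'   conditions.
#' @param treatment,control Condition labels.
#' @return One-row tibble: `gene, treatment, control, ddct, rel_expr,
#'   sd_ddct, sd_rel_expr, n_replicates`.
#' @export
ddct <- function(ct, target_gene, reference_gene, treatment, control) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) rlang::abort("CT values must be positive")
  pick <- function(g, cond) {
    x <- ct$ct[ct$gene == g & ct$condition == cond]
    if (length(x) == 0L) {
      rlang::abort(paste0("no CT for gene '", g, "' in condition '",
                          cond, "'"))
    }
    x
  }
  tt <- pick(target_gene, treatment); tc <- pick(target_gene, control)
  rt <- pick(reference_gene, treatment); rc <- pick(reference_gene, control)
  dct_t <- mean(tt) - mean(rt)
  dct_c <- mean(tc) - mean(rc)
  ddct_val <- dct_t - dct_c
  sem2 <- function(x) if (length(x) > 1L) stats::var(x) / length(x) else 0
  sd_ddct <- sqrt(sem2(tt) + sem2(rt) + sem2(tc) + sem2(rc))
  rel <- 2^(-ddct_val)
  tibble::tibble(
    gene = target_gene, treatment = treatment, control = control,
    ddct = ddct_val, rel_expr = rel,
    sd_ddct = sd_ddct, sd_rel_expr = log(2) * rel * sd_ddct,
    n_replicates = min(length(tt), length(tc), length(rt), length(rc))
  )
}

#' Relative expression for several genes and treatments at once
#'
#' @param ct CT tibble as in [ddct()].
#' @param reference_gene Endogenous control.
#' @param control Control condition label.
#' @param genes Genes to report (default: all non-reference genes).
#' @param treatments Treatment conditions (default: all non-control).
#' @return Tibble with one [ddct()] row per gene x treatment.
#' @export
ddct_table <- function(ct, reference_gene, control,
                       genes = NULL, treatments = NULL) {
  genes <- genes %||% setdiff(unique(ct$gene), reference_gene)
  treatments <- treatments %||% setdiff(unique(ct$condition), control)
  purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(treatments, function(tr) {
      ddct(ct, g, reference_gene, tr, control)
    })
  })
}
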
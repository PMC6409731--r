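#' Classify a paralog pair as tandem, segmental or transposition
#'
#' Tandem: both genes on the same chromosome of the same species and
#' separated by fewer than five genes (i.e. at most 4 intervening genes,
#' adjacency included); tandem takes precedence over block membership.
#' Segmental: not tandem, but the pair (in either orientation) shares a
#' synteny `block_id`. Transposition: neither. Symmetric in its two genes.
#'
#' @param gene_a,gene_b Gene ids (must be present in `gene_table`,
#'   same species).
#' @param gene_table Gene table from [read_gene_table()] (needs
#'   `order_index`).
#' @param blocks Synteny block tibble (`block_id, species_a, gene_a,
#'   species_b, gene_b`), or `NULL` for none.
#' @param max_intervening Tandem cut-off: maximum number of intervening
#'   genes (default 4, "separated by less than five genes").
#' @return One of `"tandem"`, `"segmental"`, `"transposition"`.
#' @export
classify_pair <- function(gene_a, gene_b, gene_table, blocks = NULL,
                          max_intervening = 4L) {
  ra <- gene_table[gene_table$gene_id == gene_a, ]
  rb <- gene_table[gene_table$gene_id == gene_b, ]
  if (nrow(ra) != 1L) rlang::abort(paste0("gene not in table: ", gene_a))
  if (nrow(rb) != 1L) rlang::abort(paste0("gene not in table: ", gene_b))
  if (ra$species != rb$species) {
    rlang::abort("paralog pair must belong to one species")
  }
  if (ra$chromosome == rb$chromosome) {
    intervening <- abs(ra$order_index - rb$order_index) - 1L
    if (intervening <= max_intervening) return("tandem")
  }
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    in_pair <- (blocks$gene_a == gene_a & blocks$gene_b == gene_b) |
      (blocks$gene_a == gene_b & blocks$gene_b == gene_a)
    if (any(in_pair)) return("segmental")
    ids_by_block <- split(c(blocks$gene_a, blocks$gene_b),
                          c(blocks$block_id, blocks$block_id))
    shared <- vapply(ids_by_block,
                     function(g) gene_a %in% g && gene_b %in% g, logical(1))
    if (any(shared)) return("segmental")
  }
  "transposition"
}

# --- Nei-Gojobori (1986) Ka/Ks ------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

ng_site_counts <- function(codon, code) {
  nts <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (code[[alt]] == "*") next        # change to stop: nonsynonymous
      if (code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

ng_pair_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  paths <- perms(pos)
  tally <- function(skip_stops) {
    sd <- nd <- 0
    n_valid <- 0L
    for (r in seq_len(nrow(paths))) {
      cur <- c1
      steps_s <- steps_n <- 0
      valid <- TRUE
      for (p in paths[r, ]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (skip_stops && code[[nxt]] == "*") { valid <- FALSE; break }
        if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") {
          steps_s <- steps_s + 1
        } else {
          steps_n <- steps_n + 1
        }
        cur <- nxt
      }
      if (valid) {
        sd <- sd + steps_s
        nd <- nd + steps_n
        n_valid <- n_valid + 1L
      }
    }
    if (n_valid == 0L) return(NULL)
    c(Sd = sd / n_valid, Nd = nd / n_valid)
  }
  # pathways through stop codons are excluded; if every pathway hits a
  # stop, fall back to averaging over all pathways (stop steps count as
  # nonsynonymous)
  out <- tally(skip_stops = TRUE)
  if (is.null(out)) out <- tally(skip_stops = FALSE)
  out
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], perms(v[-i]))
  }))
}

#' Nei-Gojobori estimates of Ka and Ks for one aligned CDS pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (fractional
#' thirds; changes to stop codons count as nonsynonymous), averages site
#' totals over the two sequences, counts synonymous/nonsynonymous
#' differences by equal-weight enumeration of all mutational pathways for
#' multi-hit codons (pathways through stop codons excluded), and applies
#' the Jukes-Cantor correction `d = -3/4 * log(1 - 4p/3)` to the
#' proportions `pN = Nd/N`, `pS = Sd/S`. Codon pairs containing a gap in
#' either sequence are dropped.
#'
#' @param cds_a,cds_b Aligned coding sequences (equal length, length
#'   divisible by 3, no internal stop codons).
#' @return A list with `ka`, `ks` (NA and `saturated_*` flags set when
#'   p >= 3/4 makes the correction undefined), and the raw counts
#'   `S`, `N`, `Sd`, `Nd`, `ps`, `pn`.
#' @export
nei_gojobori <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) rlang::abort("sequences must be aligned")
  if (nchar(cds_a) %% 3 != 0) rlang::abort("alignment length not divisible by 3")
  code <- codon_table()
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) rlang::abort("no ungapped codon pairs to compare")
  stops <- code[ca] == "*" | code[cb] == "*"
  if (any(stops)) {
    rlang::abort(paste0("internal stop codon at codon position ",
                        which(stops)[1]))
  }
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    sa <- ng_site_counts(ca[i], code)
    sb <- ng_site_counts(cb[i], code)
    S <- S + (sa[["S"]] + sb[["S"]]) / 2
    N <- N + (sa[["N"]] + sb[["N"]]) / 2
    d <- ng_pair_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(ka = jc(pn), ks = jc(ps),
       saturated_ka = pn >= 3 / 4, saturated_ks = ps >= 3 / 4,
       S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       n_codons = length(ca))
}

#' Date a duplication from synonymous divergence
#'
#' Molecular-clock dating `T = Ks / (2 * lambda)`, reported in million
#' years and rounded to 2 decimals (round-half-even). The default rate is
#' 1.5e-8 synonymous substitutions per site per year, the clock used for
#' tomato and soybean paralog dating.
#'
#' @param ks Numeric vector of Ks values (>= 0; NA allowed, propagated).
#' @param lambda_rate Synonymous substitution rate per site per year.
#' @return Numeric vector of times in Mya, rounded to 2 decimals.
#' @export
date_duplication <- function(ks, lambda_rate = 1.5e-8) {
  stopifnot(lambda_rate > 0)
  if (any(ks < 0, na.rm = TRUE)) rlang::abort("negative Ks")
  round(ks / (2 * lambda_rate) / 1e6, 2)
}

#' Build a paralog-pair report (Ks, age, duplication type)
#'
#' One row per pair with the species, both gene ids, Ka/Ks, duplication
#' classification and clock age; rows ordered by (species, gene_a,
#' gene_b). Ks values can either be supplied directly in a `ks` column of
#' `pairs` (e.g. previously published estimates) or estimated with
#' [nei_gojobori()] from aligned CDS.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` and optionally `ks`.
#' @param gene_table Gene table with `order_index` (see
#'   [read_gene_table()]).
#' @param blocks Synteny block table or `NULL`.
#' @param cds Named character vector of CDS sequences (aligned within each
#'   pair), or `NULL` if `pairs$ks` is supplied.
#' @param lambda_rate Clock rate passed to [date_duplication()].
#' @return Tibble: `species, gene_a, gene_b, ka, ks, dup_type, time_mya,
#'   saturated`.
#' @export
build_pair_report <- function(pairs, gene_table, blocks = NULL, cds = NULL,
                              lambda_rate = 1.5e-8) {
  cols <- c("species", "gene_a", "gene_b", "ka", "ks", "dup_type",
            "time_mya", "saturated")
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(species = character(), gene_a = character(),
                          gene_b = character(), ka = numeric(),
                          ks = numeric(), dup_type = character(),
                          time_mya = numeric(), saturated = logical()))
  }
  rows <- purrr::pmap(pairs, function(gene_a, gene_b, ...) {
    extra <- list(...)
    sp <- gene_table$species[gene_table$gene_id == gene_a]
    if (length(sp) != 1L) rlang::abort(paste0("gene not in table: ", gene_a))
    ka <- NA_real_
    saturated <- FALSE
    if (!is.null(extra$ks) && !is.na(extra$ks)) {
      ks <- extra$ks
    } else if (!is.null(cds)) {
      if (!all(c(gene_a, gene_b) %in% names(cds))) {
        rlang::abort(paste0("CDS missing for pair ", gene_a, "-", gene_b))
      }
      est <- nei_gojobori(cds[[gene_a]], cds[[gene_b]])
      ks <- est$ks
      ka <- est$ka
      saturated <- est$saturated_ks
    } else {
      rlang::abort("either pairs$ks or cds must be provided")
    }
    tibble::tibble(
      species = sp, gene_a = gene_a, gene_b = gene_b, ka = ka, ks = ks,
      dup_type = classify_pair(gene_a, gene_b, gene_table, blocks),
      time_mya = if (is.na(ks)) NA_real_
                 else date_duplication(ks, lambda_rate),
      saturated = saturated
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$species, .data$gene_a, .data$gene_b) |>
    (\(x) x[cols])()
}

#' Thread a protein alignment back onto coding sequences
#'
#' pal2nal-style: each aligned residue becomes its source codon, each gap
#' a `---` triplet; a trailing stop codon on the CDS is stripped.
#'
#' @param protein_alignment Named character vector of aligned proteins.
#' @param cds Named character vector of ungapped CDS (same ids).
#' @return Named character vector of aligned codon sequences.
#' @export
thread_codon_alignment <- function(protein_alignment, cds) {
  check_alignment(protein_alignment)
  missing <- setdiff(names(protein_alignment), names(cds))
  if (length(missing) > 0L) {
    rlang::abort(paste0("CDS missing for: ", paste(missing, collapse = ", ")))
  }
  code <- codon_table()
  out <- vapply(names(protein_alignment), function(id) {
    prot <- strsplit(protein_alignment[[id]], "")[[1]]
    dna <- toupper(cds[[id]])
    if (nchar(dna) %% 3 != 0) {
      rlang::abort(paste0("CDS length of ", id, " not divisible by 3"))
    }
    codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
    if (code[[codons[length(codons)]]] == "*") {
      codons <- codons[-length(codons)]
    }
    if (sum(prot != "-") != length(codons)) {
      rlang::abort(paste0("protein/CDS length mismatch for ", id))
    }
    res <- character(length(prot))
    res[prot == "-"] <- "---"
    res[prot != "-"] <- codons
    paste(res, collapse = "")
  }, character(1))
  setNames(out, names(protein_alignment))
}
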
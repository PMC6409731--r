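#' Construct a gene model
#'
#' A minimal transcript model: ordered exon and CDS intervals (1-based
#' inclusive genomic coordinates). Intervals must be non-overlapping; they
#' are stored sorted in transcription order (ascending coordinates on `+`,
#' descending on `-`), and the total CDS length must be divisible by 3.
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Data frames (or tibbles) with `start` and `end`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  norm <- function(x) {
    x <- as.data.frame(x)[c("start", "end")]
    if (any(x$start > x$end)) rlang::abort("interval start > end")
    x <- x[order(x$start), ]
    if (nrow(x) > 1L && any(x$start[-1] <= x$end[-nrow(x)])) {
      rlang::abort(paste0("overlapping intervals in ", gene_id))
    }
    if (strand == "-") x <- x[rev(seq_len(nrow(x))), ]
    rownames(x) <- NULL
    x
  }
  cds <- norm(cds)
  exons <- norm(exons)
  if (sum(cds$end - cds$start + 1L) %% 3L != 0L) {
    rlang::abort(paste0("CDS length of ", gene_id, " not divisible by 3"))
  }
  structure(list(gene_id = gene_id, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' Intron positions and phases of a gene model
#'
#' Introns are the gaps between consecutive CDS intervals in transcription
#' order. The phase is the cumulative CDS length upstream of the intron
#' modulo 3 (0 = between codons, 1/2 = after the first/second nucleotide
#' of a codon); the codon index is the 1-based codon into which (or after
#' which) the intron falls.
#'
#' @param model A [gene_model()].
#' @return Tibble: `gene_id, intron_index, codon_index, phase,
#'   genomic_start, genomic_end, length` (zero rows for intronless genes).
#' @export
intron_phases <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  cds <- model$cds
  n <- nrow(cds)
  if (n < 2L) {
    return(tibble::tibble(gene_id = character(), intron_index = integer(),
                          codon_index = integer(), phase = integer(),
                          genomic_start = integer(), genomic_end = integer(),
                          length = integer()))
  }
  lens <- cds$end - cds$start + 1L
  upstream <- cumsum(lens)[-n]
  if (model$strand == "+") {
    gs <- cds$end[-n] + 1L
    ge <- cds$start[-1L] - 1L
  } else {
    gs <- cds$end[-1L] + 1L
    ge <- cds$start[-n] - 1L
  }
  if (any(ge < gs)) rlang::abort("adjacent CDS intervals with no intron gap")
  tibble::tibble(
    gene_id = model$gene_id,
    intron_index = seq_len(n - 1L),
    codon_index = as.integer(ceiling((upstream + 1L) / 3L)),
    phase = as.integer(upstream %% 3L),
    genomic_start = as.integer(gs),
    genomic_end = as.integer(ge),
    length = as.integer(ge - gs + 1L)
  )
}

#' Detect candidate intron-retention events between two paralogs
#'
#' After duplication one paralog may splice out an intron that the other
#' retains in its mature transcript, translated in frame. Structurally
#' this shows up as: paralog X has an intron boundary at some protein
#' position, while paralog Y has no intron there and instead carries a run
#' of extra residues (an insertion relative to X in the protein alignment)
#' starting at the homologous position. Events are reported when the
#' inserted run is at least `min_codons` long, begins within
#' `position_tolerance` alignment columns of the intron position, and Y
#' has no intron of its own inside the run.
#'
#' @param model_a,model_b [gene_model()]s of the paralog pair.
#' @param protein_alignment Named character vector of the two aligned
#'   protein sequences (ids = gene ids).
#' @param min_codons Minimum retained-segment length in codons (default 6).
#' @param position_tolerance Allowed offset (alignment columns) between
#'   the intron position and the start of the inserted run.
#' @param min_identity Minimum fraction of identical residues over shared
#'   columns; below this the pair is considered unalignable (error).
#' @return Tibble: one row per event with `retained_in, spliced_in,
#'   intron_index, aln_start, aln_end, codons_retained,
#'   retained_from, retained_to` (protein coordinates in the retaining
#'   paralog).
#' @export
detect_intron_retention <- function(model_a, model_b, protein_alignment,
                                    min_codons = 6L,
                                    position_tolerance = 2L,
                                    min_identity = 0.3) {
  stopifnot(inherits(model_a, "gene_model"), inherits(model_b, "gene_model"))
  ids <- c(model_a$gene_id, model_b$gene_id)
  if (!setequal(names(protein_alignment), ids)) {
    rlang::abort("protein_alignment ids must match the two gene models")
  }
  check_alignment(protein_alignment)
  a <- strsplit(protein_alignment[[ids[1]]], "")[[1]]
  b <- strsplit(protein_alignment[[ids[2]]], "")[[1]]
  shared <- a != "-" & b != "-"
  if (sum(shared) == 0L || mean(a[shared] == b[shared]) < min_identity) {
    rlang::abort(paste0("pair ", ids[1], "/", ids[2],
                        " below identity floor (", min_identity, ")"))
  }
  col_of_residue <- function(chars) which(chars != "-")
  events <- list()
  scan_direction <- function(mx, my, x, y, xid, yid) {
    # x retains nothing; y may have inserted runs; mx introns mark donors
    ix <- intron_phases(mx)
    iy <- intron_phases(my)
    runs <- insertion_runs(x, y)
    if (nrow(runs) == 0L || nrow(ix) == 0L) return(NULL)
    xcols <- col_of_residue(x)
    ycols <- col_of_residue(y)
    out <- list()
    for (r in seq_len(nrow(runs))) {
      len <- runs$end[r] - runs$start[r] + 1L
      if (len < min_codons) next
      for (k in seq_len(nrow(ix))) {
        # the intron sits before (phase 0) or inside (phase 1/2) residue
        # codon_index, i.e. just after residue codon_index - 1; a retained
        # version shows as an insertion starting at the next column
        ci <- ix$codon_index[k]
        if (ci > length(xcols) + 1L) next
        expected_start <- if (ci <= 1L) 1L else xcols[ci - 1L] + 1L
        if (abs(runs$start[r] - expected_start) > position_tolerance) next
        # y must not carry its own intron inside the run
        y_from <- match(runs$start[r], ycols)
        y_to <- match(runs$end[r], ycols)
        if (nrow(iy) > 0L &&
            any(iy$codon_index >= y_from & iy$codon_index <= y_to)) next
        out[[length(out) + 1L]] <- tibble::tibble(
          retained_in = yid, spliced_in = xid,
          intron_index = ix$intron_index[k],
          aln_start = runs$start[r], aln_end = runs$end[r],
          codons_retained = len,
          retained_from = y_from, retained_to = y_to)
        break
      }
    }
    if (length(out) > 0L) dplyr::bind_rows(out) else NULL
  }
  ev <- dplyr::bind_rows(
    scan_direction(model_a, model_b, a, b, ids[1], ids[2]),
    scan_direction(model_b, model_a, b, a, ids[2], ids[1])
  )
  if (nrow(ev) == 0L) {
    return(tibble::tibble(retained_in = character(), spliced_in = character(),
                          intron_index = integer(), aln_start = integer(),
                          aln_end = integer(), codons_retained = integer(),
                          retained_from = integer(), retained_to = integer()))
  }
  dplyr::distinct(ev)
}

# maximal runs of columns gapped in x but occupied in y
insertion_runs <- function(x, y) {
  ins <- x == "-" & y != "-"
  if (!any(ins)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(ins)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}
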
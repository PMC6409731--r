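#' Read a FASTA file into a named sequence vector
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"dna"` or `"protein"`; recorded as an attribute
#'   and used for light validation (DNA restricted to `ACGTN-`).
#' @return A named character vector of uppercase sequences with attribute
#'   `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) rlang::abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate sequence id(s): ",
                        paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) rlang::abort("empty sequence record")
  if (alphabet == "dna" &&
      any(grepl("[^ACGTN-]", seqs))) {
    rlang::abort("non-ACGTN character in DNA sequences")
  }
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con)
  }
  invisible(path)
}

#' Read a gene coordinate table and assign gene order
#'
#' Accepts either a 6-column TSV with header
#' `gene_id, species, chromosome, strand, start, end` or a GFF3 file
#' (feature type `gene`, gene id from the `ID`/`Name` attribute; species
#' supplied via `species`). Coordinates are 1-based inclusive. A 0-based
#' `order_index` is assigned per `(species, chromosome)` by ascending start
#' coordinate, ties broken by lexicographic `gene_id`; gene order is
#' strand-agnostic because intervening-gene counts (the tandem rule) are.
#'
#' @param path Path to the TSV or GFF3 file.
#' @param species Species label used for every record when reading GFF3
#'   (GFF3 files carry no species column).
#' @return A tibble of gene records with an `order_index` column.
#' @export
read_gene_table <- function(path, species = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (grepl("^##gff-version", first)) {
    tab <- read_gff_genes(path, species = species)
  } else {
    tab <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
    needed <- c("gene_id", "species", "chromosome", "strand", "start", "end")
    missing <- setdiff(needed, names(tab))
    if (length(missing) > 0L) {
      rlang::abort(paste0("gene table missing column(s): ",
                          paste(missing, collapse = ", ")))
    }
    tab <- tab[needed]
  }
  validate_gene_table(tab)
  assign_order_index(tab)
}

read_gff_genes <- function(path, species = NULL) {
  if (is.null(species)) rlang::abort("`species` is required when reading GFF3")
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
  ids <- as.character(gr$ID)
  if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  tibble::tibble(
    gene_id    = ids,
    species    = species,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand     = as.character(GenomicRanges::strand(gr)),
    start      = GenomicRanges::start(gr),
    end        = GenomicRanges::end(gr)
  )
}

validate_gene_table <- function(tab) {
  if (any(tab$start > tab$end)) {
    bad <- tab$gene_id[tab$start > tab$end]
    rlang::abort(paste0("start > end for gene(s): ", paste(bad, collapse = ", ")))
  }
  if (any(tab$start < 1L)) rlang::abort("coordinates must be positive (1-based)")
  if (!all(tab$strand %in% c("+", "-"))) {
    rlang::abort("strand must be '+' or '-'")
  }
  key <- paste(tab$species, tab$gene_id)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicate gene_id within species: ",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  invisible(tab)
}

assign_order_index <- function(tab) {
  tab |>
    dplyr::group_by(.data$species, .data$chromosome) |>
    dplyr::arrange(.data$start, .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(order_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that check
#' parenthesis balance up front (reporting the character offset of the
#' first imbalance) and write branch lengths to 6 decimal places so that a
#' write/read round trip preserves topology, lengths and support labels.
#'
#' @param path Path to a Newick file (one tree).
#' @return For `read_newick`, an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_balance(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) rlang::abort(paste0("could not parse Newick in ", path))
  tr
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      rlang::abort(paste0("unbalanced ')' at character ", i))
    }
  }
  if (depth != 0L) {
    rlang::abort(paste0("unbalanced '(': ", depth,
                        " unclosed at end of input (length ",
                        length(chars), ")"))
  }
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a synteny block table
#'
#' Expects a TSV with header columns
#' `block_id, species_a, gene_a, species_b, gene_b`; each gene pair may
#' appear at most once per block.
#'
#' @param path Path to the TSV file.
#' @return A tibble of block rows.
#' @export
read_block_table <- function(path) {
  tab <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  needed <- c("block_id", "species_a", "gene_a", "species_b", "gene_b")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    rlang::abort(paste0("block table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  key <- paste(tab$block_id, tab$gene_a, tab$gene_b)
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (gene_a, gene_b) pair within a block_id")
  }
  tab[needed]
}

#' Write a tibble as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map gene ids to species labels with a regex
#'
#' Convenience for inputs where the species is encoded in the gene id
#' (e.g. `Glyma.`, `Solyc`): the first regex that matches assigns its
#' species label.
#'
#' @param gene_ids Character vector of gene ids.
#' @param rules Named character vector: `species_label = regex`.
#' @return Character vector of species labels (`NA` where nothing matched).
#' @export
species_from_id <- function(gene_ids, rules) {
  out <- rep(NA_character_, length(gene_ids))
  for (sp in names(rules)) {
    hit <- is.na(out) & grepl(rules[[sp]], gene_ids)
    out[hit] <- sp
  }
  out
}
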
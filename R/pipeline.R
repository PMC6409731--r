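#' Read a gene -> species map from TSV
#'
#' Two columns with header `gene`, `species`.
#'
#' @param path TSV path.
#' @return Named character vector (names = genes).
#' @export
read_species_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "species") %in% names(tab)))
  setNames(tab$species, tab$gene)
}

#' Read gene models from a CDS-interval TSV
#'
#' One row per CDS piece with header `gene_id, strand, start, end`
#' (1-based inclusive).
#'
#' @param path TSV path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "strand", "start", "end") %in% names(tab)))
  by_gene <- split(tab, tab$gene_id)
  lapply(by_gene, function(d) {
    gene_model(d$gene_id[1], d$strand[1],
               exons = d[c("start", "end")], cds = d[c("start", "end")])
  })
}

#' Run the analysis pipeline from a declarative configuration
#'
#' Stages (any subset): `tree` (NJ + bootstrap from a protein alignment),
#' `reconcile` (duplication-loss reconciliation), `dupdate` (pair
#' classification, Ka/Ks, dating), `selection` (codon site model +
#' per-site posterior omega), `introns` (intron phases), `expression`
#' (log10 FPKM matrix and 2^-ddCT table). All referenced input files are
#' checked before any stage runs; any stage failure aborts with the stage
#' named. Numeric outputs are written as TSV/Newick/JSON into `out_dir`
#' and a JSON manifest records package version, configuration hash, seeds
#' and per-stage status, so identical configurations reproduce identical
#' outputs.
#'
#' @param config A nested list (or path to a YAML file): `out_dir`, and a
#'   `stages` list keyed by stage name with per-stage inputs/parameters.
#' @return The manifest as a tibble (one row per stage), invisibly also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% list()

  # pre-flight: every referenced input must exist before any work starts
  inputs <- unlist(lapply(stages, function(s) {
    s[names(s) %in% c("alignment", "gene_tree", "species_tree", "map",
                      "pairs", "genes", "blocks", "cds", "tree",
                      "models", "fpkm", "ct")]
  }), use.names = TRUE)
  inputs <- as.character(inputs %||% character(0))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    rlang::abort(paste0("missing input file(s): ",
                        paste(unique(missing), collapse = ", ")))
  }

  rows <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) {
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = name, status = "ok",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = paste(outputs, collapse = ";"))
  }

  if (!is.null(stages$tree)) run_stage("tree", function() {
    s <- stages$tree
    aln <- read_fasta(s$alignment, alphabet = "protein")
    tr <- bootstrap_support(aln, n_reps = s$bootstrap %||% 1000L,
                            seed = s$seed %||% 1L)
    write_newick(tr, file.path(out_dir, "tree.nwk"))
  })

  if (!is.null(stages$reconcile)) run_stage("reconcile", function() {
    s <- stages$reconcile
    gt <- read_newick(s$gene_tree)
    if (!ape::is.rooted(gt)) gt <- midpoint_root(gt)
    recon <- lca_reconcile(gt, read_newick(s$species_tree),
                           read_species_map(s$map))
    write_tsv_file(family_census(recon), file.path(out_dir, "census.tsv"))
  })

  if (!is.null(stages$dupdate)) run_stage("dupdate", function() {
    s <- stages$dupdate
    pairs <- tibble::as_tibble(read.delim(s$pairs,
                                          stringsAsFactors = FALSE))
    genes <- read_gene_table(s$genes)
    blocks <- if (!is.null(s$blocks)) read_block_table(s$blocks) else NULL
    cds <- if (!is.null(s$cds)) read_fasta(s$cds, alphabet = "dna") else NULL
    rep <- build_pair_report(pairs, genes, blocks, cds,
                             lambda_rate = s$lambda %||% 1.5e-8)
    write_tsv_file(rep, file.path(out_dir, "pair_report.tsv"))
  })

  if (!is.null(stages$selection)) run_stage("selection", function() {
    s <- stages$selection
    aln <- read_fasta(s$cds, alphabet = "dna")
    fit <- fit_site_model(aln, read_newick(s$tree),
                          model = s$model %||% "M8", K = s$K %||% 8L)
    f1 <- write_tsv_file(posterior_site_omega(fit),
                         file.path(out_dir, "site_omega.tsv"))
    f2 <- file.path(out_dir, "selection_fit.json")
    jsonlite::write_json(list(model = fit$model, K = fit$K,
                              params = fit$params, kappa = fit$kappa,
                              branch_scale = fit$scale, logL = fit$logL,
                              AIC = fit$aic,
                              convergence = fit$convergence),
                         f2, auto_unbox = TRUE, digits = NA)
    c(f1, f2)
  })

  if (!is.null(stages$introns)) run_stage("introns", function() {
    s <- stages$introns
    models <- read_gene_models_tsv(s$models)
    ann <- dplyr::bind_rows(lapply(models, intron_phases))
    write_tsv_file(ann, file.path(out_dir, "intron_phases.tsv"))
  })

  if (!is.null(stages$expression)) run_stage("expression", function() {
    s <- stages$expression
    outputs <- character(0)
    if (!is.null(s$fpkm)) {
      fpkm <- read.delim(s$fpkm, stringsAsFactors = FALSE)
      em <- log_transform(fpkm, pseudocount = s$pseudocount %||% 1,
                          normalize = s$normalize %||% "none")
      outputs <- c(outputs, write_tsv_file(
        tibble::as_tibble(em$transformed, rownames = "gene"),
        file.path(out_dir, "expression_log10.tsv")))
    }
    if (!is.null(s$ct)) {
      ct <- tibble::as_tibble(read.delim(s$ct, stringsAsFactors = FALSE))
      dd <- ddct_table(ct, reference_gene = s$reference_gene,
                       control = s$control %||% "control")
      outputs <- c(outputs, write_tsv_file(
        dd, file.path(out_dir, "ddct.tsv")))
    }
    outputs
  })

  manifest <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(stage = character(), status = character(),
                   elapsed_s = numeric(), outputs = character())
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("famevol")),
    config_hash = rlang::hash(config),
    seeds = unlist(lapply(stages, function(s) s$seed)),
    stages = manifest
  )
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}

#' Write a synthetic preset's input files
#'
#' Generates the files one pipeline stage consumes, with ground truth
#' alongside, so a full run can be reproduced from a seed alone.
#'
#' @param preset One of `"reconciliation"`, `"selection"`, `"layout"`,
#'   `"expression"`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created).
#' @return Named list of written file paths (plus `truth` objects).
#' @export
simulate_preset <- function(preset = c("reconciliation", "selection",
                                       "layout", "expression"),
                            seed, out_dir) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "reconciliation") {
    sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
    repeat {
      fam <- simulate_family(sp, birth_rate = 0.3, death_rate = 0.1,
                             seed = seed)
      if (!fam$extinct && !isTRUE(fam$single_copy) &&
          length(fam$species_map) >= 3L) break
      seed <- seed + 1000L
    }
    f1 <- file.path(out_dir, "species.nwk"); write_newick(sp, f1)
    f2 <- file.path(out_dir, "genes.nwk")
    write_newick(ape::unroot(fam$gene_tree), f2)
    f3 <- file.path(out_dir, "map.tsv")
    write_tsv_file(tibble::tibble(gene = names(fam$species_map),
                                  species = unname(fam$species_map)), f3)
    list(species_tree = f1, gene_tree = f2, map = f3, truth = fam)
  } else if (preset == "selection") {
    tr <- withr::with_seed(stream_seed(seed, "preset_tree"),
                           ape::rtree(8, br = function(n) runif(n, 0.05, 0.4)))
    mix <- tibble::tibble(omega = c(0.1, 0.5, 2), weight = c(0.5, 0.4, 0.1))
    sim <- simulate_codon_alignment(tr, mix, L = 120L, seed = seed)
    f1 <- file.path(out_dir, "cds_aln.fa"); write_fasta(sim$alignment, f1)
    f2 <- file.path(out_dir, "tree.nwk"); write_newick(tr, f2)
    list(cds = f1, tree = f2, truth = sim)
  } else if (preset == "layout") {
    lay <- simulate_genome_layout(seed)
    f1 <- file.path(out_dir, "genes.tsv"); write_tsv_file(lay$gene_table, f1)
    f2 <- file.path(out_dir, "blocks.tsv"); write_tsv_file(lay$blocks, f2)
    f3 <- file.path(out_dir, "pairs.tsv")
    write_tsv_file(lay$truth[c("gene_a", "gene_b")], f3)
    list(genes = f1, blocks = f2, pairs = f3, truth = lay$truth)
  } else {
    sim <- simulate_expression(seed)
    f1 <- file.path(out_dir, "fpkm.tsv")
    write_tsv_file(tibble::as_tibble(sim$fpkm, rownames = "gene"), f1)
    f2 <- file.path(out_dir, "ct.tsv"); write_tsv_file(sim$ct, f2)
    list(fpkm = f1, ct = f2, truth = sim$truth)
  }
}
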
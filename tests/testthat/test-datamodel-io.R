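test_that("FASTA reading takes the first header token and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_equal(unname(read_fasta(f)["a"]), "ACGT")

  writeLines(c(">a some description", "AC", "GT", ">b", "GGGG"), f)
  s <- read_fasta(f)
  expect_equal(names(s), c("a", "b"))
  expect_equal(unname(s["a"]), "ACGT")
})

test_that("FASTA reading rejects duplicate ids and empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA write/read round-trips random sequence sets", {
  withr::with_seed(11, {
    for (i in 1:5) {
      n <- sample(2:8, 1)
      seqs <- setNames(
        vapply(seq_len(n), function(j) {
          paste(sample(c("A", "C", "G", "T"), sample(10:200, 1),
                       replace = TRUE), collapse = "")
        }, character(1)),
        paste0("seq", seq_len(n)))
      f <- tempfile(fileext = ".fa")
      write_fasta(seqs, f)
      back <- read_fasta(f)
      expect_equal(unclass(back)[names(seqs)], unclass(seqs),
                   ignore_attr = TRUE)
      unlink(f)
    }
  })
})

test_that("gene tables get per-chromosome order indices with the tie rule", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    species = "sp",
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    strand = c("+", "-", "+", "+", "-"),
    start = c(500, 100, 300, 300, 50),
    end = c(600, 200, 400, 400, 80))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_gene_table(f)
  expect_equal(g$order_index[g$gene_id == "g2"], 0L)
  expect_equal(g$order_index[g$gene_id == "g1"], 1L)
  # both chromosomes restart at 0
  expect_equal(sort(g$order_index[g$chromosome == "chr2"]), 0:2)
  # tie at start 300 broken lexicographically: g3 before g4
  expect_lt(g$order_index[g$gene_id == "g3"],
            g$order_index[g$gene_id == "g4"])
  # order_index is a permutation of 0..n-1 per chromosome
  for (cn in unique(g$chromosome)) {
    oi <- sort(g$order_index[g$chromosome == cn])
    expect_equal(oi, seq_along(oi) - 1L)
  }
})

test_that("gene table validation rejects bad coordinates and strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- data.frame(gene_id = "g1", species = "sp", chromosome = "c",
                    strand = "+", start = 10, end = 5)
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(f), "start > end.*g1")
  bad$start <- 1; bad$strand <- "?"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(f), "strand")
})

test_that("Newick round trip preserves topology, lengths and support", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a:1,(b:2,c:3):4);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_true(4 %in% tr$edge.length)

  withr::with_seed(7, {
    for (i in 1:5) {
      tr <- ape::rtree(sample(4:12, 1))
      tr$node.label <- c("", as.character(
        sample(0:100, tr$Nnode - 1, replace = TRUE)))
      write_newick(tr, f)
      back <- read_newick(f)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back))[1], 0)
      expect_equal(sort(back$edge.length), sort(round(tr$edge.length, 6)),
                   tolerance = 1e-9)
      expect_setequal(back$node.label, tr$node.label)
    }
  })
})

test_that("unbalanced Newick input fails with a character offset", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b);", f)
  expect_error(read_newick(f), "unbalanced")
  writeLines("(a,b));", f)
  expect_error(read_newick(f), "character 6")
})

test_that("synteny block tables reject duplicated pairs per block", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(block_id = c("b1", "b1"), species_a = "s",
                    gene_a = c("x", "x"), species_b = "s",
                    gene_b = c("y", "y"))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_block_table(f), "duplicate")
  tab$gene_b <- c("y", "z")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_block_table(f)), 2L)
})

test_that("species ids can be mapped from gene-id prefixes", {
  ids <- c("Glyma.08G075900", "Solyc01g104780", "AT1G21140")
  out <- species_from_id(ids, c(soybean = "^Glyma", tomato = "^Solyc"))
  expect_equal(out, c("soybean", "tomato", NA))
})

test_that("GFF3 gene features become gene records with assigned order", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t600\t.\t+\t.\tID=gA",
               "chr1\tsrc\tgene\t700\t900\t.\t-\t.\tID=gB",
               "chr2\tsrc\tgene\t50\t80\t.\t+\t.\tID=gC"), f)
  g <- read_gene_table(f, species = "sp")
  expect_equal(g$gene_id, c("gA", "gB", "gC"))
  expect_equal(g$order_index, c(0L, 1L, 0L))
  expect_error(read_gene_table(f), "species")
})
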
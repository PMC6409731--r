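test_that("intron phases follow cumulative CDS length mod 3", {
  # 99 + 150 nt: intron after a full codon -> phase 0
  m <- gene_model("g0", "+",
                  exons = data.frame(start = c(1, 200), end = c(99, 349)),
                  cds = data.frame(start = c(1, 200), end = c(99, 349)))
  ann <- intron_phases(m)
  expect_equal(ann$phase, 0L)
  expect_equal(ann$codon_index, 34L)
  expect_equal(ann$genomic_start, 100L)
  expect_equal(ann$genomic_end, 199L)

  # 100 + 149 nt: phase 1
  m1 <- gene_model("g1", "+",
                   exons = data.frame(start = c(1, 200), end = c(100, 348)),
                   cds = data.frame(start = c(1, 200), end = c(100, 348)))
  expect_equal(intron_phases(m1)$phase, 1L)

  # single-exon gene: no introns
  m2 <- gene_model("g2", "+", exons = data.frame(start = 1, end = 300),
                   cds = data.frame(start = 1, end = 300))
  expect_equal(nrow(intron_phases(m2)), 0L)
})

test_that("minus-strand models are read in transcription order", {
  # transcription right to left: upstream piece is the high-coordinate one
  m <- gene_model("gm", "-",
                  exons = data.frame(start = c(1, 200), end = c(102, 298)),
                  cds = data.frame(start = c(1, 200), end = c(102, 298)))
  ann <- intron_phases(m)
  # upstream CDS length is 99 (the 200-298 piece) -> phase 0
  expect_equal(ann$phase, 0L)
  expect_equal(ann$genomic_start, 103L)
  expect_equal(ann$genomic_end, 199L)
})

test_that("gene models enforce interval and frame invariants", {
  expect_error(gene_model("bad", "+",
                          exons = data.frame(start = c(1, 50), end = c(60, 99)),
                          cds = data.frame(start = c(1, 50), end = c(60, 99))),
               "overlap")
  expect_error(gene_model("bad2", "+",
                          exons = data.frame(start = 1, end = 100),
                          cds = data.frame(start = 1, end = 100)),
               "divisible")
})

test_that("planted retained introns are recovered at the right coordinates", {
  for (seed in c(1, 7, 23)) {
    sim <- simulate_retention_pair(seed)
    ev <- detect_intron_retention(sim$model_a, sim$model_b, sim$alignment)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$retained_in, sim$truth$retained_in)
    expect_equal(ev$aln_start, sim$truth$aln_start)
    expect_equal(ev$aln_end, sim$truth$aln_end)
    expect_equal(ev$codons_retained, sim$truth$codons_retained)
    # symmetric in argument order (same event, same polarity)
    ev2 <- detect_intron_retention(sim$model_b, sim$model_a,
                                   sim$alignment)
    expect_equal(ev2$retained_in, ev$retained_in)
    expect_equal(ev2$aln_start, ev$aln_start)
  }
})

test_that("identical models and shared introns produce no events", {
  sim <- simulate_retention_pair(5)
  aln_id <- setNames(rep(gsub("-", "", sim$alignment[["geneA"]]), 2),
                     c("geneA", "geneB"))
  # same model on both sides: no retention
  ev <- detect_intron_retention(sim$model_a, sim$model_a_copy %||% {
    m <- sim$model_a; m$gene_id <- "geneB"; m
  }, aln_id)
  expect_equal(nrow(ev), 0L)
})

test_that("unalignable pairs fail the identity floor", {
  sim <- simulate_retention_pair(9)
  aln <- sim$alignment
  aln[["geneA"]] <- paste(rev(strsplit(aln[["geneA"]], "")[[1]]),
                          collapse = "")
  expect_error(detect_intron_retention(sim$model_a, sim$model_b, aln,
                                       min_identity = 0.9),
               "identity")
})

test_that("short in-frame insertions below the codon floor are not called", {
  sim <- simulate_retention_pair(13, retained_codons = 4L)
  ev <- detect_intron_retention(sim$model_a, sim$model_b, sim$alignment,
                                min_codons = 6L)
  expect_equal(nrow(ev), 0L)
})
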
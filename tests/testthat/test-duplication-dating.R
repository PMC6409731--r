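make_gene_table <- function(ids_per_chr) {
  tab <- dplyr::bind_rows(lapply(names(ids_per_chr), function(cn) {
    ids <- ids_per_chr[[cn]]
    tibble::tibble(gene_id = ids, species = "sp", chromosome = cn,
                   strand = "+", start = seq_along(ids) * 100L,
                   end = seq_along(ids) * 100L + 50L)
  }))
  famevol:::assign_order_index(tab)
}

test_that("tandem classification follows the fewer-than-five-genes rule", {
  gt <- make_gene_table(list(chr1 = paste0("g", 1:20)))
  # adjacent
  expect_equal(classify_pair("g1", "g2", gt), "tandem")
  # 4 intervening genes
  expect_equal(classify_pair("g1", "g6", gt), "tandem")
  # exactly 5 intervening genes: not tandem
  expect_equal(classify_pair("g1", "g7", gt), "transposition")
  # symmetric
  expect_equal(classify_pair("g6", "g1", gt), "tandem")
  expect_error(classify_pair("g1", "nope", gt), "nope")
})

test_that("shared blocks give segmental, with tandem taking precedence", {
  gt <- make_gene_table(list(chr1 = paste0("a", 1:10),
                             chr2 = paste0("b", 1:10)))
  blocks <- tibble::tibble(block_id = "blk1", species_a = "sp",
                           gene_a = c("a1", "a2"), species_b = "sp",
                           gene_b = c("b1", "b2"))
  expect_equal(classify_pair("a1", "b1", gt, blocks), "segmental")
  # both genes in the same block though not paired directly
  expect_equal(classify_pair("a1", "b2", gt, blocks), "segmental")
  # tandem proximity wins over block membership
  expect_equal(classify_pair("a1", "a2", gt, blocks), "tandem")
  expect_equal(classify_pair("a1", "b3", gt, blocks), "transposition")
})

test_that("Nei-Gojobori handles the hand-checkable cases", {
  ng0 <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(c(ng0$ka, ng0$ks), c(0, 0))
  # Asp -> Glu, third-position nonsynonymous change
  ng1 <- nei_gojobori("GAT", "GAA")
  expect_equal(ng1$Sd, 0)
  expect_equal(ng1$Nd, 1)
  expect_error(nei_gojobori("ATGTAAGG T", "ATGTAAGGT"), "divisible|aligned")
  expect_error(nei_gojobori("ATGTAA", "ATGTAC"), "stop")
  # gapped codons dropped pairwise
  ngg <- nei_gojobori("ATG---AAA", "ATGCCCAAA")
  expect_equal(ngg$n_codons, 2)
})

test_that("Nei-Gojobori counts match the pathway-enumeration oracle", {
  cm <- famevol:::codon_machinery()
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- paste(sample(cm$codons, 3, replace = TRUE), collapse = "")
      b <- paste(sample(cm$codons, 3, replace = TRUE), collapse = "")
      got <- nei_gojobori(a, b)
      want <- ng_oracle(a, b)
      expect_equal(got$S, want$S, tolerance = 1e-12)
      expect_equal(got$N, want$N, tolerance = 1e-12)
      expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
      # Jukes-Cantor correction against the closed form
      if (!got$saturated_ks) {
        expect_equal(got$ks, -3 / 4 * log(1 - 4 * got$ps / 3),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("clock dating is linear in Ks and reproduces known pairs", {
  expect_equal(date_duplication(0.78947), 26.32)
  expect_equal(date_duplication(0.08789), 2.93)
  expect_equal(date_duplication(0), 0)
  expect_error(date_duplication(-0.1), "negative")
  withr::with_seed(3, {
    ks <- runif(20, 0, 2)
    expect_equal(date_duplication(2 * ks),
                 round(2 * (ks / (2 * 1.5e-8) / 1e6), 2))
    # inverse-linear in lambda
    expect_equal(date_duplication(ks, 3e-8),
                 round(date_duplication(ks) / 2 +
                         ks * 0, 2), tolerance = 0.011)
  })
})

test_that("pair reports combine Ks, dating and classification", {
  gt <- make_gene_table(list(chr1 = paste0("g", 1:10)))
  pairs <- tibble::tibble(gene_a = c("g1", "g9"), gene_b = c("g2", "g1"),
                          ks = c(0.3, NA))
  cds <- setNames(rep(strrep("GCT", 9), 10), paste0("g", 1:10))
  cds["g9"] <- paste0("GCA", strrep("GCT", 8))
  rep <- build_pair_report(pairs, gt, cds = cds)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$dup_type[rep$gene_a == "g1" & rep$gene_b == "g2"],
               "tandem")
  expect_equal(rep$time_mya[rep$gene_a == "g1" & rep$gene_b == "g2"],
               date_duplication(0.3))
  # second pair estimated from CDS (two synonymous third positions)
  est <- rep[rep$gene_a == "g9", ]
  expect_equal(est$ka, 0, tolerance = 1e-12)
  expect_gt(est$ks, 0)
  # empty input gives an empty typed table
  empty <- build_pair_report(pairs[0, ], gt)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("ks", "time_mya", "dup_type") %in% names(empty)))
})

test_that("saturated pairs are flagged with NA time", {
  gt <- make_gene_table(list(chr1 = c("x1", "x2")))
  # maximally diverged synonymous positions: use a hand-built saturated pair
  pairs <- tibble::tibble(gene_a = "x1", gene_b = "x2")
  cds <- c(x1 = strrep("TTA", 12), x2 = strrep("CTG", 12))
  repx <- build_pair_report(pairs, gt, cds = cds)
  if (is.na(repx$ks[1])) {
    expect_true(repx$saturated[1])
    expect_true(is.na(repx$time_mya[1]))
  } else {
    succeed("pair not saturated under NG counting; flag path not exercised")
  }
})

test_that("protein alignments thread back onto codon alignments", {
  prot <- c(p1 = "M-AK", p2 = "MGAK")
  cds <- c(p1 = "ATGGCTAAATAA", p2 = "ATGGGAGCCAAG")
  out <- thread_codon_alignment(prot, cds)
  expect_equal(unname(out["p1"]), "ATG---GCTAAA")
  expect_equal(unname(out["p2"]), "ATGGGAGCCAAG")
  expect_error(thread_codon_alignment(c(p1 = "MAKK", p2 = "MGAK"),
                                      c(p1 = "ATGGCTAAA",
                                        p2 = "ATGGGAGCCAAG")),
               "mismatch")
})
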
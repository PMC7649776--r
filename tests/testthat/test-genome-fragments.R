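test_that("digestion cuts at every motif occurrence", {
  frags <- digest_genome(c(chrA = "AAGATCGGATCT"), enzyme_preset("MboI"))
  expect_equal(frags$start, c(0L, 2L, 7L))
  expect_equal(frags$end, c(2L, 7L, 12L))
  expect_equal(frags$frag_id, 1:3)

  # HindIII cuts one base into its motif: A^AGCTT
  frags <- digest_genome(c(chrB = "TTAAGCTTGG"), enzyme_preset("HindIII"))
  expect_equal(frags$start, c(0L, 3L))
  expect_equal(frags$end, c(3L, 10L))

  # no motif occurrence: a single fragment spanning the chromosome
  frags <- digest_genome(c(chrC = "AAAAAA"), enzyme_preset("MboI"))
  expect_equal(nrow(frags), 1L)
  expect_equal(c(frags$start, frags$end), c(0L, 6L))

  # overlapping occurrences each yield a cut
  enz <- restriction_enzyme("toy", "AA", 1L)
  frags <- digest_genome(c(chrD = "CAAAAC"), enz)
  # AA at 0-based 1, 2, 3 -> cuts at 2, 3, 4
  expect_equal(frags$start, c(0L, 2L, 3L, 4L))
})

test_that("digestion rejects empty chromosomes and bad enzymes", {
  expect_error(digest_genome(c(chrA = ""), enzyme_preset("MboI")),
               "empty chromosome")
  expect_error(restriction_enzyme("bad", "GAXC", 0L), "A/C/G/T")
  expect_error(restriction_enzyme("bad", "GATC", 5L), "cut_offset")
})

test_that("fragments tile random chromosomes exactly", {
  set.seed(42)
  for (i in 1:25) {
    len <- sample(50:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    frags <- digest_genome(stats::setNames(s, "chr"), enzyme_preset("MboI"))
    expect_equal(frags$start[1], 0L)
    expect_equal(frags$end[nrow(frags)], len)
    expect_equal(sum(frags$end - frags$start), len)
    # consecutive, no gaps/overlaps; ids follow coordinate order
    expect_equal(frags$start[-1], frags$end[-nrow(frags)])
    expect_equal(frags$frag_id, seq_len(nrow(frags)))
    # deterministic: re-digesting yields the identical fragment set
    expect_identical(frags,
                     digest_genome(stats::setNames(s, "chr"),
                                   enzyme_preset("MboI")))
  }
})

test_that("locate_fragment maps positions to containing fragments", {
  frags <- toy_fragments()
  expect_equal(locate_fragment(frags, "chrA", 3L), 2L)
  expect_equal(locate_fragment(frags, "chrA", 1L), 1L)
  # a position on a cut site belongs to the fragment starting there
  expect_equal(locate_fragment(frags, "chrA", 8L), 3L)
  expect_equal(locate_fragment(frags, "chrA", c(1L, 3L, 12L)),
               c(1L, 2L, 3L))
  expect_error(locate_fragment(frags, "chrA", 13L), "out of range")
  expect_error(locate_fragment(frags, "chrA", 0L), "out of range")
  expect_error(locate_fragment(frags, "chrZ", 1L), "chrZ")
})

test_that("every valid position locates inside its fragment", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  frags <- digest_genome(c(chr = s), enzyme_preset("MboI"))
  for (pos in seq_len(500)) {
    id <- locate_fragment(frags, "chr", pos)
    row <- frags[frags$frag_id == id, ]
    expect_true(row$start <= pos - 1L && pos - 1L < row$end)
  }
})

test_that("fragment-gene overlap matches interval arithmetic", {
  frags <- toy_fragments()
  genes <- data.frame(gene_id = "G1", gene_name = "G1", chrom = "chrA",
                      start = 2L, end = 10L, strand = "+",
                      stringsAsFactors = FALSE)
  # 1-based [2,10] = 0-based [1,10): overlaps [0,2) and [2,7) and [7,12)?
  # [1,10) vs [0,2): yes; vs [2,7): yes; vs [7,12): yes on [7,10)
  res <- genes_on_fragments(frags, genes)
  expect_equal(res$map$frag_id, c(1L, 2L, 3L))

  genes2 <- data.frame(gene_id = "G2", gene_name = "G2", chrom = "chrA",
                       start = 3L, end = 6L, strand = "+",
                       stringsAsFactors = FALSE)
  res2 <- genes_on_fragments(frags, genes2)
  expect_equal(res2$map$frag_id, 2L)

  expect_equal(nrow(genes_on_fragments(frags, genes[0, ])$map), 0L)

  # unknown chromosome: skipped with a warning and a count
  genes3 <- rbind(genes, data.frame(gene_id = "G3", gene_name = "G3",
                                    chrom = "chrZ", start = 1L, end = 5L,
                                    strand = "+", stringsAsFactors = FALSE))
  expect_warning(res3 <- genes_on_fragments(frags, genes3), "skipped")
  expect_equal(res3$n_skipped, 1L)
  expect_equal(unique(res3$map$gene_id), "G1")
})

test_that("fragment-gene overlap agrees with brute-force all-pairs check", {
  set.seed(13)
  for (rep in 1:5) {
    len <- 400L
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    frags <- digest_genome(c(chr1 = s), enzyme_preset("MboI"))
    n_genes <- sample(3:20, 1)
    starts <- sample(seq_len(len - 10L), n_genes)
    genes <- data.frame(
      gene_id = sprintf("G%02d", seq_len(n_genes)),
      gene_name = sprintf("G%02d", seq_len(n_genes)),
      chrom = "chr1", start = starts,
      end = pmin(len, starts + sample(1:50, n_genes, replace = TRUE)),
      strand = "+", stringsAsFactors = FALSE)
    got <- genes_on_fragments(frags, genes)$map
    want <- frag_gene_overlap_oracle(frags, genes)
    expect_equal(got, want)
  }
})

test_that("fragment BED round-trips", {
  frags <- toy_fragments()
  path <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(frags, path)
  expect_equal(read_fragments_bed(path), frags)
})

test_that("SNP table loading applies the GWAS significance cut-off", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tphenotype\tgwas_p",
               "rs1\tchr1\t100\tADHD\t1e-8",
               "rs2\tchr1\t200\tADHD\t1e-6",
               "rs3\tchr1\t300\tSCZ\t2e-6"), path)
  snps <- read_snp_table(path)
  expect_equal(snps$rsid, c("rs1", "rs2"))
})
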
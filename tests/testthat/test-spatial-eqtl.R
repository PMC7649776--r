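make_pair_fixture <- function() {
  snps <- data.frame(rsid = c("rs1", "rs2"), chrom = c("chr1", "chr1"),
                     pos = c(100L, 500L),
                     phenotype = c("ADHD", "SCZ"),
                     gwas_p = 1e-8, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "G2"), gene_name = c("G1", "G2"),
                      chrom = c("chr1", "chr2"),
                      start = c(1000L, 50L), end = c(2000L, 90L),
                      strand = "+", stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}

test_that("spatial pairs union supporting libraries across captures", {
  captures <- rbind(
    data.frame(rsid = "rs1", library_id = "libA", partner_chrom = "chr1",
               partner_frag = 9L, n_contacts = 2L, self_contact = FALSE),
    data.frame(rsid = "rs1", library_id = "libB", partner_chrom = "chr1",
               partner_frag = 9L, n_contacts = 1L, self_contact = FALSE),
    data.frame(rsid = "rs2", library_id = "libA", partner_chrom = "chr1",
               partner_frag = 2L, n_contacts = 1L, self_contact = FALSE))
  map <- data.frame(chrom = "chr1", frag_id = 9L, gene_id = "G1",
                    stringsAsFactors = FALSE)
  pairs <- build_pairs(captures, map)
  # rs2's partner fragment carries no gene -> no pair
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$libraries, "libA,libB")
  expect_equal(pairs$n_libraries, 2L)

  # a partner fragment carrying two genes expands to two pairs
  map2 <- rbind(map, data.frame(chrom = "chr1", frag_id = 9L,
                                gene_id = "G9", stringsAsFactors = FALSE))
  expect_equal(nrow(build_pairs(captures, map2)), 2L)
})

test_that("interaction classification respects the 1 Mb cis boundary", {
  snps <- data.frame(rsid = c("rs_cis", "rs_trans", "rs_inter", "rs_in"),
                     chrom = c("chr1", "chr1", "chr2", "chr1"),
                     pos = c(1L, 1L, 10L, 1500000L),
                     phenotype = "ADHD", gwas_p = 1e-8,
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "G1", gene_name = "G1", chrom = "chr1",
                      start = 1000000L, end = 2000000L, strand = "+",
                      stringsAsFactors = FALSE)
  pairs <- data.frame(rsid = snps$rsid, gene_id = "G1",
                      libraries = "libA", n_libraries = 1L,
                      stringsAsFactors = FALSE)
  out <- classify_pairs(pairs, snps, genes)
  # gap 999,999 -> cis (strictly below 1 Mb)
  expect_equal(out$interaction_class[1], "cis")
  expect_equal(out$distance_bp[1], 999999L)
  # the boundary itself is trans: gap exactly 1,000,000
  snps2 <- snps
  genes2 <- genes
  genes2$start <- 1000001L
  out2 <- classify_pairs(pairs, snps2, genes2)
  expect_equal(out2$distance_bp[2], 1000000L)
  expect_equal(out2$interaction_class[2], "trans_intra")
  # different chromosomes -> trans_inter with no distance
  expect_equal(out$interaction_class[3], "trans_inter")
  expect_true(is.na(out$distance_bp[3]))
  # SNP inside the gene body: distance 0, cis
  out3 <- classify_pairs(pairs[4, ], snps, genes)
  expect_equal(out3$distance_bp, 0L)
  expect_equal(out3$interaction_class, "cis")
  # unknown gene -> error
  expect_error(classify_pairs(transform(pairs, gene_id = "GX"), snps, genes),
               "unknown gene")
})

test_that("eQTL join keeps only assayed pairs and rejects ambiguity", {
  pairs <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                      gene_id = c("G1", "G2", "G3"),
                      libraries = "libA", n_libraries = 1L,
                      interaction_class = "cis", distance_bp = 10L,
                      stringsAsFactors = FALSE)
  assoc <- data.frame(
    rsid = c("rs1", "rs1", "rs2", "rs2", "rs9"),
    gene_id = c("G1", "G1", "G2", "G2", "G9"),
    tissue = c("Liver", "Lung", "Liver", "Cortex", "Liver"),
    p_nominal = c(0.01, 0.2, 0.5, 1e-9, 0.3),
    stringsAsFactors = FALSE)
  tests <- join_eqtl(pairs, assoc)
  expect_equal(nrow(tests), 4L)
  expect_true(all(c("libraries", "interaction_class") %in% names(tests)))
  expect_equal(nrow(join_eqtl(pairs, assoc[0, ])), 0L)
  expect_equal(nrow(join_eqtl(pairs[2, ], assoc[assoc$tissue == "Cortex", ])),
               1L)
  dup <- rbind(assoc, assoc[1, ])
  expect_error(join_eqtl(pairs, dup), "duplicate")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 8)), rep(0.2, 8))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    expect_lt(max(abs(bh_fdr(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("discoveries are monotone in alpha and bounded by Bonferroni", {
  set.seed(123)
  tests <- data.frame(rsid = "rs", gene_id = "G", tissue = "T",
                      p_nominal = c(runif(50), runif(20, 0, 1e-4)))
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  n_disc <- vapply(alphas, function(a) {
    sum(call_significant(tests, a)$significant)
  }, numeric(1))
  expect_true(all(diff(n_disc) >= 0))
  # pooled BH finds at least as many as Bonferroni at the same alpha
  bonf <- sum(tests$p_nominal < 0.05 / nrow(tests))
  expect_gte(n_disc[2], bonf)
})

test_that("brain filter requires a brain library AND a brain tissue", {
  libs <- data.frame(library_id = c("liver_lib", "cortical_plate"),
                     is_brain = c(FALSE, TRUE), stringsAsFactors = FALSE)
  tissues <- data.frame(tissue = c("Brain_Cerebellum", "Thyroid", "Cortex"),
                        is_brain_or_spinal = c(TRUE, FALSE, TRUE),
                        stringsAsFactors = FALSE)
  results <- data.frame(
    rsid = c("a", "b", "c"), gene_id = "G",
    libraries = c("liver_lib", "cortical_plate", "cortical_plate"),
    tissue = c("Cortex", "Brain_Cerebellum", "Thyroid"),
    stringsAsFactors = FALSE)
  out <- brain_filter(results, libs, tissues)
  expect_equal(out$rsid, "b")
  # subset of input, and idempotent
  expect_true(all(out$rsid %in% results$rsid))
  expect_identical(brain_filter(out, libs, tissues), out)
})

test_that("tissue correlation recovers linear and degenerate structure", {
  meta <- data.frame(tissue = paste0("t", 1:5),
                     sample_size = c(100L, 200L, 300L, 400L, 500L),
                     is_brain_or_spinal = FALSE, stringsAsFactors = FALSE)
  # counts exactly proportional to sample size -> r = 1
  results <- data.frame(
    rsid = "rs", gene_id = "G",
    tissue = rep(meta$tissue, times = meta$sample_size / 100L),
    interaction_class = "cis", stringsAsFactors = FALSE)
  out <- tissue_counts_and_correlation(results, meta)
  expect_equal(out$correlations$r[out$correlations$class == "cis"], 1)
  # constant counts -> zero-variance flag, r reported 0
  const <- data.frame(rsid = "rs", gene_id = "G", tissue = meta$tissue,
                      interaction_class = "trans_intra",
                      stringsAsFactors = FALSE)
  out2 <- tissue_counts_and_correlation(const, meta)
  row <- out2$correlations[out2$correlations$class == "trans_intra", ]
  expect_equal(row$r, 0)
  expect_match(row$flag, "zero variance")
  # hand-computed Pearson on a 5-tissue table matches the textbook formula
  set.seed(3)
  counts <- c(3L, 9L, 7L, 15L, 11L)
  results3 <- data.frame(rsid = "rs", gene_id = "G",
                         tissue = rep(meta$tissue, times = counts),
                         interaction_class = "cis", stringsAsFactors = FALSE)
  out3 <- tissue_counts_and_correlation(results3, meta)
  x <- meta$sample_size
  r_hand <- sum((x - mean(x)) * (counts - mean(counts))) /
    sqrt(sum((x - mean(x))^2) * sum((counts - mean(counts))^2))
  expect_equal(out3$correlations$r[1], r_hand)
  # fewer than 3 tissues: skipped with notice
  out4 <- tissue_counts_and_correlation(results3[results3$tissue %in%
                                                   c("t1", "t2"), ],
                                        meta[1:2, ])
  expect_match(out4$correlations$flag[1], "fewer than 3")
})

test_that("closest-gene fraction counts nearest-gene pairs", {
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3"), gene_name = c("G1", "G2", "G3"),
    chrom = "chr1", start = c(1000L, 5000L, 9000L),
    end = c(1999L, 5999L, 9999L), strand = "+", stringsAsFactors = FALSE)
  snps <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                     chrom = c("chr1", "chr1", "chr1", "chr9"),
                     pos = c(900L, 902L, 5500L, 5L),
                     phenotype = "ADHD", gwas_p = 1e-8,
                     stringsAsFactors = FALSE)
  # rs1 -> G1 (nearest); rs2 -> G3 (not nearest); rs3 -> G1 (inside G2, not
  # nearest); rs4 on a chromosome with no genes -> excluded
  results <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    gene_id = c("G1", "G3", "G1", "G1"),
    tissue = "Liver", stringsAsFactors = FALSE)
  out <- closest_gene_fraction(results, snps, genes)
  expect_equal(out$n_no_gene_chrom, 1L)
  expect_equal(out$per_phenotype$n_pairs, 3L)
  expect_equal(out$per_phenotype$fraction, 1 / 3)
  # every eGene the nearest gene -> fraction 1; none -> 0
  all_near <- data.frame(rsid = c("rs1", "rs3"), gene_id = c("G1", "G2"),
                         stringsAsFactors = FALSE)
  expect_equal(closest_gene_fraction(all_near, snps, genes)$overall, 1)
  none_near <- data.frame(rsid = c("rs1", "rs3"), gene_id = c("G3", "G1"),
                          stringsAsFactors = FALSE)
  expect_equal(closest_gene_fraction(none_near, snps, genes)$overall, 0)
})

test_that("planted eQTLs are recovered with FDR control on synthetic tables", {
  # planted tests at p <= 1e-8 against uniform background: sensitivity and
  # empirical FDR behave as BH guarantees, across seeds
  n_seeds <- 20
  sens <- numeric(n_seeds)
  fdp <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n_true <- 60L
    n_null <- 400L
    p <- c(runif(n_true, 0, 1e-8), runif(n_null))
    truth <- rep(c(TRUE, FALSE), c(n_true, n_null))
    disc <- bh_fdr(p) < 0.05
    sens[s] <- sum(disc & truth) / n_true
    fdp[s] <- if (any(disc)) sum(disc & !truth) / sum(disc) else 0
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))
})
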
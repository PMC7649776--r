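#' Build SNP-gene spatial pairs from capture results
#'
#' Joins captured partner fragments with the fragment-to-gene map: each
#' (SNP, partner fragment, gene) match yields a candidate SNP-gene pair, and
#' pairs are deduplicated across libraries, accumulating the set of
#' supporting libraries.
#'
#' @param captures Row-bound capture tables from [capture_partners()]
#'   (one or many libraries).
#' @param frag_gene_map `map` element from [genes_on_fragments()].
#' @return data.frame with columns rsid, gene_id, libraries
#'   (comma-separated, sorted), n_libraries.
#' @export
build_pairs <- function(captures, frag_gene_map) {
  empty <- data.frame(rsid = character(), gene_id = character(),
                      libraries = character(), n_libraries = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(captures) == 0L || nrow(frag_gene_map) == 0L) return(empty)
  hit <- merge(captures, frag_gene_map,
               by.x = c("partner_chrom", "partner_frag"),
               by.y = c("chrom", "frag_id"))
  if (nrow(hit) == 0L) return(empty)
  key <- paste(hit$rsid, hit$gene_id, sep = "\r")
  libsets <- tapply(hit$library_id, key, function(x) sort(unique(x)))
  parts <- strsplit(names(libsets), "\r", fixed = TRUE)
  out <- data.frame(
    rsid = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    libraries = vapply(libsets, paste, character(1), collapse = ","),
    n_libraries = lengths(libsets),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rsid, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SNP-gene pairs as cis, trans intra- or inter-chromosomal
#'
#' A pair on different chromosomes is `trans_inter`. On the same chromosome
#' the distance is the minimal gap between the SNP position and the gene body
#' (0 when the SNP lies inside the gene); a distance strictly below
#' `cis_max_bp` (default 1 Mb) is `cis`, otherwise `trans_intra` — the
#' boundary value itself is trans.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param snps SNP table with rsid, chrom, pos (a SNP may recur under
#'   several phenotypes; its coordinates must agree).
#' @param genes Gene model table.
#' @param cis_max_bp cis/trans distance boundary in bp (default 1e6).
#' @return `pairs` with added columns interaction_class and distance_bp
#'   (NA for inter-chromosomal pairs).
#' @export
classify_pairs <- function(pairs, snps, genes, cis_max_bp = 1e6) {
  snp_pos <- snps[!duplicated(snps$rsid), c("rsid", "chrom", "pos")]
  si <- match(pairs$rsid, snp_pos$rsid)
  gi <- match(pairs$gene_id, genes$gene_id)
  if (anyNA(gi)) {
    stop("unknown gene coordinates for: ",
         paste(utils::head(pairs$gene_id[is.na(gi)]), collapse = ", "))
  }
  if (anyNA(si)) {
    stop("unknown SNP coordinates for: ",
         paste(utils::head(pairs$rsid[is.na(si)]), collapse = ", "))
  }
  same <- snp_pos$chrom[si] == genes$chrom[gi]
  dist <- ifelse(same,
                 pmax(0L, pmax(genes$start[gi] - snp_pos$pos[si],
                               snp_pos$pos[si] - genes$end[gi])),
                 NA_integer_)
  pairs$distance_bp <- as.integer(dist)
  pairs$interaction_class <- ifelse(!same, "trans_inter",
                                    ifelse(dist < cis_max_bp, "cis",
                                           "trans_intra"))
  pairs
}

#' Join spatial pairs with a multi-tissue eQTL association table
#'
#' Inner join on (rsid, gene_id): only spatial pairs present in the
#' association table produce candidate tests, one per tissue in which the
#' pair was assayed. Duplicate (rsid, gene, tissue) rows in the association
#' table are an error (the nominal p would be ambiguous).
#'
#' @param pairs Classified pair table (see [classify_pairs()]).
#' @param assoc Association table with columns rsid, gene_id, tissue,
#'   p_nominal and optionally effect_sign.
#' @return data.frame of candidate tests carrying the pair provenance
#'   (libraries, interaction_class, distance_bp).
#' @export
join_eqtl <- function(pairs, assoc) {
  need <- c("rsid", "gene_id", "tissue", "p_nominal")
  if (!all(need %in% names(assoc))) {
    stop("association table must have columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(assoc[, c("rsid", "gene_id", "tissue")])
  if (any(dup)) {
    stop("duplicate (rsid, gene, tissue) rows in association table, e.g.: ",
         paste(assoc$rsid[dup][1L], assoc$gene_id[dup][1L],
               assoc$tissue[dup][1L]))
  }
  if (!"effect_sign" %in% names(assoc)) {
    assoc[["effect_sign"]] <- rep("unknown", nrow(assoc))
  }
  tests <- merge(pairs, assoc[, c(need, "effect_sign")],
                 by = c("rsid", "gene_id"))
  tests <- tests[order(tests$rsid, tests$gene_id, tests$tissue), ,
                 drop = FALSE]
  rownames(tests) <- NULL
  tests
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment over one pooled list of tests; the mapping back to
#' the input order is preserved. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param p Numeric vector of nominal p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call significant eQTL-eGene-tissue tests under pooled FDR control
#'
#' Adjusts the nominal p-values of all candidate tests jointly (one pooled
#' BH correction across every SNP, gene, tissue — and phenotype — in the
#' run) and flags tests with adjusted p below `alpha`. A per-phenotype
#' pooling mode is available via `by`.
#'
#' @param tests Candidate test table from [join_eqtl()].
#' @param alpha FDR threshold (default 0.05); significance is adjusted
#'   p < alpha.
#' @param by Optional column name to pool the correction within (e.g. a
#'   phenotype column); default NULL pools everything.
#' @return `tests` with added p_adjusted and significant columns.
#' @export
call_significant <- function(tests, alpha = 0.05, by = NULL) {
  if (nrow(tests) == 0L) {
    tests$p_adjusted <- numeric(0)
    tests$significant <- logical(0)
    return(tests)
  }
  if (is.null(by)) {
    tests$p_adjusted <- bh_fdr(tests$p_nominal)
  } else {
    tests$p_adjusted <- stats::ave(tests$p_nominal, tests[[by]],
                                   FUN = bh_fdr)
  }
  tests$significant <- tests$p_adjusted < alpha
  tests
}

#' Brain-specific filter for significant eQTL-eGene interactions
#'
#' An interaction is brain-specific iff (1) its spatial pair is supported by
#' at least one brain Hi-C library, and (2) the eQTL tissue belongs to the
#' brain-and-spinal-cord tissue group. Both conditions are required.
#'
#' @param results Significant test table (rows of [call_significant()] output
#'   with `significant == TRUE`), carrying the `libraries` column.
#' @param libraries Library metadata with library_id and is_brain.
#' @param tissues Tissue metadata with tissue and is_brain_or_spinal.
#' @return The brain-specific subset of `results`.
#' @export
brain_filter <- function(results, libraries, tissues) {
  if (nrow(results) == 0L) return(results)
  brain_libs <- libraries$library_id[as.logical(libraries$is_brain)]
  brain_tissues <- tissues$tissue[as.logical(tissues$is_brain_or_spinal)]
  has_brain_lib <- vapply(
    strsplit(results$libraries, ",", fixed = TRUE),
    function(x) any(x %in% brain_libs), logical(1)
  )
  keep <- has_brain_lib & results$tissue %in% brain_tissues
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tissue interaction counts and sample-size correlation
#'
#' Counts significant interactions per tissue, split by interaction class,
#' and tests the Pearson correlation of each class count against tissue
#' sample size (two-sided). Residuals from a linear fit are reported so
#' tissues with more interactions than their sample size predicts can be
#' identified. With fewer than 3 tissues, or a zero-variance count vector,
#' the correlation is reported as 0 with a flag instead of failing.
#'
#' @param results Significant test table with tissue and interaction_class.
#' @param tissue_meta Tissue metadata with tissue and sample_size.
#' @return list with `counts` (tissue x class count table, one row per
#'   tissue) and `correlations` (class, r, p, flag) and `residuals`
#'   (per tissue and class, observed minus linear fit).
#' @export
tissue_counts_and_correlation <- function(results, tissue_meta) {
  classes <- c("cis", "trans_intra", "trans_inter")
  counts <- data.frame(tissue = tissue_meta$tissue,
                       sample_size = tissue_meta$sample_size,
                       stringsAsFactors = FALSE)
  for (cl in classes) {
    tab <- table(results$tissue[results$interaction_class == cl])
    counts[[cl]] <- as.integer(tab[counts$tissue])
    counts[[cl]][is.na(counts[[cl]])] <- 0L
  }
  counts$total <- counts$cis + counts$trans_intra + counts$trans_inter
  cors <- data.frame(class = classes, r = NA_real_, p = NA_real_,
                     flag = "", stringsAsFactors = FALSE)
  residuals <- NULL
  for (i in seq_along(classes)) {
    y <- counts[[classes[i]]]
    if (nrow(counts) < 3L) {
      cors$flag[i] <- "fewer than 3 tissues; correlation skipped"
      next
    }
    if (stats::sd(y) == 0 || stats::sd(counts$sample_size) == 0) {
      cors$r[i] <- 0
      cors$p[i] <- NA_real_
      cors$flag[i] <- "zero variance"
      next
    }
    ct <- stats::cor.test(counts$sample_size, y, method = "pearson")
    cors$r[i] <- unname(ct$estimate)
    cors$p[i] <- ct$p.value
    fit <- stats::lm(y ~ counts$sample_size)
    residuals <- rbind(residuals, data.frame(
      tissue = counts$tissue, class = classes[i],
      residual = unname(stats::residuals(fit)), stringsAsFactors = FALSE
    ))
  }
  list(counts = counts, correlations = cors, residuals = residuals)
}

#' Fraction of significant pairs explained by the SNP's closest gene
#'
#' For each distinct significant (rsid, gene) pair, asks whether the eGene is
#' the SNP's nearest gene: the gene minimizing the gap between the SNP
#' position and any gene body on the same chromosome (ties count as
#' nearest). SNPs with no same-chromosome gene are excluded from the
#' denominator and counted separately. Reported per phenotype and overall.
#'
#' @param results Significant test table.
#' @param snps SNP table (rsid, chrom, pos, phenotype).
#' @param genes Gene model table.
#' @return list with `per_phenotype` (phenotype, n_pairs, n_closest,
#'   fraction), `overall` fraction, and `n_no_gene_chrom` (pairs excluded
#'   because the SNP's chromosome carries no gene).
#' @export
closest_gene_fraction <- function(results, snps, genes) {
  pairs <- unique(results[, c("rsid", "gene_id")])
  pheno <- unique(snps[, c("rsid", "phenotype", "chrom", "pos")])
  pairs <- merge(pairs, pheno, by = "rsid")
  gi <- match(pairs$gene_id, genes$gene_id)
  gap_to <- function(pos, gs, ge) pmax(0L, pmax(gs - pos, pos - ge))
  pair_gap <- ifelse(pairs$chrom == genes$chrom[gi],
                     gap_to(pairs$pos, genes$start[gi], genes$end[gi]),
                     NA_integer_)
  # minimal gap from each distinct SNP to any same-chromosome gene body,
  # under the same gap convention as pair_gap (0 inside the body)
  usnp <- unique(pairs[, c("rsid", "chrom", "pos")])
  min_gap <- rep(NA_integer_, nrow(usnp))
  for (ch in unique(usnp$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    si <- which(usnp$chrom == ch)
    if (nrow(g) == 0L) next
    min_gap[si] <- vapply(usnp$pos[si], function(p) {
      min(gap_to(p, g$start, g$end))
    }, numeric(1))
  }
  pairs$min_gap <- min_gap[match(pairs$rsid, usnp$rsid)]
  no_chrom_gene <- is.na(pairs$min_gap) | is.na(pair_gap)
  pairs$is_closest <- !no_chrom_gene & pair_gap == pairs$min_gap
  eligible <- pairs[!no_chrom_gene, , drop = FALSE]
  per_pheno <- if (nrow(eligible) > 0L) {
    agg <- stats::aggregate(
      list(n_pairs = rep(1L, nrow(eligible)),
           n_closest = as.integer(eligible$is_closest)),
      by = list(phenotype = eligible$phenotype), FUN = sum)
    agg$fraction <- agg$n_closest / agg$n_pairs
    agg
  } else {
    data.frame(phenotype = character(), n_pairs = integer(),
               n_closest = integer(), fraction = numeric())
  }
  list(
    per_phenotype = per_pheno,
    overall = if (nrow(eligible) > 0L) mean(eligible$is_closest) else NaN,
    n_no_gene_chrom = sum(no_chrom_gene)
  )
}

#' Read tissue metadata
#'
#' TSV with header: tissue, sample_size, is_brain_or_spinal.
#'
#' @param path TSV path.
#' @return data.frame of tissue metadata.
#' @export
read_tissue_table <- function(path) {
  tis <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tis$is_brain_or_spinal <- as.logical(tis$is_brain_or_spinal)
  if (any(tis$sample_size < 1L)) stop("tissue sample sizes must be >= 1")
  tis
}

#' Read a multi-tissue eQTL association table
#'
#' TSV with header: rsid, gene_id, tissue, p_nominal and optional
#' effect_sign.
#'
#' @param path TSV path.
#' @return data.frame of associations.
#' @export
read_association_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
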
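#' Read and write gene sets in GMT format
#'
#' Standard tab-separated GMT: pathway id, description, then one gene per
#' remaining column. Empty member lists are rejected on read.
#'
#' @param path GMT file path.
#' @param pathways Named list of gene id vectors; names are pathway ids.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @return `read_gmt` returns a named list of unique gene id vectors, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(pathways, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(pathways))
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, names(pathways), descriptions, pathways)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the query gene set overlaps it more than
#' expected by chance from the background, with the one-sided hypergeometric
#' tail P(X >= k). P-values are BH-adjusted over the tested pathways;
#' significance is adjusted p < alpha. Query genes absent from the
#' background are dropped with a warning. Pathway members outside the
#' background do not count toward pathway size.
#'
#' @param query Character vector of query gene ids (e.g. a phenotype's
#'   eGenes).
#' @param pathways Named list of pathway member gene id vectors.
#' @param background Character vector: the gene universe.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return data.frame with pathway_id, k (overlap), n (query size), K
#'   (pathway size within background), M (background size), p_hyper,
#'   p_adjusted, significant.
#' @export
ora <- function(query, pathways, background, alpha = 0.05) {
  background <- unique(background)
  m_bg <- length(background)
  if (m_bg == 0L) stop("background gene universe is empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) absent from the background",
            " were dropped")
    query <- intersect(query, background)
  }
  n <- length(query)
  res <- data.frame(
    pathway_id = names(pathways),
    k = vapply(pathways, function(p) {
      length(intersect(unique(p), query))
    }, integer(1)),
    n = n,
    K = vapply(pathways, function(p) {
      length(intersect(unique(p), background))
    }, integer(1)),
    M = m_bg,
    stringsAsFactors = FALSE
  )
  # P(X >= k) for X ~ Hypergeom(M, K, n); k = 0 gives p = 1 exactly
  res$p_hyper <- stats::phyper(res$k - 1L, res$K, res$M - res$K, res$n,
                               lower.tail = FALSE)
  res$p_adjusted <- bh_fdr(res$p_hyper)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

#' Significant pathway sets per phenotype
#'
#' Runs [ora()] on each phenotype's eGene list and collects the significant
#' pathway ids, ready for [pathway_overlap_bootstrap()].
#'
#' @param egene_lists Named list: eGene ids per phenotype.
#' @param pathways Named list of pathway member vectors.
#' @param background Gene universe for the test.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Named list: significant pathway id vector per phenotype.
#' @export
pathway_sets_per_phenotype <- function(egene_lists, pathways, background,
                                       alpha = 0.05) {
  lapply(egene_lists, function(genes) {
    if (length(genes) == 0L) return(character(0))
    res <- ora(genes, pathways, background, alpha = alpha)
    res$pathway_id[res$significant]
  })
}

#' Read a drug-gene interaction table
#'
#' TSV with header: drug, gene_id, interaction_type and optional source
#' (a DGIdb-style export).
#'
#' @param path TSV path.
#' @return data.frame of interactions.
#' @export
read_drug_table <- function(path) {
  drugs <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
  need <- c("drug", "gene_id", "interaction_type")
  if (!all(need %in% names(drugs))) {
    stop("drug table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(drugs$drug)) || any(!nzchar(drugs$gene_id))) {
    stop("drug and gene_id must be non-empty")
  }
  drugs
}

#' Join eGene lists with drug-gene interactions
#'
#' Inner join on gene id per phenotype. The druggable fraction is the
#' proportion of a phenotype's eGenes with at least one interaction
#' (duplicate interaction rows do not inflate it). Genes targeted in every
#' phenotype's list are reported separately.
#'
#' @param egene_lists Named list: eGene ids per phenotype.
#' @param interactions Drug-gene interaction table
#'   (see [read_drug_table()]).
#' @return list with `interactions` (phenotype, drug, gene_id,
#'   interaction_type rows), `druggable` (phenotype, n_egenes, n_druggable,
#'   fraction), and `targeted_in_all` (genes druggable and present in every
#'   phenotype's eGene list).
#' @export
drug_join <- function(egene_lists, interactions) {
  interactions <- unique(interactions[, intersect(
    c("drug", "gene_id", "interaction_type", "source"),
    names(interactions)), drop = FALSE])
  per_pheno <- lapply(names(egene_lists), function(ph) {
    genes <- unique(egene_lists[[ph]])
    hit <- interactions[interactions$gene_id %in% genes, , drop = FALSE]
    if (nrow(hit) > 0L) hit <- cbind(phenotype = ph, hit)
    hit
  })
  joined <- do.call(rbind, per_pheno[vapply(per_pheno, nrow,
                                            integer(1)) > 0L])
  druggable_genes <- unique(interactions$gene_id)
  druggable <- data.frame(
    phenotype = names(egene_lists),
    n_egenes = vapply(egene_lists, function(g) length(unique(g)),
                      integer(1)),
    n_druggable = vapply(egene_lists, function(g) {
      length(intersect(unique(g), druggable_genes))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  druggable$fraction <- ifelse(druggable$n_egenes > 0L,
                               druggable$n_druggable / druggable$n_egenes, 0)
  rownames(druggable) <- NULL
  in_all <- Reduce(intersect, lapply(egene_lists, unique))
  list(
    interactions = if (is.null(joined)) {
      data.frame(phenotype = character(), drug = character(),
                 gene_id = character(), interaction_type = character(),
                 stringsAsFactors = FALSE)
    } else {
      `rownames<-`(joined, NULL)
    },
    druggable = druggable,
    targeted_in_all = intersect(in_all, druggable_genes)
  )
}
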
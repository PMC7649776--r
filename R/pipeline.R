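#' Analysis configuration with study defaults
#'
#' Houses the numeric constants of the analysis: the GWAS suggestive
#' association cut-off (1e-6), the Hi-C mapping-quality minimum (30), the
#' pooled FDR threshold (0.05), the cis distance boundary (1 Mb), the
#' bootstrap iteration count (10,000) and rejection threshold (0.01), the
#' pathway universe size (536) and the RNG seed.
#'
#' @param gwas_p_cut,mapq_min,fdr_alpha,cis_max_bp,bootstrap_n,bootstrap_sig,pathway_universe_n,seed
#'   See description; any can be overridden.
#' @return A named list of validated constants.
#' @export
analysis_config <- function(gwas_p_cut = 1e-6, mapq_min = 30L,
                            fdr_alpha = 0.05, cis_max_bp = 1e6,
                            bootstrap_n = 10000L, bootstrap_sig = 0.01,
                            pathway_universe_n = 536L, seed = 1L) {
  cfg <- list(gwas_p_cut = gwas_p_cut, mapq_min = as.integer(mapq_min),
              fdr_alpha = fdr_alpha, cis_max_bp = cis_max_bp,
              bootstrap_n = as.integer(bootstrap_n),
              bootstrap_sig = bootstrap_sig,
              pathway_universe_n = as.integer(pathway_universe_n),
              seed = as.integer(seed))
  if (any(unlist(cfg[1:7]) <= 0)) stop("all thresholds must be positive")
  if (cfg$fdr_alpha >= 1 || cfg$bootstrap_sig >= 1) {
    stop("fdr_alpha and bootstrap_sig must lie in (0, 1)")
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML lists input paths (genome_fasta or fragments_bed, snps, gtf,
#' contacts_dir, libraries, associations, tissues, gmt, drugs), the output
#' directory (`outdir`), the enzyme name, the declared `phenotypes`, and an
#' optional `params` block overriding [analysis_config()] defaults.
#'
#' @param path YAML file path.
#' @return A config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$params <- do.call(analysis_config, as.list(cfg$params))
  cfg
}

#' Run the full spatial eQTL multimorbidity analysis
#'
#' Executes digestion (or fragment-map loading), SNP fragment assignment,
#' library QC, contact filtering and capture, SNP-gene pair building and
#' classification, the eQTL join with pooled BH FDR, the brain-specific
#' sub-analysis, multi-phenotype overlap tables and bootstrap significance
#' tests under both reference-set conventions, pathway over-representation
#' with its own overlap bootstrap, the drug-gene join, tissue sample-size
#' correlations and the closest-gene diagnostic. Tabular outputs, a summary
#' and a run manifest are written to `config$outdir`. Each stage fails with
#' its name attached; with `resume = TRUE` the expensive tabular stages are
#' reloaded from existing outputs instead of recomputed.
#'
#' @param config A list (see [read_pipeline_config()]) or path to a YAML
#'   file. Required entries: snps, gtf, contacts_dir, libraries,
#'   associations, tissues, gmt, drugs, outdir, phenotypes, and either
#'   genome_fasta (+ enzyme) or fragments_bed.
#' @param resume Reload existing stage outputs from outdir (default FALSE).
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$params)) config$params <- analysis_config()
  params <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message("[pipeline] ", ...)
  in_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv_out <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage_table <- function(name, file, compute) {
    path <- file.path(outdir, file)
    if (resume && file.exists(path)) {
      msg("stage ", name, ": reusing ", file)
      return(utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
    }
    out <- in_stage(name, compute())
    tsv_out(out, file)
    out
  }
  need <- c("snps", "gtf", "contacts_dir", "libraries", "associations",
            "tissues", "gmt", "drugs", "outdir", "phenotypes")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys) > 0L) {
    stop("config is missing: ", paste(missing_keys, collapse = ", "))
  }
  paths <- unlist(config[c("snps", "gtf", "libraries", "associations",
                           "tissues", "gmt", "drugs")])
  if (!is.null(config$genome_fasta)) paths <- c(paths, config$genome_fasta)
  if (!is.null(config$fragments_bed)) paths <- c(paths, config$fragments_bed)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }

  # --- fragments -----------------------------------------------------------
  fragments <- in_stage("digest", {
    if (!is.null(config$fragments_bed)) {
      read_fragments_bed(config$fragments_bed)
    } else if (!is.null(config$genome_fasta)) {
      enz <- enzyme_preset(if (is.null(config$enzyme)) "MboI"
                           else config$enzyme)
      digest_genome(Biostrings::readDNAStringSet(config$genome_fasta), enz)
    } else {
      stop("config needs genome_fasta or fragments_bed")
    }
  })
  msg("fragments: ", nrow(fragments))

  # --- SNPs and genes ------------------------------------------------------
  snps <- in_stage("snps", read_snp_table(config$snps, params$gwas_p_cut))
  undeclared <- setdiff(unique(snps$phenotype), config$phenotypes)
  if (length(undeclared) > 0L) {
    stop("stage 'snps' failed: SNP file contains undeclared phenotype(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  genes <- in_stage("genes", read_gene_models(config$gtf))
  fg <- in_stage("genes", genes_on_fragments(fragments, genes))
  usnp <- snps[!duplicated(snps$rsid), , drop = FALSE]
  snp_frags <- in_stage("snp_fragments", data.frame(
    rsid = usnp$rsid, chrom = usnp$chrom,
    frag_id = locate_fragment(fragments, usnp$chrom, usnp$pos),
    stringsAsFactors = FALSE))
  msg("SNPs kept: ", nrow(snps), " (", nrow(usnp), " distinct); genes: ",
      nrow(genes))

  # --- libraries, contacts, capture ---------------------------------------
  libraries <- in_stage("library_qc",
                        library_qc_pass(read_library_table(config$libraries)))
  pass_libs <- libraries$library_id[libraries$qc_pass]
  msg("libraries passing QC: ", length(pass_libs), " of ", nrow(libraries))
  captures <- in_stage("capture", {
    do.call(rbind, lapply(pass_libs, function(lib) {
      f <- file.path(config$contacts_dir, paste0(lib, ".txt"))
      if (!file.exists(f)) stop("contact file missing for library ", lib)
      capture_partners(snp_frags,
                       filter_contacts(read_contacts(f), params$mapq_min),
                       lib)
    }))
  })

  # --- spatial pairs -------------------------------------------------------
  pairs <- stage_table("pairs", "pairs.tsv", function() {
    classify_pairs(build_pairs(captures, fg$map), snps, genes,
                   params$cis_max_bp)
  })
  msg("spatial SNP-gene pairs: ", nrow(pairs))

  # --- eQTL join + pooled FDR ----------------------------------------------
  assoc <- in_stage("eqtl", read_association_table(config$associations))
  tissues <- in_stage("eqtl", read_tissue_table(config$tissues))
  significant <- stage_table("eqtl", "significant.tsv", function() {
    tests <- join_eqtl(pairs, assoc)
    tests <- call_significant(tests, params$fdr_alpha)
    msg("candidate tests: ", nrow(tests), "; significant: ",
        sum(tests$significant))
    tests[tests$significant, , drop = FALSE]
  })

  # --- brain sub-analysis --------------------------------------------------
  brain <- in_stage("brain_filter",
                    brain_filter(significant, libraries, tissues))
  tsv_out(brain, "brain_significant.tsv")
  msg("brain-specific significant tests: ", nrow(brain))

  # --- per-phenotype sets --------------------------------------------------
  pheno_of <- snps[, c("rsid", "phenotype")]
  sig_ph <- merge(significant, pheno_of, by = "rsid")
  set_by <- function(df, col) {
    lapply(stats::setNames(config$phenotypes, config$phenotypes),
           function(ph) sort(unique(df[[col]][df$phenotype == ph])))
  }
  snp_sets <- set_by(snps, "rsid")
  eqtl_sets <- set_by(sig_ph, "rsid")
  egene_sets <- set_by(sig_ph, "gene_id")
  brain_ph <- merge(brain, pheno_of, by = "rsid")
  brain_egene_sets <- set_by(brain_ph, "gene_id")
  egene_summary <- data.frame(
    phenotype = config$phenotypes,
    n_snps = lengths(snp_sets),
    n_eqtls = lengths(eqtl_sets),
    n_egenes = lengths(egene_sets),
    n_brain_egenes = lengths(brain_egene_sets),
    stringsAsFactors = FALSE)
  tsv_out(egene_summary, "egene_summary.tsv")

  # --- overlaps and bootstraps ---------------------------------------------
  overlaps <- in_stage("overlap", list(
    snp = overlap_table(snp_sets),
    eqtl = overlap_table(eqtl_sets),
    egene = overlap_table(egene_sets)))
  tsv_out(overlaps$egene, "overlap_egenes.tsv")
  tsv_out(overlaps$eqtl, "overlap_eqtls.tsv")
  tsv_out(overlaps$snp, "overlap_snps.tsv")
  ref1 <- sort(unique(genes$gene_id))
  ref2 <- sort(unique(pairs$gene_id))
  boots <- in_stage("bootstrap", {
    res <- list(
      all_ref1 = bootstrap_overlap_sets(egene_sets, ref1,
                                        n_iter = params$bootstrap_n,
                                        seed = params$seed,
                                        reference_set_id = "ref1_all_genes"),
      all_ref2 = bootstrap_overlap_sets(egene_sets, ref2,
                                        n_iter = params$bootstrap_n,
                                        seed = params$seed,
                                        reference_set_id = "ref2_hic_genes"))
    prs <- utils::combn(config$phenotypes, 2L, simplify = FALSE)
    pairwise <- lapply(prs, function(pp) {
      bootstrap_overlap_sets(egene_sets[pp], ref1,
                             n_iter = params$bootstrap_n,
                             seed = params$seed,
                             reference_set_id = "ref1_all_genes")
    })
    c(res, stats::setNames(pairwise, vapply(prs, paste, character(1),
                                            collapse = "+")))
  })
  boot_df <- do.call(rbind, lapply(boots, function(b) data.frame(
    combination = b$combination, reference = b$reference_set_id,
    observed = b$observed, n_iter = b$n_iter, n_ge = b$n_ge,
    p_value = b$p_value, reject_null = significance_call(b,
                                                         params$bootstrap_sig),
    seed = b$seed, stringsAsFactors = FALSE)))
  tsv_out(boot_df, "bootstrap_egenes.tsv")

  # --- pathways ------------------------------------------------------------
  pathways <- in_stage("pathways", read_gmt(config$gmt))
  enrich <- in_stage("pathways", {
    res <- lapply(config$phenotypes, function(ph) {
      if (length(egene_sets[[ph]]) == 0L) return(NULL)
      cbind(phenotype = ph,
            ora(egene_sets[[ph]], pathways, ref1, alpha = params$fdr_alpha))
    })
    do.call(rbind, res)
  })
  tsv_out(enrich, "pathway_enrichment.tsv")
  pathway_sets <- in_stage("pathways", pathway_sets_per_phenotype(
    egene_sets, pathways, ref1, alpha = params$fdr_alpha))
  shared_paths <- shared_elements(pathway_sets)
  pathway_boot <- in_stage("pathways", pathway_overlap_bootstrap(
    pathway_sets, universe_n = params$pathway_universe_n,
    n_iter = params$bootstrap_n, seed = params$seed))
  msg("pathways shared by all phenotypes: ", length(shared_paths),
      " (bootstrap p = ", format(pathway_boot$p_value), ")")

  # --- drugs, correlations, closest gene -----------------------------------
  drugs <- in_stage("drugs", drug_join(egene_sets,
                                       read_drug_table(config$drugs)))
  tsv_out(drugs$druggable, "druggable.tsv")
  if (nrow(drugs$interactions) > 0L) {
    tsv_out(drugs$interactions, "drug_interactions.tsv")
  }
  corr <- in_stage("correlation",
                   tissue_counts_and_correlation(significant, tissues))
  tsv_out(corr$counts, "tissue_counts.tsv")
  closest <- in_stage("closest_gene",
                      closest_gene_fraction(significant, snps, genes))

  # --- summary + manifest --------------------------------------------------
  shared_egenes <- shared_elements(egene_sets)
  summary_lines <- c(
    sprintf("input SNPs (after GWAS p filter): %d", nrow(snps)),
    sprintf("distinct SNPs: %d", nrow(usnp)),
    sprintf("spatial SNP-gene pairs: %d", nrow(pairs)),
    sprintf("significant eQTL-eGene-tissue tests: %d", nrow(significant)),
    sprintf("distinct eQTL SNPs: %d",
            length(unique(significant$rsid))),
    sprintf("distinct eGenes: %d", length(unique(significant$gene_id))),
    sprintf("eGenes shared by all phenotypes: %d (bootstrap p ref1 = %s, ref2 = %s)",
            length(shared_egenes), format(boots$all_ref1$p_value),
            format(boots$all_ref2$p_value)),
    sprintf("pathways shared by all phenotypes: %d (bootstrap p = %s)",
            length(shared_paths), format(pathway_boot$p_value)),
    sprintf("druggable eGene fraction range: %.3f-%.3f",
            min(drugs$druggable$fraction), max(drugs$druggable$fraction)),
    sprintf("closest-gene fraction (overall): %.4f", closest$overall),
    sprintf("brain-specific significant tests: %d", nrow(brain)))
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  manifest <- list(
    params = params,
    phenotypes = config$phenotypes,
    inputs = as.list(tools::md5sum(paths)),
    counts = list(
      snps = nrow(snps), fragments = nrow(fragments), genes = nrow(genes),
      libraries_pass = length(pass_libs), pairs = nrow(pairs),
      significant = nrow(significant), brain_significant = nrow(brain),
      egenes_per_phenotype = lengths(egene_sets),
      shared_egenes = length(shared_egenes),
      shared_pathways = length(shared_paths)),
    seed = params$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    fragments = fragments, snps = snps, genes = genes,
    frag_gene_map = fg$map, snp_frags = snp_frags, libraries = libraries,
    captures = captures, pairs = pairs, significant = significant,
    brain = brain, snp_sets = snp_sets, eqtl_sets = eqtl_sets,
    egene_sets = egene_sets, brain_egene_sets = brain_egene_sets,
    overlaps = overlaps, bootstraps = boots, bootstrap_table = boot_df,
    shared_egenes = shared_egenes, pathway_sets = pathway_sets,
    shared_pathways = shared_paths, pathway_bootstrap = pathway_boot,
    enrichment = enrich, drugs = drugs, correlation = corr,
    closest_gene = closest, egene_summary = egene_summary,
    manifest = manifest))
}

#' Write a pipeline config for a simulated study directory
#'
#' Convenience for running [run_pipeline()] on the outputs of
#' [simulate_study()].
#'
#' @param simdir Directory written by [simulate_study()].
#' @param outdir Pipeline result directory.
#' @param spec The [sim_spec()] used (for phenotypes and enzyme).
#' @param params An [analysis_config()].
#' @return The config list.
#' @export
sim_pipeline_config <- function(simdir, outdir,
                                spec = sim_spec(),
                                params = analysis_config()) {
  list(
    genome_fasta = file.path(simdir, "genome.fa"),
    enzyme = spec$enzyme$name,
    snps = file.path(simdir, "snps.tsv"),
    gtf = file.path(simdir, "genes.gtf"),
    contacts_dir = file.path(simdir, "contacts"),
    libraries = file.path(simdir, "libraries.tsv"),
    associations = file.path(simdir, "associations.tsv"),
    tissues = file.path(simdir, "tissues.tsv"),
    gmt = file.path(simdir, "pathways.gmt"),
    drugs = file.path(simdir, "drugs.tsv"),
    outdir = outdir,
    phenotypes = spec$phenotypes,
    params = params)
}
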
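#' Simulation specification for a synthetic multimorbidity study
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a desk-scale study with the same structure as a multi-phenotype spatial
#' eQTL analysis: six psychiatric/cognitive phenotypes, a planted set of
#' eGenes shared by all of them, per-phenotype specific eGenes, Hi-C
#' libraries with brain flags and QC statistics, a GTEx-like multi-tissue
#' association table whose row counts scale with tissue sample size, a
#' KEGG-sized pathway universe, and a DGIdb-like drug table.
#'
#' @param seed Master RNG seed; every generator derives its own substream
#'   from it, so outputs are byte-identical given the same spec.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param enzyme A [restriction_enzyme] (default MboI).
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_range Gene length range in bp; lengths are
#'   log-uniform.
#' @param phenotypes Phenotype labels.
#' @param n_snps_per_phenotype SNPs per phenotype (planted + background).
#' @param n_shared_egenes Genes planted as eGenes of every phenotype.
#' @param n_unique_egenes Phenotype-specific planted eGenes each.
#' @param planted_cis_frac Fraction of planted SNPs placed within 1 Mb of
#'   their target gene (the rest land anywhere, giving trans links).
#' @param planted_closest_frac Fraction of planted SNPs placed immediately
#'   adjacent to their target so the eGene is usually the nearest gene.
#' @param n_libraries,n_brain_libraries QC-passing Hi-C libraries and how
#'   many of them are brain-derived.
#' @param n_failing_libraries Extra libraries that fail QC (background
#'   contacts only; the pipeline must exclude them).
#' @param contacts_per_planted_link Contact records emitted per planted link
#'   per supporting library.
#' @param background_contacts_per_library Uniform background contacts per
#'   library.
#' @param mapq_fail_frac Fraction of background contacts given one end with
#'   mapq < 30, to exercise the mapq filter.
#' @param tissues Tissue metadata data.frame (tissue, sample_size,
#'   is_brain_or_spinal); default is a 12-tissue panel with 4 brain/spinal
#'   tissues and realistic sample sizes.
#' @param n_tissues_per_effect Tissues (sample-size-weighted, at least one
#'   brain/spinal) in which each planted eQTL is significant.
#' @param planted_p_max Planted nominal p-values are Uniform(0,
#'   planted_p_max).
#' @param background_assoc_frac Fraction of background spatial SNP-gene
#'   candidates given association rows (p ~ Uniform(0,1)).
#' @param background_tests_per_pair Mean tissues per background association.
#' @param n_pathways Pathways written to the GMT (a subset of the universe).
#' @param pathway_size_range Pathway sizes (uniform integer range).
#' @param n_shared_pathways Pathways over-populated with the planted shared
#'   eGenes, so they enrich in every phenotype.
#' @param pathway_universe_n Size of the notional pathway universe used by
#'   the pathway bootstrap (default 536).
#' @param drug_fraction Fraction of genes given at least one drug
#'   interaction.
#' @return An object of class `sim_spec` (a validated list).
#' @export
sim_spec <- function(seed = 1L,
                     chrom_lengths = c(chr1 = 3e6, chr2 = 3e6, chr3 = 2.5e6),
                     enzyme = enzyme_preset("MboI"),
                     n_genes = 300L,
                     gene_length_range = c(1000, 50000),
                     phenotypes = c("ADHD", "anxiety", "BD", "SCZ", "UD",
                                    "cognition"),
                     n_snps_per_phenotype = 60L,
                     n_shared_egenes = 33L,
                     n_unique_egenes = 12L,
                     planted_cis_frac = 0.7,
                     planted_closest_frac = 0.06,
                     n_libraries = 6L,
                     n_brain_libraries = 2L,
                     n_failing_libraries = 1L,
                     contacts_per_planted_link = 2L,
                     background_contacts_per_library = 2000L,
                     mapq_fail_frac = 0.1,
                     tissues = default_tissue_panel(),
                     n_tissues_per_effect = 5L,
                     planted_p_max = 1e-8,
                     background_assoc_frac = 0.8,
                     background_tests_per_pair = 2L,
                     n_pathways = 120L,
                     pathway_size_range = c(10L, 60L),
                     n_shared_pathways = 5L,
                     pathway_universe_n = 536L,
                     drug_fraction = 0.18) {
  spec <- as.list(environment())
  stopifnot(all(spec$chrom_lengths >= 1e4),
            inherits(spec$enzyme, "restriction_enzyme"))
  n_planted <- spec$n_shared_egenes + spec$n_unique_egenes
  if (n_planted > spec$n_snps_per_phenotype) {
    stop("n_shared_egenes + n_unique_egenes must not exceed ",
         "n_snps_per_phenotype")
  }
  need_genes <- spec$n_shared_egenes +
    spec$n_unique_egenes * length(spec$phenotypes)
  if (need_genes > spec$n_genes) {
    stop("not enough genes (", spec$n_genes, ") for the planted eGene ",
         "budget (", need_genes, ")")
  }
  if (spec$n_brain_libraries < 1L || spec$n_brain_libraries >= spec$n_libraries) {
    stop("need at least one brain and one non-brain QC-passing library")
  }
  if (!any(tissues$is_brain_or_spinal)) {
    stop("tissue panel needs at least one brain/spinal tissue")
  }
  structure(spec, class = "sim_spec")
}

#' Default synthetic tissue panel
#'
#' Twelve tissues with sample sizes in a realistic multi-tissue-atlas range;
#' four belong to the brain-and-spinal-cord group.
#'
#' @return data.frame with tissue, sample_size, is_brain_or_spinal.
#' @export
default_tissue_panel <- function() {
  data.frame(
    tissue = c("Adipose_Subcutaneous", "Artery_Tibial", "Brain_Cerebellum",
               "Brain_Cortex", "Brain_Hippocampus",
               "Spinal_cord_cervical_c1", "Heart_Left_Ventricle", "Liver",
               "Lung", "Muscle_Skeletal", "Thyroid", "Whole_Blood"),
    sample_size = c(385L, 388L, 154L, 136L, 111L, 83L, 272L, 153L, 383L,
                    491L, 399L, 369L),
    is_brain_or_spinal = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                           FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a random genome and non-overlapping gene models
#'
#' Chromosomes are uniform-random ACGT of the spec'd lengths. Genes are
#' placed uniformly without overlap by rejection sampling, with log-uniform
#' lengths.
#'
#' @param spec A [sim_spec()].
#' @return list with `sequences` (DNAStringSet) and `genes` (data.frame:
#'   gene_id, gene_name, chrom, start, end, strand; 1-based inclusive).
#' @export
gen_genome <- function(spec) {
  with_local_seed(derive_seed(spec$seed, "genome"), function() {
    seqs <- Biostrings::DNAStringSet(vapply(spec$chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- names(spec$chrom_lengths)
    if (spec$n_genes == 0L) {
      genes <- data.frame(gene_id = character(), gene_name = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
      return(list(sequences = seqs, genes = genes))
    }
    lens <- round(exp(stats::runif(spec$n_genes,
                                   log(spec$gene_length_range[1]),
                                   log(spec$gene_length_range[2]))))
    if (any(lens > max(spec$chrom_lengths))) {
      stop("requested gene length exceeds every chromosome length")
    }
    chrom_names <- names(spec$chrom_lengths)
    chrom_prob <- spec$chrom_lengths / sum(spec$chrom_lengths)
    placed <- stats::setNames(
      lapply(chrom_names, function(x) list(start = integer(0),
                                           end = integer(0))),
      chrom_names)
    rows <- vector("list", spec$n_genes)
    # longest first: keeps rejection sampling feasible at high occupancy
    for (i in order(lens, decreasing = TRUE)) {
      ok <- FALSE
      for (attempt in seq_len(1e5)) {
        ch <- sample(chrom_names, 1L, prob = chrom_prob)
        L <- spec$chrom_lengths[[ch]]
        if (lens[i] > L) next
        st <- sample.int(L - lens[i] + 1L, 1L)
        en <- st + lens[i] - 1L
        if (!any(st <= placed[[ch]]$end & en >= placed[[ch]]$start)) {
          placed[[ch]]$start <- c(placed[[ch]]$start, st)
          placed[[ch]]$end <- c(placed[[ch]]$end, en)
          rows[[i]] <- data.frame(
            gene_id = sprintf("GENE%04d", i),
            gene_name = sprintf("Gene-%04d", i),
            chrom = ch, start = st, end = en,
            strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place gene ", i, " without overlap after 1e5 ",
             "attempts; use longer chromosomes or fewer/shorter genes")
      }
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    list(sequences = seqs, genes = genes)
  })
}

# Sample a 1-based position outside every gene body, optionally restricted
# to a window near a target gene.
sample_intergenic_pos <- function(chrom_lengths, genes, chrom = NULL,
                                  window = NULL, max_tries = 1e4) {
  chrom_names <- names(chrom_lengths)
  prob <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_len(max_tries)) {
    ch <- if (is.null(chrom)) sample(chrom_names, 1L, prob = prob) else chrom
    L <- chrom_lengths[[ch]]
    rng <- if (is.null(window)) c(1L, L) else {
      c(max(1L, window[1]), min(L, window[2]))
    }
    pos <- sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L || !any(pos >= g$start & pos <= g$end)) {
      return(list(chrom = ch, pos = as.integer(pos)))
    }
  }
  stop("could not sample an intergenic position after ", max_tries,
       " attempts")
}

#' Generate phenotype-tagged SNPs with planted regulatory targets
#'
#' Each phenotype receives its planted SNPs first — one per planted eGene
#' (the shared eGenes, common to all phenotypes, then its specific eGenes) —
#' followed by background SNPs with no planted target. SNPs are placed in
#' intergenic positions; a spec'd fraction of planted SNPs is placed within
#' 1 Mb of its target (cis) and a smaller fraction immediately adjacent to
#' it (so the target is typically the nearest gene).
#'
#' @param spec A [sim_spec()].
#' @param genes Gene table from [gen_genome()].
#' @return list with `snps` (rsid, chrom, pos, phenotype, gwas_p),
#'   `planted_links` (phenotype, rsid, gene_id), `shared_egenes`,
#'   `unique_egenes` (named list per phenotype).
#' @export
gen_snps <- function(spec, genes) {
  with_local_seed(derive_seed(spec$seed, "snps"), function() {
    gene_pool <- sample(genes$gene_id)
    shared <- gene_pool[seq_len(spec$n_shared_egenes)]
    rest <- setdiff(gene_pool, shared)
    unique_sets <- stats::setNames(vector("list", length(spec$phenotypes)),
                                   spec$phenotypes)
    for (i in seq_along(spec$phenotypes)) {
      take <- seq_len(spec$n_unique_egenes) + (i - 1L) * spec$n_unique_egenes
      unique_sets[[i]] <- rest[take]
    }
    snp_rows <- list()
    link_rows <- list()
    counter <- 0L
    for (ph in spec$phenotypes) {
      targets <- c(shared, unique_sets[[ph]])
      n_bg <- spec$n_snps_per_phenotype - length(targets)
      for (g in targets) {
        counter <- counter + 1L
        rsid <- sprintf("rs%06d", counter)
        gi <- match(g, genes$gene_id)
        u <- stats::runif(1)
        loc <- if (u < spec$planted_closest_frac) {
          side <- sample(c(-1L, 1L), 1L)
          w <- if (side < 0L) c(genes$start[gi] - 2000L, genes$start[gi] - 1L)
               else c(genes$end[gi] + 1L, genes$end[gi] + 2000L)
          sample_intergenic_pos(spec$chrom_lengths, genes,
                                chrom = genes$chrom[gi], window = w)
        } else if (u < spec$planted_closest_frac + spec$planted_cis_frac) {
          w <- c(genes$start[gi] - 9e5, genes$end[gi] + 9e5)
          sample_intergenic_pos(spec$chrom_lengths, genes,
                                chrom = genes$chrom[gi], window = w)
        } else {
          sample_intergenic_pos(spec$chrom_lengths, genes)
        }
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          rsid = rsid, chrom = loc$chrom, pos = loc$pos, phenotype = ph,
          gwas_p = stats::runif(1, 1e-12, 1e-6), stringsAsFactors = FALSE)
        link_rows[[length(link_rows) + 1L]] <- data.frame(
          phenotype = ph, rsid = rsid, gene_id = g, stringsAsFactors = FALSE)
      }
      for (j in seq_len(n_bg)) {
        counter <- counter + 1L
        loc <- sample_intergenic_pos(spec$chrom_lengths, genes)
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          rsid = sprintf("rs%06d", counter), chrom = loc$chrom,
          pos = loc$pos, phenotype = ph,
          gwas_p = stats::runif(1, 1e-12, 1e-6), stringsAsFactors = FALSE)
      }
    }
    list(snps = do.call(rbind, snp_rows),
         planted_links = do.call(rbind, link_rows),
         shared_egenes = shared,
         unique_egenes = unique_sets)
  })
}

#' Generate the Hi-C library metadata table
#'
#' QC-passing libraries draw their statistics inside the passing region
#' (>90% alignable, >50% unique contacts, <40% duplication); brain libraries
#' come last among the passing ones. Failing libraries violate the
#' alignability threshold.
#'
#' @param spec A [sim_spec()].
#' @return data.frame: library_id, tissue_label, is_brain,
#'   pct_alignable_unique, pct_unique_contacts, duplication_rate.
#' @export
gen_libraries <- function(spec) {
  with_local_seed(derive_seed(spec$seed, "libraries"), function() {
    n_pass <- spec$n_libraries
    n_tot <- n_pass + spec$n_failing_libraries
    is_brain <- c(rep(FALSE, n_pass - spec$n_brain_libraries),
                  rep(TRUE, spec$n_brain_libraries),
                  rep(FALSE, spec$n_failing_libraries))
    tissue_label <- ifelse(is_brain, "cortical_plate", "cell_line")
    data.frame(
      library_id = sprintf("lib%02d", seq_len(n_tot)),
      tissue_label = tissue_label,
      is_brain = is_brain,
      pct_alignable_unique = c(round(stats::runif(n_pass, 91, 99), 1),
                               round(stats::runif(spec$n_failing_libraries,
                                                  70, 89), 1)),
      pct_unique_contacts = round(stats::runif(n_tot, 55, 85), 1),
      duplication_rate = round(stats::runif(n_tot, 5, 35), 1),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate per-library Hi-C contact files with planted spatial links
#'
#' Every planted SNP-gene link receives contact records joining the SNP's
#' restriction fragment to a fragment overlapping the target gene, in one
#' randomly chosen non-brain and one brain QC-passing library (so every
#' planted link can survive the brain-library criterion). Background
#' contacts are drawn uniformly over fragment pairs in all libraries,
#' including QC-failing ones; a spec'd fraction of background records gets
#' one end with mapq below 30.
#'
#' @param spec A [sim_spec()].
#' @param fragments Fragment table from [digest_genome()].
#' @param snp_frags data.frame rsid, chrom, frag_id for every distinct SNP.
#' @param planted_links From [gen_snps()].
#' @param frag_gene_map From [genes_on_fragments()].
#' @param libraries From [gen_libraries()].
#' @return list with `contacts` (named list of contact data.frames per
#'   library) and `planted_libraries` (phenotype, rsid, gene_id, libraries).
#' @export
gen_contacts <- function(spec, fragments, snp_frags, planted_links,
                         frag_gene_map, libraries) {
  with_local_seed(derive_seed(spec$seed, "contacts"), function() {
    qc <- library_qc_pass(libraries)
    pass <- qc$library_id[qc$qc_pass]
    brain_pass <- qc$library_id[qc$qc_pass & qc$is_brain]
    nonbrain_pass <- setdiff(pass, brain_pass)
    frag_key <- paste(fragments$chrom, fragments$frag_id)
    frag_mid <- function(idx) {
      # 1-based position inside the fragment
      fragments$start[idx] +
        sample.int(fragments$end[idx] - fragments$start[idx], 1L)
    }
    rec <- function(chrom1, idx1, mapq1, chrom2, idx2, mapq2, name) {
      data.frame(read_name = name,
                 strand1 = sample(c("0", "16"), 1L), chrom1 = chrom1,
                 pos1 = frag_mid(idx1), frag1 = fragments$frag_id[idx1],
                 mapq1 = mapq1,
                 strand2 = sample(c("0", "16"), 1L), chrom2 = chrom2,
                 pos2 = frag_mid(idx2), frag2 = fragments$frag_id[idx2],
                 mapq2 = mapq2, stringsAsFactors = FALSE)
    }
    per_lib <- stats::setNames(
      lapply(libraries$library_id, function(x) list()),
      libraries$library_id)
    planted_lib_rows <- vector("list", nrow(planted_links))
    for (i in seq_len(nrow(planted_links))) {
      rsid <- planted_links$rsid[i]
      gene <- planted_links$gene_id[i]
      srow <- match(rsid, snp_frags$rsid)
      sidx <- which(frag_key == paste(snp_frags$chrom[srow],
                                      snp_frags$frag_id[srow]))
      gfrags <- frag_gene_map[frag_gene_map$gene_id == gene, , drop = FALSE]
      if (nrow(gfrags) == 0L) {
        stop("planted link target gene ", gene,
             " does not resolve to any restriction fragment")
      }
      libs_i <- c(sample(nonbrain_pass, 1L), sample(brain_pass, 1L))
      planted_lib_rows[[i]] <- data.frame(
        phenotype = planted_links$phenotype[i], rsid = rsid, gene_id = gene,
        libraries = paste(sort(libs_i), collapse = ","),
        stringsAsFactors = FALSE)
      for (lib in libs_i) {
        for (k in seq_len(spec$contacts_per_planted_link)) {
          gi <- sample.int(nrow(gfrags), 1L)
          gidx <- which(frag_key == paste(gfrags$chrom[gi],
                                          gfrags$frag_id[gi]))
          per_lib[[lib]][[length(per_lib[[lib]]) + 1L]] <- rec(
            fragments$chrom[sidx], sidx, sample(30:60, 1L),
            fragments$chrom[gidx], gidx, sample(30:60, 1L),
            sprintf("planted_%s_%s_%d", rsid, lib, k))
        }
      }
    }
    n_frag <- nrow(fragments)
    for (lib in libraries$library_id) {
      n_bg <- spec$background_contacts_per_library
      if (n_bg > 0L) {
        i1 <- sample.int(n_frag, n_bg, replace = TRUE)
        i2 <- sample.int(n_frag, n_bg, replace = TRUE)
        fail <- stats::runif(n_bg) < spec$mapq_fail_frac
        fail_end <- sample(1:2, n_bg, replace = TRUE)
        m1 <- sample(30:60, n_bg, replace = TRUE)
        m2 <- sample(30:60, n_bg, replace = TRUE)
        m1[fail & fail_end == 1L] <- sample(0:29, sum(fail & fail_end == 1L),
                                            replace = TRUE)
        m2[fail & fail_end == 2L] <- sample(0:29, sum(fail & fail_end == 2L),
                                            replace = TRUE)
        pos_in <- function(idx) {
          fragments$start[idx] + (sample.int(.Machine$integer.max, n_bg,
                                             replace = TRUE) %%
            (fragments$end[idx] - fragments$start[idx])) + 1L
        }
        bg <- data.frame(
          read_name = sprintf("bg_%s_%06d", lib, seq_len(n_bg)),
          strand1 = sample(c("0", "16"), n_bg, replace = TRUE),
          chrom1 = fragments$chrom[i1], pos1 = pos_in(i1),
          frag1 = fragments$frag_id[i1], mapq1 = m1,
          strand2 = sample(c("0", "16"), n_bg, replace = TRUE),
          chrom2 = fragments$chrom[i2], pos2 = pos_in(i2),
          frag2 = fragments$frag_id[i2], mapq2 = m2,
          stringsAsFactors = FALSE)
        per_lib[[lib]][[length(per_lib[[lib]]) + 1L]] <- bg
      }
    }
    contacts <- lapply(per_lib, function(x) {
      if (length(x) == 0L) {
        read_contacts(textConnection(character(0)))
      } else {
        out <- do.call(rbind, x)
        rownames(out) <- NULL
        out
      }
    })
    list(contacts = contacts,
         planted_libraries = do.call(rbind, planted_lib_rows))
  })
}

#' Generate the multi-tissue eQTL association table and tissue metadata
#'
#' Planted (SNP, gene) links receive association rows with nominal
#' p ~ Uniform(0, planted_p_max) in a sample-size-weighted draw of tissues
#' that always includes at least one brain/spinal tissue. Background
#' spatial candidates (SNP-gene pairs arising from background contacts,
#' supplied by the caller) receive rows with p ~ Uniform(0, 1), again in
#' sample-size-weighted tissues, so per-tissue row counts scale with sample
#' size.
#'
#' @param spec A [sim_spec()].
#' @param planted_links From [gen_snps()].
#' @param background_pairs data.frame with rsid, gene_id for non-planted
#'   spatial candidates (may be empty).
#' @return list with `assoc` (rsid, gene_id, tissue, p_nominal,
#'   effect_sign), `tissues` (the spec's panel) and `planted_triples`.
#' @export
gen_eqtl_table <- function(spec, planted_links, background_pairs = NULL) {
  with_local_seed(derive_seed(spec$seed, "eqtl"), function() {
    tis <- spec$tissues
    w <- tis$sample_size / sum(tis$sample_size)
    brain <- tis$tissue[tis$is_brain_or_spinal]
    pick_tissues <- function(n, force_brain) {
      n <- min(n, nrow(tis))
      t <- sample(tis$tissue, n, prob = w)
      if (force_brain && !any(t %in% brain)) {
        t[sample.int(n, 1L)] <- sample(brain, 1L)
      }
      unique(t)
    }
    rows <- list()
    planted <- list()
    for (i in seq_len(nrow(planted_links))) {
      ts <- pick_tissues(spec$n_tissues_per_effect, force_brain = TRUE)
      df <- data.frame(
        rsid = planted_links$rsid[i], gene_id = planted_links$gene_id[i],
        tissue = ts,
        p_nominal = stats::runif(length(ts), 0, spec$planted_p_max),
        effect_sign = sample(c("+", "-"), length(ts), replace = TRUE),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df
      planted[[length(planted) + 1L]] <- df
    }
    if (!is.null(background_pairs) && nrow(background_pairs) > 0L) {
      keep <- stats::runif(nrow(background_pairs)) < spec$background_assoc_frac
      bp <- background_pairs[keep, , drop = FALSE]
      for (i in seq_len(nrow(bp))) {
        n_t <- 1L + stats::rpois(1L, spec$background_tests_per_pair - 1L)
        ts <- pick_tissues(n_t, force_brain = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = bp$rsid[i], gene_id = bp$gene_id[i], tissue = ts,
          p_nominal = stats::runif(length(ts)),
          effect_sign = sample(c("+", "-"), length(ts), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    assoc <- if (length(rows) > 0L) do.call(rbind, rows) else {
      data.frame(rsid = character(), gene_id = character(),
                 tissue = character(), p_nominal = numeric(),
                 effect_sign = character(), stringsAsFactors = FALSE)
    }
    # a background pair may duplicate a planted key; planted rows win
    assoc <- assoc[!duplicated(assoc[, c("rsid", "gene_id", "tissue")]), ,
                   drop = FALSE]
    rownames(assoc) <- NULL
    list(assoc = assoc, tissues = tis,
         planted_triples = if (length(planted) > 0L) {
           do.call(rbind, planted)
         } else {
           NULL
         })
  })
}

#' Generate pathway gene sets and a drug-gene interaction table
#'
#' A spec'd number of "shared" pathways is over-populated with the planted
#' all-phenotype shared eGenes (plus random filler), so each enriches in
#' every phenotype's over-representation analysis; the remaining pathways
#' are uniform random gene draws. The drug table covers a fixed fraction of
#' genes.
#'
#' @param spec A [sim_spec()].
#' @param genes Gene table.
#' @param shared_egenes The planted all-phenotype shared eGene ids.
#' @return list with `pathways` (named list for [write_gmt()]),
#'   `shared_pathways` (ids), `drugs` (data.frame drug, gene_id,
#'   interaction_type, source).
#' @export
gen_pathways_and_drugs <- function(spec, genes, shared_egenes) {
  with_local_seed(derive_seed(spec$seed, "pathways"), function() {
    all_genes <- genes$gene_id
    sizes <- sample(spec$pathway_size_range[1]:spec$pathway_size_range[2],
                    spec$n_pathways, replace = TRUE)
    pathways <- vector("list", spec$n_pathways)
    names(pathways) <- sprintf("path%04d", seq_len(spec$n_pathways))
    shared_ids <- names(pathways)[seq_len(spec$n_shared_pathways)]
    for (i in seq_len(spec$n_pathways)) {
      if (i <= spec$n_shared_pathways) {
        filler <- sample(setdiff(all_genes, shared_egenes),
                         max(0L, sizes[i] - length(shared_egenes)))
        pathways[[i]] <- sample(c(shared_egenes, filler))
      } else {
        pathways[[i]] <- sample(all_genes, min(sizes[i], length(all_genes)))
      }
    }
    n_drug <- round(spec$drug_fraction * length(all_genes))
    drug_genes <- sample(all_genes, n_drug)
    drugs <- if (n_drug > 0L) {
      data.frame(
        drug = sprintf("DRUG%04d", sample.int(2 * max(n_drug, 1L), n_drug,
                                              replace = TRUE)),
        gene_id = drug_genes,
        interaction_type = sample(c("inhibitor", "agonist", "antagonist",
                                    "modulator"), n_drug, replace = TRUE),
        source = "synthetic",
        stringsAsFactors = FALSE)
    } else {
      data.frame(drug = character(), gene_id = character(),
                 interaction_type = character(), source = character(),
                 stringsAsFactors = FALSE)
    }
    list(pathways = pathways, shared_pathways = shared_ids, drugs = drugs)
  })
}

#' Generate a complete synthetic study and write its input files
#'
#' Runs every generator, derives the background spatial candidates implied
#' by the generated contacts (so the association table contains realistic
#' non-planted tests), and writes the seven pipeline inputs plus a ground
#' truth JSON to `outdir`: genome.fa, genes.gtf, snps.tsv, contacts/<lib>.txt,
#' libraries.tsv, associations.tsv, tissues.tsv, pathways.gmt, drugs.tsv,
#' ground_truth.json.
#'
#' @param spec A [sim_spec()].
#' @param outdir Output directory (created if needed). NULL skips writing.
#' @return Invisibly, a list with all in-memory objects: sequences, genes,
#'   fragments, snps, libraries, contacts, assoc, tissues, pathways, drugs
#'   and `ground_truth`.
#' @export
simulate_study <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  genome <- gen_genome(spec)
  fragments <- digest_genome(genome$sequences, spec$enzyme)
  fg <- genes_on_fragments(fragments, genome$genes)
  snp_out <- gen_snps(spec, genome$genes)
  snps <- snp_out$snps
  usnp <- snps[!duplicated(snps$rsid), c("rsid", "chrom", "pos")]
  snp_frags <- data.frame(
    rsid = usnp$rsid, chrom = usnp$chrom,
    frag_id = locate_fragment(fragments, usnp$chrom, usnp$pos),
    stringsAsFactors = FALSE)
  libraries <- gen_libraries(spec)
  contact_out <- gen_contacts(spec, fragments, snp_frags,
                              snp_out$planted_links, fg$map, libraries)
  # background spatial candidates: what capture would see minus planted keys
  qc <- library_qc_pass(libraries)
  caps <- do.call(rbind, lapply(qc$library_id[qc$qc_pass], function(lib) {
    capture_partners(snp_frags, filter_contacts(contact_out$contacts[[lib]]),
                     lib)
  }))
  cand <- build_pairs(caps, fg$map)
  planted_key <- paste(snp_out$planted_links$rsid,
                       snp_out$planted_links$gene_id)
  background_pairs <- cand[!(paste(cand$rsid, cand$gene_id) %in% planted_key),
                           c("rsid", "gene_id"), drop = FALSE]
  eqtl <- gen_eqtl_table(spec, snp_out$planted_links, background_pairs)
  pw <- gen_pathways_and_drugs(spec, genome$genes, snp_out$shared_egenes)
  ground_truth <- list(
    planted_links = contact_out$planted_libraries,
    planted_triples = eqtl$planted_triples,
    egene_sets = lapply(stats::setNames(spec$phenotypes, spec$phenotypes),
                        function(ph) {
                          sort(unique(snp_out$planted_links$gene_id[
                            snp_out$planted_links$phenotype == ph]))
                        }),
    shared_egenes = sort(snp_out$shared_egenes),
    unique_egenes = lapply(snp_out$unique_egenes, sort),
    shared_pathways = pw$shared_pathways
  )
  result <- list(
    spec = spec, sequences = genome$sequences, genes = genome$genes,
    fragments = fragments, frag_gene_map = fg$map, snps = snps,
    snp_frags = snp_frags, libraries = libraries,
    contacts = contact_out$contacts, assoc = eqtl$assoc,
    tissues = eqtl$tissues, pathways = pw$pathways, drugs = pw$drugs,
    ground_truth = ground_truth
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "contacts"), showWarnings = FALSE)
    Biostrings::writeXStringSet(genome$sequences,
                                file.path(outdir, "genome.fa"))
    write_gtf(genome$genes, file.path(outdir, "genes.gtf"))
    utils::write.table(snps, file.path(outdir, "snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(libraries, file.path(outdir, "libraries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lib in names(contact_out$contacts)) {
      utils::write.table(contact_out$contacts[[lib]],
                         file.path(outdir, "contacts",
                                   paste0(lib, ".txt")),
                         sep = " ", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    utils::write.table(eqtl$assoc, file.path(outdir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(eqtl$tissues, file.path(outdir, "tissues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(pw$pathways, file.path(outdir, "pathways.gmt"))
    utils::write.table(pw$drugs, file.path(outdir, "drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ground_truth, file.path(outdir, "ground_truth.json"),
                         dataframe = "columns", pretty = TRUE)
    result$outdir <- outdir
  }
  invisible(result)
}

# Minimal GENCODE-style GTF writer for gene feature lines.
write_gtf <- function(genes, path) {
  lines <- sprintf(
    '%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id,
    genes$gene_name)
  writeLines(lines, path)
  invisible(path)
}
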
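# Shared fixtures built in code.

# A 12 bp chromosome digested by MboI: motif GATC at 0-based offsets 2 and 7,
# cut_offset 0, so fragments [0,2), [2,7), [7,12).
toy_fragments <- function() {
  data.frame(chrom = "chrA", start = c(0L, 2L, 7L), end = c(2L, 7L, 12L),
             frag_id = 1:3, stringsAsFactors = FALSE)
}

make_contact <- function(chrom1, frag1, chrom2, frag2, mapq1 = 60L,
                         mapq2 = 60L, name = "r") {
  data.frame(read_name = name, strand1 = "0", chrom1 = chrom1, pos1 = 1L,
             frag1 = as.integer(frag1), mapq1 = as.integer(mapq1),
             strand2 = "16", chrom2 = chrom2, pos2 = 1L,
             frag2 = as.integer(frag2), mapq2 = as.integer(mapq2),
             stringsAsFactors = FALSE)
}

make_contacts <- function(...) {
  do.call(rbind, list(...))
}

# A small simulation spec that keeps module and pipeline tests fast.
small_sim_spec <- function(seed = 11, ...) {
  args <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 6e5, chr2 = 6e5),
    n_genes = 60L,
    gene_length_range = c(1000, 15000),
    phenotypes = c("ADHD", "SCZ", "cognition"),
    n_snps_per_phenotype = 15L,
    n_shared_egenes = 5L,
    n_unique_egenes = 3L,
    n_libraries = 3L,
    n_brain_libraries = 1L,
    n_failing_libraries = 1L,
    background_contacts_per_library = 300L,
    n_pathways = 30L,
    pathway_size_range = c(5L, 15L),
    n_shared_pathways = 2L
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_spec, args)
}
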
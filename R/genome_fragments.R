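#' Restriction enzyme definition
#'
#' A restriction enzyme is described by its recognition motif and the offset,
#' in bp from the motif start, at which the double-strand cut occurs. Presets
#' follow standard REBASE definitions: MboI cuts 5' of GATC (offset 0),
#' HindIII cuts A^AGCTT (offset 1).
#'
#' @param name Enzyme name.
#' @param motif Recognition motif, uppercase ACGT.
#' @param cut_offset Cut position in bp from motif start, in `[0, nchar(motif)]`.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("MboI", "GATC", 0L)
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("enzyme motif must be a non-empty string over A/C/G/T, got: ", motif)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie in [0, ", nchar(motif), "] for motif ", motif)
  }
  structure(
    list(name = name, motif = motif, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @rdname restriction_enzyme
#' @export
enzyme_preset <- function(name = c("MboI", "HindIII")) {
  name <- match.arg(name)
  switch(name,
    MboI = restriction_enzyme("MboI", "GATC", 0L),
    HindIII = restriction_enzyme("HindIII", "AAGCTT", 1L)
  )
}

#' Convert a 1-based genomic position to the internal 0-based convention
#'
#' Fragments are held internally as 0-based half-open intervals (BED
#' convention); SNP tables, GTF gene models and contact files are 1-based at
#' the I/O boundary (VCF/GTF convention). This helper is the single place
#' where the conversion happens.
#'
#' @param pos 1-based position(s).
#' @return 0-based position(s).
#' @keywords internal
pos1_to_pos0 <- function(pos) {
  as.integer(pos) - 1L
}

#' In-silico restriction digestion of genome sequences
#'
#' Scans each chromosome for every occurrence of the enzyme recognition motif
#' (overlapping occurrences included) and cuts at `motif start + cut_offset`.
#' The resulting fragments tile each chromosome exactly: the first fragment
#' starts at 0, the last ends at the chromosome length, with no gaps or
#' overlaps. Fragment ids are integers, consecutive in coordinate order and
#' unique within a chromosome.
#'
#' @param sequences A named character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet].
#' @param enzyme A [restriction_enzyme].
#' @return A data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `frag_id` (1-based, per chromosome).
#' @examples
#' digest_genome(c(chrA = "AAGATCGGATCT"), enzyme_preset("MboI"))
#' @export
digest_genome <- function(sequences, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("all sequences must be named by chromosome")
  }
  lens <- Biostrings::width(sequences)
  if (any(lens == 0L)) {
    stop("empty chromosome(s): ",
         paste(names(sequences)[lens == 0L], collapse = ", "))
  }
  hits <- Biostrings::vmatchPattern(enzyme$motif, sequences, fixed = TRUE)
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    len <- lens[i]
    # cut coordinates are 0-based; a cut at 0 or len adds no new boundary
    cuts <- BiocGenerics::start(hits[[i]]) - 1L + enzyme$cut_offset
    cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
    bounds <- c(0L, cuts, len)
    out[[i]] <- data.frame(
      chrom = names(sequences)[i],
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      frag_id = seq_len(length(bounds) - 1L),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Locate the restriction fragment containing a genomic position
#'
#' Positions are 1-based; each maps to the unique fragment whose half-open
#' 0-based interval contains it. A position that coincides with a cut site
#' therefore belongs to exactly one fragment (the one starting there).
#'
#' @param fragments Fragment table from [digest_genome()] or
#'   [read_fragments_bed()].
#' @param chrom,pos Parallel vectors of chromosome names and 1-based positions.
#' @return Integer vector of fragment ids.
#' @export
locate_fragment <- function(fragments, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  pos0 <- pos1_to_pos0(pos)
  res <- integer(length(pos))
  for (ch in unique(chrom)) {
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(fr) == 0L) {
      stop("no fragments for chromosome ", ch)
    }
    fr <- fr[order(fr$start), , drop = FALSE]
    chrom_len <- fr$end[nrow(fr)]
    bad <- pos[idx] < 1L | pos0[idx] >= chrom_len
    if (any(bad)) {
      stop("position out of range on ", ch, ": ",
           paste(pos[idx][bad], collapse = ", "),
           " (chromosome length ", chrom_len, ")")
    }
    res[idx] <- fr$frag_id[findInterval(pos0[idx], fr$start)]
  }
  res
}

#' Map restriction fragments to the genes they overlap
#'
#' A gene maps to every fragment that its body (1-based inclusive start..end,
#' converted to 0-based half-open) overlaps by at least 1 bp. A fragment may
#' carry several genes and a gene may span several fragments. Genes on
#' chromosomes absent from the fragment table are skipped with a warning.
#'
#' @param fragments Fragment table (see [digest_genome()]).
#' @param genes Gene model table (see [read_gene_models()]).
#' @return A list with `map`, a data.frame (`chrom`, `frag_id`, `gene_id`),
#'   and `n_skipped`, the number of genes dropped for unknown chromosomes.
#' @export
genes_on_fragments <- function(fragments, genes) {
  known <- genes$chrom %in% unique(fragments$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    warning(n_skipped, " gene(s) on chromosomes absent from the fragment map",
            " were skipped")
  }
  genes <- genes[known, , drop = FALSE]
  empty <- data.frame(chrom = character(), frag_id = integer(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (nrow(genes) == 0L || nrow(fragments) == 0L) {
    return(list(map = empty, n_skipped = n_skipped))
  }
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(start = fragments$start + 1L, end = fragments$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start, end = genes$end)
  )
  ov <- GenomicRanges::findOverlaps(frag_gr, gene_gr, minoverlap = 1L)
  map <- data.frame(
    chrom = fragments$chrom[S4Vectors::queryHits(ov)],
    frag_id = fragments$frag_id[S4Vectors::queryHits(ov)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  map <- map[order(map$chrom, map$frag_id, map$gene_id), , drop = FALSE]
  rownames(map) <- NULL
  list(map = map, n_skipped = n_skipped)
}

#' Read and write fragment maps as BED-like TSV
#'
#' Four columns, no header: chrom, start (0-based), end (0-based exclusive),
#' frag_id.
#'
#' @param path File path.
#' @param fragments Fragment table.
#' @return `read_fragments_bed` returns the fragment data.frame.
#' @export
read_fragments_bed <- function(path) {
  fr <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "frag_id"),
                          colClasses = c("character", "integer", "integer",
                                         "integer"))
  fr
}

#' @rdname read_fragments_bed
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end", "frag_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype-tagged SNP table
#'
#' Tab-separated with header: rsid, chrom, pos (1-based), phenotype, gwas_p.
#' Rows with association p above `gwas_p_cut` (the suggestive-significance
#' cut-off) are dropped.
#'
#' @param path TSV path.
#' @param gwas_p_cut GWAS association p-value cut-off (default 1e-6).
#' @return data.frame of retained SNPs.
#' @export
read_snp_table <- function(path, gwas_p_cut = 1e-6) {
  snps <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "phenotype", "gwas_p")
  if (!all(need %in% names(snps))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(snps$pos < 1L)) stop("SNP positions must be >= 1")
  snps[snps$gwas_p <= gwas_p_cut, , drop = FALSE]
}

#' Read gene models from a GTF file
#'
#' Keeps `gene` feature lines; coordinates stay 1-based inclusive as in GTF.
#'
#' @param path GTF path (GENCODE-style attributes).
#' @return data.frame with gene_id, gene_name, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  gene_name <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) {
    gr$gene_name
  } else {
    gr$gene_id
  }
  data.frame(
    gene_id = gr$gene_id,
    gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}
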
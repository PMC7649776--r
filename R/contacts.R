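#' Read Hi-C contact records
#'
#' Contact files are whitespace-delimited with eleven fields per record:
#' read name, strand1, chrom1, pos1, frag1, mapq1, strand2, chrom2, pos2,
#' frag2, mapq2 (the post-deduplication "merged_nodups" layout). In lenient
#' mode extra trailing columns are ignored; in strict mode any row with a
#' field count other than eleven is an error reported with its line number.
#'
#' @param path Contact file path.
#' @param lenient Ignore extra trailing columns (default TRUE).
#' @return data.frame with columns read_name, strand1, chrom1, pos1, frag1,
#'   mapq1, strand2, chrom2, pos2, frag2, mapq2.
#' @export
read_contacts <- function(path, lenient = TRUE) {
  cols <- c("read_name", "strand1", "chrom1", "pos1", "frag1", "mapq1",
            "strand2", "chrom2", "pos2", "frag2", "mapq2")
  int_cols <- c("pos1", "frag1", "mapq1", "pos2", "frag2", "mapq2")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols), stringsAsFactors = FALSE)
    for (nm in int_cols) out[[nm]] <- integer(0)
    return(out)
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  bad <- if (lenient) which(nf < 11L) else which(nf != 11L)
  if (length(bad) > 0L) {
    stop("malformed contact record at line ", bad[1L], " of ", path,
         " (", nf[bad[1L]], " fields, expected 11)")
  }
  mat <- t(vapply(fields, function(f) f[1:11], character(11)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols
  for (nm in int_cols) {
    v <- suppressWarnings(as.integer(out[[nm]]))
    if (anyNA(v)) {
      stop("non-integer value in column ", nm, " at line ",
           which(is.na(v))[1L], " of ", path)
    }
    out[[nm]] <- v
  }
  out
}

#' Filter contacts on per-end mapping quality
#'
#' A record is kept iff both ends have mapq >= `mapq_min` (inclusive, default
#' 30).
#'
#' @param contacts Contact table from [read_contacts()].
#' @param mapq_min Minimum mapping quality (default 30).
#' @return The filtered contact table.
#' @export
filter_contacts <- function(contacts, mapq_min = 30L) {
  keep <- contacts$mapq1 >= mapq_min & contacts$mapq2 >= mapq_min
  contacts[keep, , drop = FALSE]
}

#' Hi-C library quality control
#'
#' A library passes iff it has more than 90% alignable unique read pairs,
#' more than 50% unique contacts, and a duplication rate below 40%. All three
#' inequalities are strict; boundary values fail.
#'
#' @param libraries data.frame with columns library_id, pct_alignable_unique,
#'   pct_unique_contacts, duplication_rate (percentages in `[0, 100]`).
#' @return The input with added logical `qc_pass` and character `qc_reasons`
#'   (semicolon-separated failure reasons, empty when passing).
#' @export
library_qc_pass <- function(libraries) {
  need <- c("pct_alignable_unique", "pct_unique_contacts", "duplication_rate")
  missing <- setdiff(need, names(libraries))
  if (length(missing) > 0L) {
    stop("missing library QC field(s): ", paste(missing, collapse = ", "))
  }
  for (nm in need) {
    if (anyNA(libraries[[nm]])) stop("missing values in QC field ", nm)
  }
  reasons <- mapply(function(a, u, d) {
    r <- character(0)
    if (!(a > 90)) r <- c(r, sprintf("alignable unique read pairs %.4g%% not > 90%%", a))
    if (!(u > 50)) r <- c(r, sprintf("unique contacts %.4g%% not > 50%%", u))
    if (!(d < 40)) r <- c(r, sprintf("duplication rate %.4g%% not < 40%%", d))
    paste(r, collapse = "; ")
  }, libraries$pct_alignable_unique, libraries$pct_unique_contacts,
     libraries$duplication_rate)
  libraries$qc_pass <- !nzchar(reasons)
  libraries$qc_reasons <- unname(reasons)
  libraries
}

#' Read the Hi-C library metadata table
#'
#' TSV with header: library_id, tissue_label, is_brain (logical or 0/1),
#' pct_alignable_unique, pct_unique_contacts, duplication_rate.
#'
#' @param path TSV path.
#' @return data.frame of library metadata.
#' @export
read_library_table <- function(path) {
  libs <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  libs$is_brain <- as.logical(libs$is_brain)
  libs
}

#' Capture fragments spatially interacting with SNP-containing fragments
#'
#' For every contact in which either end falls on a SNP's restriction
#' fragment, the other end's fragment is recorded as a spatial partner of
#' that SNP. A contact whose two ends both carry SNP fragments contributes
#' in both directions; self-contacts (both ends on the same fragment) are
#' recorded once per contact and flagged, since a SNP may regulate a gene
#' residing on its own fragment. Contacts are expected to be mapq-filtered
#' already (see [filter_contacts()]).
#'
#' @param snp_frags data.frame with columns rsid, chrom, frag_id (one row per
#'   SNP; from [locate_fragment()]).
#' @param contacts mapq-filtered contact table.
#' @param library_id Library identifier attached to the result.
#' @return data.frame with columns rsid, library_id, partner_chrom,
#'   partner_frag, n_contacts, self_contact.
#' @export
capture_partners <- function(snp_frags, contacts, library_id) {
  empty <- data.frame(rsid = character(), library_id = character(),
                      partner_chrom = character(), partner_frag = integer(),
                      n_contacts = integer(), self_contact = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(contacts) == 0L || nrow(snp_frags) == 0L) return(empty)
  snp_key <- paste(snp_frags$chrom, snp_frags$frag_id)
  key1 <- paste(contacts$chrom1, contacts$frag1)
  key2 <- paste(contacts$chrom2, contacts$frag2)
  is_self <- key1 == key2
  expand <- function(keys, partner_chrom, partner_frag, self) {
    # several SNPs may share a fragment: expand every (contact, SNP) match
    hits <- lapply(keys, function(k) which(snp_key == k))
    n <- lengths(hits)
    if (sum(n) == 0L) return(NULL)
    data.frame(snp_row = unlist(hits),
               partner_chrom = rep(partner_chrom, n),
               partner_frag = rep(partner_frag, n),
               self_contact = rep(self, n),
               stringsAsFactors = FALSE)
  }
  recs <- rbind(
    expand(key1, contacts$chrom2, contacts$frag2, is_self),
    # self-contacts already matched through end 1; match end 2 only otherwise
    expand(ifelse(is_self, NA_character_, key2),
           contacts$chrom1, contacts$frag1, is_self)
  )
  if (is.null(recs) || nrow(recs) == 0L) return(empty)
  agg <- stats::aggregate(
    list(n_contacts = rep(1L, nrow(recs))),
    by = list(snp_row = recs$snp_row, partner_chrom = recs$partner_chrom,
              partner_frag = recs$partner_frag,
              self_contact = recs$self_contact),
    FUN = sum
  )
  out <- data.frame(
    rsid = snp_frags$rsid[agg$snp_row],
    library_id = library_id,
    partner_chrom = agg$partner_chrom,
    partner_frag = as.integer(agg$partner_frag),
    n_contacts = as.integer(agg$n_contacts),
    self_contact = agg$self_contact,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rsid, out$partner_chrom, out$partner_frag), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
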
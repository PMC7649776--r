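#' Inclusive and exclusive overlap counts for phenotype sets
#'
#' For every non-empty combination of phenotypes, reports the inclusive
#' count (size of the intersection of the named sets, ignoring the others)
#' and the exclusive count (elements belonging to exactly that combination,
#' UpSet-style). Exclusive counts partition the union of all sets.
#'
#' @param sets Named list of character vectors (SNP, eQTL, eGene or pathway
#'   ids per phenotype). Duplicates within a set are ignored.
#' @return data.frame with columns combination (phenotype names joined by
#'   "+"), degree, inclusive, exclusive.
#' @export
overlap_table <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 phenotype sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named by phenotype")
  }
  sets <- lapply(sets, unique)
  phenos <- names(sets)
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(which(row), collapse = ","))
  combos <- unlist(lapply(seq_len(k), function(d) {
    utils::combn(seq_len(k), d, simplify = FALSE)
  }), recursive = FALSE)
  out <- data.frame(
    combination = vapply(combos, function(ix) paste(phenos[ix],
                                                    collapse = "+"),
                         character(1)),
    degree = vapply(combos, length, integer(1)),
    inclusive = vapply(combos, function(ix) {
      sum(rowSums(member[, ix, drop = FALSE]) == length(ix))
    }, integer(1)),
    exclusive = vapply(combos, function(ix) {
      sum(sig == paste(ix, collapse = ","))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  out
}

#' Elements shared by a combination of phenotype sets
#'
#' @param sets Named list of id vectors.
#' @param combination Phenotype names to intersect (default: all).
#' @return Character vector: the inclusive intersection.
#' @export
shared_elements <- function(sets, combination = names(sets)) {
  Reduce(intersect, lapply(sets[combination], unique))
}

# Deterministic 31-bit sub-seed from a master seed and a text tag, so each
# phenotype combination gets its own reproducible RNG stream and adding a
# combination never perturbs the others.
derive_seed <- function(seed, tag) {
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Run fn() under a private RNG stream without disturbing the caller's RNG.
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Bootstrap significance of an observed multi-set overlap
#'
#' Tests whether an observed number of shared elements (e.g. eGenes) across
#' phenotypes exceeds chance. Each iteration draws, independently for each
#' phenotype, a uniform without-replacement sample of that phenotype's set
#' size from the reference universe, and counts the size of the intersection
#' of all drawn samples. The p-value is the fraction of iterations whose
#' resampled overlap is greater than or equal to the observed overlap
#' (count / N, reported exactly as such, so p = 0 is possible; `p_upper`
#' = (count + 1)/(N + 1) is also provided). Deterministic given `seed`.
#'
#' @param sizes Integer vector: per-phenotype set sizes.
#' @param reference The element universe: either a vector of element ids or
#'   a single integer universe size (only the size matters).
#' @param observed Observed overlap count (integer >= 0).
#' @param n_iter Number of bootstrap iterations N (default 10000).
#' @param seed RNG seed for this test.
#' @param combination Label for the tested phenotype combination.
#' @param reference_set_id Label for the universe convention, e.g.
#'   "ref1_all_genes", "ref2_hic_genes", "pathway_universe".
#' @return An object of class `bootstrap_result`: list with combination,
#'   observed, n_iter, n_ge, p_value, p_upper, reference_set_id, seed,
#'   unattainable flag and the vector of resampled overlap counts
#'   (`null_counts`).
#' @export
bootstrap_overlap <- function(sizes, reference, observed, n_iter = 10000L,
                              seed = 1L, combination = "all",
                              reference_set_id = "ref1_all_genes") {
  m <- if (length(reference) == 1L && is.numeric(reference)) {
    as.integer(reference)
  } else {
    length(unique(reference))
  }
  sizes <- as.integer(sizes)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (any(sizes > m)) {
    stop("phenotype set size (", max(sizes),
         ") exceeds reference universe size (", m, ")")
  }
  if (any(sizes < 0L) || observed < 0L) stop("sizes and observed must be >= 0")
  k <- length(sizes)
  unattainable <- observed > min(sizes)
  null_counts <- with_local_seed(seed, function() {
    out <- integer(n_iter)
    for (i in seq_len(n_iter)) {
      draws <- unlist(lapply(sizes, function(s) sample.int(m, s)))
      out[i] <- sum(tabulate(draws, nbins = m) == k)
    }
    out
  })
  n_ge <- sum(null_counts >= observed)
  structure(list(
    combination = combination,
    observed = as.integer(observed),
    n_iter = n_iter,
    n_ge = n_ge,
    p_value = n_ge / n_iter,
    p_upper = (n_ge + 1) / (n_iter + 1),
    reference_set_id = reference_set_id,
    seed = as.integer(seed),
    unattainable = unattainable,
    null_counts = null_counts
  ), class = "bootstrap_result")
}

#' Bootstrap overlap test from the phenotype sets themselves
#'
#' Convenience wrapper: computes the observed inclusive intersection of the
#' given sets and calls [bootstrap_overlap()] with their sizes.
#'
#' @param sets Named list of id vectors (the phenotype combination to test).
#' @param reference Universe (id vector or size); every set must be a subset
#'   of it in size.
#' @param n_iter,seed,reference_set_id Passed to [bootstrap_overlap()].
#' @return A `bootstrap_result`.
#' @export
bootstrap_overlap_sets <- function(sets, reference, n_iter = 10000L,
                                   seed = 1L,
                                   reference_set_id = "ref1_all_genes") {
  sets <- lapply(sets, unique)
  observed <- length(Reduce(intersect, sets))
  combination <- paste(names(sets), collapse = "+")
  bootstrap_overlap(lengths(sets), reference, observed, n_iter = n_iter,
                    seed = derive_seed(seed, paste(reference_set_id,
                                                   combination)),
                    combination = combination,
                    reference_set_id = reference_set_id)
}

#' Null-hypothesis rejection for a bootstrap overlap test
#'
#' The null (the observed overlap is due to chance) is rejected iff the
#' bootstrap p-value is strictly below the threshold (default 0.01).
#'
#' @param result A `bootstrap_result` or a bare p-value.
#' @param threshold Rejection threshold (default 0.01, strict).
#' @return Logical.
#' @export
significance_call <- function(result, threshold = 0.01) {
  p <- if (inherits(result, "bootstrap_result")) result$p_value else result
  p < threshold
}

#' Bootstrap significance of shared pathways across phenotypes
#'
#' Identical resampling machinery to [bootstrap_overlap()], with pathway ids
#' drawn from a pathway universe of fixed size (default 536, the size of a
#' KEGG-style reference collection).
#'
#' @param pathway_sets Named list: significant pathway ids per phenotype.
#' @param universe_n Pathway universe size (default 536).
#' @param n_iter,seed Passed to [bootstrap_overlap()].
#' @return A `bootstrap_result` with reference_set_id "pathway_universe".
#' @export
pathway_overlap_bootstrap <- function(pathway_sets, universe_n = 536L,
                                      n_iter = 10000L, seed = 1L) {
  bootstrap_overlap_sets(pathway_sets, universe_n, n_iter = n_iter,
                         seed = seed, reference_set_id = "pathway_universe")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap overlap test [", x$reference_set_id, "]\n", sep = "")
  cat("  combination: ", x$combination, "\n", sep = "")
  cat("  observed overlap: ", x$observed,
      if (x$unattainable) "  (exceeds smallest set: unattainable)" else "",
      "\n", sep = "")
  cat("  N = ", x$n_iter, ", #(null >= observed) = ", x$n_ge,
      ", p = ", format(x$p_value), " (p_upper = ",
      format(x$p_upper), ")\n", sep = "")
  invisible(x)
}
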
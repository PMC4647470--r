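#' Per-gene, per-tissue, per-species expression variability
#'
#' For every (gene, tissue, species) cell with enough replicates the linear
#' scale mean, sample standard deviation (n-1 denominator) and coefficient of
#' variation `cv = sd / mean` are computed. Cells with fewer than
#' `min_replicates` samples are skipped with a warning; rows with
#' non-positive mean are dropped and counted in the `n_dropped` attribute.
#'
#' @param m A linear-scale [expression_matrix()].
#' @param min_replicates Minimum replicates per cell (default 3).
#' @param by_sex Also stratify cells by sex (default `FALSE`).
#' @return Data frame with columns `gene`, `tissue`, `species` (and `sex` when
#'   stratified), `n`, `mean`, `sd`, `cv`.
#' @export
cv_table <- function(m, min_replicates = 3, by_sex = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "linear")
    stop("the coefficient of variation is computed on linear-scale values")
  meta <- m$meta
  key <- if (by_sex) interaction(meta$tissue, meta$species, meta$sex, drop = TRUE)
         else interaction(meta$tissue, meta$species, drop = TRUE)
  cells <- split(seq_len(nrow(meta)), key)
  res <- vector("list", length(cells))
  dropped <- 0L
  for (i in seq_along(cells)) {
    cols <- cells[[i]]
    n <- length(cols)
    info <- meta[cols[1], , drop = FALSE]
    if (n < min_replicates) {
      warning(sprintf("cell (%s, %s%s): %d replicate(s) < %d, skipped",
                      info$tissue, info$species,
                      if (by_sex) paste0(", ", info$sex) else "",
                      n, min_replicates))
      next
    }
    x <- m$values[, cols, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (n - 1))
    keep <- mu > 0
    dropped <- dropped + sum(!keep)
    df <- data.frame(gene = rownames(x)[keep], tissue = info$tissue,
                     species = info$species, n = n, mean = mu[keep],
                     sd = sdv[keep], cv = sdv[keep] / mu[keep],
                     stringsAsFactors = FALSE, row.names = NULL)
    if (by_sex) df$sex <- info$sex
    res[[i]] <- df
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) stop("no cell reached the replicate minimum")
  attr(out, "n_dropped") <- dropped
  out
}

#' Count highly variable genes per tissue and species
#'
#' A gene is highly variable in a cell when its coefficient of variation
#' strictly exceeds the cutoff (reading a "CV > 10 %" rule literally, a CV of
#' exactly 0.10 is not flagged).
#'
#' @param vt A variability table from [cv_table()].
#' @param cutoff CV cutoff (default 0.10).
#' @return Data frame with `tissue`, `species`, `n_genes`, `n_high`,
#'   `fraction`.
#' @export
count_high_variance <- function(vt, cutoff = 0.10) {
  if (nrow(vt) == 0) stop("empty variability table")
  key <- interaction(vt$tissue, vt$species, drop = TRUE)
  cells <- split(seq_len(nrow(vt)), key)
  out <- do.call(rbind, lapply(cells, function(idx) {
    data.frame(tissue = vt$tissue[idx[1]], species = vt$species[idx[1]],
               n_genes = length(idx), n_high = sum(vt$cv[idx] > cutoff),
               stringsAsFactors = FALSE)
  }))
  out$fraction <- out$n_high / out$n_genes
  rownames(out) <- NULL
  out
}

#' Two-proportion test for highly variable gene counts between species
#'
#' Standard two-proportion chi-square test (no continuity correction by
#' default, matching large-sample usage) comparing `kA / nA` against
#' `kB / nB`, with the fold-difference of the proportions.
#'
#' @param kA,nA Count and total for species A.
#' @param kB,nB Count and total for species B.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list of class `prop_test_result` with `statistic` (chi-square),
#'   `p_value` (two-sided), `fold` (`(kA/nA)/(kB/nB)`, `Inf` when `kB` is 0)
#'   and the input counts.
#' @export
compare_species_proportions <- function(kA, nA, kB, nB, correct = FALSE) {
  for (v in list(kA, nA, kB, nB))
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop("counts must be single non-negative numbers")
  if (nA <= 0 || nB <= 0) stop("totals must be positive")
  if (kA > nA || kB > nB) stop("counts cannot exceed totals")
  ht <- suppressWarnings(
    stats::prop.test(c(kA, kB), c(nA, nB), correct = correct))
  pA <- kA / nA
  pB <- kB / nB
  fold <- if (pB == 0) {
    if (pA == 0) NA_real_ else Inf
  } else pA / pB
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value), fold = fold,
                 kA = kA, nA = nA, kB = kB, nB = nB, correct = correct),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("two-proportion test: %d/%d vs %d/%d\n",
              x$kA, x$nA, x$kB, x$nB))
  cat(sprintf("  chi-square = %.4g, p = %.4g, fold = %.4g\n",
              x$statistic, x$p_value, x$fold))
  invisible(x)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each annotation term, the one-sided (upper tail) hypergeometric
#' probability of observing at least the actual overlap between `gene_set` and
#' the term's genes within `universe`, with Benjamini-Hochberg adjusted
#' p-values across terms. Term gene lists are intersected with the universe
#' first.
#'
#' @param gene_set Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene background.
#' @param term_map Named list mapping term ids to character vectors of genes.
#' @return Data frame with one row per term: `term`, `overlap`, `set_size`,
#'   `term_size`, `universe_size`, `p`, `p_adj`.
#' @export
overrepresentation <- function(gene_set, universe, term_map) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  gene_set <- unique(as.character(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0)
    stop("gene_set not contained in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (!is.list(term_map) || is.null(names(term_map)))
    stop("'term_map' must be a named list of gene vectors")
  N <- length(universe)
  K <- length(gene_set)
  rows <- lapply(names(term_map), function(term) {
    tg <- intersect(unique(as.character(term_map[[term]])), universe)
    k <- length(intersect(gene_set, tg))
    p <- stats::phyper(k - 1, length(tg), N - length(tg), K,
                       lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = K,
               term_size = length(tg), universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read a term-to-gene annotation map
#'
#' Accepts either a GMT-style file (term, description, genes...) or a
#' two-column TSV (`term`, `gene`).
#'
#' @param path Input path.
#' @return Named list mapping terms to gene id vectors.
#' @export
read_term_map <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 2)) {  # two-column TSV, possibly with a header
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(df[1, 1]), "term")) df <- df[-1, , drop = FALSE]
    return(split(as.character(df[[2]]), df[[1]]))
  }
  out <- lapply(fields, function(f) {
    if (length(f) < 3) stop("malformed term map line: ", paste(f, collapse = " "))
    f[-(1:2)]
  })
  names(out) <- vapply(fields, `[[`, character(1), 1)
  out
}
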
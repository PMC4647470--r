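#' Expression matrix with sample metadata
#'
#' Container for a genes x samples expression matrix together with per-sample
#' metadata (species, tissue, sex, age group) and a scale flag. Values must be
#' finite; on the linear scale they must also be non-negative. Gene identifiers
#' must be unique; when the matrix spans two species they are expected to live
#' in a shared ortholog namespace (see [merge_cross_species()]).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param meta Data frame with one row per sample and at least columns
#'   `sample_id`, `species`, `tissue`. Optional `sex` and `age_group` columns
#'   default to `"unknown"`. Rows are reordered to match the matrix columns.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `meta` and `scale`.
#' @export
expression_matrix <- function(values, meta, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0)
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale values must be non-negative")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in c("sample_id", "species", "tissue")) {
    if (!col %in% names(meta)) stop("metadata lacks required column '", col, "'")
  }
  for (col in c("sex", "age_group")) {
    if (!col %in% names(meta)) meta[[col]] <- "unknown"
  }
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing) > 0)
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  species: %s | tissues: %d\n",
              paste(unique(x$meta$species), collapse = ", "),
              length(unique(x$meta$tissue))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file holds genes in rows with a header row of sample ids; the
#' first column carries the gene ids. The metadata file has one row per sample
#' with columns `sample_id`, `species`, `tissue` and optionally `sex`,
#' `age_group`.
#'
#' @param path Path to the matrix TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param scale Scale flag to record, `"linear"` (default) or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, meta_path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file must have a gene id column plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric value in row %d, column '%s' of %s",
                   bad, names(vals)[j], path))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- gene_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = scale)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' @param m An [expression_matrix()].
#' @param path Output path for the matrix TSV (first column `gene_id`).
#' @param meta_path Optional output path for the metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, meta_path = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  out <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(m$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale expression matrix
#'
#' Applies `log2(value + offset)` and flips the scale flag. A small positive
#' offset keeps zero intensities finite.
#'
#' @param m A linear-scale [expression_matrix()].
#' @param offset Small positive constant added before the logarithm (default 1).
#' @return A log2-scale `expression_matrix`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0)
    stop("'offset' must be a single positive number")
  m$values <- log2(m$values + offset)
  m$scale <- "log2"
  m
}

#' Quantile-normalize an expression matrix
#'
#' After normalization every column shares the identical sorted value multiset
#' (the row-wise mean of the sorted columns). Tied values within a column
#' receive the mean of their candidate quantile targets.
#'
#' @param m An [expression_matrix()] with at least two samples.
#' @return The normalized `expression_matrix` (same scale flag).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m$values) < 2) stop("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  m$values <- norm
  m
}

#' Global rank-invariant set normalization (GRSN)
#'
#' Corrects intensity-dependent distortions between a log2-scale matrix and a
#' reference using genes whose expression ranks are stable across samples. The
#' rank-invariant set is found by iteratively discarding the genes with the
#' largest cross-sample rank spread until `invariant_fraction` of the genes
#' remains; each sample is then corrected by a lowess fit of its M-vs-A
#' deviation from the reference, restricted to the invariant set and evaluated
#' at every gene's abundance.
#'
#' A constant log2 offset between target and reference is removed exactly, and
#' a sample identical to its reference profile is returned unchanged. Genes at
#' the extreme mean ranks are excluded from invariant candidacy (a gene that
#' is the highest or lowest in every sample has a trivially stable rank while
#' its level may still be sample-specific).
#'
#' @param m A log2-scale [expression_matrix()].
#' @param reference Optional log2-scale `expression_matrix` whose gene space
#'   covers that of `m`. A reference with the same number of samples is
#'   compared column-by-column (matched samples); otherwise its per-gene mean
#'   profile is the common reference. With `NULL` (default) the pooled
#'   per-gene mean of `m` itself is used.
#' @param invariant_fraction Fraction of genes retained in the invariant set
#'   (default 0.05).
#' @param iterations Number of trimming iterations (default 4).
#' @param span Lowess smoother span for the M-vs-A fit (default 0.3).
#' @return The corrected `expression_matrix`.
#' @export
grsn_normalize <- function(m, reference = NULL, invariant_fraction = 0.05,
                           iterations = 4, span = 0.3) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2") stop("GRSN operates on log2-scale matrices")
  if (invariant_fraction <= 0 || invariant_fraction >= 1)
    stop("'invariant_fraction' must be in (0, 1)")
  genes <- rownames(m$values)
  if (is.null(reference)) {
    ref_mat <- matrix(rowMeans(m$values), nrow = nrow(m$values),
                      ncol = ncol(m$values))
  } else {
    stopifnot(inherits(reference, "expression_matrix"))
    if (reference$scale != "log2") stop("reference must be on the log2 scale")
    shared <- intersect(genes, rownames(reference$values))
    if (length(shared) < 100)
      stop("fewer than 100 genes shared with the reference; fit unstable")
    if (length(shared) < length(genes))
      stop("reference must cover all genes of the target matrix (",
           length(genes) - length(shared), " missing)")
    rv <- reference$values[genes, , drop = FALSE]
    ref_mat <- if (ncol(rv) == ncol(m$values)) rv else
      matrix(rowMeans(rv), nrow = nrow(m$values), ncol = ncol(m$values))
  }
  if (length(genes) < 100)
    stop("fewer than 100 genes; fit unstable")

  # iterative global rank-invariant set: trim genes with the widest rank
  # spread across all samples plus the reference profile
  rank_mat <- apply(cbind(m$values, ref = rowMeans(ref_mat)), 2, rank)
  n0 <- length(genes)
  mean_rank <- rowMeans(rank_mat)
  trim <- stats::quantile(mean_rank, c(0.02, 0.98))
  keep <- which(mean_rank > trim[1] & mean_rank < trim[2])
  target_n <- max(20L, ceiling(invariant_fraction * n0))
  fracs <- invariant_fraction^(seq_len(iterations) / iterations)
  for (fr in fracs) {
    sub <- rank_mat[keep, , drop = FALSE]
    sub <- apply(sub, 2, rank)  # re-rank within the surviving set
    spread <- apply(sub, 1, function(r) max(r) - min(r))
    n_keep <- max(target_n, ceiling(fr * n0))
    keep <- keep[order(spread)[seq_len(min(n_keep, length(keep)))]]
  }
  inv <- keep

  out <- m$values
  for (j in seq_len(ncol(out))) {
    x <- m$values[, j]
    mm <- x - ref_mat[, j]
    aa <- (x + ref_mat[, j]) / 2
    if (all(abs(mm[inv]) < .Machine$double.eps^0.5)) next  # identity sample
    fit <- stats::lowess(aa[inv], mm[inv], f = span)
    corr <- stats::approx(fit$x, fit$y, xout = aa, rule = 2, ties = mean)$y
    out[, j] <- x - corr
  }
  m$values <- out
  attr(m, "invariant_set") <- genes[inv]
  m
}

#' Merge two single-species matrices into one cross-species matrix
#'
#' Genes are restricted to the 1:1 ortholog pairs present in both matrices and
#' renamed to a common namespace; samples are concatenated with their species
#' metadata preserved.
#'
#' @param mA,mB [expression_matrix()] objects on the same scale.
#' @param ortholog_map Data frame with columns `gene_a` (ids in `mA`) and
#'   `gene_b` (ids in `mB`); an optional `name` column supplies the common
#'   gene id (defaults to `gene_a`). The map must be 1:1 on the retained set.
#' @return A merged `expression_matrix`.
#' @export
merge_cross_species <- function(mA, mB, ortholog_map) {
  stopifnot(inherits(mA, "expression_matrix"), inherits(mB, "expression_matrix"))
  if (mA$scale != mB$scale) stop("matrices are on different scales")
  map <- as.data.frame(ortholog_map, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(map)))
    stop("ortholog map needs columns 'gene_a' and 'gene_b'")
  keep <- map$gene_a %in% rownames(mA$values) & map$gene_b %in% rownames(mB$values)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0) stop("empty gene intersection under the ortholog map")
  dup_a <- unique(map$gene_a[duplicated(map$gene_a)])
  dup_b <- unique(map$gene_b[duplicated(map$gene_b)])
  if (length(dup_a) + length(dup_b) > 0)
    stop("ortholog map is not 1:1; offenders: ",
         paste(utils::head(c(dup_a, dup_b), 5), collapse = ", "))
  common <- if ("name" %in% names(map)) map$name else map$gene_a
  va <- mA$values[map$gene_a, , drop = FALSE]
  vb <- mB$values[map$gene_b, , drop = FALSE]
  rownames(va) <- rownames(vb) <- common
  meta <- rbind(mA$meta, mB$meta)
  expression_matrix(cbind(va, vb), meta, scale = mA$scale)
}

#' Principal component analysis of expression samples
#'
#' Samples are the observations; genes are centered (and optionally scaled)
#' internally. Scores are the projections onto the top-`k` right singular
#' directions of the gene-centered matrix, and variance fractions come from
#' the squared singular values.
#'
#' @param m An [expression_matrix()] with at least two samples.
#' @param k Number of components to return.
#' @param scale_genes Scale genes to unit variance before the decomposition
#'   (default `FALSE`, matching common microarray practice).
#' @return An object of class `pca_result` with `scores` (samples x k) and
#'   `variance_fraction` (length k, non-increasing, summing to <= 1).
#' @export
pca <- function(m, k = 3, scale_genes = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (ncol(m$values) < 2) stop("PCA needs at least 2 samples")
  if (k < 1 || k > min(dim(m$values)))
    stop("'k' must be between 1 and min(genes, samples)")
  x <- t(m$values)
  if (scale_genes) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_genes)
  total <- sum(pr$sdev^2)
  vf <- if (total > 0) (pr$sdev^2 / total)[seq_len(k)] else rep(0, k)
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}
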
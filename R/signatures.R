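#' Gini index of a non-negative vector
#'
#' Inequality measure used here to quantify tissue specificity of a gene's
#' per-tissue mean expression: 0 for a perfectly uniform profile, approaching
#' 1 when a single tissue carries all the signal. Computed as
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar{x}),}
#' which for a vector of length n is bounded by (n-1)/n. The index is
#' scale-invariant: `gini(c * x) == gini(x)` for any c > 0.
#'
#' @param x Non-negative numeric vector of length >= 2 with at least one
#'   positive entry. Per-tissue means on the linear scale.
#' @return The Gini index, a value in `[0, (n-1)/n]`.
#' @export
gini <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("'x' must be a numeric vector of length >= 2")
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative")
  s <- sum(x)
  if (s == 0) stop("Gini index undefined for an all-zero vector")
  n <- length(x)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
}

#' Tissue signature: genes specific to one tissue
#'
#' @param tissue Tissue label.
#' @param gene_ids Character vector of member genes.
#' @param gini_values Named numeric vector of Gini indices, one per member.
#' @param threshold Gini threshold that was applied.
#' @param source Dataset label the signature was derived from.
#' @return An object of class `tissue_signature`.
#' @export
tissue_signature <- function(tissue, gene_ids, gini_values,
                             threshold = 0.7, source = "synthetic") {
  stopifnot(length(gene_ids) == length(gini_values))
  structure(list(tissue = tissue, gene_ids = as.character(gene_ids),
                 gini_values = stats::setNames(as.numeric(gini_values),
                                               gene_ids),
                 threshold_used = threshold, source = source),
            class = "tissue_signature")
}

#' @export
print.tissue_signature <- function(x, ...) {
  cat(sprintf("tissue_signature '%s' (%s): %d genes, Gini >= %g\n",
              x$tissue, x$source, length(x$gene_ids), x$threshold_used))
  invisible(x)
}

#' Per-gene per-tissue mean expression
#'
#' @param m A linear-scale [expression_matrix()].
#' @return Numeric matrix, genes x tissues.
#' @export
tissue_means <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  tissues <- unique(m$meta$tissue)
  out <- vapply(tissues, function(t) {
    cols <- which(m$meta$tissue == t)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  colnames(out) <- tissues
  out
}

#' Extract tissue signatures by Gini-index thresholding
#'
#' For each gene the per-tissue mean profile is summarized by its Gini index;
#' a gene joins the signature of its maximally expressing tissue when the
#' index reaches the threshold (inclusive: a Gini of exactly `threshold`
#' qualifies). Genes whose maximum is tied between tissues are ambiguous and
#' excluded, so the signatures partition the selected genes.
#'
#' @param m A linear-scale [expression_matrix()] with >= 2 tissues, each with
#'   at least one sample.
#' @param threshold Minimum Gini index for signature membership (default 0.7).
#' @param source Dataset label recorded in each signature.
#' @return Named list of [tissue_signature()] objects, one per tissue.
#' @export
extract_signatures <- function(m, threshold = 0.7, source = "synthetic") {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "linear")
    stop("signatures are extracted from linear-scale values")
  tissues <- unique(m$meta$tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues")
  counts <- table(factor(m$meta$tissue, levels = tissues))
  if (any(counts == 0))
    stop("tissue with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  tm <- tissue_means(m)
  ok <- rowSums(tm) > 0
  if (any(!ok))
    warning(sum(!ok), " all-zero gene(s) excluded from signature extraction")
  tm <- tm[ok, , drop = FALSE]
  gi <- apply(tm, 1, gini)
  top <- apply(tm, 1, function(v) {
    w <- which(v == max(v))
    if (length(w) > 1) NA_integer_ else w  # ambiguous argmax: exclude
  })
  sel <- !is.na(top) & gi >= threshold
  out <- lapply(tissues, function(t) {
    idx <- which(sel & tissues[top] == t)
    tissue_signature(t, rownames(tm)[idx], gi[idx],
                     threshold = threshold, source = source)
  })
  names(out) <- tissues
  out
}

#' Score samples for signature enrichment
#'
#' Each gene is z-scored across samples (log2 scale); a sample's score for a
#' signature is the mean z over the signature's genes (`method = "zscore"`).
#' The alternative `"percentile"` method uses the mean per-gene rank
#' percentile instead. Signatures with fewer than 3 genes present in the
#' matrix are reported as missing. `row_scaled` rescales each sample row of
#' the score matrix to `[0, 1]` for display, mirroring the relative-by-row
#' color scale of enrichment heat maps.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param signatures List of [tissue_signature()] objects.
#' @param method `"zscore"` (default) or `"percentile"`.
#' @return An object of class `enrichment_result` with `scores` (samples x
#'   signatures), `row_scaled` (same shape) and `n_missing` (dropped genes
#'   per signature).
#' @export
enrichment_score <- function(m, signatures, method = c("zscore", "percentile")) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  if (m$scale != "log2") stop("enrichment scoring expects log2-scale values")
  v <- m$values
  if (method == "zscore") {
    mu <- rowMeans(v)
    sdv <- apply(v, 1, stats::sd)
    z <- (v - mu) / ifelse(sdv > 0, sdv, Inf)  # constant genes score 0
  } else {
    z <- t(apply(v, 1, rank)) / (ncol(v) + 1)
  }
  nm <- vapply(signatures, function(s) s$tissue, character(1))
  scores <- matrix(NA_real_, nrow = ncol(v), ncol = length(signatures),
                   dimnames = list(colnames(v), nm))
  n_missing <- integer(length(signatures))
  for (i in seq_along(signatures)) {
    genes <- intersect(signatures[[i]]$gene_ids, rownames(v))
    n_missing[i] <- length(signatures[[i]]$gene_ids) - length(genes)
    if (n_missing[i] > 0)
      message(sprintf("signature '%s': %d gene(s) absent from the matrix",
                      nm[i], n_missing[i]))
    if (length(genes) < 3) next  # reported as missing
    scores[, i] <- colMeans(z[genes, , drop = FALSE])
  }
  row_scaled <- scores
  for (i in seq_len(nrow(scores))) {
    r <- scores[i, ]
    rng <- suppressWarnings(range(r, na.rm = TRUE))
    row_scaled[i, ] <- if (!all(is.finite(rng)) || diff(rng) == 0) r * 0
                       else (r - rng[1]) / diff(rng)
  }
  structure(list(scores = scores, row_scaled = row_scaled,
                 n_missing = stats::setNames(n_missing, nm), method = method),
            class = "enrichment_result")
}

#' Write signatures as a GMT-style gene-set file
#'
#' One line per signature: name, source, then the member gene ids, all
#' tab-separated.
#'
#' @param signatures List of [tissue_signature()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    paste(c(s$tissue, s$source, s$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT-style gene-set file
#'
#' @param path Path to a GMT file (name, source/description, gene ids).
#' @param threshold Gini threshold to record on the resulting signatures
#'   (GMT files do not carry per-gene Gini values; they are set to `NA`).
#' @return Named list of [tissue_signature()] objects.
#' @export
read_gmt <- function(path, threshold = NA_real_) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(l, 1, 40))
    genes <- f[-(1:2)]
    tissue_signature(f[1], genes, rep(NA_real_, length(genes)),
                     threshold = threshold, source = f[2])
  })
  names(out) <- vapply(out, function(s) s$tissue, character(1))
  out
}
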
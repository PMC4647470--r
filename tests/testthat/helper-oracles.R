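# Independent oracles used to cross-check the implementation.

# Gini by the literal pairwise double sum.
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Global affine-gap alignment score by dynamic programming over the three
# explicit states (match, gap-in-a, gap-in-b); independent of the package's
# alignment engine. Gap of length L costs |open| + (L - 1) * |extend|.
align_score_oracle <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- gap_open + (i - 1) * gap_extend
  for (j in seq_len(m)) Iy[1, j + 1] <- gap_open + (j - 1) * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + gap_open,
                              Ix[i, j + 1] + gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                              Iy[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Local (Smith-Waterman) affine-gap score by the same explicit recursion.
local_score_oracle <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(0, n + 1, m + 1)
  Ix[] <- Iy[] <- NEG
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, s + max(M[i, j], Ix[i, j], Iy[i, j]))
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + gap_open,
                              Ix[i, j + 1] + gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                              Iy[i + 1, j] + gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# All sequences over an alphabet up to a maximum length.
all_seqs <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Small expression simulation used across tests (13 tissues, low gene count).
small_expression_spec <- function(seed = 1, noise = cv_to_sigma_log2(0.03),
                                  n_genes = 400, n_sig = 5, n_hv = 10,
                                  reps = 12) {
  expression_sim_spec(n_genes = n_genes,
                      n_signature_genes_per_tissue = n_sig,
                      n_high_cv_genes_per_tissue = n_hv,
                      replicates_per_tissue = reps,
                      replicate_noise_sd_log2 = noise,
                      seed = seed)
}

# A minimal hand-written PDB text fixture (fixed-column records).
pdb_line <- function(type, eleno, elety, alt, resid, chain, resno,
                     x, y, z, occ, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, alt, resid, chain, resno, x, y, z, occ, 0,
          element)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
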
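#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = read_count / ((length_nt / 1000) * (library_size / 1e6))`.
#'
#' @param read_count Reads mapped to the transcript (>= 0); vectorized.
#' @param length_nt Transcript length in nucleotides (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(read_count, length_nt, library_size) {
  if (any(length_nt <= 0)) stop("'length_nt' must be positive")
  if (any(library_size <= 0)) stop("'library_size' must be positive")
  if (any(read_count < 0)) stop("'read_count' must be non-negative")
  read_count / ((length_nt / 1000) * (library_size / 1e6))
}

#' Contig length filter
#'
#' Pass if and only if the contig is strictly longer than `min_nt`
#' (a 500-nt contig fails a "longer than 500 nucleotides" rule).
#'
#' @param length_nt Vector of contig lengths.
#' @param min_nt Length threshold (default 500).
#' @return Logical vector of pass flags.
#' @export
filter_length <- function(length_nt, min_nt = 500) {
  length_nt > min_nt
}

#' Protein-coding hit filter
#'
#' A candidate fails when any hit against the protein-coding reference sets
#' (mRNAs, proteins) reaches both the identity and the query-coverage gate.
#'
#' @param candidate_ids Candidate contig ids.
#' @param hits Data frame of hits with columns `query`, `target`, `identity`
#'   (percent) and `coverage` (fraction of query length).
#' @param min_identity Identity gate in percent (default 70).
#' @param min_coverage Coverage gate as a fraction (default 0.5).
#' @return Named logical vector: `TRUE` = pass (no disqualifying hit).
#' @export
filter_coding <- function(candidate_ids, hits,
                          min_identity = 70, min_coverage = 0.5) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  need <- c("query", "target", "identity", "coverage")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  for (col in c("identity", "coverage")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(hits[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("malformed hit row %d: non-numeric '%s'", bad[1], col))
    hits[[col]] <- as.numeric(hits[[col]])
  }
  disq <- unique(hits$query[hits$identity >= min_identity &
                            hits$coverage >= min_coverage])
  stats::setNames(!(candidate_ids %in% disq), candidate_ids)
}

#' Read a tabular alignment hit table
#'
#' Accepts either a 12-column BLAST `outfmt 6` table (query, target, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore) -- query coverage is then derived from the aligned
#' query span and `query_lengths` -- or a 4-column table (`query`, `target`,
#' `identity`, `coverage`).
#'
#' @param path Path to the hit table (no header for the 12-column format).
#' @param query_lengths Named vector of query lengths; required for the
#'   12-column format.
#' @return Data frame with columns `query`, `target`, `identity`, `coverage`.
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 12) {
    if (is.null(query_lengths))
      stop("12-column hit tables need 'query_lengths' to derive coverage")
    q <- as.character(tab[[1]])
    missing <- setdiff(unique(q), names(query_lengths))
    if (length(missing) > 0)
      stop("no query length for: ", paste(utils::head(missing, 5), collapse = ", "))
    data.frame(query = q, target = as.character(tab[[2]]),
               identity = as.numeric(tab[[3]]),
               coverage = (abs(tab[[8]] - tab[[7]]) + 1) / query_lengths[q],
               stringsAsFactors = FALSE, row.names = NULL)
  } else if (ncol(tab) == 4) {
    first <- tab[1, ]
    if (identical(tolower(as.character(first[[1]])), "query"))
      tab <- tab[-1, , drop = FALSE]
    data.frame(query = as.character(tab[[1]]), target = as.character(tab[[2]]),
               identity = as.numeric(tab[[3]]), coverage = as.numeric(tab[[4]]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else stop("hit table must have 4 or 12 columns, found ", ncol(tab))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

shares_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  any(ka %in% kb)
}

local_align_stats <- function(candidate, genome, match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(candidate), Biostrings::DNAString(genome),
    type = "local", substitutionMatrix = sm,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend))
  ar <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncols <- length(ar)
  if (ncols == 0) return(list(identity = 0, coverage = 0))
  matches <- sum(ar == as_ & ar != "-")
  list(identity = 100 * matches / ncols,
       coverage = sum(ar != "-") / nchar(candidate))
}

#' Classify the presence of a candidate transcript in a genome
#'
#' A seed-and-extend matcher: genomes without any shared k-mer with the
#' candidate (either strand) are called absent outright; otherwise the best
#' local alignment on each strand determines the call. `present_full` requires
#' the full-identity and near-full-coverage gates; `present_partial` the
#' partial-homology floor; anything weaker is `absent`.
#'
#' @param candidate Candidate sequence (single string).
#' @param genome Genome sequence (single string); must be nonempty.
#' @param k Seed k-mer size (default 15).
#' @param full_identity Identity (percent) required for `present_full`
#'   (default 100).
#' @param full_coverage Candidate coverage required for `present_full`
#'   (default 0.95).
#' @param partial_identity,partial_coverage Floors for `present_partial`
#'   (defaults 80 percent over 0.3 coverage).
#' @return List with `status` (`present_full`/`present_partial`/`absent`),
#'   `best_identity` and `best_coverage`.
#' @export
genome_presence <- function(candidate, genome, k = 15,
                            full_identity = 100, full_coverage = 0.95,
                            partial_identity = 80, partial_coverage = 0.3) {
  if (!nzchar(genome)) stop("empty genome sequence")
  if (!nzchar(candidate)) stop("empty candidate sequence")
  strands <- c(fwd = genome, rev = revcomp(genome))
  best <- list(identity = 0, coverage = 0)
  for (g in strands) {
    if (!shares_kmer(candidate, g, k)) next
    st <- local_align_stats(candidate, g)
    # rank by coverage at qualifying identity, then identity
    if (st$coverage > best$coverage ||
        (st$coverage == best$coverage && st$identity > best$identity))
      best <- st
  }
  status <- if (best$identity >= full_identity && best$coverage >= full_coverage)
    "present_full"
  else if (best$identity >= partial_identity && best$coverage >= partial_coverage)
    "present_partial"
  else "absent"
  list(status = status, best_identity = best$identity,
       best_coverage = best$coverage)
}

#' Run the four-stage species-specific transcript cascade
#'
#' Stages, in fixed order: (1) length -- contig strictly longer than `min_nt`;
#' (2) coding -- no protein-coding hit above the identity/coverage gates;
#' (3) genome depletion -- absent from every non-pig genome (vacuously passed
#' when none are supplied); (4) expression -- RPKM strictly above `min_rpkm`.
#' All four predicates are evaluated for every candidate, so each decoy's
#' ledger names its failing stage and the surviving set does not depend on
#' stage order. A conservation profile (presence calls across the pig genome
#' panel) is computed for the survivors.
#'
#' @param candidates Named character vector of candidate contig sequences.
#' @param counts Data frame with columns `contig_id`, `length_nt`,
#'   `read_count`.
#' @param library_size Total mapped reads for RPKM.
#' @param coding_hits Hit table as in [filter_coding()] (may have zero rows).
#' @param nonpig_genomes Named character vector/list of non-pig genome
#'   sequences (may be empty).
#' @param pig_genomes Named character vector/list of pig genome sequences.
#' @param min_rpkm Expression gate (default 10).
#' @param min_nt Length gate (default 500).
#' @param min_identity,min_coverage Coding-hit gates (defaults 70 / 0.5).
#' @param ... Additional arguments for [genome_presence()].
#' @return List of class `cascade_result`: `specific` (surviving ids),
#'   `ledger` (long data frame: contig, stage, pass, reason), `candidates`
#'   (per-candidate summary with rpkm), `conservation` (presence calls of
#'   survivors across pig genomes).
#' @export
run_cascade <- function(candidates, counts, library_size, coding_hits,
                        nonpig_genomes = list(), pig_genomes = list(),
                        min_rpkm = 10, min_nt = 500,
                        min_identity = 70, min_coverage = 0.5, ...) {
  ids <- names(candidates)
  if (is.null(ids)) stop("'candidates' must be named")
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length_nt", "read_count") %in% names(counts)))
  counts <- counts[match(ids, counts$contig_id), , drop = FALSE]
  if (any(is.na(counts$contig_id)))
    stop("counts missing for: ",
         paste(utils::head(ids[is.na(counts$contig_id)], 5), collapse = ", "))
  rp <- rpkm(counts$read_count, counts$length_nt, library_size)

  pass_len <- filter_length(counts$length_nt, min_nt)
  pass_cod <- filter_coding(ids, coding_hits, min_identity, min_coverage)
  pres_nonpig <- lapply(ids, function(id) {
    vapply(nonpig_genomes, function(g)
      genome_presence(candidates[[id]], g, ...)$status, character(1))
  })
  pass_dep <- vapply(pres_nonpig, function(st) {
    length(st) == 0 || all(st == "absent")
  }, logical(1))
  pass_exp <- rp > min_rpkm

  stage_tab <- data.frame(
    contig_id = rep(ids, times = 4),
    stage = rep(c("length", "coding", "genome_depletion", "expression"),
                each = length(ids)),
    pass = c(pass_len, unname(pass_cod), pass_dep, pass_exp),
    stringsAsFactors = FALSE)
  stage_tab$reason <- ""
  stage_tab$reason[!stage_tab$pass & stage_tab$stage == "length"] <-
    sprintf("length <= %d nt", min_nt)
  stage_tab$reason[!stage_tab$pass & stage_tab$stage == "coding"] <-
    sprintf("coding hit at >= %g%% identity over >= %g coverage",
            min_identity, min_coverage)
  stage_tab$reason[!stage_tab$pass & stage_tab$stage == "genome_depletion"] <-
    "detected in a non-pig genome"
  stage_tab$reason[!stage_tab$pass & stage_tab$stage == "expression"] <-
    sprintf("RPKM <= %g", min_rpkm)
  # keep ledger in fixed stage order per candidate
  stage_tab <- stage_tab[order(match(stage_tab$contig_id, ids),
                               match(stage_tab$stage,
                                     c("length", "coding", "genome_depletion",
                                       "expression"))), ]
  rownames(stage_tab) <- NULL

  specific <- ids[pass_len & pass_cod & pass_dep & pass_exp]

  conservation <- NULL
  if (length(pig_genomes) > 0 && length(specific) > 0) {
    rows <- list()
    for (id in specific) {
      for (gn in names(pig_genomes)) {
        pc <- genome_presence(candidates[[id]], pig_genomes[[gn]], ...)
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = id, genome = gn, status = pc$status,
          best_identity = pc$best_identity, best_coverage = pc$best_coverage,
          stringsAsFactors = FALSE)
      }
    }
    conservation <- do.call(rbind, rows)
  }

  structure(list(
    specific = specific,
    ledger = stage_tab,
    candidates = data.frame(contig_id = ids, length_nt = counts$length_nt,
                            read_count = counts$read_count, rpkm = rp,
                            specific = ids %in% specific,
                            stringsAsFactors = FALSE),
    conservation = conservation),
    class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result: %d / %d candidates species-specific\n",
              length(x$specific), nrow(x$candidates)))
  invisible(x)
}

#' Detect lncRNAs in unassembled read libraries by read votes
#'
#' A read supports a target when its best (gapped) match against the target,
#' over the full read length, reaches the identity floor on either strand; a
#' target is detected when the number of supporting reads reaches
#' `min_reads`. This is the reversed-mapping strategy used when only raw WGS
#' reads, not an assembly, are available for a genome.
#'
#' @param targets Named character vector of lncRNA sequences.
#' @param reads Named character vector of reads (each shorter than the
#'   targets).
#' @param identity_floor Minimum percent identity over the full read
#'   (default 95).
#' @param min_reads Detection threshold on supporting reads (default 3).
#' @param k Seed k-mer size for prescreening (default 8).
#' @return Data frame: `lncrna_id`, `supporting_reads`, `detected`.
#' @export
read_vote_detection <- function(targets, reads, identity_floor = 95,
                                min_reads = 3, k = 8) {
  stopifnot(!is.null(names(targets)), !is.null(names(reads)))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  support <- stats::setNames(integer(length(targets)), names(targets))
  if (identity_floor <= 100) {
    for (tid in names(targets)) {
      tseq <- targets[[tid]]
      for (rid in names(reads)) {
        rseq <- reads[[rid]]
        hit <- FALSE
        for (rs in c(rseq, revcomp(rseq))) {
          if (!shares_kmer(rs, tseq, k)) next
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(rs), Biostrings::DNAString(tseq),
            type = "global-local", substitutionMatrix = sm,
            gapOpening = 3, gapExtension = 1)
          ar <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
          as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
          ident <- 100 * sum(ar == as_ & ar != "-") / nchar(rs)
          if (ident >= identity_floor) { hit <- TRUE; break }
        }
        if (hit) support[tid] <- support[tid] + 1L
      }
    }
  }
  data.frame(lncrna_id = names(targets), supporting_reads = unname(support),
             detected = unname(support) >= min_reads,
             stringsAsFactors = FALSE, row.names = NULL)
}
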
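STOP_CODONS <- c("TAA", "TAG", "TGA")

check_alphabet <- function(x, letters, what) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% letters)
  if (length(bad) > 0)
    stop(sprintf("invalid %s character(s) at position(s) %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  invisible(TRUE)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under match/mismatch (nucleotide) or a
#' substitution matrix (protein) scoring, with affine gaps: a gap of length L
#' costs `|gap_open| + (L - 1) * |gap_extend|`. The optimal score and one
#' optimal alignment are returned; the score is symmetric under swapping the
#' two sequences.
#'
#' @param a,b Sequences (single strings) to align; `a` is treated as the
#'   reference.
#' @param type `"dna"` (default) or `"protein"`.
#' @param match,mismatch Nucleotide scores (defaults +1 / -1).
#' @param gap_open,gap_extend Gap penalties (defaults -4 / -1); both negative,
#'   with `|gap_open| >= |gap_extend|`.
#' @param substitution_matrix Protein substitution matrix; defaults to
#'   BLOSUM62 when `type = "protein"`.
#' @return An object of class `alignment`: `ref`, `alt` (inputs),
#'   `aligned_ref`, `aligned_alt` (gapped strings of equal length, gap `'-'`)
#'   and `score`.
#' @export
global_align <- function(a, b, type = c("dna", "protein"),
                         match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1,
                         substitution_matrix = NULL) {
  type <- match.arg(type)
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("'a' and 'b' must be single strings")
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be nonempty")
  if (gap_open >= 0 || gap_extend >= 0 || abs(gap_open) < abs(gap_extend))
    stop("gap penalties must be negative with |gap_open| >= |gap_extend|")
  if (type == "dna") {
    a <- toupper(a); b <- toupper(b)
    check_alphabet(a, c("A", "C", "G", "T"), "nucleotide")
    check_alphabet(b, c("A", "C", "G", "T"), "nucleotide")
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                   mismatch = mismatch,
                                                   baseOnly = TRUE)
    pat <- Biostrings::DNAString(a)
    sub <- Biostrings::DNAString(b)
  } else {
    aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWYBZX*", "")[[1]]
    a <- toupper(a); b <- toupper(b)
    check_alphabet(a, aa_letters, "amino acid")
    check_alphabet(b, aa_letters, "amino acid")
    if (is.null(substitution_matrix)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      sm <- e$BLOSUM62
    } else sm <- substitution_matrix
    pat <- Biostrings::AAString(a)
    sub <- Biostrings::AAString(b)
  }
  pa <- Biostrings::pairwiseAlignment(
    pat, sub, type = "global", substitutionMatrix = sm,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend))
  structure(list(ref = a, alt = b,
                 aligned_ref = as.character(Biostrings::alignedPattern(pa)),
                 aligned_alt = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "alignment")
}

#' Bulk global alignment scores
#'
#' Optimal global affine-gap alignment scores of many query sequences against
#' one subject, under the same scoring scheme and engine as [global_align()].
#' Useful for screening; only scores are computed.
#'
#' @param queries Character vector of nucleotide sequences.
#' @param subject Single nucleotide sequence.
#' @inheritParams global_align
#' @return Numeric vector of scores, one per query.
#' @export
global_align_scores <- function(queries, subject, match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  if (gap_open >= 0 || gap_extend >= 0 || abs(gap_open) < abs(gap_extend))
    stop("gap penalties must be negative with |gap_open| >= |gap_extend|")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(toupper(queries)),
    Biostrings::DNAString(toupper(subject)),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend), scoreOnly = TRUE)
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment (score ", x$score, "):\n", sep = "")
  cat(" ", x$aligned_ref, "\n ", x$aligned_alt, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x matching columns / aligned columns. Internal gap columns count in the
#' denominator; terminal gap runs (leading or trailing columns in which either
#' sequence is gapped) are excluded by default.
#'
#' @param al An [global_align()] result, or any list with `aligned_ref` and
#'   `aligned_alt`.
#' @param mode `"exclude_terminal_gaps"` (default) or
#'   `"include_terminal_gaps"`.
#' @return Percent identity (0-100).
#' @export
percent_identity <- function(al, mode = c("exclude_terminal_gaps",
                                          "include_terminal_gaps")) {
  mode <- match.arg(mode)
  r <- strsplit(al$aligned_ref, "", fixed = TRUE)[[1]]
  c_ <- strsplit(al$aligned_alt, "", fixed = TRUE)[[1]]
  stopifnot(length(r) == length(c_))
  from <- 1L
  to <- length(r)
  if (mode == "exclude_terminal_gaps") {
    gapcol <- r == "-" | c_ == "-"
    while (from <= to && gapcol[from]) from <- from + 1L
    while (to >= from && gapcol[to]) to <- to - 1L
  }
  if (to < from) stop("zero-length effective alignment")
  idx <- from:to
  100 * sum(r[idx] == c_[idx] & r[idx] != "-") / length(idx)
}

validate_ref_cds <- function(ref_cds) {
  ref_cds <- toupper(ref_cds)
  check_alphabet(ref_cds, c("A", "C", "G", "T"), "nucleotide")
  n <- nchar(ref_cds)
  if (n < 6 || n %% 3 != 0)
    stop("reference CDS length must be a positive multiple of 3 (>= 2 codons)")
  codons <- substring(ref_cds, seq(1, n, 3), seq(3, n, 3))
  if (codons[1] != "ATG") stop("reference CDS must begin with ATG")
  if (!codons[length(codons)] %in% STOP_CODONS)
    stop("reference CDS must end with a stop codon")
  if (any(codons[-length(codons)] %in% STOP_CODONS))
    stop("reference CDS contains an internal stop codon; reference not functional")
  ref_cds
}

#' Detect gene-disrupting mutations in a candidate ortholog
#'
#' The candidate is globally aligned to a functional reference CDS and scanned
#' for the three classes of disrupting events: loss of the start codon,
#' frameshifting insertions/deletions (net length not a multiple of 3), and
#' premature in-frame stop codons. The candidate is read in the *reference*
#' frame projection: its characters aligned opposite each reference position
#' form the codons that are scanned for stops, so stops and frameshifts are
#' reported as independent events. Indel runs separated by fewer than
#' `merge_window` aligned columns are merged (alignment jitter) and their net
#' signed length decides frameshift status; terminal gap runs are ignored.
#' Positions are 1-based on the ungapped reference CDS.
#'
#' @param ref_cds Functional reference CDS: starts with ATG, ends with a stop
#'   codon, no internal stop (violations raise an error).
#' @param candidate Candidate ortholog nucleotide sequence.
#' @param merge_window Indel runs closer than this many aligned columns are
#'   merged (default 3).
#' @param ... Scoring parameters passed to [global_align()].
#' @return Data frame of events sorted by position, with columns `kind`
#'   (`start_loss`, `premature_stop`, `frameshift_indel`), `position` (1-based
#'   reference CDS nucleotide) and `detail`.
#' @export
detect_disruptions <- function(ref_cds, candidate, merge_window = 3, ...) {
  ref_cds <- validate_ref_cds(ref_cds)
  al <- global_align(ref_cds, candidate, type = "dna", ...)
  r <- strsplit(al$aligned_ref, "", fixed = TRUE)[[1]]
  cc <- strsplit(al$aligned_alt, "", fixed = TRUE)[[1]]
  ncol_ <- length(r)
  ref_pos <- cumsum(r != "-")          # reference position at/before column
  L <- nchar(ref_cds)

  # reference-frame projection of the candidate
  proj <- rep("-", L)
  proj[ref_pos[r != "-"]] <- cc[r != "-"]

  events <- list()

  # (1) start codon
  start <- paste(proj[1:3], collapse = "")
  if (start != "ATG")
    events[[length(events) + 1]] <- data.frame(
      kind = "start_loss", position = 1L,
      detail = paste0("ATG>", start), stringsAsFactors = FALSE)

  # (2) indel runs -> frameshifts
  gap_r <- r == "-"
  gap_c <- cc == "-"
  runs <- list()
  i <- 1L
  while (i <= ncol_) {
    if (gap_r[i] || gap_c[i]) {
      j <- i
      ins <- gap_r[i]
      while (j < ncol_ && ((ins && gap_r[j + 1]) || (!ins && gap_c[j + 1])))
        j <- j + 1L
      len <- j - i + 1L
      pos <- if (ins) ref_pos[i] + 1L else ref_pos[i]  # ins: after prev ref nt
      terminal <- (i == 1L) || (j == ncol_)
      if (!terminal)
        runs[[length(runs) + 1]] <- list(start_col = i, end_col = j,
                                         signed = if (ins) len else -len,
                                         pos = pos)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) > 0) {
    merged <- list(runs[[1]])
    for (k in seq_along(runs)[-1]) {
      prev <- merged[[length(merged)]]
      if (runs[[k]]$start_col - prev$end_col - 1L < merge_window) {
        prev$signed <- prev$signed + runs[[k]]$signed
        prev$end_col <- runs[[k]]$end_col
        merged[[length(merged)]] <- prev
      } else merged[[length(merged) + 1]] <- runs[[k]]
    }
    for (rn in merged) {
      if (rn$signed %% 3 != 0)
        events[[length(events) + 1]] <- data.frame(
          kind = "frameshift_indel", position = as.integer(max(1L, rn$pos)),
          detail = sprintf("%+d nt", rn$signed), stringsAsFactors = FALSE)
    }
  }

  # (3) premature stops in the reference frame projection
  n_codons <- L %/% 3
  ref_codons <- substring(ref_cds, seq(1, L, 3), seq(3, L, 3))
  for (ci in seq_len(n_codons - 1L)) {
    cod <- proj[(3 * ci - 2):(3 * ci)]
    if (any(cod == "-")) next  # codon disrupted by a deletion: not readable
    cand_codon <- paste(cod, collapse = "")
    if (cand_codon %in% STOP_CODONS && !(ref_codons[ci] %in% STOP_CODONS))
      events[[length(events) + 1]] <- data.frame(
        kind = "premature_stop", position = as.integer(3 * ci - 2),
        detail = paste0(ref_codons[ci], ">", cand_codon),
        stringsAsFactors = FALSE)
  }

  if (length(events) == 0)
    return(data.frame(kind = character(0), position = integer(0),
                      detail = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  out[order(out$position, out$kind), , drop = FALSE]
}

#' Screen a gene panel for pseudogenization across genomes
#'
#' Runs [detect_disruptions()] for every gene and genome and applies the
#' consensus verdict: a gene is called pseudogenized only when disrupting
#' events are present in *all* required genomes and the gene is absent from
#' the supplied set of known functional protein ids (which suppresses false
#' positives from annotated functional copies). Genes lacking a candidate for
#' a required genome are reported as unscreened.
#'
#' @param panel Named list, one element per gene: `list(ref = <CDS>,
#'   candidates = <named character vector, one sequence per genome>)`.
#' @param required_genomes Genomes that must all show events (default: every
#'   genome observed in the panel).
#' @param functional_ids Gene ids with annotated functional protein evidence.
#' @param ... Passed to [detect_disruptions()].
#' @return A list of class `disruption_screen` with `verdicts` (data frame:
#'   `gene`, `status` in pseudogenized/functional/unscreened, per-kind event
#'   counts) and `events` (data frame: `gene`, `genome`, `kind`, `position`,
#'   `detail`).
#' @export
screen_disruptions <- function(panel, required_genomes = NULL,
                               functional_ids = character(0), ...) {
  if (is.null(names(panel))) stop("'panel' must be a named list of genes")
  all_genomes <- unique(unlist(lapply(panel, function(g) names(g$candidates))))
  if (is.null(required_genomes)) required_genomes <- all_genomes
  ev_rows <- list()
  verdicts <- lapply(names(panel), function(gene) {
    entry <- panel[[gene]]
    if (!all(required_genomes %in% names(entry$candidates))) {
      return(data.frame(gene = gene, status = "unscreened",
                        n_start_loss = NA_integer_,
                        n_premature_stop = NA_integer_,
                        n_frameshift_indel = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    per_genome <- lapply(required_genomes, function(gn) {
      ev <- detect_disruptions(entry$ref, entry$candidates[[gn]], ...)
      if (nrow(ev) > 0)
        ev_rows[[length(ev_rows) + 1]] <<- cbind(
          data.frame(gene = gene, genome = gn, stringsAsFactors = FALSE), ev)
      ev
    })
    disrupted_everywhere <- all(vapply(per_genome, nrow, integer(1)) > 0)
    status <- if (disrupted_everywhere && !(gene %in% functional_ids))
      "pseudogenized" else "functional"
    allev <- do.call(rbind, per_genome)
    data.frame(gene = gene, status = status,
               n_start_loss = sum(allev$kind == "start_loss"),
               n_premature_stop = sum(allev$kind == "premature_stop"),
               n_frameshift_indel = sum(allev$kind == "frameshift_indel"),
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev_rows) > 0) do.call(rbind, ev_rows) else
    data.frame(gene = character(0), genome = character(0), kind = character(0),
               position = integer(0), detail = character(0))
  structure(list(verdicts = do.call(rbind, verdicts), events = events,
                 required_genomes = required_genomes),
            class = "disruption_screen")
}

#' @export
print.disruption_screen <- function(x, ...) {
  tab <- table(x$verdicts$status)
  cat("disruption_screen over genomes:",
      paste(x$required_genomes, collapse = ", "), "\n")
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  invisible(x)
}
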
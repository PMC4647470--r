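#' Run configuration with the pipeline's default thresholds
#'
#' Collects every tunable threshold of the analysis stages in one validated
#' list: the Gini signature threshold, the CV cutoff, the RPKM and contig
#' length gates, the contact distance cutoff, the read-vote identity floor,
#' the GRSN internals and the aligner scores. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    gini_threshold = 0.7,
    cv_cutoff = 0.10,
    min_rpkm = 10,
    min_contig_nt = 500,
    contact_cutoff = 4.5,
    read_identity_floor = 95,
    read_vote_min_reads = 3,
    grsn_invariant_fraction = 0.05,
    grsn_iterations = 4,
    grsn_span = 0.3,
    align_match = 1,
    align_mismatch = -1,
    align_gap_open = -4,
    align_gap_extend = -1,
    coding_min_identity = 70,
    coding_min_coverage = 0.5,
    log2_offset = 1,
    seed = 1L,
    out_dir = ".",
    log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

config_header <- function(config, keys) {
  paste0("# ", paste(sprintf("%s=%s", keys,
                             vapply(config[keys], format, character(1))),
                     collapse = " "))
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
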
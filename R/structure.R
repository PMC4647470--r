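#' Read a macromolecular structure from a PDB file
#'
#' Fixed-column parsing of ATOM/HETATM records. Alternate locations are
#' resolved per atom site by highest occupancy, ties broken alphabetically by
#' altloc code. Hydrogens are flagged (element `H`) so contact calculations
#' can exclude them.
#'
#' @param path Path to a PDB-format text file.
#' @return An object of class `structure_model` wrapping the atom table
#'   (`type`, `eleno`, `elety`, `alt`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o`, `element`, `is_hydrogen`).
#' @export
read_pdb_model <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  coord_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord_lines) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], cols[1], cols[2])))
      if (is.na(v))
        stop(sprintf("malformed coordinate field at line %d of %s", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  element <- at$elesy
  fallback <- is.na(element) | element == ""
  if (any(fallback)) {
    guess <- gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", at$elety[fallback]))
    element[fallback] <- toupper(substr(guess, 1, 1))
  }
  at$element <- toupper(trimws(element))
  # altloc resolution: one atom per (chain, resno, insert, resid, elety) site
  site <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(site, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(site[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]
  at$is_hydrogen <- at$element == "H"
  rownames(at) <- NULL
  structure(list(atoms = at, source = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms (%d HETATM), chains: %s\n",
              nrow(x$atoms), sum(x$atoms$type == "HETATM"),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Write a structure model to a PDB file
#'
#' @param model A [read_pdb_model()] result or the `model` element of
#'   [simulate_toy_structure()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_model <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   type = at$type, eleno = at$eleno, elety = at$elety,
                   resid = at$resid, chain = at$chain, resno = at$resno,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   o = at$o, b = rep(0, nrow(at)), elesy = at$element)
  invisible(path)
}

#' Ligand/partner contact residues of a structure
#'
#' A subject residue is a contact when the minimum Euclidean distance over all
#' (subject atom, partner atom) pairs is less than or equal to `cutoff`
#' (inclusive: a pair at exactly the cutoff counts). By default only heavy
#' atoms are considered and waters are excluded from the partner selection.
#'
#' @param model A [read_pdb_model()] result.
#' @param ligand HET residue name selecting the partner (e.g. a ligand code);
#'   give either this or `partner_chains`.
#' @param partner_chains Chain id(s) selecting the partner atoms.
#' @param subject_chains Protein chain(s) to scan (default: all chains with
#'   ATOM records, excluding pure-partner chains).
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @param heavy_only Exclude hydrogens (default `TRUE`).
#' @param exclude_water Drop water residues from the partner (default `TRUE`).
#' @return An object of class `contact_set`: data frame of contact residues
#'   (`chain`, `resno`, `insert`, `resid`, `aa`, `min_dist`) ordered by chain
#'   and residue number, with the cutoff as attribute.
#' @export
contact_residues <- function(model, ligand = NULL, partner_chains = NULL,
                             subject_chains = NULL, cutoff = 4.5,
                             heavy_only = TRUE, exclude_water = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (heavy_only) at <- at[!at$is_hydrogen, , drop = FALSE]
  if (is.null(ligand) && is.null(partner_chains))
    stop("give a 'ligand' HET code or 'partner_chains'")
  if (!is.null(ligand)) {
    partner <- at[at$type == "HETATM" & at$resid %in% ligand, , drop = FALSE]
    sel_name <- paste("ligand", paste(ligand, collapse = ","))
  } else {
    partner <- at[at$chain %in% partner_chains, , drop = FALSE]
    sel_name <- paste("chain(s)", paste(partner_chains, collapse = ","))
  }
  if (exclude_water)
    partner <- partner[!partner$resid %in% c("HOH", "WAT", "H2O"), , drop = FALSE]
  if (nrow(partner) == 0)
    stop("partner selector matched nothing: ", sel_name)
  subject <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(partner_chains))
    subject <- subject[!subject$chain %in% partner_chains, , drop = FALSE]
  if (!is.null(subject_chains))
    subject <- subject[subject$chain %in% subject_chains, , drop = FALSE]
  if (nrow(subject) == 0) stop("subject selector matched no protein atoms")

  px <- as.matrix(partner[, c("x", "y", "z")])
  sx <- as.matrix(subject[, c("x", "y", "z")])
  # squared distance of every subject atom to its nearest partner atom
  d2 <- outer(rowSums(sx^2), rowSums(px^2), "+") - 2 * (sx %*% t(px))
  min_d <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- paste(subject$chain, subject$resno, subject$insert, sep = "|")
  res_min <- tapply(min_d, key, min)
  first <- !duplicated(key)
  res_tab <- subject[first, c("chain", "resno", "insert", "resid")]
  res_tab$min_dist <- as.numeric(res_min[paste(res_tab$chain, res_tab$resno,
                                               res_tab$insert, sep = "|")])
  hits <- res_tab[res_tab$min_dist <= cutoff, , drop = FALSE]
  hits <- hits[order(hits$chain, hits$resno, hits$insert), , drop = FALSE]
  hits$aa <- if (nrow(hits) > 0) bio3d::aa321(hits$resid) else character(0)
  rownames(hits) <- NULL
  structure(hits[, c("chain", "resno", "insert", "resid", "aa", "min_dist")],
            cutoff = cutoff, heavy_only = heavy_only, class = c("contact_set",
                                                                "data.frame"))
}

#' Read a protein multiple alignment
#'
#' @param path FASTA or Clustal alignment file.
#' @param format `"fasta"` or `"clustal"`; guessed from the first line by
#'   default.
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  as.character(msa)
}

chain_sequence <- function(model, chain) {
  at <- model$atoms
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain ", chain)
  key <- paste(at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(resno = at$resno[first], insert = at$insert[first],
             aa = bio3d::aa321(at$resid[first]), stringsAsFactors = FALSE)
}

#' Map contact residues onto a cross-species alignment
#'
#' Structure residue numbers are mapped to alignment columns through the
#' reference species' row: the chain's residue sequence is located within the
#' ungapped reference row and each contact residue inherits that row's
#' column. Every other species is then read off at those columns: identical
#' residue = conserved; a different residue = substituted, reported in
#' `<ref aa><structure resno><species aa>` notation (e.g. `I272F`); a gap =
#' missing. Contacts that fall outside the alignment span are reported as
#' unmapped.
#'
#' @param contacts A [contact_residues()] result (single chain).
#' @param model The [read_pdb_model()] the contacts came from.
#' @param msa Named character vector of aligned sequences (see
#'   [read_alignment()]), one row per species.
#' @param reference_species Name of the alignment row matching the structure.
#' @return Data frame of class `conservation_report`: `resno`, `ref_aa`,
#'   `species`, `aa`, `status` (conserved/substituted/missing/unmapped),
#'   `notation` (only for substituted rows).
#' @export
map_conservation <- function(contacts, model, msa, reference_species) {
  stopifnot(inherits(contacts, "contact_set"))
  if (!reference_species %in% names(msa))
    stop("reference species '", reference_species, "' not in the alignment")
  chain <- unique(contacts$chain)
  if (length(chain) != 1)
    stop("contacts must come from a single chain; found: ",
         paste(chain, collapse = ", "))
  chs <- chain_sequence(model, chain)
  chain_str <- paste(chs$aa, collapse = "")

  ref_chars <- strsplit(msa[[reference_species]], "", fixed = TRUE)[[1]]
  ungapped <- ref_chars[ref_chars != "-"]
  ungapped_str <- paste(ungapped, collapse = "")
  col_of <- which(ref_chars != "-")

  hit <- gregexpr(chain_str, ungapped_str, fixed = TRUE)[[1]]
  if (hit[1] == -1) {
    # fall back to the span covering the contacts only
    idx <- match(paste(contacts$resno, contacts$insert, sep = "|"),
                 paste(chs$resno, chs$insert, sep = "|"))
    span <- range(idx)
    sub_str <- paste(chs$aa[span[1]:span[2]], collapse = "")
    hit <- gregexpr(sub_str, ungapped_str, fixed = TRUE)[[1]]
    if (hit[1] == -1)
      stop("reference alignment row does not match the structure chain ",
           "sequence over the contact span")
    offset <- hit[1] - span[1]
  } else offset <- hit[1] - 1L
  if (length(hit) > 1)
    warning("chain sequence matches the reference row more than once; ",
            "using the first occurrence")

  species <- names(msa)
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    ridx <- match(paste(contacts$resno[i], contacts$insert[i], sep = "|"),
                  paste(chs$resno, chs$insert, sep = "|"))
    upos <- offset + ridx
    if (is.na(upos) || upos < 1 || upos > length(col_of)) {
      rows[[length(rows) + 1]] <- data.frame(
        resno = contacts$resno[i], ref_aa = contacts$aa[i],
        species = species, aa = NA_character_, status = "unmapped",
        notation = NA_character_, stringsAsFactors = FALSE)
      next
    }
    column <- col_of[upos]
    ref_aa <- ungapped[upos]
    if (ref_aa != contacts$aa[i])
      stop(sprintf(paste0("reference row residue '%s' at mapped column %d ",
                          "does not match structure residue %s%d"),
                   ref_aa, column, contacts$aa[i], contacts$resno[i]))
    aa <- vapply(species, function(sp)
      substr(msa[[sp]], column, column), character(1))
    status <- ifelse(aa == "-", "missing",
                     ifelse(aa == ref_aa, "conserved", "substituted"))
    notation <- ifelse(status == "substituted",
                       paste0(ref_aa, contacts$resno[i], aa), NA_character_)
    rows[[length(rows) + 1]] <- data.frame(
      resno = contacts$resno[i], ref_aa = ref_aa, species = species,
      aa = aa, status = status, notation = notation,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conservation_report", "data.frame")
  out
}
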
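#' Convert a linear-scale CV to the log2-normal noise sd (and back)
#'
#' Under multiplicative lognormal noise (normal on the log2 scale with sd
#' `sigma`), the linear-scale coefficient of variation is
#' `sqrt(exp((sigma * ln 2)^2) - 1)`.
#'
#' @param cv Linear-scale coefficient of variation.
#' @return The log2-scale standard deviation.
#' @export
cv_to_sigma_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' @rdname cv_to_sigma_log2
#' @param sigma_log2 Log2-scale standard deviation.
#' @export
sigma_log2_to_cv <- function(sigma_log2) sqrt(exp((sigma_log2 * log(2))^2) - 1)

DEFAULT_TISSUES <- c("cerebrum", "cerebellum", "colon", "heart", "kidney",
                     "liver", "lung", "muscle", "ovary", "spleen", "stomach",
                     "testis", "thyroid")

#' Specification for the two-species multi-tissue expression simulation
#'
#' Defaults emulate a 13-tissue two-species panel over a shared ortholog
#' namespace of 16,032 genes with 12 replicates per tissue: per-tissue
#' signature genes with a strong home-tissue upshift, planted highly variable
#' genes with a controlled linear-scale CV against a quiet background, and a
#' per-gene cross-species offset that separates the species along the first
#' principal component.
#'
#' @param n_genes Shared gene count (default 16032).
#' @param tissues Tissue labels (default: a 13-tissue panel).
#' @param replicates_per_tissue Replicates per tissue per species (default 12,
#'   half female, half male).
#' @param species Two species labels.
#' @param n_signature_genes_per_tissue Planted signature genes per tissue
#'   (default 50).
#' @param signature_effect Log2 upshift in the home tissue (default 6.0).
#' @param baseline_log2_mean,baseline_log2_sd Baseline distribution of gene
#'   log2 intensities (defaults 6 and 1.5).
#' @param replicate_noise_sd_log2 Background replicate noise, log2 sd
#'   (default: the sd implying a 3 percent linear CV).
#' @param n_high_cv_genes_per_tissue Planted variable genes per tissue
#'   (default 500).
#' @param target_cv Linear-scale CV of the planted variable genes
#'   (default 0.20); must exceed the background CV.
#' @param species_offset_sd_log2 Per-gene cross-species log2 shift sd
#'   (default 1.0).
#' @param seed Integer seed.
#' @return A validated list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 16032,
                                tissues = DEFAULT_TISSUES,
                                replicates_per_tissue = 12,
                                species = c("human", "minipig"),
                                n_signature_genes_per_tissue = 50,
                                signature_effect = 6.0,
                                baseline_log2_mean = 6,
                                baseline_log2_sd = 1.5,
                                replicate_noise_sd_log2 = cv_to_sigma_log2(0.03),
                                n_high_cv_genes_per_tissue = 500,
                                target_cv = 0.20,
                                species_offset_sd_log2 = 1.0,
                                seed = 1L) {
  counts <- c(n_genes = n_genes,
              replicates_per_tissue = replicates_per_tissue,
              n_signature_genes_per_tissue = n_signature_genes_per_tissue,
              n_high_cv_genes_per_tissue = n_high_cv_genes_per_tissue)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers: ",
         paste(names(counts)[counts <= 0 | counts != round(counts)],
               collapse = ", "))
  if (length(species) != 2) stop("exactly two species labels required")
  if (length(tissues) < 2 || anyDuplicated(tissues))
    stop("need >= 2 distinct tissue labels")
  if (target_cv <= sigma_log2_to_cv(replicate_noise_sd_log2))
    stop("'target_cv' must exceed the CV implied by the background noise")
  need <- length(tissues) * (n_signature_genes_per_tissue +
                             n_high_cv_genes_per_tissue)
  if (n_genes < need)
    stop("n_genes too small for the planted gene sets (need >= ", need, ")")
  structure(as.list(environment())[c(
    "n_genes", "tissues", "replicates_per_tissue", "species",
    "n_signature_genes_per_tissue", "signature_effect", "baseline_log2_mean",
    "baseline_log2_sd", "replicate_noise_sd_log2",
    "n_high_cv_genes_per_tissue", "target_cv", "species_offset_sd_log2",
    "seed")], class = "expression_sim_spec")
}

#' Simulate two-species multi-tissue expression with planted ground truth
#'
#' Generates one linear-scale [expression_matrix()] per species over a shared
#' gene namespace, plus truth tables for the planted tissue-signature genes
#' and the planted highly variable genes. The noise model is multiplicative
#' lognormal (normal on the log2 scale); all draws come from one generator
#' seeded with `spec$seed`, so runs are bit-identical for identical specs.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `matrices` (named list of two `expression_matrix`
#'   objects), `truth` (list: `signature` data frame with `tissue`, `gene`;
#'   `high_cv` data frame with `species`, `tissue`, `gene`) and `spec`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  nt <- length(spec$tissues)
  genes <- sprintf("gene%05d", seq_len(spec$n_genes))

  pool <- sample(genes)  # planted roles assigned at random gene positions
  nsig <- spec$n_signature_genes_per_tissue
  nhv <- spec$n_high_cv_genes_per_tissue
  sig_genes <- lapply(seq_len(nt), function(i)
    pool[((i - 1) * nsig + 1):(i * nsig)])
  off <- nt * nsig
  hv_genes <- lapply(seq_len(nt), function(i)
    pool[off + ((i - 1) * nhv + 1):(i * nhv)])
  names(sig_genes) <- names(hv_genes) <- spec$tissues

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_log2_mean,
                           spec$baseline_log2_sd)
  names(baseline) <- genes
  sp_offset <- stats::rnorm(spec$n_genes, 0, spec$species_offset_sd_log2)
  names(sp_offset) <- genes

  # per-tissue log2 mean profile (shared biology across species)
  mu <- matrix(baseline, nrow = spec$n_genes, ncol = nt,
               dimnames = list(genes, spec$tissues))
  for (t in spec$tissues)
    mu[sig_genes[[t]], t] <- mu[sig_genes[[t]], t] + spec$signature_effect

  # per-(gene, tissue) noise sd: background everywhere, target for planted
  sigma <- matrix(spec$replicate_noise_sd_log2, nrow = spec$n_genes, ncol = nt,
                  dimnames = list(genes, spec$tissues))
  sig_target <- cv_to_sigma_log2(spec$target_cv)
  for (t in spec$tissues) sigma[hv_genes[[t]], t] <- sig_target

  reps <- spec$replicates_per_tissue
  sexes <- rep(c("F", "M"), length.out = reps)
  matrices <- list()
  for (si in 1:2) {
    sp <- spec$species[si]
    vals <- matrix(NA_real_, nrow = spec$n_genes, ncol = nt * reps)
    meta <- data.frame(sample_id = character(nt * reps), species = sp,
                       tissue = "", sex = "", age_group = "adult",
                       stringsAsFactors = FALSE)
    col <- 0L
    for (ti in seq_len(nt)) {
      for (r in seq_len(reps)) {
        col <- col + 1L
        base_mu <- mu[, ti] + if (si == 2) sp_offset else 0
        noise <- if (all(sigma[, ti] == 0)) 0 else
          stats::rnorm(spec$n_genes, 0, sigma[, ti])
        vals[, col] <- 2^(base_mu + noise)
        meta$sample_id[col] <- sprintf("%s_%s_r%02d", sp, spec$tissues[ti], r)
        meta$tissue[col] <- spec$tissues[ti]
        meta$sex[col] <- sexes[r]
      }
    }
    dimnames(vals) <- list(genes, meta$sample_id)
    matrices[[sp]] <- expression_matrix(vals, meta, scale = "linear")
  }

  truth_sig <- data.frame(
    tissue = rep(spec$tissues, each = nsig),
    gene = unlist(sig_genes, use.names = FALSE), stringsAsFactors = FALSE)
  truth_hv <- do.call(rbind, lapply(spec$species, function(sp) data.frame(
    species = sp, tissue = rep(spec$tissues, each = nhv),
    gene = unlist(hv_genes, use.names = FALSE), stringsAsFactors = FALSE)))
  list(matrices = matrices,
       truth = list(signature = truth_sig, high_cv = truth_hv),
       spec = spec)
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

#' Specification for the ortholog-pair disruption simulation
#'
#' Defaults plant 12 pseudogenes among 100 ortholog pairs across two pig
#' genomes, each pseudogene carrying the event composition observed for the
#' HEPN1 locus: one start-codon mutation, two premature stops and three
#' frameshifting indels, all at identical positions in every disrupted genome.
#'
#' @param n_genes Total ortholog pairs (default 100).
#' @param n_pseudogenes Planted pseudogenes (default 12).
#' @param cds_length_codons Length range of the reference CDS in codons
#'   (default 150-300).
#' @param events_per_pseudogene Named counts over `start_loss`,
#'   `premature_stop`, `frameshift_indel` (default c(1, 2, 3)).
#' @param genomes Genome labels (default duroc + minipig).
#' @param disrupted_in Genomes carrying the planted events (default: all).
#' @param seed Integer seed.
#' @return A validated list of class `disruption_sim_spec`.
#' @export
disruption_sim_spec <- function(n_genes = 100, n_pseudogenes = 12,
                                cds_length_codons = c(150, 300),
                                events_per_pseudogene = c(start_loss = 1,
                                                          premature_stop = 2,
                                                          frameshift_indel = 3),
                                genomes = c("duroc", "minipig"),
                                disrupted_in = NULL,
                                seed = 1L) {
  if (n_genes < 1 || n_pseudogenes < 0 || n_pseudogenes > n_genes)
    stop("need 0 <= n_pseudogenes <= n_genes with n_genes >= 1")
  ev <- events_per_pseudogene
  allowed <- c("start_loss", "premature_stop", "frameshift_indel")
  if (is.null(names(ev)) || !all(names(ev) %in% allowed) || any(ev < 0))
    stop("'events_per_pseudogene' must be named counts over ",
         paste(allowed, collapse = ", "))
  full <- c(start_loss = 0L, premature_stop = 0L, frameshift_indel = 0L)
  full[names(ev)] <- as.integer(ev)
  ev <- full
  n_positional <- ev[["premature_stop"]] + ev[["frameshift_indel"]]
  min_len <- min(cds_length_codons)
  # events sit >= 10 codons apart, inside codons 12..(L - 2)
  if (min_len < 12 + 10 * max(1, n_positional))
    stop("CDS too short for the requested event composition: a ",
         min_len, "-codon CDS cannot hold ", n_positional,
         " positional event(s) spaced >= 10 codons apart")
  if (is.null(disrupted_in)) disrupted_in <- genomes
  if (!all(disrupted_in %in% genomes))
    stop("'disrupted_in' must be a subset of 'genomes'")
  structure(list(n_genes = n_genes, n_pseudogenes = n_pseudogenes,
                 cds_length_codons = cds_length_codons,
                 events_per_pseudogene = ev, genomes = genomes,
                 disrupted_in = disrupted_in, seed = seed),
            class = "disruption_sim_spec")
}

random_cds <- function(n_codons) {
  body <- sample(NON_STOP_CODONS, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Simulate ortholog pairs with planted disruption events
#'
#' Every gene gets a clean reference CDS (ATG start, stop end, no internal
#' stop). Non-pseudogene controls are copied unchanged into every genome;
#' planted pseudogenes carry the event composition of the spec at positions
#' spaced at least 10 codons apart, identical across all genomes listed in
#' `disrupted_in` (mirroring disruption before a species split).
#'
#' @param spec A [disruption_sim_spec()].
#' @param dir Optional directory: writes `reference.fa` plus one FASTA per
#'   genome and `truth.tsv`.
#' @return List with `ref` (named reference CDS), `genomes` (named list of
#'   named candidate vectors), `truth` (data frame: `gene`, `genome`, `kind`,
#'   `position`, `detail`), `pseudogenes` (planted gene ids) and `spec`.
#' @export
simulate_ortholog_pairs <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "disruption_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("orth%04d", seq_len(spec$n_genes))
  pseudo <- sort(sample(genes, spec$n_pseudogenes))
  lens <- sample(seq(spec$cds_length_codons[1], spec$cds_length_codons[2]),
                 spec$n_genes, replace = TRUE)
  ref <- stats::setNames(vapply(lens, random_cds, character(1)), genes)

  ev_counts <- spec$events_per_pseudogene
  n_start <- ev_counts[["start_loss"]]
  positional_kinds <- c(rep("premature_stop", ev_counts[["premature_stop"]]),
                        rep("frameshift_indel",
                            ev_counts[["frameshift_indel"]]))

  truth <- list()
  plans <- list()
  for (g in pseudo) {
    L <- nchar(ref[[g]]) / 3
    # positional events in codons 12..(L-2), pairwise >= 10 codons apart
    npos <- length(positional_kinds)
    repeat {
      cods <- sort(sample(12:(L - 2), npos))
      if (npos <= 1 || all(diff(cods) >= 10)) break
    }
    kinds <- sample(positional_kinds)
    plan <- data.frame(kind = kinds, codon = cods, stringsAsFactors = FALSE)
    if (n_start > 0)
      plan <- rbind(data.frame(kind = "start_loss", codon = 1,
                               stringsAsFactors = FALSE), plan)
    plan$len <- 0L
    plan$len[plan$kind == "frameshift_indel"] <-
      sample(c(-2L, -1L, 1L, 2L), sum(plan$kind == "frameshift_indel"),
             replace = TRUE)
    plans[[g]] <- plan
  }

  genomes <- list()
  for (gn in spec$genomes) {
    cand <- ref
    if (gn %in% spec$disrupted_in) {
      for (g in pseudo) {
        seqv <- ref[[g]]
        plan <- plans[[g]]
        plan <- plan[order(-plan$codon), , drop = FALSE]  # edit right-to-left
        for (i in seq_len(nrow(plan))) {
          codon <- plan$codon[i]
          p <- 3 * codon - 2
          if (plan$kind[i] == "start_loss") {
            substr(seqv, 1, 1) <- "G"
            truth[[length(truth) + 1]] <- data.frame(
              gene = g, genome = gn, kind = "start_loss", position = 1L,
              detail = "ATG>GTG", stringsAsFactors = FALSE)
          } else if (plan$kind[i] == "premature_stop") {
            orig <- substr(seqv, p, p + 2)
            stop_codon <- "TGA"
            substr(seqv, p, p + 2) <- stop_codon
            truth[[length(truth) + 1]] <- data.frame(
              gene = g, genome = gn, kind = "premature_stop",
              position = as.integer(p), detail = paste0(orig, ">", stop_codon),
              stringsAsFactors = FALSE)
          } else {
            len <- plan$len[i]
            if (len > 0) {
              ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = "")
              seqv <- paste0(substr(seqv, 1, p - 1), ins,
                             substr(seqv, p, nchar(seqv)))
            } else {
              seqv <- paste0(substr(seqv, 1, p - 1),
                             substr(seqv, p - len, nchar(seqv)))
            }
            truth[[length(truth) + 1]] <- data.frame(
              gene = g, genome = gn, kind = "frameshift_indel",
              position = as.integer(p), detail = sprintf("%+d nt", len),
              stringsAsFactors = FALSE)
          }
        }
        cand[[g]] <- seqv
      }
    }
    genomes[[gn]] <- cand
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(gene = character(0), genome = character(0), kind = character(0),
               position = integer(0), detail = character(0))
  truth <- truth[order(truth$gene, truth$genome, truth$position), , drop = FALSE]
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ref, file.path(dir, "reference.fa"))
    for (gn in names(genomes))
      write_fasta(genomes[[gn]], file.path(dir, paste0(gn, ".fa")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(ref = ref, genomes = genomes, truth = truth, pseudogenes = pseudo,
       spec = spec)
}

#' Specification for the species-specific transcript universe
#'
#' Defaults plant 5 genuinely pig-specific transcripts alongside 4 decoys that
#' each violate exactly one cascade filter: a 480-nt contig (length), a contig
#' with a strong protein-coding hit (coding), a contig embedded in the non-pig
#' genomes (depletion) and a contig at 4 RPKM (expression).
#'
#' @param n_candidates Total candidates (default 9).
#' @param planted_specific Genuinely species-specific candidates (default 5).
#' @param pig_genomes,nonpig_genomes Genome counts (defaults 2 and 3).
#' @param contig_length Length range of passing contigs (default 550-1500 nt).
#' @param library_size Reads in the quantification library (default 1e6).
#' @param rpkm_true RPKM range for passing candidates (default 20-60,
#'   straddling nothing: comfortably above the 10-RPKM gate).
#' @param rpkm_decoy RPKM of the expression decoy (default 4).
#' @param read_length,reads_per_lncrna Read-vote library geometry
#'   (defaults 50 nt, 10 reads per planted transcript).
#' @param seed Integer seed.
#' @return A validated list of class `lncrna_sim_spec`.
#' @export
lncrna_sim_spec <- function(n_candidates = 9, planted_specific = 5,
                            pig_genomes = 2, nonpig_genomes = 3,
                            contig_length = c(550, 1500),
                            library_size = 1e6,
                            rpkm_true = c(20, 60), rpkm_decoy = 4,
                            read_length = 50, reads_per_lncrna = 10,
                            seed = 1L) {
  if (planted_specific > n_candidates)
    stop("'planted_specific' cannot exceed 'n_candidates'")
  if (planted_specific < 1) stop("need >= 1 planted transcript")
  if (min(contig_length) <= 500)
    stop("passing contigs must be longer than 500 nt")
  if (pig_genomes < 1) stop("need >= 1 pig genome")
  structure(as.list(environment()), class = "lncrna_sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the transcript universe for the lncRNA cascade
#'
#' Planted species-specific transcripts are embedded verbatim in every pig
#' genome and in no non-pig genome; each decoy violates exactly one filter.
#' Also produces the counts table, the protein-coding hit table, and read
#' libraries sampled verbatim from the planted transcripts for read-vote
#' detection.
#'
#' @param spec A [lncrna_sim_spec()].
#' @return List with `candidates`, `counts`, `library_size`, `hits`,
#'   `pig_genomes`, `nonpig_genomes`, `reads`, `truth` (data frame:
#'   `contig_id`, `role`) and `spec`.
#' @export
simulate_transcript_universe <- function(spec) {
  stopifnot(inherits(spec, "lncrna_sim_spec"))
  set.seed(spec$seed)
  n_decoys <- spec$n_candidates - spec$planted_specific
  decoy_roles <- if (n_decoys > 0)
    rep(c("decoy_length", "decoy_coding", "decoy_nonpig", "decoy_rpkm"),
        length.out = n_decoys) else character(0)
  roles <- c(rep("specific", spec$planted_specific), decoy_roles)
  ids <- sprintf("contig%03d", seq_along(roles))

  lens <- integer(length(roles))
  for (i in seq_along(roles)) {
    lens[i] <- if (roles[i] == "decoy_length") 480L else
      sample(seq(spec$contig_length[1], spec$contig_length[2]), 1)
  }
  seqs <- stats::setNames(vapply(lens, random_dna, character(1)), ids)

  rp <- ifelse(roles == "decoy_rpkm", spec$rpkm_decoy,
               stats::runif(length(roles), spec$rpkm_true[1], spec$rpkm_true[2]))
  read_count <- round(rp * (lens / 1000) * (spec$library_size / 1e6))
  counts <- data.frame(contig_id = ids, length_nt = lens,
                       read_count = read_count, stringsAsFactors = FALSE)

  hits <- data.frame(query = character(0), target = character(0),
                     identity = numeric(0), coverage = numeric(0),
                     stringsAsFactors = FALSE)
  coding_ids <- ids[roles == "decoy_coding"]
  if (length(coding_ids) > 0)
    hits <- rbind(hits, data.frame(query = coding_ids, target = "refseq_mrna_1",
                                   identity = 95, coverage = 0.8,
                                   stringsAsFactors = FALSE))
  # a weak, non-disqualifying hit for realism
  hits <- rbind(hits, data.frame(query = ids[1], target = "swissprot_frag",
                                 identity = 55, coverage = 0.15,
                                 stringsAsFactors = FALSE))

  embed <- function(background, inserts) {
    # candidates separated by random spacers
    parts <- c(background)
    for (s in inserts) parts <- c(parts, s, random_dna(300))
    paste(parts, collapse = "")
  }
  # every candidate, decoys included, is embedded in the pig genomes:
  # decoys must each violate exactly one filter
  pig <- stats::setNames(lapply(seq_len(spec$pig_genomes), function(i)
    embed(random_dna(2000), seqs[ids])),
    sprintf("pig_genome_%d", seq_len(spec$pig_genomes)))
  nonpig_insert <- seqs[roles == "decoy_nonpig"]
  nonpig <- stats::setNames(lapply(seq_len(spec$nonpig_genomes), function(i)
    embed(random_dna(2000), nonpig_insert)),
    if (spec$nonpig_genomes > 0) sprintf("nonpig_genome_%d",
                                         seq_len(spec$nonpig_genomes))
    else character(0))

  reads <- character(0)
  read_names <- character(0)
  for (id in ids[roles == "specific"]) {
    for (r in seq_len(spec$reads_per_lncrna)) {
      start <- sample(seq_len(lens[ids == id] - spec$read_length + 1), 1)
      reads <- c(reads, substr(seqs[[id]], start, start + spec$read_length - 1))
      read_names <- c(read_names, sprintf("%s_read%02d", id, r))
    }
  }
  n_bg <- 20
  reads <- c(reads, vapply(seq_len(n_bg), function(i)
    random_dna(spec$read_length), character(1)))
  read_names <- c(read_names, sprintf("background_read%02d", seq_len(n_bg)))
  names(reads) <- read_names

  list(candidates = seqs, counts = counts, library_size = spec$library_size,
       hits = hits, pig_genomes = pig, nonpig_genomes = nonpig, reads = reads,
       truth = data.frame(contig_id = ids, role = roles,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Specification for the toy protein-ligand structure
#'
#' @param n_residues Protein residues (default 80).
#' @param ligand_atoms Ligand heavy atoms (default 8; 0 gives an empty
#'   contact truth).
#' @param planted_contact_residues Residue numbers planted in contact
#'   (default 12, 40, 77).
#' @param contact_distance_range Heavy-atom distances drawn for planted
#'   contacts, strictly below 4.5 Angstrom (default 3.2-4.4).
#' @param non_contact_min_distance Every atom of every other residue stays
#'   farther than this from every ligand atom (default 8, > 4.5).
#' @param seed Integer seed.
#' @return A validated list of class `structure_sim_spec`.
#' @export
structure_sim_spec <- function(n_residues = 80, ligand_atoms = 8,
                               planted_contact_residues = c(12, 40, 77),
                               contact_distance_range = c(3.2, 4.4),
                               non_contact_min_distance = 8,
                               seed = 1L) {
  if (n_residues < 2) stop("need >= 2 residues")
  if (ligand_atoms < 0) stop("'ligand_atoms' must be >= 0")
  if (ligand_atoms > 0 &&
      !all(planted_contact_residues %in% seq_len(n_residues)))
    stop("planted contact residues must lie in 1..n_residues")
  if (max(contact_distance_range) >= 4.5)
    stop("planted contact distances must be strictly below 4.5 Angstrom")
  if (non_contact_min_distance <= 4.5)
    stop("'non_contact_min_distance' must exceed the 4.5 Angstrom cutoff")
  structure(as.list(environment()), class = "structure_sim_spec")
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Simulate a toy protein-ligand structure with planted contacts
#'
#' Ligand heavy atoms cluster near the origin; protein residues sit on a
#' shell far enough out that no atom of a non-planted residue comes within
#' `non_contact_min_distance` of any ligand atom. Each planted contact
#' residue gets one side-chain atom placed at a distance drawn from
#' `contact_distance_range` (below the 4.5 Angstrom cutoff) from a ligand
#' atom; atom pairs closer than 0.5 Angstrom are regenerated.
#'
#' @param spec A [structure_sim_spec()].
#' @param path Optional output PDB path.
#' @return List with `model` (a `structure_model`), `truth` (planted residue
#'   numbers), `path` (or `NULL`) and `spec`.
#' @export
simulate_toy_structure <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "structure_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  lig_rad <- 1.5
  jitter <- 0.9

  draw_in_sphere <- function(r) {
    repeat {
      x <- stats::runif(3, -r, r)
      if (sum(x^2) <= r^2) return(x)
    }
  }
  lig <- if (spec$ligand_atoms > 0) {
    m <- t(vapply(seq_len(spec$ligand_atoms), function(i)
      draw_in_sphere(lig_rad), numeric(3)))
    repeat {
      d <- as.matrix(stats::dist(m))
      diag(d) <- Inf
      bad <- which(d < 0.5, arr.ind = TRUE)
      if (nrow(bad) == 0) break
      m[bad[1, 1], ] <- draw_in_sphere(lig_rad)
    }
    m
  } else matrix(numeric(0), ncol = 3)

  shell <- spec$non_contact_min_distance + lig_rad + sqrt(3) * jitter + 0.5
  resnames <- sample(AA3, n, replace = TRUE)
  atoms <- list()
  eleno <- 0L
  for (i in seq_len(n)) {
    u <- stats::rnorm(3)
    centre <- (shell + stats::runif(1, 0, 4)) * u / sqrt(sum(u^2))
    for (an in c("N", "CA", "C", "CB")) {
      eleno <- eleno + 1L
      xyz <- centre + stats::runif(3, -jitter, jitter)
      atoms[[eleno]] <- data.frame(
        type = "ATOM", eleno = eleno, elety = an, alt = "",
        resid = resnames[i], chain = "A", resno = i, insert = "",
        x = xyz[1], y = xyz[2], z = xyz[3], o = 1,
        element = substr(an, 1, 1), stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, atoms)

  if (spec$ligand_atoms > 0) {
    for (r in spec$planted_contact_residues) {
      idx <- which(at$resno == r & at$elety == "CB")
      repeat {
        anchor <- lig[sample(nrow(lig), 1), ]
        d <- stats::runif(1, spec$contact_distance_range[1],
                          spec$contact_distance_range[2])
        u <- stats::rnorm(3)
        xyz <- anchor + d * u / sqrt(sum(u^2))
        dists <- sqrt(rowSums((lig - matrix(xyz, nrow(lig), 3,
                                            byrow = TRUE))^2))
        # nearest ligand atom must land inside the planted contact band
        if (min(dists) >= spec$contact_distance_range[1] &&
            min(dists) <= spec$contact_distance_range[2]) break
      }
      at$x[idx] <- xyz[1]; at$y[idx] <- xyz[2]; at$z[idx] <- xyz[3]
    }
    lig_at <- data.frame(
      type = "HETATM", eleno = max(at$eleno) + seq_len(nrow(lig)),
      elety = sprintf("C%d", seq_len(nrow(lig))), alt = "",
      resid = "LIG", chain = "L", resno = 1, insert = "",
      x = lig[, 1], y = lig[, 2], z = lig[, 3], o = 1, element = "C",
      stringsAsFactors = FALSE)
    at <- rbind(at, lig_at)
  }
  at$is_hydrogen <- FALSE
  model <- structure(list(atoms = at, source = "simulated"),
                     class = "structure_model")
  if (!is.null(path)) write_pdb_model(model, path)
  list(model = model,
       truth = if (spec$ligand_atoms > 0) sort(spec$planted_contact_residues)
               else integer(0),
       path = path, spec = spec)
}

#' Write named sequences as 60-column wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
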
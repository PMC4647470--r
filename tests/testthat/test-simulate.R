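test_that("spec constructors validate their inputs", {
  expect_error(expression_sim_spec(n_genes = 0), "positive")
  expect_error(expression_sim_spec(target_cv = 0.01), "exceed")
  expect_error(expression_sim_spec(n_genes = 100), "too small")
  expect_error(disruption_sim_spec(n_pseudogenes = 200), "n_pseudogenes")
  # a 1-codon CDS cannot hold a premature stop
  expect_error(disruption_sim_spec(cds_length_codons = c(1, 1)), "too short")
  expect_error(lncrna_sim_spec(planted_specific = 99), "exceed")
  expect_error(lncrna_sim_spec(contig_length = c(400, 600)), "longer than 500")
  expect_error(structure_sim_spec(contact_distance_range = c(3, 4.6)),
               "below 4.5")
  expect_error(structure_sim_spec(non_contact_min_distance = 4), "exceed")
  expect_error(run_config(not_a_key = 1), "unknown config key")
})

test_that("seeded simulations are bit-identical and seeds matter", {
  s <- small_expression_spec(seed = 71)
  a <- simulate_expression(s)
  b <- simulate_expression(s)
  expect_identical(a$matrices$human$values, b$matrices$human$values)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_expression(small_expression_spec(seed = 72))
  expect_false(identical(a$matrices$human$values, c_$matrices$human$values))

  d1 <- simulate_ortholog_pairs(disruption_sim_spec(n_genes = 5,
                                                    n_pseudogenes = 2,
                                                    seed = 73))
  d2 <- simulate_ortholog_pairs(disruption_sim_spec(n_genes = 5,
                                                    n_pseudogenes = 2,
                                                    seed = 73))
  expect_identical(d1$genomes, d2$genomes)

  u1 <- simulate_transcript_universe(lncrna_sim_spec(seed = 74))
  u2 <- simulate_transcript_universe(lncrna_sim_spec(seed = 74))
  expect_identical(u1$candidates, u2$candidates)
  expect_identical(u1$reads, u2$reads)

  t1 <- simulate_toy_structure(structure_sim_spec(seed = 75))
  t2 <- simulate_toy_structure(structure_sim_spec(seed = 75))
  expect_identical(t1$model$atoms, t2$model$atoms)
})

test_that("a noise-free planted signature gene clears the Gini threshold", {
  # construction check: effect 6.0 over 13 tissues -> (64b, b, ..., b)
  b <- 2^6.5
  profile <- c(64 * b, rep(b, 12))
  expect_gte(gini(profile), 0.7)
  expect_equal(gini(profile), gini_bruteforce(profile), tolerance = 1e-12)

  sim <- simulate_expression(small_expression_spec(seed = 76, noise = 0))
  tm <- tissue_means(sim$matrices$human)
  planted <- sim$truth$signature
  for (i in seq_len(nrow(planted))) {
    g <- gini(tm[planted$gene[i], ])
    expect_gte(g, 0.7)
    expect_identical(names(which.max(tm[planted$gene[i], ])),
                     planted$tissue[i])
  }
})

test_that("realized CV of planted variable genes is calibrated to the target", {
  sim <- simulate_expression(small_expression_spec(seed = 77, n_genes = 2000,
                                                   n_hv = 40, reps = 12))
  vt <- cv_table(sim$matrices$minipig)
  hv <- sim$truth$high_cv
  hv <- hv[hv$species == "minipig", ]
  got <- merge(vt, hv, by = c("gene", "tissue"))
  expect_identical(nrow(got), nrow(hv))  # 520 planted cells
  expect_gt(mean(got$cv), 0.18)
  expect_lt(mean(got$cv), 0.22)
  # CV converges with replicates: more replicates, tighter spread
  sim2 <- simulate_expression(small_expression_spec(seed = 78, n_genes = 500,
                                                    n_hv = 20, reps = 48))
  vt2 <- cv_table(sim2$matrices$minipig)
  got2 <- merge(vt2, sim2$truth$high_cv, by = c("gene", "tissue"))
  expect_lt(stats::sd(got2$cv), stats::sd(got$cv))
})

test_that("ortholog simulation plants the stated composition and clean controls", {
  spec <- disruption_sim_spec(n_genes = 12, n_pseudogenes = 3, seed = 79)
  sim <- simulate_ortholog_pairs(spec)
  for (g in sim$pseudogenes) {
    tg <- sim$truth[sim$truth$gene == g & sim$truth$genome == "minipig", ]
    expect_identical(nrow(tg), 6L)
    expect_identical(sum(tg$kind == "start_loss"), 1L)
    expect_identical(sum(tg$kind == "premature_stop"), 2L)
    expect_identical(sum(tg$kind == "frameshift_indel"), 3L)
    # events >= 10 codons apart
    pos <- sort(tg$position)
    expect_true(all(diff(pos) >= 30))
  }
  controls <- setdiff(names(sim$ref), sim$pseudogenes)
  for (g in controls) {
    expect_identical(sim$genomes$duroc[[g]], sim$ref[[g]])
    expect_identical(nrow(detect_disruptions(sim$ref[[g]],
                                             sim$genomes$duroc[[g]])), 0L)
  }
  # reference CDS contract holds for every gene
  for (g in names(sim$ref)) {
    s <- sim$ref[[g]]
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("zero planted events yield zero downstream calls", {
  spec <- disruption_sim_spec(n_genes = 6, n_pseudogenes = 0, seed = 80)
  sim <- simulate_ortholog_pairs(spec)
  expect_identical(nrow(sim$truth), 0L)
  for (g in names(sim$ref))
    expect_identical(nrow(detect_disruptions(sim$ref[[g]],
                                             sim$genomes$duroc[[g]])), 0L)
})

test_that("transcript universe honours its embedding invariants", {
  u <- simulate_transcript_universe(lncrna_sim_spec(seed = 81))
  planted <- u$truth$contig_id[u$truth$role == "specific"]
  for (id in planted) {
    for (g in u$pig_genomes)
      expect_true(grepl(u$candidates[[id]], g, fixed = TRUE))
    for (g in u$nonpig_genomes)
      expect_false(grepl(u$candidates[[id]], g, fixed = TRUE))
  }
  nonpig_decoy <- u$truth$contig_id[u$truth$role == "decoy_nonpig"]
  for (g in u$nonpig_genomes)
    expect_true(grepl(u$candidates[[nonpig_decoy]], g, fixed = TRUE))

  # with no non-pig genomes, every non-decoy candidate is species-specific
  u0 <- simulate_transcript_universe(lncrna_sim_spec(seed = 82,
                                                     n_candidates = 5,
                                                     planted_specific = 5,
                                                     nonpig_genomes = 0))
  res <- run_cascade(u0$candidates, u0$counts, u0$library_size, u0$hits,
                     nonpig_genomes = u0$nonpig_genomes,
                     pig_genomes = list())
  expect_setequal(res$specific, u0$truth$contig_id)
})

test_that("toy structure truth equals geometric contacts at the 4.5 A cutoff", {
  sim <- simulate_toy_structure(structure_sim_spec(
    seed = 83, planted_contact_residues = c(2, 8, 44, 60)))
  cs <- contact_residues(sim$model, ligand = "LIG", cutoff = 4.5)
  expect_identical(cs$resno, sim$truth)
  # no planted pair below the overlap floor
  at <- sim$model$atoms
  lig <- at[at$type == "HETATM", c("x", "y", "z")]
  prot <- at[at$type == "ATOM", c("x", "y", "z")]
  d2 <- outer(rowSums(prot^2), rowSums(lig^2), "+") -
    2 * as.matrix(prot) %*% t(as.matrix(lig))
  expect_gte(sqrt(min(d2)), 0.5)
})
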
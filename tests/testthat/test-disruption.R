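test_that("global alignment matches its stated examples and is symmetric", {
  al <- global_align("ACGT", "ACGT", gap_open = -2, gap_extend = -1)
  expect_equal(al$score, 4)
  expect_identical(al$aligned_ref, "ACGT")

  al2 <- global_align("ACGT", "AGT", gap_open = -2, gap_extend = -1)
  expect_equal(al2$score, 1)  # 3 matches - one 1-nt gap at cost 2
  expect_equal(align_score_oracle("ACGT", "AGT", gap_open = -2), 1)

  sw <- global_align("AGT", "ACGT", gap_open = -2, gap_extend = -1)
  expect_equal(sw$score, al2$score)  # symmetry under swap

  expect_error(global_align("ACGX", "ACGT"), "position")
  expect_error(global_align("", "ACGT"), "nonempty")
})

test_that("alignment engine equals the affine-gap DP oracle on short pairs", {
  seqs <- all_seqs(c("A", "C"), 4)
  for (a in seqs) {
    for (b in seqs) {
      got <- global_align(a, b)$score
      want <- align_score_oracle(a, b)
      expect_equal(got, want,
                   info = sprintf("pair %s / %s", a, b))
    }
  }
})

test_that("percent identity handles internal and terminal gaps as specified", {
  expect_equal(percent_identity(global_align("ACGTACGT", "ACGTACGT")), 100)
  expect_equal(percent_identity(global_align("ACGT", "ACGA")), 75)
  expect_equal(percent_identity(list(aligned_ref = "ACGT",
                                     aligned_alt = "TGCA")), 0)
  # internal gap counts in the denominator
  al <- list(aligned_ref = "AC-GT", aligned_alt = "ACAGT")
  expect_equal(percent_identity(al), 100 * 4 / 5)
  # terminal gaps excluded by default, included on request
  al2 <- list(aligned_ref = "--ACGT", aligned_alt = "GGACGT")
  expect_equal(percent_identity(al2), 100)
  expect_equal(percent_identity(al2, mode = "include_terminal_gaps"),
               100 * 4 / 6)
  al3 <- list(aligned_ref = "----", aligned_alt = "ACGT")
  expect_error(percent_identity(al3), "zero-length")
})

test_that("reference CDS contract is enforced", {
  expect_error(detect_disruptions("CCCTAA", "CCCTAA"), "ATG")
  expect_error(detect_disruptions("ATGCCC", "ATGCCC"), "stop")
  expect_error(detect_disruptions("ATGTAACCCTAA", "ATGTAACCCTAA"), "internal")
})

test_that("disruption detector classifies the three event kinds", {
  set.seed(31)
  body <- paste(sample(c("GCA", "GAA", "CTG", "AAC", "TGG", "TCC"), 60,
                       replace = TRUE), collapse = "")
  ref <- paste0("ATG", body, "TAA")

  expect_identical(nrow(detect_disruptions(ref, ref)), 0L)

  # start loss
  cand <- paste0("GTG", substr(ref, 4, nchar(ref)))
  ev <- detect_disruptions(ref, cand)
  expect_identical(ev$kind, "start_loss")
  expect_identical(ev$position, 1L)
  expect_identical(ev$detail, "ATG>GTG")

  # single premature stop at codon 20
  cand2 <- ref
  substr(cand2, 58, 60) <- "TGA"
  ev2 <- detect_disruptions(ref, cand2)
  expect_identical(ev2$kind, "premature_stop")
  expect_identical(ev2$position, 58L)

  # k frameshifts of +/-1 nt, k up to 5, spaced far apart
  for (k in 1:5) {
    cand3 <- ref
    offsets <- 0
    pos <- 30 + 33 * (seq_len(k) - 1)
    for (i in seq_len(k)) {
      p <- pos[i] + offsets
      if (i %% 2 == 1) {  # insertion
        cand3 <- paste0(substr(cand3, 1, p - 1), "A",
                        substr(cand3, p, nchar(cand3)))
        offsets <- offsets + 1
      } else {            # deletion
        cand3 <- paste0(substr(cand3, 1, p - 1),
                        substr(cand3, p + 1, nchar(cand3)))
        offsets <- offsets - 1
      }
    }
    ev3 <- detect_disruptions(ref, cand3)
    expect_identical(sum(ev3$kind == "frameshift_indel"), as.integer(k),
                     info = sprintf("k = %d", k))
  }

  # in-frame (3-nt) indel is not a frameshift
  cand4 <- paste0(substr(ref, 1, 29), substr(ref, 33, nchar(ref)))
  ev4 <- detect_disruptions(ref, cand4)
  expect_false("frameshift_indel" %in% ev4$kind)
})

test_that("event positions are stable under candidate flanking sequence", {
  set.seed(32)
  body <- paste(sample(c("GGA", "CAT", "ACC", "TTG"), 50, replace = TRUE),
                collapse = "")
  ref <- paste0("ATG", body, "TGA")
  cand <- ref
  substr(cand, 61, 63) <- "TAA"
  ev <- detect_disruptions(ref, cand)
  flanked <- paste0("CCTTGCGA", cand, "TTACCGGA")
  ev2 <- detect_disruptions(ref, flanked)
  expect_identical(ev2[c("kind", "position")], ev[c("kind", "position")])
})

test_that("a planted HEPN1-style composition is recovered exactly", {
  spec <- disruption_sim_spec(n_genes = 4, n_pseudogenes = 1,
                              cds_length_codons = c(120, 160), seed = 33)
  sim <- simulate_ortholog_pairs(spec)
  g <- sim$pseudogenes[1]
  truth_g <- sim$truth[sim$truth$gene == g & sim$truth$genome == "duroc", ]
  expect_identical(nrow(truth_g), 6L)  # 1 + 2 + 3 planted events
  ev <- detect_disruptions(sim$ref[[g]], sim$genomes$duroc[[g]])
  expect_identical(sum(ev$kind == "start_loss"), 1L)
  expect_identical(sum(ev$kind == "premature_stop"), 2L)
  expect_identical(sum(ev$kind == "frameshift_indel"), 3L)
  # positions recoverable (within a few columns of alignment jitter)
  for (kind in unique(truth_g$kind)) {
    got <- sort(ev$position[ev$kind == kind])
    want <- sort(truth_g$position[truth_g$kind == kind])
    expect_true(all(abs(got - want) <= 4), info = kind)
  }
})

test_that("screen applies the all-genomes consensus and the functional-id veto", {
  spec <- disruption_sim_spec(n_genes = 30, n_pseudogenes = 5,
                              cds_length_codons = c(80, 120),
                              events_per_pseudogene = c(start_loss = 0,
                                                        premature_stop = 1,
                                                        frameshift_indel = 1),
                              seed = 34)
  sim <- simulate_ortholog_pairs(spec)
  panel <- lapply(names(sim$ref), function(g) list(
    ref = sim$ref[[g]],
    candidates = vapply(sim$genomes, `[[`, character(1), g)))
  names(panel) <- names(sim$ref)

  scr <- screen_disruptions(panel)
  called <- scr$verdicts$gene[scr$verdicts$status == "pseudogenized"]
  expect_setequal(called, sim$pseudogenes)

  # a known functional protein id vetoes the call
  scr2 <- screen_disruptions(panel, functional_ids = sim$pseudogenes[1])
  expect_identical(
    scr2$verdicts$status[scr2$verdicts$gene == sim$pseudogenes[1]],
    "functional")

  # events in one genome only fail the consensus
  spec3 <- disruption_sim_spec(n_genes = 10, n_pseudogenes = 2,
                               cds_length_codons = c(80, 120),
                               events_per_pseudogene = c(premature_stop = 1,
                                                         frameshift_indel = 1),
                               disrupted_in = "duroc", seed = 35)
  sim3 <- simulate_ortholog_pairs(spec3)
  panel3 <- lapply(names(sim3$ref), function(g) list(
    ref = sim3$ref[[g]],
    candidates = vapply(sim3$genomes, `[[`, character(1), g)))
  names(panel3) <- names(sim3$ref)
  scr3 <- screen_disruptions(panel3, required_genomes = c("duroc", "minipig"))
  expect_false(any(scr3$verdicts$status == "pseudogenized"))

  # missing candidate -> unscreened
  panel3[[1]]$candidates <- panel3[[1]]$candidates["duroc"]
  scr4 <- screen_disruptions(panel3, required_genomes = c("duroc", "minipig"))
  expect_identical(scr4$verdicts$status[1], "unscreened")
})
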
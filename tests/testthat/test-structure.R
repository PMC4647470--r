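write_toy_pdb <- function(path, altloc = FALSE) {
  lines <- c(
    pdb_line("ATOM", 1, "N", "", "ALA", "A", 1, 1.234, 2.345, 3.456, 1, "N"),
    pdb_line("ATOM", 2, "CA", "", "ALA", "A", 1, 2.001, 3.002, 4.003, 1, "C"),
    pdb_line("ATOM", 3, "C", "", "ALA", "A", 1, 3.500, 4.500, 5.500, 1, "C"))
  if (altloc) {
    lines <- c(lines,
      pdb_line("ATOM", 4, "CB", "A", "ALA", "A", 1, 9.000, 9.000, 9.000, 0.6, "C"),
      pdb_line("ATOM", 5, "CB", "B", "ALA", "A", 1, 8.000, 8.000, 8.000, 0.4, "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB parsing recovers coordinates and resolves altlocs by occupancy", {
  dir <- withr::local_tempdir()
  p <- write_toy_pdb(file.path(dir, "toy.pdb"))
  model <- read_pdb_model(p)
  expect_identical(nrow(model$atoms), 3L)
  expect_equal(model$atoms$x[1], 1.234, tolerance = 1e-3)
  expect_equal(model$atoms$z[2], 4.003, tolerance = 1e-3)

  p2 <- write_toy_pdb(file.path(dir, "alt.pdb"), altloc = TRUE)
  m2 <- read_pdb_model(p2)
  cb <- m2$atoms[m2$atoms$elety == "CB", ]
  expect_identical(nrow(cb), 1L)
  expect_equal(cb$x, 9.000, tolerance = 1e-3)  # occupancy 0.6 copy retained

  bad <- file.path(dir, "bad.pdb")
  lines <- readLines(p)
  substr(lines[2], 31, 38) <- "   xx.xx"
  writeLines(lines, bad)
  expect_error(read_pdb_model(bad), "line 2")
})

test_that("PDB write/read round-trip preserves the atom count and coordinates", {
  sim <- simulate_toy_structure(structure_sim_spec(seed = 61))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sim.pdb")
  write_pdb_model(sim$model, p)
  back <- read_pdb_model(p)
  expect_identical(nrow(back$atoms), nrow(sim$model$atoms))
  expect_equal(back$atoms$x, sim$model$atoms$x, tolerance = 1e-3)
  expect_identical(sum(back$atoms$type == "HETATM"), 8L)
})

test_that("planted contacts are recovered exactly and the cutoff is inclusive", {
  sim <- simulate_toy_structure(structure_sim_spec(seed = 62))
  cs <- contact_residues(sim$model, ligand = "LIG")
  expect_identical(cs$resno, sim$truth)

  # a hand-built three-residue system probing 4.4 / 4.5 / 4.6 Angstrom
  at <- data.frame(
    type = c("ATOM", "ATOM", "ATOM", "HETATM"),
    eleno = 1:4, elety = c("CA", "CA", "CA", "C1"), alt = "",
    resid = c("GLY", "ALA", "VAL", "LIG"), chain = c("A", "A", "A", "L"),
    resno = c(1, 2, 3, 1), insert = "",
    x = c(4.4, 4.5, 4.6, 0), y = 0, z = 0, o = 1,
    element = c("C", "C", "C", "C"), is_hydrogen = FALSE,
    stringsAsFactors = FALSE)
  model <- structure(list(atoms = at, source = "inline"),
                     class = "structure_model")
  cs2 <- contact_residues(model, ligand = "LIG", cutoff = 4.5)
  expect_identical(cs2$resno, c(1, 2))  # 4.5 included, 4.6 excluded

  expect_error(contact_residues(model, ligand = "XYZ"), "XYZ")
})

test_that("contacts are monotone in cutoff and rigid-motion invariant", {
  sim <- simulate_toy_structure(structure_sim_spec(
    seed = 63, planted_contact_residues = c(5, 20, 33, 50),
    contact_distance_range = c(3.0, 4.4)))
  cs_small <- contact_residues(sim$model, ligand = "LIG", cutoff = 4.0)
  cs_large <- contact_residues(sim$model, ligand = "LIG", cutoff = 4.5)
  expect_true(all(cs_small$resno %in% cs_large$resno))

  # random rotation + translation
  set.seed(64)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  shift <- c(10, -5, 3)
  rot <- sim$model
  xyz <- as.matrix(rot$atoms[, c("x", "y", "z")]) %*% R +
    matrix(shift, nrow(rot$atoms), 3, byrow = TRUE)
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  cs_rot <- contact_residues(rot, ligand = "LIG", cutoff = 4.5)
  expect_identical(cs_rot$resno, cs_large$resno)
})

test_that("contact distances equal the exhaustive all-pairs oracle", {
  sim <- simulate_toy_structure(structure_sim_spec(seed = 65, n_residues = 30,
                                                   planted_contact_residues =
                                                     c(3, 17)))
  at <- sim$model$atoms
  prot <- at[at$type == "ATOM", ]
  lig <- at[at$type == "HETATM", ]
  oracle <- vapply(unique(prot$resno), function(r) {
    pa <- prot[prot$resno == r, c("x", "y", "z")]
    min(vapply(seq_len(nrow(pa)), function(i)
      min(sqrt((lig$x - pa$x[i])^2 + (lig$y - pa$y[i])^2 +
               (lig$z - pa$z[i])^2)), numeric(1)))
  }, numeric(1))
  want <- unique(prot$resno)[oracle <= 4.5]
  cs <- contact_residues(sim$model, ligand = "LIG")
  expect_identical(cs$resno, want)
  expect_equal(cs$min_dist, oracle[oracle <= 4.5], tolerance = 1e-9)
})

test_that("an empty ligand yields an empty contact truth", {
  sim <- simulate_toy_structure(structure_sim_spec(seed = 66,
                                                   ligand_atoms = 0))
  expect_identical(sim$truth, integer(0))
  expect_error(contact_residues(sim$model, ligand = "LIG"), "matched nothing")
})

test_that("conservation mapping reports substitutions in I272F-style notation", {
  sim <- simulate_toy_structure(structure_sim_spec(seed = 67))
  model <- sim$model
  cs <- contact_residues(model, ligand = "LIG")
  chainseq <- paste(bio3d::aa321(
    model$atoms$resid[model$atoms$type == "ATOM" &
                      model$atoms$elety == "CA"]), collapse = "")

  # identical rows: everything conserved
  msa <- c(human = chainseq, pig = chainseq, macaque = chainseq)
  rep0 <- map_conservation(cs, model, msa, "human")
  expect_true(all(rep0$status == "conserved"))

  # substitute the first contact residue in the mouse row
  r1 <- cs$resno[1]
  ref_aa <- cs$aa[1]
  other <- if (ref_aa == "F") "Y" else "F"
  mouse <- chainseq
  substr(mouse, r1, r1) <- other
  msa2 <- c(human = chainseq, mouse = mouse)
  rep2 <- map_conservation(cs, model, msa2, "human")
  sub <- rep2[rep2$status == "substituted", ]
  expect_identical(nrow(sub), 1L)
  expect_identical(sub$notation, paste0(ref_aa, r1, other))
  expect_true(all(is.na(rep2$notation[rep2$status != "substituted"])))

  # an all-gap species row is missing at every contact
  msa3 <- c(human = chainseq,
            ghost = paste(rep("-", nchar(chainseq)), collapse = ""))
  rep3 <- map_conservation(cs, model, msa3, "human")
  expect_true(all(rep3$status[rep3$species == "ghost"] == "missing"))

  # gapped reference row: columns still map through the ungapped index
  gapped_ref <- paste0(substr(chainseq, 1, 10), "----",
                       substr(chainseq, 11, nchar(chainseq)))
  gapped_mouse <- paste0(substr(mouse, 1, 10), "----",
                         substr(mouse, 11, nchar(mouse)))
  rep4 <- map_conservation(cs, model,
                           c(human = gapped_ref, mouse = gapped_mouse),
                           "human")
  expect_identical(rep4$notation[rep4$status == "substituted"],
                   paste0(ref_aa, r1, other))

  # reference row that contradicts the structure is an error
  wrong <- chainseq
  substr(wrong, r1, r1) <- other
  expect_error(map_conservation(cs, model, c(human = wrong), "human"),
               "does not match")
})

test_that("alignments read from FASTA and Clustal formats", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "aln.fa")
  writeLines(c(">human", "MKT-A", ">mouse", "MRTWA"), fa)
  msa <- read_alignment(fa)
  expect_identical(msa[["human"]], "MKT-A")
  cl <- file.path(dir, "aln.aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "human           MKT-A",
               "mouse           MRTWA",
               "                *:* *"), cl)
  msa2 <- read_alignment(cl)
  expect_identical(msa2[["mouse"]], "MRTWA")
})
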
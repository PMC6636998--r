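test_that("multi-model PDB reading: frames, atoms, units, masses", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, n_models = 2, n_res = 6)
  traj <- read_pdb_multimodel(path)
  expect_s3_class(traj, "Trajectory")
  expect_equal(dim(traj$coords), c(2, 6, 3))
  expect_equal(sum(traj$topology$name == "CA"), 6)
  # Angstrom -> nm: first CA was written at x = 3.8 A
  expect_equal(traj$coords[1, 1, 1], 0.38, tolerance = 1e-9)
  expect_equal(unique(traj$topology$mass), 12.011)
  expect_equal(traj$times, c(0, 1))
})

test_that("single-structure PDB gives a 1-frame trajectory", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, n_models = 1, n_res = 5)
  traj <- read_pdb_multimodel(path)
  expect_equal(n_frames(traj), 1L)
  expect_equal(dim(traj$coords)[2], 5L)
})

test_that("inconsistent atom counts across models raise an error naming the model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL        1",
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     1:10, 1:10, 3.8 * (1:10), 0, 0),
             "ENDMDL", "MODEL        2",
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     1:9, 1:9, 3.8 * (1:9), 0, 0),
             "ENDMDL", "END")
  writeLines(lines, path)
  expect_error(read_pdb_multimodel(path), "model 2")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_pdb_multimodel(empty), "Empty")
})

test_that("PDB write -> read round-trips coordinates to printed precision", {
  traj <- toy_traj(n_frames = 3, n_res = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(traj, path)
  back <- read_pdb_multimodel(path)
  expect_equal(n_frames(back), 3L)
  # PDB prints 3 decimals in Angstrom = 1e-4 nm resolution
  expect_equal(back$coords, traj$coords, tolerance = 1e-4)
  expect_equal(back$topology$chain, traj$topology$chain)
  expect_equal(back$topology$resid, traj$topology$resid)
})

test_that("coordinate-table reader checks shape and topology consistency", {
  ctab <- withr::local_tempfile(fileext = ".txt")
  ttab <- withr::local_tempfile(fileext = ".csv")
  set.seed(2)
  m <- matrix(rnorm(5 * 12), 5, 12)
  writeLines(apply(m, 1, paste, collapse = " "), ctab)
  writeLines(c("chain,resid,resname,name,mass",
               paste0("A,", 1:4, ",ALA,CA,12.011")), ttab)
  traj <- read_table_traj(ctab, ttab)
  expect_equal(dim(traj$coords), c(5, 4, 3))
  expect_equal(traj$coords[3, 2, 1], m[3, 4])  # x of atom 2 = column 4

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(apply(m[, 1:11], 1, paste, collapse = " "), bad)
  expect_error(read_table_traj(bad, ttab), "divisible by 3")

  short_top <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain,resid,resname,name,mass",
               paste0("A,", 1:3, ",ALA,CA,12.011")), short_top)
  expect_error(read_table_traj(ctab, short_top), "3 atoms")
})

test_that("table write -> read reproduces coordinates bit-exactly", {
  traj <- toy_traj(n_frames = 4, n_res = 5, jitter = 0.05)
  ctab <- withr::local_tempfile(fileext = ".txt")
  ttab <- withr::local_tempfile(fileext = ".csv")
  write_table_traj(traj, ctab, ttab)
  back <- read_table_traj(ctab, ttab)
  expect_identical(back$coords, traj$coords)
  expect_equal(back$topology$mass, traj$topology$mass)
})

test_that("select_calpha returns per-chain Calpha lists and filters short chains", {
  traj <- toy_traj(n_res = 20, chains = c("A", "B", "C", "D"))
  sel <- select_calpha(traj)
  expect_equal(nrow(sel), 4L)
  expect_equal(sel$n_res, rep(20L, 4))
  expect_true(all(vapply(sel$resid, function(r) all(diff(r) > 0), logical(1))))

  # a 3-residue chain is excluded with a warning
  top <- dplyr::bind_rows(
    tibble::tibble(chain = "A", resid = 1:8, resname = "ALA", name = "CA",
                   mass = 12.011),
    tibble::tibble(chain = "B", resid = 1:3, resname = "ALA", name = "CA",
                   mass = 12.011))
  coords <- array(rnorm(2 * 11 * 3), dim = c(2, 11, 3))
  tr <- trajectory(coords, top)
  expect_warning(sel2 <- select_calpha(tr), "chain.*B")
  expect_equal(sel2$chain, "A")

  # mixed atom names: only CA selected
  top3 <- tibble::tibble(
    chain = "A", resid = rep(1:5, each = 2), resname = "ALA",
    name = rep(c("N", "CA"), 5), mass = 14)
  tr3 <- trajectory(array(rnorm(1 * 10 * 3), dim = c(1, 10, 3)), top3)
  sel3 <- select_calpha(tr3)
  expect_equal(sel3$n_res, 5L)
  expect_equal(sel3$atom_idx[[1]], seq(2, 10, by = 2))

  # no CA at all
  top4 <- dplyr::mutate(top3, name = "CB")
  tr4 <- trajectory(array(rnorm(30), dim = c(1, 10, 3)), top4)
  expect_error(select_calpha(tr4), "Calpha")
})

test_that("structural-alphabet FASTA round-trips the alignment bit-exactly", {
  spec <- sim_spec(n_fragments = 5, frames = 7, seed = 11)
  aln <- simulate_alignment(spec)$alignment
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sa_fasta(aln, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^>", lines)), 7L)
  expect_equal(nchar(lines[2]), 5L)
  back <- read_sa_fasta(path, fragments = aln$fragments)
  expect_identical(back$letters, aln$letters)
  expect_equal(back$times, aln$times)
  # empty alignment rejected at construction
  expect_error(sa_alignment(matrix(character(0), 0, 0), tibble::tibble()),
               ">= 1 frame")
})

test_that("trajectory invariants are enforced", {
  top <- tibble::tibble(chain = "A", resid = 1:4, resname = "ALA",
                        name = "CA", mass = 12.011)
  co <- array(0, dim = c(2, 4, 3))
  expect_error(trajectory(co, dplyr::mutate(top, mass = 0)), "mass")
  expect_error(trajectory(co, top, times = c(1, 1)), "strictly increasing")
  expect_error(trajectory(array(0, dim = c(2, 3, 3)), top), "atoms")
})
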
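test_that("PDB write/read round-trips a synthetic structure", {
  st <- gc_structure()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(back$resolution, 2.0)
  expect_equal(sort(unique(back$atoms$comp)), sort(unique(st$atoms$comp)))
  m1 <- residue_xyz(back, "A|1|"); m0 <- residue_xyz(st, "A|1|")
  expect_equal(m1[rownames(m0), ], m0, tolerance = 1e-3)
})

test_that("PDB and mmCIF readers agree on equivalent files", {
  st <- generate_pair("m1A:U tHW(w)")
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".cif")
  write_pdb(st, p1); write_mmcif(st, p2)
  a <- read_structure(p1); b <- read_structure(p2)
  expect_equal(a$resolution, b$resolution)
  expect_equal(a$atoms$name, b$atoms$name)
  expect_equal(a$atoms$comp, b$atoms$comp)
  expect_equal(a$atoms[, c("x", "y", "z")], b$atoms[, c("x", "y", "z")],
               tolerance = 1e-3)
  # residue lookup is stable regardless of reader
  expect_equal(residue_table(a)$kind, residue_table(b)$kind)
})

test_that("unreadable or RNA-free files raise distinct errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(read_structure(empty), "parse|atoms")
  prot <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), prot)
  expect_error(read_structure(prot), "no RNA residues")
})

test_that("altlocs resolve to highest occupancy with ties to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N9 AA   A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N9 BA   A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  C8 BA   A   1       1.500   1.000   0.000  0.50  0.00           C",
    "ATOM      4  C8 AA   A   1       0.500   1.000   0.000  0.50  0.00           C",
    "END"), path)
  st <- read_structure(path)
  m <- residue_xyz(st, "A|1|")
  expect_equal(nrow(m), 2)
  expect_equal(unname(m["N9", "x"]), 1.0)   # occupancy 0.6 wins
  expect_equal(unname(m["C8", "x"]), 0.5)   # tie -> altloc A
})

test_that("resolution filtering follows the cutoff and logs missing metadata", {
  mk <- function(res) {
    st <- gc_structure(); st$resolution <- res
    st$id <- paste0("res", res); st
  }
  set <- list(mk(1.93), mk(3.35), mk(3.60))
  kept <- filter_by_resolution(set, 3.5)
  expect_equal(vapply(kept, `[[`, 0, "resolution"), c(1.93, 3.35))
  nores <- mk(NA_real_)
  expect_message(out <- filter_by_resolution(list(nores), 3.5), "no resolution")
  expect_length(out, 0)
  expect_length(filter_by_resolution(list(), 3.5), 0)
})

test_that("XYZ output round-trips with charge metadata", {
  st <- generate_pair("m7G:C cWW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frag, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), nrow(frag$atoms))
  expect_length(lines, nrow(frag$atoms) + 2)
  back <- read_xyz(path)
  expect_equal(back$net_charge, 1L)
  expect_equal(nrow(back$atoms), nrow(frag$atoms))
  expect_equal(back$atoms$x, frag$atoms$x, tolerance = 1e-5)
})
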
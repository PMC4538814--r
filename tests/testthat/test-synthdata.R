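test_that("the recipe library covers the full published atlas", {
  recs <- atlas_recipes()
  atlas <- load_paper_atlas()
  expect_setequal(names(recs), atlas$key)
  # every extended-label feature is represented
  geoms <- vapply(recs, `[[`, "", "geometry")
  expect_true(any(grepl("\\(r\\)", geoms)))
  expect_true(any(grepl("\\(w\\)", geoms)))
  expect_true(any(grepl("Bs", geoms)))
  expect_true(any(grepl("1$", geoms)))
})

test_that("generation is deterministic for a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(generate_pair("m5U:A tWH", noise_sigma = 0.05, seed = 7), p1)
  write_pdb(generate_pair("m5U:A tWH", noise_sigma = 0.05, seed = 7), p2)
  expect_identical(readLines(p1), readLines(p2))
  write_pdb(generate_pair("m5U:A tWH", noise_sigma = 0.05, seed = 8), p2)
  expect_false(identical(readLines(p1), readLines(p2)))
})

test_that("generated H-bonds hit their target distances within 0.05 A", {
  for (k in c("m5C:G cWW", "m1G:C tHH1", "Psi:G tBsW")) {
    rec <- atlas_recipes()[[k]]
    st <- generate_pair(k)
    hard <- rec$bonds[rec$bonds$w >= 100, ]
    for (i in seq_len(nrow(hard))) {
      d <- atom_xyz(st, paste0("A|", hard$res_d[i], "|"), hard$atom_d[i])
      a <- atom_xyz(st, paste0("A|", hard$res_a[i], "|"), hard$atom_a[i])
      expect_lt(abs(modbp:::vnorm(d - a) - hard$dist[i]), 0.05,
                label = paste(k, hard$atom_d[i]))
    }
  }
})

test_that("declared resolution is written to and read from the header", {
  st <- generate_pair("m5C:G cWW", resolution = 2.75)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, path)
  expect_equal(read_structure(path)$resolution, 2.75)
})

test_that("a propeller twist tilts the partner base plane", {
  flat <- classify_pair(generate_pair("m5U:A tWH"), "A|1|", "A|2|")
  twisted <- classify_pair(generate_pair("m5U:A tWH", propeller_twist = 15),
                           "A|1|", "A|2|")
  expect_lt(flat$interplane_angle, 2)
  expect_gt(twisted$interplane_angle, 8)
  expect_equal(twisted$geometry, flat$geometry)
})

test_that("structure sets carry a ground-truth manifest that scan recovers", {
  counts <- c("m5C:G cWW" = 3, "Psi:G tBsW" = 2)
  gs <- generate_structure_set(counts, seed = 5)
  expect_length(gs$structures, 5)
  expect_equal(nrow(gs$manifest), 5)
  inst <- scan_structures(gs$structures)
  atlas <- build_atlas(inst)
  expect_equal(stats::setNames(atlas$occurrences, atlas$key)[names(counts)],
               stats::setNames(as.integer(counts), names(counts)))
  expect_equal(sum(atlas$occurrences), 5)
  expect_error(generate_structure_set(c("no:such type" = 1)), "unknown pair type")
  empty <- generate_structure_set(stats::setNames(integer(), character()))
  expect_length(empty$structures, 0)
})
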
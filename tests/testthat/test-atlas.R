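test_that("packaged occurrence table reproduces the census", {
  atlas <- load_paper_atlas()
  expect_equal(nrow(atlas), 36)
  st <- atlas_stats(atlas)
  expect_equal(st$total_pairs, 573)
  expect_equal(st$natural_pairs, 424)
  expect_equal(st$modified_nucleobases_in_pairs, 443)
  expect_equal(st$pairs_by_parent$U, 96)
  expect_equal(st$pairs_by_parent$G, 82)
  expect_equal(st$pairs_by_parent$A, 66)
  expect_equal(st$pairs_by_parent$C, 60)
  expect_equal(st$pairs_by_parent$Psi, 139)
  expect_equal(st$n_types_natural, 27)
  expect_equal(st$n_trans_types, 15)
  expect_equal(st$n_cWW_types, 8)
})

test_that("reference rows match the published table", {
  atlas <- load_paper_atlas()
  m7gg <- atlas[atlas$key == "m7G:G tWH", ]
  expect_equal(m7gg$occurrences, 27)
  expect_equal(m7gg$representative, "1EHZ")
  expect_equal(m7gg$rep_resolution, 1.93)
  en <- load_paper_energies()
  expect_equal(en$e_int_modified[en$key == "m7G:C cWW"], -37.17)
})

test_that("fixture corruption is detected", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tampered", bad)
  expect_error(modbp:::check_fixture(bad, modbp:::TABLE1_MD5), "checksum")
})

test_that("atlas building counts, groups and picks representatives", {
  inst <- data.frame(
    structure_id = c("S2", "S1", "S3", "S4"),
    resolution = c(2.4, 1.93, 1.93, 3.0),
    symbol1 = c("m5C", "m5C", "m5C", "Psi"),
    symbol2 = c("G", "G", "G", "G"),
    geometry = c("cWW", "cWW", "cWW", "tBsW"),
    stringsAsFactors = FALSE)
  atlas <- build_atlas(inst)
  expect_equal(nrow(atlas), 2)
  cww <- atlas[atlas$key == "m5C:G cWW", ]
  expect_equal(cww$occurrences, 3L)
  expect_equal(cww$representative, "S1")   # best resolution, then smallest id
  expect_equal(sum(atlas$occurrences), nrow(inst))
  # order independence
  atlas2 <- build_atlas(inst[c(4, 1, 3, 2), ])
  expect_equal(atlas, atlas2)
  expect_equal(nrow(build_atlas(inst[0, ])), 0)
})

test_that("doubly modified pairs count once as pairs, twice as nucleobases", {
  inst <- data.frame(structure_id = "S", resolution = 2, symbol1 = "m1A",
                     symbol2 = "m5U", geometry = "tHW", stringsAsFactors = FALSE)
  st <- atlas_stats(build_atlas(inst))
  expect_equal(st$total_pairs, 1)
  expect_equal(st$modified_nucleobases_in_pairs, 2)
  expect_equal(st$pairs_by_parent$A, 1)
  expect_equal(st$pairs_by_parent$U, 1)
})

test_that("annotation keeps only modified pairs by default", {
  st <- gc_structure()
  anns <- annotate_structure(st)
  expect_length(anns, 1)
  expect_equal(anns[[1]]$pair_key, "m5C:G cWW")
  # an unmodified pair is skipped unless asked for
  cg <- generate_pair(modbp:::recipe("C", "G", "cWW",
    list(modbp:::bond_spec(1, "N4", 2, "O6", 2.91),
         modbp:::bond_spec(2, "N1", 1, "N3", 2.98, w = 20),
         modbp:::bond_spec(2, "N2", 1, "O2", 2.86))))
  expect_length(annotate_structure(cg), 0)
  expect_length(annotate_structure(cg, modified_only = FALSE), 1)
})
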
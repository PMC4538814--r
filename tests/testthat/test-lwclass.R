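test_that("label strings parse and render as mutual inverses", {
  atlas <- load_paper_atlas()
  for (g in unique(atlas$geometry)) {
    lb <- parse_label(g)
    expect_equal(label_to_string(lb), g, label = g)
  }
  lb <- parse_label("tHW(w)")
  expect_equal(lb$orientation, "trans")
  expect_equal(c(lb$edge1, lb$edge2), c("H", "W"))
  expect_true(lb$water); expect_false(lb$single_hbond)
  lb <- parse_label("cWW1")
  expect_true(lb$single_hbond)
  lb <- parse_label("tS(w)S(r)")
  expect_equal(lb$cross1, "W")   # cross-edge note, not a water flag
  expect_true(lb$ribose2); expect_false(lb$water)
  expect_equal(label_to_string(lb), "tS(w)S(r)")
  lb <- parse_label("tS(W)S(r)")  # the uppercase variant is accepted
  expect_equal(lb$cross1, "W")
  lb <- parse_label("tBsW")
  expect_equal(lb$edge1, "Bs")
})

test_that("malformed labels fail with a position", {
  expect_error(parse_label("xWW"), "position 1")
  expect_error(parse_label("cWQ"), "malformed")
  expect_error(parse_label("cW(q)W"), "malformed")
  expect_error(parse_label("cWW2"), "malformed")
})

test_that("glycosidic orientation distinguishes cis from trans", {
  cis <- gc_structure()
  o <- glycosidic_orientation(cis, "A|1|", "A|2|")
  expect_equal(o$orientation, "cis")
  expect_lt(abs(o$torsion), 30)
  tr <- generate_pair("m5C:G tWW")
  o2 <- glycosidic_orientation(tr, "A|1|", "A|2|")
  expect_equal(o2$orientation, "trans")
  expect_gt(abs(o2$torsion), 150)
})

test_that("missing atoms are reported by name", {
  st <- gc_structure()
  st$atoms <- st$atoms[st$atoms$name != "C1'" | st$atoms$resno != 1, ]
  expect_error(glycosidic_orientation(st, "A|1|", "A|2|"), "C1'")
})

test_that("edges follow the majority vote with boundary resolution", {
  st <- generate_pair("m7G:G tWH")
  e <- assign_edges(st, "A|1|", "A|2|", find_hbonds(st))
  expect_equal(unname(e), c("W", "H"))
  st2 <- generate_pair("Psi:G tBsW")
  e2 <- assign_edges(st2, "A|1|", "A|2|", find_hbonds(st2))
  expect_equal(unname(e2), c("Bs", "W"))
})

test_that("classification is symmetric in argument order", {
  st <- generate_pair("m5U:A tWH")
  a1 <- classify_pair(st, "A|1|", "A|2|")
  a2 <- classify_pair(st, "A|2|", "A|1|")
  expect_equal(a1$pair_key, a2$pair_key)
  expect_equal(a1$geometry, a2$geometry)
  expect_equal(a1$glyc_torsion, a2$glyc_torsion, tolerance = 1e-9)
})

test_that("labels are invariant under rigid motion", {
  set.seed(23)
  for (k in c("m1A:U tHW(w)", "Psi:C cS(r)W", "H2U:G cHS1")) {
    st <- generate_pair(k)
    ann0 <- classify_pair(st, "A|1|", "A|2|")
    st2 <- transform_structure(st, random_rotation(), rnorm(3, 0, 5))
    ann1 <- classify_pair(st2, "A|1|", "A|2|")
    expect_equal(ann1$geometry, ann0$geometry, label = k)
  }
})

test_that("stacked bases are rejected as pairs", {
  st <- gc_structure()
  # stack residue 2 directly on top of residue 1 at a 3.4 A rise
  m1 <- residue_xyz(st, "A|1|")
  sel <- st$atoms$resno == 2
  tmpl <- template_coords("G")
  base2 <- intersect(st$atoms$name[sel], rownames(tmpl))
  st$atoms <- st$atoms[st$atoms$resno == 1 | st$atoms$name %in% base2, ]
  sel <- st$atoms$resno == 2
  st$atoms$x[sel] <- tmpl[st$atoms$name[sel], 1]
  st$atoms$y[sel] <- tmpl[st$atoms$name[sel], 2]
  st$atoms$z[sel] <- tmpl[st$atoms$name[sel], 3] + 3.4
  res <- classify_pair(st, "A|1|", "A|2|")
  expect_false(modbp:::is_pair(res))
})

test_that("pairs without any base-base bond are 'not a pair'", {
  st <- gc_structure()
  sel <- st$atoms$resno == 2
  st$atoms$x[sel] <- st$atoms$x[sel] + 30
  res <- classify_pair(st, "A|1|", "A|2|")
  expect_false(modbp:::is_pair(res))
  expect_match(res$reason, "base-base")
})

test_that("the modified base leads the pair key", {
  st <- generate_pair("m5U:A tWH")   # modified pyrimidine vs canonical purine
  ann <- classify_pair(st, "A|2|", "A|1|")
  expect_equal(ann$symbol1, "m5U")
  st2 <- generate_pair("m1A:m5U tHW")  # doubly modified: purine parent first
  ann2 <- classify_pair(st2, "A|2|", "A|1|")
  expect_equal(ann2$symbol1, "m1A")
  expect_true(all(ann2$modified))
})
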
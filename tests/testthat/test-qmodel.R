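heavy <- function(frag) frag$atoms[frag$atoms$elem != "H", ]
hcount <- function(frag) sum(frag$atoms$elem == "H")

test_that("base-only models are truncated at C1' as a methyl", {
  st <- gc_structure()
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  expect_false(frag$includes_ribose)
  expect_equal(frag$net_charge, 0L)
  # heavy atoms: m5C base (9) + C1' and G base (11) + C1'
  h <- heavy(frag)
  expect_equal(sum(h$res == 1), 10)
  expect_equal(sum(h$res == 2), 12)
  expect_false(any(grepl("[2-5]'", h$name)))
  # hydrogens: m5C N4(2) C6(1) CM5(3) C1'(3) = 9 ; G N1(1) N2(2) C8(1) C1'(3) = 7
  expect_equal(hcount(frag), 16)
})

test_that("positively charged modifications propagate to the fragment", {
  st <- generate_pair("m7G:C cWW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  expect_equal(frag$net_charge, 1L)
})

test_that("the ribose is retained when its 2'-OH pairs", {
  st <- generate_pair("m66A:G tS(w)S(r)")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  expect_true(frag$includes_ribose)
  h <- heavy(frag)
  g <- h[h$res == 2, ]
  expect_true(all(c("O2'", "C2'", "C3'", "C4'", "C5'", "O4'") %in% g$name))
  expect_false(any(c("O5'", "O3'", "P") %in% g$name))       # capped
  expect_false("O2'" %in% h$name[h$res == 1])               # partner truncated
})

test_that("bridging waters are carried into the model with hydrogens", {
  st <- generate_pair("m1A:U tHW(w)")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  expect_equal(frag$waters, 1L)
  wat <- frag$atoms[frag$atoms$comp == "HOH", ]
  expect_equal(sum(wat$elem == "O"), 1)
  expect_equal(sum(wat$elem == "H"), 2)
})

test_that("capping removes the phosphate and follows the 3' rule", {
  m <- template_coords("A")
  # attach a fake 5'-phosphate along the O5'-C5' direction
  p <- m["O5'", ] + (m["O5'", ] - m["C5'", ])
  m2 <- rbind(m, P = p)
  capped <- cap_nucleoside(m2, "A")
  expect_false(any(c("P", "O5'", "O3'") %in% rownames(capped)))
  expect_true(all(c("C5'", "C3'", "O2'") %in% rownames(capped)))
  # idempotence on heavy atoms
  expect_equal(cap_nucleoside(capped, "A"), capped)
  # alternative rule keeps a 3' carbon at C-C bond length
  alt <- cap_nucleoside(m2, "A", three_prime = "methyl")
  expect_true("C3M" %in% rownames(alt))
  expect_equal(unname(modbp:::vnorm(alt["C3M", ] - alt["C3'", ])), 1.53,
               tolerance = 1e-6)
  expect_error(cap_nucleoside(m2[setdiff(rownames(m2), "C5'"), ], "A"),
               "C5'")
})

test_that("counterpart replacement preserves mapped coordinates exactly", {
  st <- generate_pair("m1A:m5U tHW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp <- make_unmodified_counterpart(frag)
  expect_equal(sort(unique(cp$atoms$comp)), c("A", "U"))
  expect_equal(cp$net_charge, 0L)
  expect_equal(rmsd_pairs(frag, cp, mode = "structural", fit = FALSE), 0,
               tolerance = 1e-12)
})

test_that("thio replacement restores O4 on the S4 axis at template length", {
  st <- generate_pair("s4U:A tWH")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp <- make_unmodified_counterpart(frag)
  s4 <- unlist(frag$atoms[frag$atoms$name == "S4", c("x", "y", "z")])
  c4 <- unlist(frag$atoms[frag$atoms$name == "C4" & frag$atoms$res == 1, c("x", "y", "z")])
  o4 <- unlist(cp$atoms[cp$atoms$name == "O4" & cp$atoms$res == 1, c("x", "y", "z")])
  v1 <- s4 - c4; v2 <- o4 - c4
  cosang <- sum(v1 * v2) / (modbp:::vnorm(v1) * modbp:::vnorm(v2))
  expect_equal(cosang, 1, tolerance = 1e-9)       # same direction
  expect_equal(unname(modbp:::vnorm(v2)),
               unname(modbp:::template_bond_length("U", "C4", "O4")),
               tolerance = 1e-9)
})

test_that("pseudouridine replacement preserves the pair orientation", {
  st <- generate_pair("Psi:A cHW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp <- make_unmodified_counterpart(frag)
  # U's N1 takes the position of Psi's C5 (the glycosidic attachment), so the
  # attachment direction from C1' is unchanged
  c1 <- unlist(frag$atoms[frag$atoms$name == "C1'" & frag$atoms$res == 1,
                          c("x", "y", "z")])
  c5 <- unlist(frag$atoms[frag$atoms$name == "C5" & frag$atoms$res == 1,
                          c("x", "y", "z")])
  n1 <- unlist(cp$atoms[cp$atoms$name == "N1" & cp$atoms$res == 1,
                        c("x", "y", "z")])
  expect_lt(modbp:::vnorm(c5 - n1), 1e-9)
  expect_lt(modbp:::vnorm(
    unlist(cp$atoms[cp$atoms$name == "C1'" & cp$atoms$res == 1, c("x", "y", "z")]) - c1),
    1e-9)
  # the counterpart has lost the extra N1-H donor position (U C5 carries H)
  expect_equal(rmsd_pairs(frag, cp, mode = "structural", fit = FALSE), 0,
               tolerance = 1e-12)
})

test_that("fragments without modifications return unchanged", {
  st <- gc_structure()
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp1 <- make_unmodified_counterpart(frag)        # replaces m5C
  cp2 <- make_unmodified_counterpart(cp1)         # nothing left to replace
  expect_identical(cp1, cp2)
})

test_that("every heavy atom has a closed valence after hydrogen completion", {
  valence <- c(C = 4, N = 3, O = 2, S = 2, BR = 1, I = 1)
  st <- generate_pair("m1A:A tHW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  a <- frag$atoms
  for (slot in 1:2) {
    sa <- a[a$res == slot, ]
    comp <- sa$comp[1]
    spec <- modbp:::residue_spec(comp)
    for (nm in sa$name[sa$elem != "H"]) {
      if (!nm %in% spec$atoms$name) next
      nbrs <- intersect(modbp:::atom_neighbors(comp, nm), sa$name)
      hn <- sa$name[sa$elem == "H"]
      rest <- substring(hn[startsWith(hn, paste0("H", nm))], nchar(nm) + 2)
      nh <- sum(rest == "" | grepl("^[0-9]+$", rest))
      el <- sa$elem[sa$name == nm][1]
      expected <- valence[[el]]
      # aromatic/charged nitrogens: N9, ring N with charge etc. allow +-1
      expect_lte(abs(length(nbrs) + nh - expected), 1,
                 label = paste(comp, nm))
    }
  }
})
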
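test_that("idealized Watson-Crick G:C pair yields exactly three base-base bonds", {
  st <- gc_structure()
  hb <- find_hbonds(st)
  bb <- hb[hb$kind == "base_base", ]
  expect_equal(nrow(bb), 3)
  got <- sort(paste(bb$donor_atom, bb$acceptor_atom, sep = ">"))
  expect_equal(got, sort(c("N4>O6", "N1>N3", "N2>O2")))
  expect_true(all(bb$distance <= 3.5 & bb$distance >= 2.4))
})

test_that("single-H-bond pair detects one bond only", {
  st <- generate_pair("m1G:C tHH1")
  hb <- find_hbonds(st)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N4")
  expect_equal(hb$acceptor_atom, "N7")
})

test_that("an isolated base has no H-bonds", {
  st <- gc_structure()
  st$atoms <- st$atoms[st$atoms$resno == 1, ]
  expect_equal(nrow(find_hbonds(st)), 0)
})

test_that("bridging waters are recovered and distance-limited", {
  st <- generate_pair("m1A:U tHW(w)")
  br <- find_bridging_waters(st, "A|1|", "A|2|")
  expect_gt(nrow(br), 0)
  expect_true(all(br$kind == "water_bridge"))
  expect_setequal(unique(br$acceptor_atom[br$acceptor_res == "A|1|"]), "N6")
  expect_setequal(unique(br$acceptor_atom[br$acceptor_res == "A|2|"]), "O2")
  # move the water 6 A away: the bridge disappears
  far <- st
  w <- far$atoms$comp == "HOH"
  far$atoms$z[w] <- far$atoms$z[w] + 6
  expect_equal(nrow(find_bridging_waters(far, "A|1|", "A|2|")), 0)
  # structure without waters
  dry <- st
  dry$atoms <- dry$atoms[!w, ]
  expect_equal(nrow(find_bridging_waters(dry, "A|1|", "A|2|")), 0)
})

test_that("detection is monotone in the distance threshold", {
  st <- generate_pair("s4U:A tWH")
  loose <- find_hbonds(st, hbond_params(dist_max = 3.8))
  tight <- find_hbonds(st, hbond_params(dist_max = 3.2))
  key <- function(h) paste(h$donor_res, h$donor_atom, h$acceptor_res, h$acceptor_atom)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("detection is invariant under rigid motion", {
  st <- generate_pair("m22G:A cWW")
  hb0 <- find_hbonds(st)
  set.seed(19)
  st2 <- transform_structure(st, random_rotation(), c(5, -3, 2))
  hb1 <- find_hbonds(st2)
  expect_equal(hb1$donor_atom, hb0$donor_atom)
  expect_equal(hb1$acceptor_atom, hb0$acceptor_atom)
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-6)
})

test_that("donors never exceed their hydrogen count", {
  for (k in c("m5C:G cWW", "m7G:C cWW", "Psi:G cWW")) {
    hb <- find_hbonds(generate_pair(k))
    dcount <- table(paste(hb$donor_res, hb$donor_atom))
    caps <- vapply(names(dcount), function(n) {
      parts <- strsplit(n, " ")[[1]]
      comp <- hb$donor_comp[paste(hb$donor_res, hb$donor_atom) == n][1]
      modbp:::donor_capacity(comp, parts[2])
    }, 0L)
    expect_true(all(as.integer(dcount) <= caps), label = k)
  }
})

test_that("donor and acceptor roles come from the chemistry dictionary", {
  hb <- find_hbonds(generate_pair("m7G:G tWH"))
  for (i in seq_len(nrow(hb))) {
    expect_true(modbp:::atom_role(hb$donor_comp[i], hb$donor_atom[i]) %in%
                  c("donor", "both"))
    expect_true(modbp:::atom_role(hb$acceptor_comp[i], hb$acceptor_atom[i]) %in%
                  c("acceptor", "both"))
  }
})
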
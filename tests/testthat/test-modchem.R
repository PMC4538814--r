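test_that("dictionary covers the expected modification catalog", {
  mods <- list_modifications()
  expect_length(mods, 14)
  expect_length(list_modifications(natural_only = TRUE), 11)
  # positive charge exactly for 1-methyladenosine and 7-methylguanosine
  charged <- mods[vapply(mods, function(m) lookup_modification(m)$net_charge == 1L, TRUE)]
  expect_setequal(charged, c("1MA", "7MG"))
})

test_that("lookup resolves codes, aliases and symbols case-insensitively", {
  psu <- lookup_modification("PSU")
  expect_equal(psu$parent, "U")
  expect_equal(psu$glycosidic_atom, "C5")
  expect_equal(psu$affected_edges, "H")
  expect_equal(lookup_modification("psu")$comp_code, "PSU")
  expect_equal(lookup_modification("m1A")$comp_code, "1MA")
  expect_equal(lookup_modification("DHU")$comp_code, "H2U")
  a <- lookup_modification("A")
  expect_length(a$atom_edits, 0)
  expect_equal(a$net_charge, 0L)
  expect_error(lookup_modification("XYZ"), "unsupported residue")
})

test_that("edge assignments follow the Leontis-Westhof faces", {
  expect_equal(edge_of_atom("U", "N3"), "W")
  expect_equal(edge_of_atom("A", "N7"), "H")
  expect_equal(edge_of_atom("G", "O2'"), "S")
  expect_equal(edge_of_atom("G", "O2*"), "S")
  # boundary atoms expose both candidate faces
  expect_setequal(edge_candidates("A", "N6"), c("W", "H"))
  expect_setequal(edge_candidates("U", "O2"), c("W", "S"))
  expect_error(edge_of_atom("A", "O4"), "not found")
})

test_that("every base atom carries exactly one primary edge", {
  for (code in c("A", "G", "C", "U", list_modifications())) {
    spec <- modbp:::residue_spec(code)
    base <- spec$atoms[spec$atoms$moiety == "base", ]
    expect_true(all(base$edge %in% c("W", "H", "S")), label = code)
    expect_false(anyDuplicated(base$name) > 0, label = code)
  }
})

test_that("ring atoms of planar templates are coplanar within 0.01 A", {
  for (code in c("A", "G", "C", "U", setdiff(list_modifications(), "H2U"))) {
    m <- template_coords(code)
    base <- intersect(rownames(m), modbp:::base_atom_names(code))
    pl <- modbp:::fit_plane(m[base, , drop = FALSE])
    dev <- abs((m[base, , drop = FALSE] - matrix(pl$center, length(base), 3,
                                                 byrow = TRUE)) %*% pl$normal)
    expect_lt(max(dev), 0.01, label = code)
  }
})

test_that("dihydrouridine template is the stated half-chair", {
  m <- template_coords("H2U")
  d1 <- modbp:::dihedral_angle(m["N1", ], m["C6", ], m["C5", ], m["C4", ])
  d2 <- modbp:::dihedral_angle(m["N1", ], m["C2", ], m["N3", ], m["C4", ])
  expect_lt(d1, -25); expect_gt(d1, -70)
  expect_lt(d2, 0); expect_gt(d2, -30)
})

test_that("atom edits round-trip to the parent heavy-atom set", {
  for (code in list_modifications()) {
    spec <- lookup_modification(code)
    mod_atoms <- modbp:::base_atom_names(code)
    # reverse the edits: drop additions, undo replacements, re-add removals
    adds <- vapply(Filter(function(e) e$op == "add", spec$atom_edits),
                   `[[`, "", "atom")
    repl <- Filter(function(e) e$op == "replace_element", spec$atom_edits)
    rest <- setdiff(mod_atoms, adds)
    for (e in repl) rest[rest == e$atom] <- e$parent_atom
    reattach <- Filter(function(e) e$op == "reattach_glycosidic", spec$atom_edits)
    expect_setequal(rest, modbp:::base_atom_names(spec$parent))
    if (code == "PSU") expect_length(reattach, 1)
  }
})

test_that("edits only touch atoms on the declared affected edges", {
  for (code in list_modifications()) {
    spec <- lookup_modification(code)
    for (e in spec$atom_edits) {
      if (e$op %in% c("add", "replace_element")) {
        expect_true(edge_of_atom(code, e$atom) %in% spec$affected_edges,
                    label = paste(code, e$atom))
      }
    }
  }
})

test_that("pseudouridine correspondence is the glycosidic ring walk", {
  map <- correspondence_map("PSU", include_sugar = FALSE)
  want <- c(C5 = "N1", C4 = "C2", O4 = "O2", N3 = "N3",
            C2 = "C4", O2 = "O4", N1 = "C5", C6 = "C6")
  expect_equal(stats::setNames(map$parent, map$mod)[names(want)], want)
})

test_that("ring-walk map is the RMSD-optimal ring correspondence", {
  # oracle: among the two rotational walks of the uracil ring aligned at the
  # glycosidic attachment, the documented map must give the smaller RMSD when
  # the templates are superimposed
  psu <- template_coords("PSU")
  u <- template_coords("U")
  walk1 <- c(C5 = "N1", C4 = "C2", N3 = "N3", C2 = "C4", N1 = "C5", C6 = "C6")
  walk2 <- c(C5 = "N1", C6 = "C2", N1 = "N3", C2 = "C4", N3 = "C5", C4 = "C6")
  rms <- function(walk) {
    best_fit(psu[names(walk), ], u[walk, ])$rmsd
  }
  expect_lt(rms(walk1), rms(walk2))
})

test_that("substituent modifications map by identity with element replacements", {
  m4su <- correspondence_map("4SU", include_sugar = FALSE)
  expect_true(any(m4su$mod == "S4" & m4su$parent == "O4"))
  ident <- m4su[m4su$mod != "S4", ]
  expect_equal(ident$mod, ident$parent)
  m5c <- correspondence_map("5MC", include_sugar = FALSE)
  expect_false("CM5" %in% m5c$mod)
  expect_equal(m5c$mod, m5c$parent)
})
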
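test_that("identity and exact recovery", {
  set.seed(11)
  P <- matrix(rnorm(30), ncol = 3)
  fit <- best_fit(P, P)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  R <- random_rotation()
  Q <- P %*% t(R) + matrix(c(1, -2, 3), nrow(P), 3, byrow = TRUE)
  fit2 <- best_fit(P, Q)
  expect_lt(fit2$rmsd, 1e-8)
  expect_equal(fit2$rotation, R, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(best_fit(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(best_fit(line, line + 1), "collinear")
})

test_that("SVD solution matches the quaternion oracle on random clouds", {
  set.seed(42)
  for (i in 1:100) {
    P <- matrix(rnorm(30), ncol = 3)
    Q <- matrix(rnorm(30), ncol = 3)
    expect_lt(abs(best_fit(P, Q)$rmsd - quaternion_fit(P, Q)$rmsd), 1e-6)
  }
})

test_that("reflections are forbidden", {
  set.seed(7)
  P <- matrix(rnorm(24), ncol = 3)
  Q <- P
  Q[, 3] <- -Q[, 3]   # mirror image
  fit <- best_fit(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_gt(fit$rmsd, 0.1)  # a proper rotation cannot superpose a mirror image
})

test_that("rotation output is orthonormal", {
  set.seed(3)
  P <- matrix(rnorm(30), ncol = 3); Q <- matrix(rnorm(30), ncol = 3)
  R <- best_fit(P, Q)$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
})

test_that("fragment RMSD is symmetric and rigid-motion invariant", {
  st <- gc_structure()
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp <- make_unmodified_counterpart(frag)
  r12 <- rmsd_pairs(frag, cp, mode = "common_atoms")
  r21 <- rmsd_pairs(cp, frag, mode = "common_atoms")
  expect_lt(abs(r12 - r21), 1e-9)
  set.seed(5)
  R <- random_rotation()
  cp2 <- cp
  xyz <- as.matrix(cp2$atoms[, c("x", "y", "z")]) %*% t(R)
  cp2$atoms$x <- xyz[, 1] + 4; cp2$atoms$y <- xyz[, 2]; cp2$atoms$z <- xyz[, 3]
  expect_lt(abs(rmsd_pairs(frag, cp2, mode = "common_atoms") - r12), 1e-6)
})

test_that("fragment self-RMSD is zero in every mode", {
  st <- generate_pair("Psi:A cHW")
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  for (mode in c("all_heavy", "common_atoms", "structural")) {
    expect_equal(rmsd_pairs(frag, frag, mode = mode), 0, tolerance = 1e-10)
  }
})

test_that("methyl is excluded from the shared-atom RMSD", {
  st <- gc_structure()   # m5C:G pair
  ann <- classify_pair(st, "A|1|", "A|2|")
  frag <- build_pair_model(ann, st)
  cp <- make_unmodified_counterpart(frag)
  # oracle: hand-selected shared heavy atoms (all parent atoms, no CM5)
  a1 <- frag$atoms[frag$atoms$elem != "H", ]
  a2 <- cp$atoms[cp$atoms$elem != "H", ]
  shared <- merge(a1, a2, by = c("res", "name"))
  expect_false(any(grepl("^CM", shared$name)))
  hand <- best_fit(as.matrix(shared[, c("x.x", "y.x", "z.x")]),
                   as.matrix(shared[, c("x.y", "y.y", "z.y")]))$rmsd
  expect_equal(rmsd_pairs(frag, cp, mode = "common_atoms"), hand,
               tolerance = 1e-9)
})
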
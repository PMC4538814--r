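# Shared helpers: small in-code fixtures for the test suite.

# all atlas pair-type keys
atlas_keys <- function() names(atlas_recipes())

# a minimal G:C Watson-Crick structure built from templates via the generator
gc_structure <- function() generate_pair("m5C:G cWW")

# random proper rotation matrix (seeded by the caller)
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sqrt(sum(q^2)) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
}

# apply a rigid transform to a Structure
transform_structure <- function(st, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st$atoms$x <- xyz[, 1] + t[1]
  st$atoms$y <- xyz[, 2] + t[2]
  st$atoms$z <- xyz[, 3] + t[3]
  st
}
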
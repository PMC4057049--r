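canonical_pair <- function(b = 0.05, sigma = pi / 6, h1 = 0, h2 = 0) {
  list(p1 = screw_from_axis(c(0, 0, b), c(cos(sigma), sin(sigma), 0), h1),
       p2 = screw_from_axis(c(0, 0, -b), c(cos(sigma), -sin(sigma), 0), h2))
}

test_that("a canonical zero-pitch pair is recovered with the hand-derived principal pitches", {
  b <- 0.05; sg <- pi / 6
  pp <- canonical_pair(b, sg)
  cyl <- build_cylindroid(pp$p1, pp$p2)
  expect_equal(cyl$b, b, tolerance = 1e-12)
  expect_equal(cyl$sigma, sg, tolerance = 1e-12)
  # hand oracle: sum/difference of the generator 6-vectors, pitch = d.m/|d|^2
  s_sum <- screw_6vec(pp$p1) + screw_6vec(pp$p2)
  s_dif <- screw_6vec(pp$p1) - screw_6vec(pp$p2)
  h_sum <- sum(s_sum[1:3] * s_sum[4:6]) / sum(s_sum[1:3]^2)
  h_dif <- sum(s_dif[1:3] * s_dif[4:6]) / sum(s_dif[1:3]^2)
  expect_equal(h_sum, -b * tan(sg), tolerance = 1e-12)
  expect_equal(h_dif, b / tan(sg), tolerance = 1e-12)
  expect_equal(cyl$h_alpha, h_sum, tolerance = 1e-12)
  expect_equal(cyl$h_beta, h_dif, tolerance = 1e-12)
  # canonical frame: origin at the generator midpoint, x along the bisector
  expect_equal(cyl$frame$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(cyl$frame$rotation[, 1]), c(1, 0, 0), tolerance = 1e-12)
})

test_that("principal screws intersect orthogonally and carry extremal pitches", {
  set.seed(31)
  for (i in 1:20) {
    cyl <- build_cylindroid(rand_screw(), rand_screw())
    expect_lt(abs(sum(cyl$p_alpha$d * cyl$p_beta$d)), 1e-9)
    cp <- screwgait:::closest_points_lines(
      axis_point(cyl$p_alpha), cyl$p_alpha$d,
      axis_point(cyl$p_beta), cyl$p_beta$d)
    expect_lt(cp$dist, 1e-9)
    # pitches over a dense sweep of the system stay within the principal band
    phis <- seq(0, pi, length.out = 181)
    hs <- vapply(phis, function(ph) {
      s <- screw_at(cyl, cos(ph), sin(ph))
      screw_pitch(s)
    }, 0)
    expect_gte(min(hs), min(cyl$h_alpha, cyl$h_beta) - 1e-10)
    expect_lte(max(hs), max(cyl$h_alpha, cyl$h_beta) + 1e-10)
    expect_equal(range(hs), range(c(cyl$h_alpha, cyl$h_beta)), tolerance = 1e-6)
  }
})

test_that("b, sigma and principal pitches are invariant under rigid transformation", {
  set.seed(37)
  for (i in 1:15) {
    p1 <- rand_screw(); p2 <- rand_screw()
    cyl <- build_cylindroid(p1, p2)
    R <- rand_rotation(); tr <- rnorm(3)
    cyl2 <- build_cylindroid(transform_screw(p1, R, tr), transform_screw(p2, R, tr))
    expect_equal(cyl2$b, cyl$b, tolerance = 1e-9)
    expect_equal(cyl2$sigma, cyl$sigma, tolerance = 1e-9)
    expect_equal(sort(c(cyl2$h_alpha, cyl2$h_beta)),
                 sort(c(cyl$h_alpha, cyl$h_beta)), tolerance = 1e-9)
  }
})

test_that("coaxial generators raise a degenerate-cylindroid error", {
  p <- screw_from_axis(c(0, 0.2, 0), c(1, 1, 0), 0.01)
  q <- screw_from_axis(c(0, 0.2, 0), c(1, 1, 0), -0.02)
  expect_error(build_cylindroid(p, q), class = "screwgait_error_degenerate_cylindroid")
})

test_that("screw_at recovers the basis, the generators, and the conoid surface law", {
  set.seed(41)
  cyl <- build_cylindroid(rand_screw(), rand_screw())
  expect_equal(screw_6vec(screw_at(cyl, 1, 0)), screw_6vec(cyl$p_alpha))
  expect_equal(screw_6vec(screw_at(cyl, 0, 1)), screw_6vec(cyl$p_beta))
  expect_error(screw_at(cyl, 0, 0), class = "screwgait_error_invalid_input")

  # generators reproduced at their stored principal coordinates
  for (j in 1:2) {
    lam <- cyl$lambda[, j]
    s <- screw_at(cyl, lam[1], lam[2])
    tgt <- screw_6vec(if (j == 1) cyl$p1 else cyl$p2)
    expect_lt(min(max(abs(screw_6vec(s) - tgt)), max(abs(screw_6vec(s) + tgt))), 1e-9)
  }

  # cubic surface law z (x^2 + y^2) = (h_beta - h_alpha) x y in the canonical
  # frame, checked on a generic point of each sampled axis
  grid <- expand.grid(la = seq(-2, 2, length.out = 9), lb = seq(-2, 2, length.out = 9))
  grid <- grid[grid$la != 0 | grid$lb != 0, ]
  for (k in seq_len(nrow(grid))) {
    s <- to_canonical(cyl, screw_at(cyl, grid$la[k], grid$lb[k]))
    pt <- axis_point(s) + s$d
    expect_lt(abs(pt[3] * (pt[1]^2 + pt[2]^2) -
                    (cyl$h_beta - cyl$h_alpha) * pt[1] * pt[2]), 1e-9)
  }
})

test_that("every screw of the system is reciprocal to the generators' reciprocal system", {
  set.seed(43)
  p1 <- rand_screw(); p2 <- rand_screw()
  cyl <- build_cylindroid(p1, p2)
  basis <- reciprocal_system(list(p1, p2))
  expect_length(basis, 4)
  for (r in seq(0.2, 3, length.out = 7)) {
    s <- screw_at(cyl, r, 1)
    for (b in basis) expect_lt(abs(virtual_coefficient(s, b)), 1e-9)
  }
})

test_that("conoid samples lie on the surface, cross the nodal line, and bound their pitch", {
  set.seed(47)
  cyl <- build_cylindroid(rand_screw(), rand_screw())
  cs <- conoid_samples(cyl, 0.3, 2.5, n = 50, frame = "canonical")
  expect_equal(nrow(cs), 50)
  # perpendicular to and intersecting the z-axis of the canonical frame
  expect_lt(max(abs(cs$dz)), 1e-9)
  expect_lt(max(abs(cs$x * cs$dy - cs$y * cs$dx) /
                  sqrt(cs$x^2 + cs$y^2 + 1e-300) * sqrt(cs$x^2 + cs$y^2) -
                  abs(cs$x * cs$dy - cs$y * cs$dx)), 1e-12)
  for (i in seq_len(nrow(cs))) {
    cp <- screwgait:::closest_points_lines(
      c(cs$x[i], cs$y[i], cs$z[i]), c(cs$dx[i], cs$dy[i], cs$dz[i]),
      c(0, 0, 0), c(0, 0, 1))
    expect_lt(cp$dist, 1e-9)
  }
  expect_gte(min(cs$pitch), min(cyl$h_alpha, cyl$h_beta) - 1e-10)
  expect_lte(max(cs$pitch), max(cyl$h_alpha, cyl$h_beta) + 1e-10)
  # endpoints reproducible through screw_at
  two <- conoid_samples(cyl, 0.3, 2.5, n = 2)
  s1 <- screw_at(cyl, 0.3, 1)
  expect_equal(c(two$dx[1], two$dy[1], two$dz[1]), s1$d, tolerance = 1e-12)
  expect_error(conoid_samples(cyl, -1, 2), class = "screwgait_error_invalid_input")
  expect_error(conoid_samples(cyl, 0.3, 2.5, n = 1), class = "screwgait_error_invalid_input")
})

test_that("twist composition obeys cancellation, identity and the parallel-axes rule", {
  z0 <- screw_from_axis(c(0, 0, 0), c(0, 0, 1))
  # exact cancellation -> flagged null twist
  r <- compose_twists(twist(z0, 1), twist(z0, -1))
  expect_equal(r$amplitude, 0)
  expect_true(attr(r, "null"))
  # zero second amplitude -> first twist back
  t1 <- twist(screw_from_axis(c(0.1, 0, 0), c(0, 1, 1), 0.02), 1.3)
  r2 <- compose_twists(t1, twist(z0, 0))
  expect_equal(twist_6vec(r2), twist_6vec(t1), tolerance = 1e-12)

  # two rotations about parallel axes: resultant divides the separation
  # inversely to the amplitudes (classical oracle via direct 6-vector sums)
  set.seed(53)
  for (i in 1:20) {
    d <- runif(1, 0.05, 0.5); w1 <- runif(1, 0.2, 2); w2 <- runif(1, 0.2, 2)
    za <- screw_from_axis(c(0, 0, 0), c(0, 0, 1))
    zb <- screw_from_axis(c(d, 0, 0), c(0, 0, 1))
    r3 <- compose_twists(twist(za, w1), twist(zb, w2))
    expect_equal(r3$amplitude, w1 + w2, tolerance = 1e-12)
    expect_equal(axis_point(r3$screw)[1], d * w2 / (w1 + w2), tolerance = 1e-12)
  }

  # commutative and associative in 6-coordinates
  t2 <- twist(rand_screw(), 0.7); t3 <- twist(rand_screw(), -0.4)
  expect_equal(twist_6vec(compose_twists(t1, t2)), twist_6vec(compose_twists(t2, t1)))
  expect_equal(twist_6vec(compose_twists(compose_twists(t1, t2), t3)),
               twist_6vec(compose_twists(t1, compose_twists(t2, t3))),
               tolerance = 1e-12)

  # resultant lies on the cylindroid of the two screws
  cylr <- build_cylindroid(t1$screw, t2$screw)
  res <- compose_twists(t1, t2)
  lam <- qr.solve(cbind(screw_6vec(cylr$p_alpha), screw_6vec(cylr$p_beta)),
                  screw_6vec(res$screw))
  expect_equal(screw_6vec(screw_at(cylr, lam[1], lam[2])), screw_6vec(res$screw),
               tolerance = 1e-9)
})

test_that("a nearly coaxial pair collapses toward a degenerate line system", {
  # as sigma -> 0 and b -> 0 every screw at a fixed finite ratio becomes
  # coaxial with the generators and its pitch vanishes with the system
  eps <- 1e-8
  pp <- canonical_pair(b = eps, sigma = eps)
  cyl <- build_cylindroid(pp$p1, pp$p2)
  expect_equal(cyl$b, eps, tolerance = 1e-6)
  expect_equal(cyl$sigma, eps, tolerance = 1e-6)
  expect_lt(abs(cyl$h_alpha), 1e-7)
  for (r in seq(0.3, 2.5, length.out = 5)) {
    s <- as_screw(r * screw_6vec(pp$p1) + screw_6vec(pp$p2))
    expect_lt(dir_angle(s$d, pp$p1$d), 1e-6)
    expect_lt(line_distance(s, pp$p1), 1e-6)
    expect_lt(abs(screw_pitch(s)), 1e-6)
  }
})
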
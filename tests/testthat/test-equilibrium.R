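test_that("reciprocal_system returns nullspace bases of the right dimension", {
  set.seed(71)
  # one generic screw: a fifth-order system, every member reciprocal
  s <- rand_screw()
  basis <- reciprocal_system(list(s))
  expect_length(basis, 5)
  for (b in basis) expect_lt(abs(virtual_coefficient(s, b)), 1e-9)

  # five independent lines all meeting one axis: the reciprocal system is
  # one-dimensional and reproduces that axis
  ax <- screw_from_axis(c(0.05, -0.02, 0), c(0.1, 1, 0.3))
  lines5 <- lapply(1:5, function(i) {
    p <- axis_point(ax) + runif(1, -0.3, 0.3) * ax$d
    screw_from_axis(p, rnorm(3))
  })
  r5 <- reciprocal_system(lines5)
  expect_length(r5, 1)
  got <- screw_6vec(r5[[1]]); want <- screw_6vec(ax)
  expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-9)

  # six screws spanning all of screw space: empty basis
  full <- c(lapply(1:3, function(i) screw_from_axis(c(0, 0, 0), diag(3)[i, ])),
            lapply(1:3, function(i) screw_from_axis(c(0, 0, 0), diag(3)[i, ], pitch = Inf)))
  expect_length(reciprocal_system(full), 0)

  expect_error(reciprocal_system(list(s), tol = -1),
               class = "screwgait_error_invalid_input")
})

test_that("random screw sets always give dimension 6 - rank with tiny pairings", {
  set.seed(73)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    screws <- replicate(k, rand_screw(), simplify = FALSE)
    basis <- reciprocal_system(screws)
    S <- do.call(rbind, lapply(screws, screw_6vec))
    expect_length(basis, 6 - screwgait:::mat_rank(S))
    for (b in basis) for (s in screws) {
      expect_lt(abs(virtual_coefficient(s, b)), 1e-9)
    }
  }
})

test_that("grf_wrench reduces force-plate records correctly", {
  # vertical force through the origin: zero-pitch wrench along z
  w <- grf_wrench(c(0, 0, 700), c(0, 0, 0))
  expect_equal(w$intensity, 700)
  expect_equal(w$screw$d, c(0, 0, 1))
  expect_equal(screw_pitch(w$screw), 0)

  # offset centre of pressure: moment part is cop x F (cross-product oracle)
  F <- c(0, 0, 700); cop <- c(0.1, 0, 0)
  w2 <- grf_wrench(F, cop)
  oracle_m <- c(cop[2] * F[3] - cop[3] * F[2],
                cop[3] * F[1] - cop[1] * F[3],
                cop[1] * F[2] - cop[2] * F[1])
  expect_equal(wrench_6vec(w2)[4:6], oracle_m, tolerance = 1e-12)

  # pure free moment: infinite-pitch wrench
  w3 <- grf_wrench(c(0, 0, 0), c(0, 0, 0), c(0, 0, 5))
  expect_true(w3$screw$infinite)
  expect_equal(w3$intensity, 5)

  # nothing at all: flagged null
  w4 <- grf_wrench(c(0, 0, 0))
  expect_true(attr(w4, "null"))
  expect_equal(w4$intensity, 0)
})

test_that("replace_wrench zeroes the combined virtual work and detects no leverage", {
  set.seed(79)
  for (i in 1:50) {
    iak <- rand_screw()
    phi <- wrench(rand_screw(), runif(1, 100, 900))
    eta_screw <- rand_screw()
    eta <- replace_wrench(phi, eta_screw, iak)
    work <- eta * virtual_coefficient(eta_screw, iak) +
      phi$intensity * virtual_coefficient(phi$screw, iak)
    expect_lt(abs(work), 1e-10 * max(1, phi$intensity))
  }

  # a wrench already reciprocal to the freedom needs no replacement
  iak <- screw_from_axis(c(0, 0, 0), c(1, 0, 0))
  recip_line <- screw_from_axis(c(0.2, 0, 0), c(1, 1, 0))  # meets the axis
  phi0 <- wrench(recip_line, 500)
  eta_screw <- rand_screw()
  expect_equal(replace_wrench(phi0, eta_screw, iak), 0, tolerance = 1e-9)

  # self-replacement flips the sign of the intensity
  phi <- wrench(rand_screw(), 321)
  expect_equal(replace_wrench(phi, phi$screw, rand_screw()), -321, tolerance = 1e-9)

  # eta reciprocal to the IAK: no leverage on this freedom
  expect_error(replace_wrench(phi0, recip_line, iak),
               class = "screwgait_error_no_leverage")
})

test_that("decompose_wrench recovers forward-constructed intensities", {
  geo <- gen_constraint_geometry(seed = 7)
  iak <- reciprocal_system(geo)[[1]]
  Smat <- do.call(cbind, lapply(geo, screw_6vec))
  nu <- screwgait:::nullspace_basis(Smat)

  # zero wrench: all intensities zero
  sol0 <- decompose_wrench(grf_wrench(c(0, 0, 0)), geo)
  expect_equal(unname(sol0$intensities), rep(0, 6))

  set.seed(83)
  for (i in 1:20) {
    g0 <- runif(6, 0, 500)
    g <- g0 - drop(nu %*% (t(nu) %*% g0))   # minimum-norm representative
    W <- -drop(Smat %*% g)
    w <- grf_wrench(W[1:3], c(0, 0, 0), W[4:6])
    sol <- decompose_wrench(w, geo, iak = iak)
    expect_equal(unname(sol$intensities), g, tolerance = 1e-6 * max(abs(g)))
    expect_lt(sol$residual, 1e-9 * max(1, max(abs(g))))
    expect_equal(sol$rank, 5)
    # re-synthesis closes in 6-coordinates
    expect_lt(max(abs(Smat %*% sol$intensities + W)), 1e-8)
    # zero virtual work of applied wrench + reactions on the IAK twist
    total <- wrench_6vec(w) + drop(Smat %*% sol$intensities)
    expect_lt(abs(sum(screw_6vec(iak) * (screwgait:::.delta6 %*% total))), 1e-9)
    # scaling equivariance
    w2 <- grf_wrench(2 * W[1:3], c(0, 0, 0), 2 * W[4:6])
    sol2 <- decompose_wrench(w2, geo)
    expect_equal(sol2$intensities, 2 * sol$intensities, tolerance = 1e-10)
  }
})

test_that("a wrench on a single constraint line is reacted along that line", {
  geo <- gen_constraint_geometry(seed = 7)
  w <- wrench(geo$P1, 300)

  # with six rank-5 lines the solution is the minimum-norm representative:
  # -300 times the projection of the P1 unit load off the 1-D gauge direction
  sol <- decompose_wrench(w, geo)
  Smat <- do.call(cbind, lapply(geo, screw_6vec))
  nu <- drop(screwgait:::nullspace_basis(Smat))
  e1 <- as.numeric(names(geo) == "P1")
  expect_equal(unname(sol$intensities), -300 * (e1 - nu * sum(nu * e1)),
               tolerance = 1e-8)
  expect_lt(sol$residual, 1e-8)
  expect_true("P1" %in% sol$tension_flags)

  # with five independent lines the solution is unique: exactly -300 on P1
  geo5 <- constraint_set(unclass(geo)[c("ACL", "PCL", "MCL", "P1", "P2")])
  expect_equal(attr(geo5, "rank"), 5L)
  sol5 <- decompose_wrench(w, geo5)
  expect_equal(sol5$medial_force, -300, tolerance = 1e-8)
  others <- sol5$intensities[setdiff(names(sol5$intensities), "P1")]
  expect_lt(max(abs(others)), 1e-7)
})

test_that("a wrench that works on the IAK is rejected as inconsistent", {
  geo <- gen_constraint_geometry(seed = 7)
  iak <- reciprocal_system(geo)[[1]]
  # a pure force along a line far from reciprocal to the IAK
  bad <- wrench(screw_from_axis(axis_point(iak) + c(0, 0.3, 0), iak$d, 0.05), 400)
  expect_gt(abs(virtual_coefficient(bad$screw, iak)), 1e-3)
  expect_error(decompose_wrench(bad, geo, iak = iak),
               class = "screwgait_error_inconsistent")
})

test_that("tidy and glance summarise an equilibrium solution", {
  geo <- gen_constraint_geometry(seed = 7)
  Smat <- do.call(cbind, lapply(geo, screw_6vec))
  W <- -drop(Smat %*% rep(100, 6))
  sol <- decompose_wrench(grf_wrench(W[1:3], c(0, 0, 0), W[4:6]), geo)
  td <- tidy(sol)
  expect_equal(td$constraint, names(geo))
  gl <- glance(sol)
  expect_equal(gl$rank, 5)
  expect_equal(gl$medial_force, sol$medial_force)
})

test_that("special-configuration ratios follow their limit conventions", {
  r <- special_config_ratios(list(0, 0), 1, list(200, 300), 400)
  expect_equal(r$ratio1, 0)
  expect_equal(r$ratio2, 1.25)
  expect_false(r$is_special)

  # vanishing end-effector wrench with live actuators: ratio2 diverges
  r2 <- special_config_ratios(list(twist(rand_line(), 0)), twist(rand_line(), 1),
                              list(wrench(rand_line(), 150)), wrench(rand_line(), 0))
  expect_identical(r2$ratio2, Inf)
  expect_true(r2$is_special)

  # generic state: both finite positive, not special
  r3 <- special_config_ratios(list(0.4, 0.2), 0.5, list(120), 300)
  expect_true(is.finite(r3$ratio1) && r3$ratio1 > 0)
  expect_true(is.finite(r3$ratio2) && r3$ratio2 > 0)
  expect_false(r3$is_special)
})
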
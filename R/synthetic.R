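#' Default marker cluster: 8 markers at cube corners
#'
#' @param center Cluster centre (m).
#' @param half_edge Half edge length (m); 0.15 m emulates a thigh/shank
#'   marker plate with a realistic spread.
#' @param prefix Label prefix.
#' @return Tibble `marker`, `x`, `y`, `z`.
#' @export
marker_cluster <- function(center = c(0, 0, 0), half_edge = 0.15, prefix = "M") {
  g <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  tibble::tibble(
    marker = paste0(prefix, seq_len(8)),
    x = center[1] + half_edge * g$x,
    y = center[2] + half_edge * g$y,
    z = center[3] + half_edge * g$z)
}

# Apply the displacement of a screw motion (angle theta about `axis` with
# pitch h) to an n x 3 matrix of points.
screw_displace <- function(points, axis, theta, pitch = 0) {
  u <- axis$d
  r0 <- axis_point(axis)
  R <- rot_axis_angle(u, theta)
  shifted <- sweep(as.matrix(points), 2, r0)
  out <- shifted %*% t(R)
  sweep(out, 2, r0 + pitch * theta * u, FUN = "+")
}

#' Generate rigid marker motion about a known screw
#'
#' Moves a marker cluster rigidly along a helical motion about `axis` with
#' the given pitch, following a smooth angle profile, and returns both the
#' noisy marker trajectories and the exact generating twist per frame. This
#' closes the loop for the ISA estimator: in the noiseless case the
#' recovered axis and pitch equal the generator's to machine precision.
#'
#' @param seed Integer seed; all randomness (marker noise) derives from it.
#' @param axis A zero-pitch `screw`, the motion axis.
#' @param pitch Pitch of the motion (m/rad).
#' @param total_angle Total rotation over the trial (rad); the default 60
#'   degrees matches a knee flexion sweep.
#' @param duration Trial length (s).
#' @param rate Sampling rate (Hz).
#' @param cluster Marker layout tibble (default [marker_cluster()] centred
#'   0.25 m off-axis).
#' @param noise_sd Isotropic Gaussian marker noise SD (m).
#' @return A list of class `synthetic_motion`: `markers` (tidy tibble with
#'   `frame`, `time`, `marker`, `x`, `y`, `z`), `truth` (per-frame tibble
#'   with the generating axis, pitch and angular velocity), `rate`, `seed`.
#' @export
gen_helical_motion <- function(seed = 1, axis = screw_from_axis(c(0, 0, 0), c(0, 0, 1)),
                               pitch = 0, total_angle = pi / 3, duration = 1,
                               rate = 100, cluster = NULL, noise_sd = 0) {
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  stopifnot(is_screw(axis), !axis$infinite)
  if (is.null(cluster)) {
    off <- axis_point(axis) + 0.25 * orthonormal_to(axis$d)
    cluster <- marker_cluster(center = off, half_edge = 0.15)
  }
  base <- as.matrix(cluster[, c("x", "y", "z")])
  if (mat_rank(sweep(base, 2, colMeans(base)), rtol = 1e-9) < 2) {
    rlang::abort("degenerate marker layout: markers are collinear",
                 class = "screwgait_error_rank")
  }
  n <- round(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  # smooth ramp: zero angular velocity at both ends
  theta <- total_angle * (1 - cos(pi * t / duration)) / 2
  omega <- total_angle * pi / (2 * duration) * sin(pi * t / duration)
  set.seed(seed)
  noise <- if (noise_sd > 0) array(stats::rnorm(n * nrow(base) * 3, 0, noise_sd),
                                   c(n, nrow(base), 3)) else NULL
  markers <- purrr::map_dfr(seq_len(n), function(i) {
    pts <- screw_displace(base, axis, theta[i], pitch)
    if (!is.null(noise)) pts <- pts + noise[i, , ]
    tibble::tibble(frame = i, time = t[i], marker = cluster$marker,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  gen_screw <- screw_from_axis(axis_point(axis), axis$d, pitch)
  p <- axis_point(gen_screw)
  truth <- tibble::tibble(frame = seq_len(n), time = t,
                          dx = gen_screw$d[1], dy = gen_screw$d[2], dz = gen_screw$d[3],
                          px = p[1], py = p[2], pz = p[3],
                          pitch = pitch, amplitude = omega)
  structure(list(markers = markers, truth = truth, rate = rate, seed = seed,
                 axis = gen_screw),
            class = "synthetic_motion")
}

# A unit vector orthogonal to u.
orthonormal_to <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(cross3(u, v))
}

#' Generate a synthetic knee constraint geometry
#'
#' Builds six zero-pitch lines in the tibia frame emulating a frontal-plane
#' view of the joint: cruciate and collateral ligaments as lines through
#' their tibial attachment points toward the femoral attachments, and
#' medial/lateral contact normals P1, P2 as near-vertical lines through the
#' compartment contact points. Axes: x medial(-)/lateral(+), y anterior, z
#' up; origin at the joint centre on the tibial plateau. Default dimensions
#' follow adult knee anatomy (contact points ~25 mm either side of the
#' centre); `jitter` adds seeded variation.
#'
#' Six generic lines would span the whole screw space; the constraint
#' manifold of a one-DOF joint instead has rank 5 because every line is
#' reciprocal to the joint's freedom. The generator therefore first draws a
#' physiological flexion axis (mediolateral through the joint centre, small
#' pitch) and then tilts each nominal anatomical direction minimally into
#' the reciprocal plane of that axis, so the six lines have rank 5 exactly
#' and their one-dimensional reciprocal system is the constructed axis.
#' Contact-normal directions point downward (the load the femur transmits),
#' so compressive contact intensities come out positive in the equilibrium
#' decomposition.
#'
#' @param seed Integer seed.
#' @param plateau_halfwidth Contact-point offset from the joint centre (m).
#' @param axis_pitch_sd SD of the flexion-axis pitch (m/rad).
#' @param jitter SD of attachment-point and axis jitter (m; also scales the
#'   axis direction jitter in rad). `jitter = 0` gives the symmetric
#'   default geometry with P1 and P2 mirror images about the sagittal
#'   plane.
#' @param max_tries Regeneration attempts if the lines come out rank
#'   deficient (< 5).
#' @return A `constraint_set` of rank 5; its `source` metadata records the
#'   seed and the generating axis.
#' @export
gen_constraint_geometry <- function(seed = 1, plateau_halfwidth = 0.025,
                                    axis_pitch_sd = 0.003, jitter = 0.002,
                                    max_tries = 20) {
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    jit <- function(v) if (jitter > 0) v + stats::rnorm(3, 0, jitter) else v
    axis_dir <- unit3(c(1, 0, 0) + if (jitter > 0) stats::rnorm(3, 0, 10 * jitter) else 0)
    axis_pitch <- if (jitter > 0) stats::rnorm(1, 0, axis_pitch_sd) else 0
    iak <- screw_from_axis(jit(c(0, 0, 0)), axis_dir, axis_pitch)
    # reciprocal plane at point p: directions d with d . (m_iak + d_iak x p) = 0
    recip_dir <- function(p, d0) {
      w <- iak$m + cross3(iak$d, p)
      if (norm3(w) < 1e-12) return(unit3(d0))   # p lies on a zero-pitch axis
      d <- d0 - sum(d0 * w) / sum(w * w) * w
      if (norm3(d) < 1e-9) d <- cross3(w, orthonormal_to(w))
      unit3(d)
    }
    # attachment point and nominal direction (tibial insertion -> femoral origin)
    nominal <- list(
      ACL = list(p = c(0.000, 0.015, 0.000), d = c(0.005, -0.030, 0.030)),
      PCL = list(p = c(0.000, -0.020, -0.005), d = c(-0.005, 0.030, 0.030)),
      MCL = list(p = c(-0.040, 0.000, -0.060), d = c(-0.005, 0.005, 0.080)),
      LCL = list(p = c(0.045, 0.000, -0.050), d = c(0.005, -0.005, 0.070)),
      P1 = list(p = c(-plateau_halfwidth, 0, 0), d = c(0, 0, -1)),
      P2 = list(p = c(+plateau_halfwidth, 0, 0), d = c(0, 0, -1))
    )
    lines <- lapply(nominal, function(l) {
      p <- jit(l$p)
      screw_from_axis(p, recip_dir(p, l$d))
    })
    cs <- constraint_set(lines, source = list(kind = "synthetic", seed = seed,
                                              try = try, axis = iak))
    if (attr(cs, "rank") == 5) return(cs)
  }
  rlang::abort(sprintf("could not generate a rank-5 constraint geometry in %d tries", max_tries),
               class = "screwgait_error_rank")
}

#' Generate a full synthetic stance trial with known ground truth
#'
#' Forward-constructs every quantity the pipeline estimates, so the truth is
#' exact by construction rather than simulated dynamics: the constraint
#' geometry fixes a unique reciprocal axis (the IAK); the thigh cluster
#' rotates about that axis with a smooth flexion profile while the shank
#' cluster stays stationary (the foot is planted in stance); and the GRF
#' wrench of every stance frame is a known nonnegative combination of the
#' constraint lines, `W = -sum(g_i * S_i)`. Because six lines of rank 5
#' carry a one-dimensional static indeterminacy, the stored per-frame truth
#' is the minimum-norm representative of the applied combination (the
#' decomposition convention); the raw nonnegative loads are kept alongside
#' as `truth$applied`. Contact loading follows the classic double-hump
#' vertical profile with a medial-dominant split; swing padding frames
#' before and after stance carry zero GRF and zero intensities.
#'
#' @param seed Integer seed.
#' @param stance_duration Stance time (s), 0.4-0.8.
#' @param rate Sampling rate (Hz).
#' @param mass Body mass (kg).
#' @param peak_vgrf Peak vertical GRF in body weights, 0.8-1.5.
#' @param medial_share Medial fraction of the contact load (the medial
#'   compartment typically carries 60-70% of the total).
#' @param flexion_range Thigh rotation over the trial (rad).
#' @param noise_sd Marker noise SD (m).
#' @param pad Swing padding on each side (s).
#' @return A list of class `synthetic_trial`: `markers` (both clusters,
#'   tidy), `grf` (force-plate tibble), `geometry` (`constraint_set`),
#'   `truth` (`iak` screw, `iak_track`, `intensities` per-frame tibble),
#'   `rate`, `seed`, `params`.
#' @export
gen_stance_trial <- function(seed = 1, stance_duration = 0.6, rate = 100,
                             mass = 70, peak_vgrf = 1.2, medial_share = 0.65,
                             flexion_range = 15 * pi / 180, noise_sd = 0,
                             pad = 0.1) {
  if (stance_duration < 0.4 || stance_duration > 0.8) {
    abort_input("stance_duration must lie in 0.4-0.8 s")
  }
  if (peak_vgrf < 0.8 || peak_vgrf > 1.5) {
    abort_input("peak_vgrf must lie in 0.8-1.5 body weights")
  }
  geometry <- gen_constraint_geometry(seed = seed)
  rec <- reciprocal_system(geometry)
  stopifnot(length(rec) == 1)
  iak <- rec[[1]]
  iak_pitch <- screw_pitch(iak)

  duration <- stance_duration + 2 * pad
  n <- round(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  theta <- flexion_range * (1 - cos(pi * t / duration)) / 2
  omega <- flexion_range * pi / (2 * duration) * sin(pi * t / duration)
  stance <- t >= pad & t <= pad + stance_duration

  # marker clusters: thigh above the knee, shank below; tibia frame = lab frame
  thigh0 <- marker_cluster(center = c(0, 0.02, 0.25), half_edge = 0.12, prefix = "T")
  shank0 <- marker_cluster(center = c(0, 0.02, -0.25), half_edge = 0.12, prefix = "S")
  set.seed(seed + 1L)
  noise <- if (noise_sd > 0) stats::rnorm(n * 16 * 3, 0, noise_sd) else NULL
  k <- 0
  markers <- purrr::map_dfr(seq_len(n), function(i) {
    th <- screw_displace(as.matrix(thigh0[, c("x", "y", "z")]), iak, theta[i], iak_pitch)
    sh <- as.matrix(shank0[, c("x", "y", "z")])
    pts <- rbind(th, sh)
    if (!is.null(noise)) {
      idx <- ((i - 1) * 48 + 1):(i * 48)
      pts <- pts + matrix(noise[idx], 16, 3)
    }
    tibble::tibble(frame = i, time = t[i],
                   marker = c(thigh0$marker, shank0$marker),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })

  # per-frame constraint intensities: double-hump contacts, small ligament tone
  tau <- rep(0, n)
  tau[stance] <- (t[stance] - pad) / stance_duration
  hump <- function(x) sin(pi * x) * (1 - 0.35 * sin(2 * pi * x)^2 * (x > 0.25 & x < 0.75))
  total <- ifelse(stance, peak_vgrf * mass * 9.81 * pmax(hump(tau), 0), 0)
  set.seed(seed + 2L)
  lig_tone <- stats::runif(4, 10, 40)          # N, constant ligament loads in stance
  g0 <- tibble::tibble(
    time = t,
    ACL = ifelse(stance, lig_tone[1], 0), PCL = ifelse(stance, lig_tone[2], 0),
    MCL = ifelse(stance, lig_tone[3], 0), LCL = ifelse(stance, lig_tone[4], 0),
    P1 = medial_share * total, P2 = (1 - medial_share) * total)

  Smat <- do.call(cbind, lapply(geometry, screw_6vec))
  # Six lines of rank 5 leave a one-dimensional gauge: the same wrench is
  # produced by any g + c * nu with Smat nu = 0. The stored truth is the
  # minimum-norm representative (the decomposition convention), obtained by
  # projecting the applied nonnegative combination off the gauge direction.
  nu <- nullspace_basis(Smat)
  g0m <- as.matrix(g0[, names(geometry)])
  gm <- g0m - (g0m %*% nu) %*% t(nu)
  g <- dplyr::bind_cols(tibble::tibble(time = t),
                        tibble::as_tibble(as.data.frame(gm)))
  grf <- purrr::map_dfr(seq_len(n), function(i) {
    gi <- as.numeric(unlist(g[i, names(geometry)]))
    W <- -drop(Smat %*% gi)
    F <- W[1:3]; M0 <- W[4:6]
    if (norm3(F) < 1e-9) {
      return(tibble::tibble(time = t[i], Fx = 0, Fy = 0, Fz = 0,
                            COPx = 0, COPy = 0, COPz = 0, Tz = 0, stance = FALSE))
    }
    copx <- -M0[2] / F[3]; copy <- M0[1] / F[3]
    Tz <- M0[3] - (copx * F[2] - copy * F[1])
    tibble::tibble(time = t[i], Fx = F[1], Fy = F[2], Fz = F[3],
                   COPx = copx, COPy = copy, COPz = 0, Tz = Tz,
                   stance = TRUE)
  })

  # keep the trial consistent with the 20 N stance-detection convention:
  # frames whose vertical force falls below the detection threshold are
  # zeroed, so rereading the written force-plate file reproduces the same
  # stance mask and the same stored truth
  faint <- grf$stance & grf$Fz < 20
  if (any(faint)) {
    grf[faint, c("Fx", "Fy", "Fz", "COPx", "COPy", "COPz", "Tz")] <- 0
    grf$stance[faint] <- FALSE
    g[faint, names(geometry)] <- 0
    g0[faint, names(geometry)] <- 0
    stance <- stance & !faint
  }

  p <- axis_point(iak)
  iak_track <- tibble::tibble(
    frame = seq_len(n), time = t,
    dx = iak$d[1], dy = iak$d[2], dz = iak$d[3],
    px = p[1], py = p[2], pz = p[3],
    pitch = iak_pitch, amplitude = omega)

  structure(list(
    markers = markers, grf = grf, geometry = geometry,
    truth = list(iak = iak, iak_track = iak_track,
                 intensities = g, applied = g0, stance = stance),
    rate = rate, seed = seed,
    params = list(stance_duration = stance_duration, rate = rate, mass = mass,
                  peak_vgrf = peak_vgrf, medial_share = medial_share,
                  flexion_range = flexion_range, noise_sd = noise_sd, pad = pad)
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial: seed %d, %d frames at %g Hz, peak vertical GRF %.0f N>\n",
              x$seed, length(unique(x$markers$frame)), x$rate, max(x$grf$Fz)))
  invisible(x)
}
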
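#' Anatomical constraint set of the knee
#'
#' The one-DOF knee model is constrained by six zero-pitch lines: the
#' anterior and posterior cruciate ligaments (ACL, PCL), the medial and
#' lateral collateral ligaments (MCL, LCL), and the contact normals of the
#' medial (P1) and lateral (P2) tibiofemoral compartments. When these lines
#' are the constraint manifold of a single instantaneous knee axis they span
#' a screw space of rank at most 5, and each is reciprocal to that axis:
#' reactions along them can neutralize any wrench reciprocal to the IAK
#' while doing no work on motion about it.
#'
#' @param ... Named zero-pitch screws; the conventional names are `ACL`,
#'   `PCL`, `MCL`, `LCL`, `P1`, `P2` but any 1-6 named lines are accepted.
#' @param source Optional metadata describing where the geometry came from.
#' @return An object of class `constraint_set`: a named list of screws with
#'   attributes `source` and `rank`.
#' @export
constraint_set <- function(..., source = NULL) {
  lines <- list(...)
  if (length(lines) == 1 && is.list(lines[[1]]) && !is_screw(lines[[1]])) {
    lines <- lines[[1]]
  }
  if (!length(lines) || is.null(names(lines)) || any(names(lines) == "")) {
    abort_input("constraint_set() needs named screws")
  }
  for (nm in names(lines)) {
    s <- lines[[nm]]
    if (!is_screw(s)) abort_input(sprintf("constraint '%s' is not a screw", nm))
    if (s$infinite || abs(screw_pitch(s)) > 1e-9) {
      abort_input(sprintf("constraint '%s' must be a zero-pitch line", nm))
    }
  }
  M <- do.call(rbind, lapply(lines, screw_6vec))
  structure(lines, class = "constraint_set", source = source,
            rank = mat_rank(M))
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set: %s (rank %d)>\n",
              paste(names(x), collapse = ", "), attr(x, "rank")))
  invisible(x)
}

#' Tidy a constraint set
#' @param x A `constraint_set`.
#' @param ... Unused.
#' @return A tibble with one row per constraint line.
#' @export
tidy.constraint_set <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    dplyr::bind_cols(tibble::tibble(constraint = nm), tidy.screw(x[[nm]]))
  })
}

#' Map a constraint set through a rigid pose
#'
#' Constraint geometry is typically given in the tibia (shank) frame; this
#' maps every line through the shank pose into the lab frame.
#'
#' @param constraints A `constraint_set`.
#' @param rotation,translation The pose.
#' @return The transformed `constraint_set`.
#' @export
transform_constraints <- function(constraints, rotation, translation = c(0, 0, 0)) {
  out <- lapply(constraints, transform_screw, rotation = rotation,
                translation = translation)
  constraint_set(out, source = attr(constraints, "source"))
}

#' Basis of the reciprocal screw system
#'
#' Computes, by a nullspace operation, a basis of the space of screws
#' reciprocal to every input screw. In raw 6-coordinates the virtual
#' coefficient is the bilinear pairing through the interchange matrix, so
#' the reciprocal system is the nullspace of the input 6-vectors paired
#' through it; its dimension is `6 - rank(inputs)`. A single generic screw
#' has a fifth-order reciprocal system (5 DOFs of constraint lines); five
#' independent constraint lines leave a one-dimensional system, the unique
#' freedom they permit.
#'
#' @param screws A list of screws (or a `constraint_set`), 1 to 6 of them.
#' @param tol Positive tolerance passed to the relative rank cutoff
#'   (singular values below `tol` times the largest are treated as zero).
#' @return A list of unit screws forming the reciprocal basis (possibly
#'   empty), with attribute `rank` of the input set.
#' @export
reciprocal_system <- function(screws, tol = 1e-10) {
  if (tol <= 0) abort_input("tol must be positive")
  if (is_screw(screws)) screws <- list(screws)
  screws <- unclass(screws)
  if (!length(screws) || length(screws) > 6) {
    abort_input("reciprocal_system() takes between 1 and 6 screws")
  }
  S <- do.call(rbind, lapply(screws, function(s) screw_6vec(as_screw(s))))
  M <- S %*% .delta6
  N <- nullspace_basis(M, rtol = tol)
  basis <- lapply(seq_len(ncol(N)), function(j) as_screw(N[, j]))
  attr(basis, "rank") <- 6L - ncol(N)
  basis
}

#' Reduce a force-plate record to a ground-reaction wrench
#'
#' Builds the wrench whose line of action passes through the centre of
#' pressure with the measured force, folding the free (vertical) moment into
#' the moment part, so the pitch is generally nonzero.
#'
#' @param force Force 3-vector (N).
#' @param cop Centre of pressure (m).
#' @param free_moment Free moment 3-vector (N m), typically `(0, 0, Tz)`.
#' @return A `wrench`; a zero force with zero moment returns a null wrench
#'   (`intensity = 0`, attribute `null = TRUE`).
#' @export
grf_wrench <- function(force, cop = c(0, 0, 0), free_moment = c(0, 0, 0)) {
  force <- as.numeric(force); cop <- as.numeric(cop)
  free_moment <- as.numeric(free_moment)
  v <- c(force, cross3(cop, force) + free_moment)
  sp <- split_6vec(v)
  if (sp$null) {
    out <- wrench(screw_from_axis(cop, c(0, 0, 1)), 0)
    attr(out, "null") <- TRUE
    return(out)
  }
  out <- wrench(sp$screw, sp$magnitude)
  attr(out, "null") <- FALSE
  out
}

#' Replace a wrench by one of equal effect on a one-DOF joint
#'
#' On a body only free to twist about the IAK, any applied wrench can be
#' replaced by a wrench of appropriate intensity on any other screw with
#' equal effect: the intensity that makes the pair do zero net virtual work
#' on every twist about the IAK,
#' `eta'' = -phi'' * vc(phi, iak) / vc(eta, iak)`.
#' This is how a ground-reaction wrench is traded for a muscle-line wrench.
#'
#' @param phi The applied `wrench` (e.g. the GRF).
#' @param eta_screw The replacement screw (e.g. a muscle line).
#' @param iak The freedom screw of the joint.
#' @param tol Leverage tolerance: if `|vc(eta, iak)|` falls below it the
#'   replacement line cannot act on this freedom.
#' @return The replacement intensity (scalar, N).
#' @export
replace_wrench <- function(phi, eta_screw, iak, tol = 1e-9) {
  stopifnot(inherits(phi, "wrench"), is_screw(eta_screw), is_screw(iak))
  vc_eta <- virtual_coefficient(eta_screw, iak)
  if (abs(vc_eta) <= tol) {
    rlang::abort(
      "no leverage: the replacement screw is reciprocal to the IAK and cannot act on this freedom",
      class = "screwgait_error_no_leverage")
  }
  -phi$intensity * virtual_coefficient(phi$screw, iak) / vc_eta
}

#' Decompose a wrench into constraint-line intensities
#'
#' Solves the one-DOF equilibrium `sum_i x_i S_i + W = 0` for the reaction
#' intensities `x` on the constraint lines, by minimum-norm least squares
#' (the six anatomical lines have rank at most 5). `medial_force` and
#' `lateral_force` are the intensities on the contact normals `P1` and `P2`.
#' If an IAK is supplied, the wrench is first checked to do no virtual work
#' on it: a wrench with a working component would move the joint and
#' equilibrium is impossible.
#'
#' @param w A `wrench` in the same frame as the constraints.
#' @param constraints A `constraint_set`.
#' @param iak Optional freedom `screw` for the consistency check.
#' @param tol Relative tolerance for the consistency check and rank cutoff.
#' @return An object of class `equilibrium_solution`: list with `intensities`
#'   (named numeric), `residual` (6-coordinate norm), `rank`,
#'   `medial_force`, `lateral_force`, and `tension_flags` (constraints with
#'   negative intensity, physiologically inconsistent for contacts).
#' @export
decompose_wrench <- function(w, constraints, iak = NULL, tol = 1e-8) {
  stopifnot(inherits(w, "wrench"), inherits(constraints, "constraint_set"))
  W <- wrench_6vec(w)
  A <- do.call(cbind, lapply(constraints, screw_6vec))
  if (!is.null(iak)) {
    stopifnot(is_screw(iak))
    vw <- sum(screw_6vec(iak) * (.delta6 %*% W))
    if (abs(vw) > tol * max(1, norm3(W[1:3]) + norm3(W[4:6]))) {
      rlang::abort(
        "inconsistent wrench: it does virtual work on the IAK, so it would move the joint and cannot be carried by the constraints",
        class = "screwgait_error_inconsistent")
    }
  }
  x <- -pinv_solve(A, W, rtol = 1e-10)
  names(x) <- names(constraints)
  resid <- sqrt(sum((A %*% x + W)^2))
  structure(list(
    intensities = x,
    residual = resid,
    rank = mat_rank(A),
    medial_force = unname(x["P1"]),
    lateral_force = unname(x["P2"]),
    tension_flags = names(x)[x < 0]
  ), class = "equilibrium_solution")
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf("<equilibrium_solution: medial %.4g N, lateral %.4g N, residual %.3g, rank %d>\n",
              x$medial_force, x$lateral_force, x$residual, x$rank))
  invisible(x)
}

#' @rdname decompose_wrench
#' @param x An `equilibrium_solution`.
#' @param ... Unused.
#' @export
tidy.equilibrium_solution <- function(x, ...) {
  tibble::tibble(constraint = names(x$intensities),
                 intensity = unname(x$intensities),
                 tension = names(x$intensities) %in% x$tension_flags)
}

#' @rdname decompose_wrench
#' @export
glance.equilibrium_solution <- function(x, ...) {
  tibble::tibble(medial_force = x$medial_force, lateral_force = x$lateral_force,
                 residual = x$residual, rank = x$rank,
                 n_tension = length(x$tension_flags))
}

#' Decompose a ground-reaction series frame by frame
#'
#' @param grf Force-plate tibble with columns `time`, `Fx`, `Fy`, `Fz`,
#'   `COPx`, `COPy`, `COPz`, `Tz` (SI units) and optionally `stance`.
#' @param constraints A `constraint_set` in the lab frame (or a function of
#'   frame index returning one, for a moving tibia).
#' @param iak_track Optional `twist_track` giving the per-frame IAK for the
#'   consistency check.
#' @param tol Passed to [decompose_wrench()].
#' @return A tibble of class `force_curves`: per-frame `time`, one column
#'   per constraint intensity (N), `medial_N`, `lateral_N`, `residual`,
#'   `stance`.
#' @export
decompose_trial <- function(grf, constraints, iak_track = NULL, tol = 1e-8) {
  stance <- if ("stance" %in% names(grf)) grf$stance else rep(TRUE, nrow(grf))
  rows <- purrr::map_dfr(seq_len(nrow(grf)), function(i) {
    cs <- if (is.function(constraints)) constraints(i) else constraints
    base <- tibble::tibble(time = grf$time[i], stance = stance[i])
    zero <- stats::setNames(as.list(rep(0, length(cs))), names(cs))
    if (!stance[i]) {
      return(dplyr::bind_cols(base, tibble::as_tibble(zero),
                              tibble::tibble(medial_N = 0, lateral_N = 0, residual = 0)))
    }
    w <- grf_wrench(c(grf$Fx[i], grf$Fy[i], grf$Fz[i]),
                    c(grf$COPx[i], grf$COPy[i], grf$COPz[i]),
                    c(0, 0, grf$Tz[i]))
    iak <- NULL
    if (!is.null(iak_track) && nrow(iak_track)) {
      idx <- which.min(abs(iak_track$time - grf$time[i]))
      iak <- iak_track$screw[[idx]]
    }
    sol <- decompose_wrench(w, cs, iak = iak, tol = tol)
    dplyr::bind_cols(base, tibble::as_tibble(as.list(sol$intensities)),
                     tibble::tibble(medial_N = sol$medial_force,
                                    lateral_N = sol$lateral_force,
                                    residual = sol$residual))
  })
  class(rows) <- c("force_curves", class(rows))
  rows
}

#' Plot medial/lateral contact-force curves
#'
#' @param object A [decompose_trial()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_curves <- function(object, ...) {
  d <- object |>
    dplyr::select("time", "medial_N", "lateral_N") |>
    tidyr::pivot_longer(-"time", names_to = "compartment", values_to = "force_N")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$force_N,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "contact force (N)",
                  title = "Tibiofemoral contact forces")
}

#' Special-configuration diagnostics of a one-DOF screw system
#'
#' At a special configuration the actuators lose control of the end-effector
#' freedom: the ratio of summed actuator twist amplitudes to the end-effector
#' twist amplitude collapses to 0 while the ratio of summed actuator wrench
#' intensities to the end-effector wrench intensity diverges to infinity.
#'
#' @param actuator_twists List of twists (or numeric amplitudes).
#' @param end_twist A twist (or numeric amplitude).
#' @param actuator_wrenches List of wrenches (or numeric intensities).
#' @param end_wrench A wrench (or numeric intensity).
#' @param ratio1_tol Threshold below which ratio1 counts as zero.
#' @param ratio2_tol Threshold above which ratio2 counts as divergent.
#' @return A one-row tibble `ratio1`, `ratio2`, `is_special`. Zero
#'   denominators give `Inf`, not an error.
#' @export
special_config_ratios <- function(actuator_twists, end_twist,
                                  actuator_wrenches, end_wrench,
                                  ratio1_tol = 1e-9, ratio2_tol = 1e9) {
  amp <- function(x) if (inherits(x, "twist")) x$amplitude else as.numeric(x)
  int <- function(x) if (inherits(x, "wrench")) x$intensity else as.numeric(x)
  sa <- sum(abs(vapply(actuator_twists, amp, 0)))
  ea <- abs(amp(end_twist))
  si <- sum(abs(vapply(actuator_wrenches, int, 0)))
  ei <- abs(int(end_wrench))
  ratio1 <- if (ea == 0) { if (sa == 0) 0 else Inf } else sa / ea
  ratio2 <- if (ei == 0) { if (si == 0) 0 else Inf } else si / ei
  tibble::tibble(ratio1 = ratio1, ratio2 = ratio2,
                 is_special = ratio1 <= ratio1_tol && ratio2 >= ratio2_tol)
}
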
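#' Screws in Pluecker coordinates
#'
#' A screw is a line in space together with a pitch, represented by the
#' Pluecker pair \eqn{(d, m)}: a direction 3-vector `d` and a moment 3-vector
#' `m`. Screws are the common carrier for instantaneous motions (twists) and
#' force systems (wrenches). A finite-pitch screw is stored with `|d| = 1`,
#' and its pitch is `h = d . m` (metres per radian); a pure translation or
#' couple is an infinite-pitch screw stored as `d = 0`, `|m| = 1`. A
#' zero-pitch screw (`d . m = 0`) is a pure line: a force along a line or a
#' rotation about an axis. Magnitude never lives in the screw itself; it goes
#' into [twist()] amplitudes and [wrench()] intensities.
#'
#' @param d Direction 3-vector (any magnitude; normalized on construction).
#' @param m Moment 3-vector. For a line through point `p` with direction `d`,
#'   `m = p x d`; adding pitch `h` contributes `h * d`.
#' @return An object of class `screw` with elements `d`, `m` and logical
#'   `infinite`.
#' @examples
#' s <- screw(c(0, 0, 2), c(0, 0, 0.01))   # vertical screw, pitch 5 mm/rad
#' screw_pitch(s)
#' axis_point(s)
#' @export
screw <- function(d, m) {
  d <- as.numeric(d); m <- as.numeric(m)
  if (length(d) != 3 || length(m) != 3 || anyNA(d) || anyNA(m)) {
    abort_input("a screw needs finite 3-vectors d and m")
  }
  nd <- norm3(d)
  if (nd > 1e-12) {
    structure(list(d = d / nd, m = m / nd, infinite = FALSE), class = "screw")
  } else {
    nm <- norm3(m)
    if (nm <= 1e-12) abort_input("screw with zero direction needs a nonzero moment")
    structure(list(d = c(0, 0, 0), m = m / nm, infinite = TRUE), class = "screw")
  }
}

#' @rdname screw
#' @param x Object to test or coerce.
#' @export
is_screw <- function(x) inherits(x, "screw")

#' @rdname screw
#' @export
as_screw <- function(x) {
  if (is_screw(x)) return(x)
  x <- as.numeric(x)
  if (length(x) != 6) abort_input("as_screw() expects a screw or a 6-vector c(d, m)")
  screw(x[1:3], x[4:6])
}

#' Construct a screw from an axis point, direction and pitch
#'
#' @param point 3-vector, a point on the axis (m).
#' @param direction 3-vector along the axis (for `pitch = Inf` this is the
#'   translation/couple direction and becomes the unit moment).
#' @param pitch Pitch in metres per radian; `0` gives a pure line, `Inf` a
#'   pure translation/couple.
#' @return A `screw`.
#' @examples
#' screw_from_axis(c(1, 0, 0), c(0, 0, 1))           # line through (1,0,0) along z
#' screw_from_axis(c(0, 0, 0), c(0, 0, 1), pitch = 0.008)
#' @export
screw_from_axis <- function(point, direction, pitch = 0) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  if (is.infinite(pitch)) {
    if (norm3(direction) <= 1e-12) abort_input("infinite-pitch screw needs a direction")
    return(screw(c(0, 0, 0), unit3(direction)))
  }
  if (norm3(direction) <= 1e-12) {
    abort_input("zero direction with finite pitch does not define a screw")
  }
  u <- unit3(direction)
  screw(u, cross3(point, u) + pitch * u)
}

#' Pitch, axis point and raw coordinates of a screw
#'
#' `screw_pitch()` returns `d . m` for a finite-pitch screw and `Inf` for a
#' pure translation/couple. `axis_point()` returns `d x m`, the point of the
#' axis nearest the origin (undefined for infinite pitch). `screw_6vec()`
#' returns the raw Pluecker 6-vector `c(d, m)`.
#'
#' @param s A `screw`.
#' @return A scalar, a 3-vector, or a 6-vector respectively.
#' @export
screw_pitch <- function(s) {
  stopifnot(is_screw(s))
  if (s$infinite) Inf else sum(s$d * s$m)
}

#' @rdname screw_pitch
#' @export
axis_point <- function(s) {
  stopifnot(is_screw(s))
  if (s$infinite) return(c(NA_real_, NA_real_, NA_real_))
  cross3(s$d, s$m)
}

#' @rdname screw_pitch
#' @export
screw_6vec <- function(s) {
  stopifnot(is_screw(s))
  c(s$d, s$m)
}

#' @export
print.screw <- function(x, ...) {
  if (x$infinite) {
    cat("<screw: infinite pitch, direction",
        sprintf("(%.4g, %.4g, %.4g)>\n", x$m[1], x$m[2], x$m[3]))
  } else {
    p <- axis_point(x)
    cat(sprintf("<screw: d = (%.4g, %.4g, %.4g), pitch = %.4g m/rad, axis point = (%.4g, %.4g, %.4g)>\n",
                x$d[1], x$d[2], x$d[3], screw_pitch(x), p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Relative geometry of two screw axes
#'
#' Computes the angle `theta` between the two axes (radians, in `[0, pi]`),
#' the common-perpendicular distance `a` (m), and the virtual coefficient
#' `vc`. The coordinate (mutual-moment) form of the virtual coefficient is
#' authoritative; the geometric form `(h + h') cos(theta) - a sin(theta)`
#' uses the signed perpendicular offset internally so the two agree. When one
#' operand has infinite pitch, `theta` is measured between its moment
#' direction and the other axis, `a` is reported `NA` and the relation is
#' flagged degenerate.
#'
#' @param p,q Screws.
#' @return A one-row tibble with columns `theta`, `a`, `vc`, `degenerate`.
#' @examples
#' z <- screw_from_axis(c(0, 0, 0), c(0, 0, 1))
#' x1 <- screw_from_axis(c(0, 1, 0), c(1, 0, 0))
#' screw_geometry(z, x1)   # theta = pi/2, a = 1
#' @export
screw_geometry <- function(p, q) {
  stopifnot(is_screw(p), is_screw(q))
  vc <- virtual_coefficient(p, q)
  if (p$infinite || q$infinite) {
    u <- if (p$infinite) p$m else p$d
    v <- if (q$infinite) q$m else q$d
    theta <- acos(clamp1(sum(u * v)))
    return(tibble::tibble(theta = theta, a = NA_real_, vc = vc, degenerate = TRUE))
  }
  ct <- clamp1(sum(p$d * q$d))
  theta <- acos(ct)
  n <- cross3(p$d, q$d)
  if (norm3(n) < 1e-12) {
    # parallel (or identical) axes: perpendicular distance between the lines
    dr <- axis_point(q) - axis_point(p)
    a <- norm3(dr - sum(dr * p$d) * p$d)
  } else {
    a <- abs(sum((axis_point(q) - axis_point(p)) * unit3(n)))
  }
  tibble::tibble(theta = theta, a = a, vc = vc, degenerate = FALSE)
}

#' Virtual coefficient and reciprocity of two screws
#'
#' The virtual coefficient of unit screws `p` and `q` is the mutual moment
#' `d_p . m_q + d_q . m_p`, geometrically `(h + h') cos(theta) - a
#' sin(theta)` with `a` the signed common-perpendicular offset. It measures
#' the work a unit wrench on one screw does through a unit twist about the
#' other; two screws are *reciprocal* when it vanishes, so a constraint force
#' along a reciprocal line cannot disturb motion about the screw. The full
#' mutual-moment convention is used (no factor 1/2); Ball's classical virtual
#' coefficient is half this value.
#'
#' @param p,q Screws.
#' @param geometric If `TRUE`, evaluate the geometric form from `theta`, the
#'   signed offset and the pitches (finite-pitch screws only) instead of the
#'   coordinate form; the two agree to roundoff and the coordinate form is
#'   the default.
#' @return A scalar (m).
#' @examples
#' z <- screw_from_axis(c(0, 0, 0), c(0, 0, 1))
#' x1 <- screw_from_axis(c(0, 1, 0), c(1, 0, 0))
#' virtual_coefficient(z, x1)   # -1: perpendicular lines 1 m apart
#' is_reciprocal(z, screw_from_axis(c(0, 0, 5), c(0, 0, 1)))  # coaxial: TRUE
#' @export
virtual_coefficient <- function(p, q, geometric = FALSE) {
  stopifnot(is_screw(p), is_screw(q))
  if (!geometric) {
    return(sum(p$d * q$m) + sum(q$d * p$m))
  }
  if (p$infinite || q$infinite) {
    abort_input("geometric form needs two finite-pitch screws")
  }
  ct <- clamp1(sum(p$d * q$d))
  theta <- acos(ct)
  n <- cross3(p$d, q$d)
  if (norm3(n) < 1e-12) {
    a_signed <- 0
  } else {
    a_signed <- sum((axis_point(q) - axis_point(p)) * unit3(n))
  }
  (screw_pitch(p) + screw_pitch(q)) * cos(theta) - a_signed * sin(theta)
}

#' @rdname virtual_coefficient
#' @param tol Absolute tolerance on the virtual coefficient (m); default
#'   `1e-9` in SI units.
#' @return `is_reciprocal()`: logical.
#' @export
is_reciprocal <- function(p, q, tol = 1e-9) {
  if (tol <= 0) abort_input("tol must be positive")
  abs(virtual_coefficient(p, q)) <= tol
}

#' Rigidly transform a screw
#'
#' Maps a screw through a proper rigid transformation `x -> R x + t`. Pitch
#' is invariant, and the virtual coefficient of any pair is invariant when
#' both members are transformed together.
#'
#' @param s A `screw`.
#' @param rotation 3x3 proper rotation matrix (`det = +1`).
#' @param translation Translation 3-vector (m).
#' @return The transformed `screw`.
#' @export
transform_screw <- function(s, rotation, translation = c(0, 0, 0)) {
  stopifnot(is_screw(s))
  if (!is_rotation(rotation)) {
    abort_input("rotation must be a proper rotation matrix (det = +1)")
  }
  translation <- as.numeric(translation)
  if (s$infinite) {
    return(screw(c(0, 0, 0), drop(rotation %*% s$m)))
  }
  d2 <- drop(rotation %*% s$d)
  m2 <- drop(rotation %*% s$m) + cross3(translation, d2)
  screw(d2, m2)
}

#' Twists and wrenches
#'
#' A twist is an instantaneous rigid-body motion: a screw plus an amplitude
#' (rad/s for rotational twists, m/s for infinite-pitch translations). A
#' wrench is a force system: a screw plus an intensity (N for finite pitch,
#' N m for a pure couple). Both expose a raw 6-vector `amplitude * (d, m)`
#' through [twist_6vec()] / [wrench_6vec()], in which composition is plain
#' addition.
#'
#' @param s A `screw`.
#' @param amplitude,intensity Finite scalar magnitude.
#' @return Objects of class `twist` / `wrench`.
#' @export
twist <- function(s, amplitude) {
  stopifnot(is_screw(s), is.finite(amplitude))
  structure(list(screw = s, amplitude = as.numeric(amplitude)), class = "twist")
}

#' @rdname twist
#' @export
wrench <- function(s, intensity) {
  stopifnot(is_screw(s), is.finite(intensity))
  structure(list(screw = s, intensity = as.numeric(intensity)), class = "wrench")
}

#' @rdname twist
#' @param x A twist or wrench.
#' @export
twist_6vec <- function(x) {
  stopifnot(inherits(x, "twist"))
  x$amplitude * screw_6vec(x$screw)
}

#' @rdname twist
#' @export
wrench_6vec <- function(x) {
  stopifnot(inherits(x, "wrench"))
  x$intensity * screw_6vec(x$screw)
}

# Split a raw 6-vector into (screw, magnitude); near-zero vectors become a
# flagged null result.
split_6vec <- function(v, eps = 1e-12) {
  nd <- norm3(v[1:3])
  if (nd > eps) {
    list(screw = screw(v[1:3], v[4:6]), magnitude = nd, null = FALSE)
  } else if (norm3(v[4:6]) > eps) {
    list(screw = screw(c(0, 0, 0), v[4:6]), magnitude = norm3(v[4:6]), null = FALSE)
  } else {
    list(screw = NULL, magnitude = 0, null = TRUE)
  }
}

#' @export
print.twist <- function(x, ...) {
  cat(sprintf("<twist: amplitude = %.6g>\n", x$amplitude)); print(x$screw)
  invisible(x)
}

#' @export
print.wrench <- function(x, ...) {
  cat(sprintf("<wrench: intensity = %.6g N>\n", x$intensity)); print(x$screw)
  invisible(x)
}

#' Tidy a screw (or list of screws) into a tibble
#'
#' @param x A `screw` or a list of screws.
#' @param ... Unused.
#' @return A tibble with direction, moment, pitch and axis-point columns.
#' @export
tidy.screw <- function(x, ...) {
  p <- axis_point(x)
  tibble::tibble(
    dx = x$d[1], dy = x$d[2], dz = x$d[3],
    mx = x$m[1], my = x$m[2], mz = x$m[3],
    pitch = screw_pitch(x), px = p[1], py = p[2], pz = p[3]
  )
}

#' Serialize screws to/from JSON records
#'
#' Screws serialize as records `{"d": [..], "m": [..]}` with lengths in
#' metres.
#' @param s A screw (`screw_to_json`) or JSON string / parsed list
#'   (`screw_from_json`).
#' @return A JSON string, or a `screw`.
#' @export
screw_to_json <- function(s) {
  stopifnot(is_screw(s))
  jsonlite::toJSON(list(d = s$d, m = s$m), digits = NA)
}

#' @rdname screw_to_json
#' @export
screw_from_json <- function(s) {
  x <- if (is.character(s)) jsonlite::fromJSON(s) else s
  screw(as.numeric(x$d), as.numeric(x$m))
}
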
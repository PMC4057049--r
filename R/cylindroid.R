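#' The cylindroid (Pluecker's conoid) spanned by two screws
#'
#' All screws linearly dependent on two given screws form a one-parameter
#' two-system whose axes sweep a cubic ruled surface, Ball's cylindroid. In
#' its canonical frame the nodal line (z-axis) lies along the common
#' perpendicular of the generators, every axis of the system is perpendicular
#' to and intersects the nodal line, and the two *principal screws* lie along
#' x and y through the origin with the extremal pitches \eqn{h_\alpha},
#' \eqn{h_\beta} of the system (the \eqn{\alpha} screw is the one along the
#' bisector of the generators). A screw at direction angle \eqn{\phi} from
#' the \eqn{\alpha} axis
#' has pitch \eqn{h_\alpha\cos^2\phi + h_\beta\sin^2\phi} and crosses the
#' nodal line at \eqn{z = (h_\beta - h_\alpha)\sin\phi\cos\phi}, so every
#' axis satisfies the conoid cubic \eqn{z(x^2 + y^2) = (h_\beta -
#' h_\alpha)xy}.
#'
#' `build_cylindroid()` derives the principal screws from first principles:
#' pitch over the span is the Rayleigh quotient of the mutual-moment matrix
#' against the direction Gram matrix of the generators, so the principal
#' screws are the eigenvectors of that 2x2 generalized eigenproblem.
#'
#' @param p1,p2 Generating screws (finite pitch, not coaxial or parallel).
#' @return An object of class `cylindroid` with elements `p1`, `p2`,
#'   `p_alpha`, `p_beta` (principal screws), `h_alpha`, `h_beta` (their
#'   pitches, m/rad), `b` (half the common-perpendicular distance, m),
#'   `sigma` (half the angle between the generators, rad), `frame` (list
#'   `rotation`, `origin`: canonical-to-lab pose), and `lambda` (2x2 matrix
#'   of principal-screw coordinates reproducing `p1`, `p2`).
#' @examples
#' b <- 0.05; sg <- pi / 6
#' p1 <- screw_from_axis(c(0, 0, b), c(cos(sg), sin(sg), 0))
#' p2 <- screw_from_axis(c(0, 0, -b), c(cos(sg), -sin(sg), 0))
#' cyl <- build_cylindroid(p1, p2)
#' c(cyl$h_alpha, -b * tan(sg))   # principal pitches for zero-pitch generators
#' @export
build_cylindroid <- function(p1, p2) {
  stopifnot(is_screw(p1), is_screw(p2))
  if (p1$infinite || p2$infinite) {
    abort_input("cylindroid generators must have finite pitch")
  }
  n <- cross3(p1$d, p2$d)
  if (norm3(n) < 1e-10) {
    rlang::abort(
      "degenerate cylindroid: generators are coaxial or parallel, so the two-system collapses to a pencil with no common perpendicular",
      class = "screwgait_error_degenerate_cylindroid"
    )
  }
  geom <- screw_geometry(p1, p2)
  sigma <- geom$theta / 2
  b <- geom$a / 2

  # pitch of c1*p1 + c2*p2 is (c' A c) / (c' B c)
  h1 <- screw_pitch(p1); h2 <- screw_pitch(p2)
  mm <- virtual_coefficient(p1, p2)
  A <- matrix(c(h1, mm / 2, mm / 2, h2), 2, 2)
  B <- matrix(c(1, sum(p1$d * p2$d), sum(p1$d * p2$d), 1), 2, 2)
  L <- chol(B)
  Es <- eigen((t(solve(L)) %*% A) %*% solve(L), symmetric = TRUE)
  V <- solve(L, Es$vectors)           # columns: generator coefficients
  pitches <- Es$values                # decreasing order

  S1 <- screw_6vec(p1); S2 <- screw_6vec(p2)
  cand <- lapply(1:2, function(i) screw(V[1, i] * S1[1:3] + V[2, i] * S2[1:3],
                                        V[1, i] * S1[4:6] + V[2, i] * S2[4:6]))
  # alpha = the principal screw along the bisector of the generator directions,
  # oriented with it so the canonical frame is reproducible
  bis <- unit3(p1$d + p2$d)
  i_alpha <- which.max(abs(vapply(cand, function(s) sum(s$d * bis), 0)))
  i_beta <- 3 - i_alpha
  flip <- function(s, ref) if (sum(s$d * ref) < 0) screw(-s$d, -s$m) else s
  p_alpha <- flip(cand[[i_alpha]], bis)
  p_beta <- flip(cand[[i_beta]], cross3(cross3(p_alpha$d, p1$d), p_alpha$d))
  h_alpha <- pitches[i_alpha]; h_beta <- pitches[i_beta]

  # canonical frame: principal axes intersect orthogonally at the origin
  ra <- axis_point(p_alpha); rb <- axis_point(p_beta)
  cp <- closest_points_lines(ra, p_alpha$d, rb, p_beta$d)
  origin <- (cp$p1 + cp$p2) / 2
  xhat <- p_alpha$d
  yhat <- p_beta$d - sum(p_beta$d * xhat) * xhat
  yhat <- unit3(yhat)
  zhat <- cross3(xhat, yhat)
  Rcl <- cbind(xhat, yhat, zhat)

  # principal-screw coordinates (lambda_alpha, lambda_beta) reproducing p1, p2
  Pmat <- cbind(screw_6vec(p_alpha), screw_6vec(p_beta))
  lam_gen <- qr.solve(Pmat, cbind(S1, S2))

  structure(list(
    p1 = p1, p2 = p2,
    p_alpha = p_alpha, p_beta = p_beta,
    h_alpha = h_alpha, h_beta = h_beta,
    b = b, sigma = sigma,
    frame = list(rotation = Rcl, origin = origin),
    lambda = lam_gen
  ), class = "cylindroid")
}

# Closest points between two lines given points and unit directions.
closest_points_lines <- function(r1, d1, r2, d2) {
  w <- r1 - r2
  a <- sum(d1 * d1); bq <- sum(d1 * d2); cq <- sum(d2 * d2)
  dd <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * cq - bq^2
  if (abs(den) < 1e-14) {
    s <- 0; t <- e / cq
  } else {
    s <- (bq * e - cq * dd) / den
    t <- (a * e - bq * dd) / den
  }
  list(p1 = r1 + s * d1, p2 = r2 + t * d2, dist = norm3((r1 + s * d1) - (r2 + t * d2)))
}

#' @export
print.cylindroid <- function(x, ...) {
  cat(sprintf(
    "<cylindroid: b = %.4g m, sigma = %.4g rad, principal pitches (%.4g, %.4g) m/rad>\n",
    x$b, x$sigma, x$h_alpha, x$h_beta))
  invisible(x)
}

#' Screw of the two-system at given principal coordinates
#'
#' Returns the normalization of `lambda_alpha * p_alpha + lambda_beta *
#' p_beta` in 6-coordinates; its axis is a generator of the conoid surface.
#'
#' @param cyl A [build_cylindroid()] result.
#' @param lambda_alpha,lambda_beta Coefficients on the principal screws; not
#'   both zero.
#' @return A `screw`.
#' @export
screw_at <- function(cyl, lambda_alpha, lambda_beta) {
  stopifnot(inherits(cyl, "cylindroid"))
  if (lambda_alpha == 0 && lambda_beta == 0) {
    abort_input("screw_at() needs at least one nonzero coefficient")
  }
  v <- lambda_alpha * screw_6vec(cyl$p_alpha) + lambda_beta * screw_6vec(cyl$p_beta)
  as_screw(v)
}

#' Express a screw in the canonical frame of a cylindroid
#'
#' @param cyl A `cylindroid`.
#' @param s A `screw` in lab coordinates.
#' @return The screw in the canonical (principal-axes) frame.
#' @export
to_canonical <- function(cyl, s) {
  stopifnot(inherits(cyl, "cylindroid"))
  Rt <- t(cyl$frame$rotation)
  transform_screw(s, Rt, -drop(Rt %*% cyl$frame$origin))
}

#' Compose two twists into the single replacing twist
#'
#' Two twists applied to one rigid body are equivalent to a single twist
#' about a screw of the cylindroid of their two screws, with amplitudes in
#' the proper ratio: in 6-coordinates the resultant is
#' `dv1 * p1 + dv2 * p2`, and the closure form
#' `dv1 p1 + dv2 p2 + dv_res (-p_res) = 0` holds with the equilibrating
#' twist being this resultant with negated amplitude. Exact cancellation
#' returns a flagged null twist.
#'
#' @param t1,t2 Twists.
#' @return A `twist`; a null resultant has `amplitude = 0` and attribute
#'   `null = TRUE`.
#' @examples
#' z0 <- screw_from_axis(c(0, 0, 0), c(0, 0, 1))
#' z1 <- screw_from_axis(c(1, 0, 0), c(0, 0, 1))
#' r <- compose_twists(twist(z0, 1), twist(z1, 2))
#' axis_point(r$screw)   # divides the separation inversely to the amplitudes
#' @export
compose_twists <- function(t1, t2) {
  stopifnot(inherits(t1, "twist"), inherits(t2, "twist"))
  v <- twist_6vec(t1) + twist_6vec(t2)
  sp <- split_6vec(v)
  if (sp$null) {
    out <- twist(t1$screw, 0)
    attr(out, "null") <- TRUE
    return(out)
  }
  out <- twist(sp$screw, sp$magnitude)
  attr(out, "null") <- FALSE
  out
}

#' Sample generators of the conoid surface over a transmission-ratio range
#'
#' Samples `n` screws of the two-system for transmission ratios
#' `lambda_alpha / lambda_beta` spanning `[ratio_min, ratio_max]`
#' (`lambda_beta` fixed at 1). The default range 0.3-2.5 is the
#' physiologically feasible band of thigh-versus-shank velocity ratios.
#'
#' @param cyl A `cylindroid`.
#' @param ratio_min,ratio_max Positive ratio endpoints, `ratio_min <
#'   ratio_max`.
#' @param n Number of samples (>= 2).
#' @param frame `"lab"` (default) or `"canonical"` coordinates for the
#'   output.
#' @return A tibble of class `conoid_samples` with columns `ratio`, axis
#'   point `x, y, z` (m), direction `dx, dy, dz`, and `pitch` (m/rad).
#' @export
conoid_samples <- function(cyl, ratio_min = 0.3, ratio_max = 2.5, n = 100,
                           frame = c("lab", "canonical")) {
  stopifnot(inherits(cyl, "cylindroid"))
  frame <- match.arg(frame)
  if (!(ratio_min > 0 && ratio_max > ratio_min)) {
    abort_input("need 0 < ratio_min < ratio_max")
  }
  if (n < 2) abort_input("need n >= 2 samples")
  ratios <- seq(ratio_min, ratio_max, length.out = n)
  rows <- purrr::map_dfr(ratios, function(r) {
    s <- screw_at(cyl, r, 1)
    if (frame == "canonical") s <- to_canonical(cyl, s)
    p <- axis_point(s)
    tibble::tibble(ratio = r, x = p[1], y = p[2], z = p[3],
                   dx = s$d[1], dy = s$d[2], dz = s$d[3],
                   pitch = screw_pitch(s))
  })
  class(rows) <- c("conoid_samples", class(rows))
  rows
}

#' Plot conoid samples
#'
#' Plan view of the sampled generator axes (canonical x-y plane) coloured by
#' pitch, with a companion pitch-versus-ratio panel left to the user via
#' `aes`.
#'
#' @param object A [conoid_samples()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conoid_samples <- function(object, ...) {
  seg <- dplyr::mutate(object,
    x0 = .data$x - 0.1 * .data$dx, x1 = .data$x + 0.1 * .data$dx,
    y0 = .data$y - 0.1 * .data$dy, y1 = .data$y + 0.1 * .data$dy)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$pitch)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "pitch (m/rad)",
                  title = "Conoid generators (plan view)")
}
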
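#' Least-squares rigid fit between two marker clouds
#'
#' Orthogonal Procrustes (Kabsch) fit of the pose `(R, t)` minimizing the sum
#' of squared residuals of `obs_i ~ R ref_i + t` over at least three
#' non-collinear markers.
#'
#' @param reference,observed Numeric matrices (n x 3) of matching marker
#'   positions (m).
#' @return A list with `rotation` (3x3, det +1), `translation` (3-vector) and
#'   `rms` residual (m).
#' @export
rigid_fit <- function(reference, observed) {
  reference <- as.matrix(reference); observed <- as.matrix(observed)
  if (nrow(reference) < 3 || !identical(dim(reference), dim(observed))) {
    abort_input("rigid_fit() needs matching n x 3 matrices with n >= 3")
  }
  cr <- colMeans(reference); co <- colMeans(observed)
  A <- sweep(reference, 2, cr); Bm <- sweep(observed, 2, co)
  if (mat_rank(A, rtol = 1e-9) < 2) {
    rlang::abort("degenerate marker cluster: markers are collinear",
                 class = "screwgait_error_rank")
  }
  H <- crossprod(A, Bm)
  sv <- svd(H)
  Dfix <- diag(c(1, 1, det(sv$v %*% t(sv$u))))
  R <- unname(sv$v %*% Dfix %*% t(sv$u))
  t <- unname(co - drop(R %*% cr))
  resid <- Bm - A %*% t(R)
  list(rotation = R, translation = t, rms = sqrt(mean(rowSums(resid^2))))
}

#' Fit per-frame segment poses from marker trajectories
#'
#' Takes tidy marker data (columns `frame`, `marker`, `x`, `y`, `z`) for one
#' rigid cluster and fits the pose of every frame relative to a reference
#' frame.
#'
#' @param markers Tibble with columns `frame`, `marker`, `x`, `y`, `z`
#'   (positions in m). A `time` column is carried through if present.
#' @param labels Marker labels to use (default: all).
#' @param reference_frame Frame number providing the reference cluster.
#' @param rate Sampling rate (Hz), stored on the result.
#' @return A tibble of class `pose_sequence` with columns `frame`, `time`,
#'   list-columns `rotation`, `translation`, and `rms`.
#' @export
fit_poses <- function(markers, labels = NULL, reference_frame = NULL, rate = NULL) {
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(markers))) {
    abort_input("markers must have columns frame, marker, x, y, z")
  }
  if (!is.null(labels)) markers <- dplyr::filter(markers, .data$marker %in% labels)
  frames <- sort(unique(markers$frame))
  if (is.null(reference_frame)) reference_frame <- frames[1]
  cloud <- function(f) {
    d <- dplyr::arrange(dplyr::filter(markers, .data$frame == f), .data$marker)
    as.matrix(d[, c("x", "y", "z")])
  }
  ref <- cloud(reference_frame)
  have_time <- "time" %in% names(markers)
  out <- purrr::map_dfr(frames, function(f) {
    fit <- rigid_fit(ref, cloud(f))
    tibble::tibble(
      frame = f,
      time = if (have_time) markers$time[match(f, markers$frame)] else
        if (!is.null(rate)) (f - frames[1]) / rate else NA_real_,
      rotation = list(fit$rotation), translation = list(fit$translation),
      rms = fit$rms)
  })
  attr(out, "rate") <- rate
  class(out) <- c("pose_sequence", class(out))
  out
}

#' Instantaneous screw axes from a pose sequence
#'
#' Computes the per-frame finite-displacement screw of the motion: for frame
#' `i` the relative displacement between frames `i - span` and `i + span`
#' (one-sided at the ends) is reduced to its screw via the matrix logarithm,
#' giving axis direction, axis point, pitch (m/rad) and angular amplitude
#' (rad/s). Frames whose rotation increment falls below `min_angle_deg` are
#' translation-dominated: they are reported with an infinite-pitch direction
#' and flagged, and should be excluded from cylindroid construction.
#'
#' For noiseless sampling of a constant screw motion the finite-displacement
#' screw is exact at any span. With marker noise, accuracy of the axis
#' direction improves roughly as the rotation increment grows, so a span
#' giving increments of 15-20 degrees is recommended for noisy data.
#'
#' @param poses A [fit_poses()] result (or tibble with `frame`, `time`,
#'   `rotation`, `translation`).
#' @param rate Sampling rate in Hz; taken from `poses` if absent.
#' @param span Half-width (in frames) of the symmetric displacement used per
#'   frame.
#' @param min_angle_deg Rotation increment (degrees) below which a frame is
#'   flagged translation-dominated.
#' @return A tibble of class `twist_track`: columns `frame`, `time`, `dx dy
#'   dz` (axis direction), `px py pz` (axis point, m), `pitch` (m/rad),
#'   `amplitude` (rad/s), `translation_dominated`, and a list-column `screw`.
#' @export
twist_from_poses <- function(poses, rate = NULL, span = 1, min_angle_deg = 0.1) {
  if (is.null(rate)) rate <- attr(poses, "rate")
  if (is.null(rate)) {
    dtt <- diff(poses$time)
    if (all(is.finite(dtt)) && length(dtt)) rate <- 1 / stats::median(dtt)
  }
  if (is.null(rate) || !is.finite(rate)) abort_input("sampling rate unknown")
  n <- nrow(poses)
  if (n < 3) abort_input("need at least 3 frames")
  span <- max(1L, as.integer(span))
  out <- purrr::map_dfr(seq_len(n), function(i) {
    j0 <- max(1L, i - span); j1 <- min(n, i + span)
    if (j1 == j0) j1 <- min(n, j0 + 1L)
    Ra <- poses$rotation[[j0]]; ta <- poses$translation[[j0]]
    Rb <- poses$rotation[[j1]]; tb <- poses$translation[[j1]]
    dt <- (j1 - j0) / rate
    Rrel <- Rb %*% t(Ra)
    prel <- tb - drop(Rrel %*% ta)
    w <- so3_log(Rrel)
    theta <- norm3(w)
    if (theta < min_angle_deg * pi / 180) {
      dir <- if (norm3(prel) > 1e-12) unit3(prel) else c(NA_real_, NA_real_, NA_real_)
      return(tibble::tibble(
        frame = poses$frame[i], time = poses$time[i],
        dx = dir[1], dy = dir[2], dz = dir[3],
        px = NA_real_, py = NA_real_, pz = NA_real_,
        pitch = Inf, amplitude = norm3(prel) / dt,
        translation_dominated = TRUE,
        screw = list(if (norm3(prel) > 1e-12) screw(c(0, 0, 0), unit3(prel)) else NULL)))
    }
    u <- w / theta
    h <- sum(u * prel) / theta
    # axis point: (I - Rrel) r0 = component of prel perpendicular to the axis
    p_perp <- prel - sum(u * prel) * u
    r0 <- pinv_solve(diag(3) - Rrel, p_perp)
    r0 <- r0 - sum(r0 * u) * u
    s <- screw_from_axis(r0, u, h)
    p <- axis_point(s)
    tibble::tibble(
      frame = poses$frame[i], time = poses$time[i],
      dx = s$d[1], dy = s$d[2], dz = s$d[3],
      px = p[1], py = p[2], pz = p[3],
      pitch = screw_pitch(s), amplitude = theta / dt,
      translation_dominated = FALSE, screw = list(s))
  })
  attr(out, "rate") <- rate
  class(out) <- c("twist_track", class(out))
  out
}

# Raw twist 6-vector (omega; v_origin) of one track row; zero if invalid.
track_6vec <- function(track, i) {
  s <- track$screw[[i]]
  if (is.null(s)) return(rep(0, 6))
  track$amplitude[i] * screw_6vec(s)
}

#' Relative twist of the thigh with respect to the shank (the IAK)
#'
#' Subtracts the shank twist from the thigh twist frame-by-frame in raw
#' 6-coordinates (both expressed in the lab frame), yielding the
#' instantaneous axes of the knee. The IAK lies on the cylindroid of the two
#' segment screws. Frames where the two twists cancel are flagged null.
#'
#' @param thigh,shank [twist_from_poses()] tracks on common frames.
#' @return A `twist_track` tibble with an extra logical column `null`.
#' @export
relative_twist <- function(thigh, shank) {
  if (!identical(thigh$frame, shank$frame)) {
    abort_input("thigh and shank tracks must cover identical frames")
  }
  rate <- attr(thigh, "rate")
  out <- purrr::map_dfr(seq_len(nrow(thigh)), function(i) {
    v <- track_6vec(thigh, i) - track_6vec(shank, i)
    sp <- split_6vec(v, eps = 1e-12)
    base <- tibble::tibble(frame = thigh$frame[i], time = thigh$time[i])
    if (sp$null) {
      return(dplyr::mutate(base, dx = NA_real_, dy = NA_real_, dz = NA_real_,
                           px = NA_real_, py = NA_real_, pz = NA_real_,
                           pitch = NA_real_, amplitude = 0,
                           translation_dominated = FALSE, null = TRUE,
                           screw = list(NULL)))
    }
    s <- sp$screw
    p <- axis_point(s)
    dir <- if (s$infinite) s$m else s$d
    dplyr::mutate(base,
      dx = dir[1], dy = dir[2], dz = dir[3],
      px = p[1], py = p[2], pz = p[3],
      pitch = screw_pitch(s), amplitude = sp$magnitude,
      translation_dominated = s$infinite, null = FALSE, screw = list(s))
  })
  attr(out, "rate") <- rate
  class(out) <- c("twist_track", class(out))
  out
}

#' Moving-average smoother for marker trajectories
#'
#' Optional centred moving average applied per marker coordinate before pose
#' fitting; reduces isotropic marker noise by roughly the square root of the
#' window length.
#'
#' @param markers Tidy marker tibble (`frame`, `marker`, `x`, `y`, `z`).
#' @param window Odd window length in frames.
#' @return The smoothed tibble.
#' @export
smooth_markers <- function(markers, window = 5) {
  if (window < 1 || window %% 2 == 0) abort_input("window must be odd and >= 1")
  if (window == 1) return(markers)
  k <- rep(1 / window, window)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], (window - 1) / 2), v, rep(v[n], (window - 1) / 2))
    stats::filter(vp, k, sides = 2)[((window - 1) / 2 + 1):((window - 1) / 2 + n)]
  }
  markers |>
    dplyr::group_by(.data$marker) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(c("x", "y", "z"), ~ as.numeric(pad_filter(.x)))) |>
    dplyr::ungroup()
}

#' Plot the axis track of a twist sequence
#'
#' @param object A `twist_track`.
#' @param ... Unused.
#' @return A ggplot object: axis-point coordinates and pitch over time.
#' @export
autoplot.twist_track <- function(object, ...) {
  d <- object |>
    dplyr::filter(!.data$translation_dominated) |>
    dplyr::select("time", "px", "py", "pz", "pitch") |>
    tidyr::pivot_longer(-"time", names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Instantaneous screw axis track")
}
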
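# Shared generators and comparison helpers for screw tests.

rand_screw <- function(pitch_sd = 0.05, point_sd = 0.3) {
  screw_from_axis(rnorm(3, 0, point_sd), rnorm(3), rnorm(1, 0, pitch_sd))
}

rand_line <- function(point_sd = 0.3) {
  screw_from_axis(rnorm(3, 0, point_sd), rnorm(3))
}

rand_rotation <- function() {
  ax <- rnorm(3)
  screwgait:::rot_axis_angle(ax, runif(1, 0, pi))
}

# angle (rad) between two unoriented directions; atan2 form stays accurate
# near zero where acos saturates at sqrt(machine eps)
dir_angle <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  atan2(sqrt(sum(screwgait:::cross3(u, v)^2)), abs(sum(u * v)))
}

# distance between the axes of two finite-pitch screws (0 if same line)
line_distance <- function(s1, s2) {
  g <- screw_geometry(s1, s2)
  d_ang <- dir_angle(s1$d, s2$d)
  if (d_ang > 1e-8) return(g$a)
  dr <- axis_point(s2) - axis_point(s1)
  sqrt(sum((dr - sum(dr * s1$d) * s1$d)^2))
}

# brute-force common-perpendicular distance by 2-parameter minimization
brute_axis_distance <- function(s1, s2) {
  p1 <- axis_point(s1); p2 <- axis_point(s2)
  f <- function(st) sum((p1 + st[1] * s1$d - p2 - st[2] * s2$d)^2)
  sqrt(optim(c(0, 0), f, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))$value)
}
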
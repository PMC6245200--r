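#' Hyperbolic distance between points in the native disc representation
#'
#' Computes the distance between points of the hyperbolic plane of curvature
#' K = -1, given in native polar coordinates `(r, theta)` where the radial
#' coordinate equals the hyperbolic distance from the disc origin and angular
#' separations are conformal.
#'
#' The `"approximate"` mode returns `r1 + r2 + 2*log(dtheta/2)` with
#' `dtheta` the shorter angular arc between the two points. This is the form
#' used throughout popularity-similarity modelling and is accurate whenever
#' the points are not nearly co-angular. The `"exact"` mode evaluates the
#' hyperbolic law of cosines
#' `acosh(cosh r1 * cosh r2 - sinh r1 * sinh r2 * cos(dtheta))`, clamped at 0.
#'
#' For co-angular points (`dtheta == 0`) the approximate formula diverges to
#' `-Inf`; in that case the true distance `|r1 - r2|` is returned and a
#' warning is emitted once per call.
#'
#' @param r1,theta1 Polar coordinates of the first point (vectors recycle).
#' @param r2,theta2 Polar coordinates of the second point.
#' @param mode `"approximate"` (default) or `"exact"`.
#' @return Numeric vector of non-negative distances (the approximate mode can
#'   return negative values for very close points; this mirrors its use as a
#'   likelihood argument, where only `x - R_t` matters).
#' @examples
#' hyperbolic_distance(5, 0, 5, 2)            # 10: the log term vanishes
#' hyperbolic_distance(3, 0, 4, pi, mode = "exact")
#' @export
hyperbolic_distance <- function(r1, theta1, r2, theta2,
                                mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  stopifnot(all(r1 >= 0), all(r2 >= 0))
  dtheta <- angular_separation(theta1, theta2)
  if (mode == "exact") {
    # cancellation-free rearrangement of the law of cosines:
    # cosh d = cosh(r1 - r2) + sinh r1 sinh r2 (1 - cos dtheta)
    cosd <- cosh(r1 - r2) + sinh(r1) * sinh(r2) * 2 * sin(dtheta / 2)^2
    return(acosh(pmax(cosd, 1)))
  }
  x <- r1 + r2 + 2 * log(dtheta / 2)
  zero <- dtheta == 0
  if (any(zero)) {
    warning("co-angular points in approximate mode; returning |r1 - r2|")
    x[zero] <- abs(r1 - r2)[zero]
  }
  x
}

#' Angular separation along the shorter arc
#'
#' @param theta1,theta2 Angles in radians.
#' @return Separation in `[0, pi]`.
#' @export
angular_separation <- function(theta1, theta2) {
  pi - abs(pi - abs(theta1 - theta2) %% (2 * pi))
}

#' Fermi connection probability of the popularity-similarity model
#'
#' Probability that two nodes at hyperbolic distance `x` are linked when the
#' disc radius is `R` and the network temperature is `temp`:
#' `p(x) = 1 / (1 + exp((x - R) / (2*temp)))`. At `temp = 0` the
#' zero-temperature limit is used: a step function that is 1 for `x <= R`
#' and 0 otherwise.
#'
#' @param x Hyperbolic distance(s).
#' @param R Disc radius at the current time.
#' @param temp Network temperature, `>= 0`.
#' @return Probabilities in `[0, 1]`.
#' @export
connection_probability <- function(x, R, temp) {
  stopifnot(temp >= 0)
  if (temp == 0) {
    return(as.numeric(x <= R))
  }
  1 / (1 + exp((x - R) / (2 * temp)))
}

#' Radius of the hyperbolic disc containing a growing PS network
#'
#' At birth rank `t` (with new-node radial coordinate `r_t = 2 log t`) the
#' popularity-similarity model places the half-probability point of the
#' connection function at
#' `R_t = r_t - 2*log(2*temp*(1 - exp(-(1-beta)*r_t/2)) / (m*(1-beta)*sin(pi*temp)))`.
#' The zero-temperature limit replaces `2*temp/sin(pi*temp)` by `2/pi`, and
#' the `beta = 1` (no popularity fading) case uses
#' `R_t = r_t - 2*log(temp*r_t / (m*sin(pi*temp)))` (or its `temp -> 0`
#' limit `r_t - 2*log(r_t/(pi*m))`).
#'
#' @param t Birth rank(s), `>= 1`.
#' @param m Expected number of links a new node establishes (half the target
#'   average degree); may be fractional.
#' @param beta Popularity-fading exponent `1/(gamma - 1)` in `(0, 1]`.
#' @param temp Network temperature in `[0, 1)`.
#' @return Disc radius; `t = 1` returns 0 (a lone first node makes no link
#'   decision).
#' @export
disc_radius <- function(t, m, beta, temp) {
  stopifnot(all(t >= 1), m > 0, beta > 0, beta <= 1, temp >= 0, temp < 1)
  rt <- 2 * log(t)
  R <- if (beta == 1) {
    if (temp == 0) rt - 2 * log(rt / (pi * m))
    else rt - 2 * log(temp * rt / (m * sin(pi * temp)))
  } else {
    grow <- 1 - exp(-(1 - beta) * rt / 2)
    if (temp == 0) rt - 2 * log(2 * grow / (pi * m * (1 - beta)))
    else rt - 2 * log(2 * temp * grow / (m * (1 - beta) * sin(pi * temp)))
  }
  R[t == 1] <- 0
  R
}

#' Radial coordinate update under popularity fading
#'
#' When node `t` is born, every older node `s` drifts outward:
#' `r_s(t) = beta * r_s + (1 - beta) * r_t`, with `r_s` the radius at birth.
#' `beta = 1` leaves radii unchanged.
#'
#' @param r_s Birth radial coordinate of the older node.
#' @param r_t Radial coordinate of the newborn node.
#' @param beta Popularity-fading exponent.
#' @return Updated radial coordinate.
#' @export
radial_update <- function(r_s, r_t, beta) {
  beta * r_s + (1 - beta) * r_t
}

#' Radial coordinate from degree rank
#'
#' All embedding methods in this package assign radii from the degree
#' ranking of the nodes: the node of rank `i` (rank 1 = highest degree)
#' receives `r_i = 2*beta*log(i) + 2*(1 - beta)*log(N)` with
#' `beta = 1/(gamma - 1)`. This reproduces the final radii of a
#' popularity-similarity network in which degree decays with seniority.
#'
#' @param i Degree rank(s) in `1..n`.
#' @param n Number of nodes.
#' @param gamma Power-law degree exponent in `[2, 3]`.
#' @return Radial coordinates, non-decreasing in `i`.
#' @export
radial_from_rank <- function(i, n, gamma) {
  stopifnot(all(i >= 1), all(i <= n), gamma >= 2, gamma <= 3)
  beta <- 1 / (gamma - 1)
  2 * beta * log(i) + 2 * (1 - beta) * log(n)
}

#' Normalize angles into `[0, 2*pi)`
#' @param theta Angles in radians.
#' @return Equivalent angles in `[0, 2*pi)`.
#' @export
normalize_angle <- function(theta) {
  out <- theta %% (2 * pi)
  out[out == 2 * pi] <- 0
  out
}
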
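## Deterministic generators for benchmark shapes: circles, segments,
## Fourier-coefficient closed curves and the high-frequency wave/line pair
## used to illustrate ECT instability under the Hausdorff distance.

#' Circle as an embedded complex
#'
#' One vertex at angle 0 and one loop edge sampled at `n` uniform angles.
#'
#' @param r radius (> 0).
#' @param n number of samples (>= 8).
#' @return an [embedded_complex()].
#' @export
make_circle <- function(r = 1, n = 512) {
  if (r <= 0 || n < 8) stop("need r > 0 and n >= 8")
  u <- seq(0, 1, length.out = n)
  th <- 2 * pi * u
  pts <- cbind(r * cos(th), r * sin(th))
  pts[n, ] <- pts[1, ]  # exact closure
  st <- cw_structure("v1", data.frame(edge_id = "e1", u = "v1", v = "v1"))
  embedded_complex(st, matrix(pts[1, ], 1, 2, dimnames = list("v1", NULL)),
                   list(e1 = sampled_curve(pts, u)))
}

#' Straight segment as an embedded complex
#'
#' @param p0,p1 endpoints (numeric vectors of equal dimension).
#' @param n number of samples (>= 3).
#' @return an [embedded_complex()] with two vertices and one edge.
#' @export
make_segment <- function(p0 = c(0, 0), p1 = c(1, 0), n = 64) {
  u <- seq(0, 1, length.out = n)
  pts <- outer(1 - u, as.numeric(p0)) + outer(u, as.numeric(p1))
  st <- cw_structure(c("v1", "v2"),
                     data.frame(edge_id = "e1", u = "v1", v = "v2"))
  vc <- rbind(p0, p1); rownames(vc) <- c("v1", "v2")
  embedded_complex(st, vc, list(e1 = sampled_curve(pts, u)))
}

#' High-frequency wave and its straight baseline
#'
#' The classical example of two shapes close in Hausdorff distance whose ECTs
#' stay far apart: a straight unit segment and the wave
#' `(x, eps * sin(2*pi*osc*x))`. With `osc = ceiling(1/eps)` oscillations the
#' bottom-up Euler characteristic curves are at least distance 1 apart while
#' the Hausdorff distance between the shapes is `eps`.
#'
#' @param eps wave amplitude, in (0, 0.5).
#' @param oscillations number of full sine periods; `NULL` for `ceiling(1/eps)`.
#' @param n samples for the wave; at least `40 * oscillations` enforced.
#' @return list(line, wave) of [embedded_complex()]es.
#' @export
make_wave_and_line <- function(eps, oscillations = NULL, n = NULL) {
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  osc <- if (is.null(oscillations)) ceiling(1 / eps) else as.integer(oscillations)
  if (osc < 1) stop("need at least one oscillation")
  n <- max(if (is.null(n)) 0 else n, 40 * osc)
  x <- seq(0, 1, length.out = n)
  wave_pts <- cbind(x, eps * sin(2 * pi * osc * x))
  wave_pts[c(1, n), 2] <- 0  # exact endpoints on the axis
  st <- cw_structure(c("v1", "v2"),
                     data.frame(edge_id = "e1", u = "v1", v = "v2"))
  vc <- rbind(c(0, 0), c(1, 0)); rownames(vc) <- c("v1", "v2")
  wave <- embedded_complex(st, vc, list(e1 = sampled_curve(wave_pts, x)))
  list(line = make_segment(c(0, 0), c(1, 0), n = 128), wave = wave)
}

#' Specification of a Fourier-coefficient closed curve
#'
#' Complex coefficients `c_k` over a symmetric index range define the closed
#' planar curve `t -> sum_k c_k exp(i k t)` (real/imaginary parts as x/y).
#' When drawn randomly, `c_1 = 1` (the base circle) and the remaining
#' harmonics get independent complex Gaussian coefficients with magnitude
#' decay `|k|^-3`, which keeps curvature bounded and the curve simple for
#' moderate amplitudes.
#'
#' @param coefficients named complex vector, names the integer frequencies k;
#'   `NULL` to draw randomly.
#' @param n_harmonics largest |k| for random draws (default 5).
#' @param amplitude scale of the random harmonics (default 0.15).
#' @param n sample count of the resulting curve.
#' @param seed RNG seed for random draws.
#' @return list of class `fourier_spec`.
#' @export
fourier_spec <- function(coefficients = NULL, n_harmonics = 5,
                         amplitude = 0.15, n = 600, seed = 4) {
  if (is.null(coefficients)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    ks <- setdiff(-n_harmonics:n_harmonics, c(0, 1))
    coefficients <- complex(real = stats::rnorm(length(ks)),
                            imaginary = stats::rnorm(length(ks))) *
      amplitude / abs(ks)^3
    names(coefficients) <- as.character(ks)
    coefficients <- c(coefficients, stats::setNames(1 + 0i, "1"))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  } else {
    coefficients <- as.complex(coefficients)
    if (is.null(names(coefficients))) stop("coefficients must be named by k")
  }
  structure(list(coefficients = coefficients, n = n, seed = seed),
            class = "fourier_spec")
}

#' Closed curve from complex Fourier coefficients
#'
#' @param spec a [fourier_spec()].
#' @return an [embedded_complex()] with one vertex (at t = 0) and one loop.
#' @export
make_fourier_curve <- function(spec = fourier_spec()) {
  stopifnot(inherits(spec, "fourier_spec"))
  u <- seq(0, 1, length.out = spec$n)
  t <- 2 * pi * u
  z <- rep(0 + 0i, spec$n)
  ks <- as.integer(names(spec$coefficients))
  for (i in seq_along(ks)) {
    z <- z + spec$coefficients[i] * exp(1i * ks[i] * t)
  }
  pts <- cbind(Re(z), Im(z))
  if (max(abs(pts[1, ] - pts[spec$n, ])) > 1e-9) {
    stop("generator bug: Fourier curve failed to close")
  }
  pts[spec$n, ] <- pts[1, ]
  st <- cw_structure("v1", data.frame(edge_id = "e1", u = "v1", v = "v1"))
  embedded_complex(st, matrix(pts[1, ], 1, 2, dimnames = list("v1", NULL)),
                   list(e1 = sampled_curve(pts, u)))
}

#' Analytic ECT field of a circle
#'
#' The sublevel set of a circle in any direction is an arc (Euler
#' characteristic 1) from level `-r` up to, but not including, level `r`,
#' where it closes up into the full circle (Euler characteristic 0). Serves
#' as a closed-form reference for the PL approximation.
#'
#' @param r radius.
#' @param directions a [direction_set()].
#' @param a bounding radius, `a > r`.
#' @return an [ect_field()]-shaped object.
#' @export
analytic_circle_ect <- function(r = 1, directions = direction_set(64), a = NULL) {
  if (is.null(a)) a <- 1.05 * r
  if (a <= r) stop("bounding radius a must exceed r")
  curves <- replicate(nrow(directions),
                      step_function(c(-r, r), c(1, 0)), simplify = FALSE)
  structure(list(directions = directions, curves = curves, a = a, chi = 0),
            class = "ect_field")
}
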
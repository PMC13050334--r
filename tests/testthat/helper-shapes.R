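# shared fixtures, built in code

# random smooth closed curve with seeded coefficients
random_fourier <- function(seed, n = 400, amplitude = 0.15) {
  make_fourier_curve(fourier_spec(seed = seed, n = n, amplitude = amplitude))
}

# random unit direction in the plane
random_direction <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  c(cos(th), sin(th))
}

# smooth open curve: seeded trigonometric polynomial graph over [0, 1]
random_open_curve <- function(seed, n = 300) {
  set.seed(seed)
  a <- stats::rnorm(3, 0, 0.2) / (1:3)^2
  x <- seq(0, 1, length.out = n)
  y <- drop(vapply(1:3, function(k) sin(2 * pi * k * x), numeric(n)) %*% a)
  sampled_curve(cbind(x, y))
}

# wrap a closed sampled curve (first point == last point) into a one-vertex
# loop complex
as_loop_complex <- function(cu) {
  st <- cw_structure("v1", data.frame(edge_id = "e1", u = "v1", v = "v1"))
  vc <- cu$points[1, , drop = FALSE]
  rownames(vc) <- "v1"
  embedded_complex(st, vc, list(e1 = cu), tol = 1e-6)
}

# wrap an open sampled curve into a two-vertex embedded complex
as_open_complex <- function(cu) {
  st <- cw_structure(c("v1", "v2"),
                     data.frame(edge_id = "e1", u = "v1", v = "v2"))
  vc <- rbind(cu$points[1, ], cu$points[nrow(cu$points), ])
  rownames(vc) <- c("v1", "v2")
  embedded_complex(st, vc, list(e1 = cu))
}

# dense-grid trapezoid quadrature of |f1 - f2| for piecewise-linear oracles
pl_l1_quadrature <- function(p1, p2, n = 200001) {
  lo <- min(p1$knots[1], p2$knots[1])
  hi <- max(p1$knots[length(p1$knots)], p2$knots[length(p2$knots)])
  t <- seq(lo, hi, length.out = n)
  v <- abs(pl_eval(p1, t) - pl_eval(p2, t))
  sum((v[-1] + v[-n]) / 2) * (hi - lo) / (n - 1)
}
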
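## Kernels, Gaussian-process posteriors, derivative-process variance and the
## covering-number entropy integral. Observation noise is parametrised by its
## VARIANCE sigma2 throughout.

# build vectorised kernel-derivative functions symbolically from a kernel
# expression in (s, t); avoids hand-coded algebra errors.
kernel_from_expression <- function(expr, periodic = FALSE, params = list(),
                                   name = "kernel", env = parent.frame()) {
  mk <- function(e) {
    f <- function(s, t) {}
    body(f) <- e
    environment(f) <- list2env(params, parent = baseenv())
    f
  }
  ex_x <- stats::D(expr, "s")
  ex_y <- stats::D(expr, "t")
  ex_xy <- stats::D(ex_x, "t")
  ex_xx <- stats::D(ex_x, "s")
  ex_yy <- stats::D(ex_y, "t")
  ex_xxyy <- stats::D(stats::D(ex_xx, "t"), "t")
  structure(list(k = mk(expr), kx = mk(ex_x), ky = mk(ex_y), kxy = mk(ex_xy),
                 kxx = mk(ex_xx), kyy = mk(ex_yy), kxxyy = mk(ex_xxyy),
                 periodic = periodic, params = params, name = name,
                 reduced_precision = FALSE),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat("<kernel_model>", x$name,
      if (x$periodic) "(periodic)" else "", "\n")
  invisible(x)
}

#' Sine-squared exponential kernel on the circle
#'
#' `k(s, t) = exp(-2 sin((s - t)/2)^2)`, a 2*pi-periodic, infinitely
#' differentiable positive-semidefinite kernel on `[0, 2*pi)` whose RKHS
#' contains all finite trigonometric polynomials; the standard choice for
#' Gaussian-process regression of closed curves. Analytic partial derivatives
#' up to the fourth mixed order are attached (generated symbolically).
#'
#' @return a `kernel_model`.
#' @examples
#' k <- kernel_sine_squared()
#' k$k(0, pi)          # exp(-2)
#' k$kxy(1, 1)         # prior derivative variance at the diagonal: 1
#' @export
kernel_sine_squared <- function() {
  kernel_from_expression(quote(exp(-2 * sin((s - t) / 2)^2)),
                         periodic = TRUE, name = "sine-squared exponential")
}

#' Gaussian (squared-exponential) kernel on the line
#'
#' `k(s, t) = exp(-(s - t)^2 / (2 l^2))`; used for open (non-loop) edges.
#'
#' @param lengthscale positive lengthscale l (default 0.2).
#' @return a `kernel_model`.
#' @export
kernel_gaussian <- function(lengthscale = 0.2) {
  kernel_from_expression(quote(exp(-(s - t)^2 / (2 * ell^2))),
                         periodic = FALSE, params = list(ell = lengthscale),
                         name = sprintf("gaussian (l = %g)", lengthscale))
}

#' Pull a kernel back along a map
#'
#' Given a positive-semidefinite base kernel on R^d and a map `f` from a
#' parameter interval into R^d, `k'(s, t) = k(f(s), f(t))` is again a kernel;
#' differentiability of `f` and the base kernel transfers by the chain rule.
#' Derivatives are approximated by central finite differences (step 1e-5)
#' because the composition has no closed form here; the model is flagged
#' `reduced_precision` and a warning is emitted once.
#'
#' @param base_k function `(x, y) -> value` on R^d vectors, PSD.
#' @param f function mapping a scalar parameter to a d-vector.
#' @param periodic whether `f` is periodic in its parameter.
#' @return a `kernel_model` with finite-difference derivatives.
#' @export
pullback_kernel <- function(base_k, f, periodic = FALSE) {
  kf <- function(s, t) {
    mapply(function(si, ti) base_k(f(si), f(ti)), s, t)
  }
  h <- 1e-5
  kx <- function(s, t) (kf(s + h, t) - kf(s - h, t)) / (2 * h)
  ky <- function(s, t) (kf(s, t + h) - kf(s, t - h)) / (2 * h)
  kxy <- function(s, t) {
    (kf(s + h, t + h) - kf(s + h, t - h) -
     kf(s - h, t + h) + kf(s - h, t - h)) / (4 * h^2)
  }
  kxx <- function(s, t) (kf(s + h, t) - 2 * kf(s, t) + kf(s - h, t)) / h^2
  kyy <- function(s, t) (kf(s, t + h) - 2 * kf(s, t) + kf(s, t - h)) / h^2
  warning("pullback kernel uses finite-difference derivatives (reduced precision)",
          call. = FALSE)
  structure(list(k = kf, kx = kx, ky = ky, kxy = kxy, kxx = kxx, kyy = kyy,
                 kxxyy = NULL, periodic = periodic, params = list(),
                 name = "pullback", reduced_precision = TRUE),
            class = "kernel_model")
}

#' Canonical kernel metric
#'
#' `d_k(s, t) = sqrt(k(s,s) + k(t,t) - 2 k(s,t))`, the metric a kernel induces
#' on its domain. Tiny negative arguments (down to -1e-10) from rounding are
#' clipped to 0; anything more negative signals an invalid kernel.
#'
#' @param k a `kernel_model` (or plain function `(s, t)`).
#' @param s,t numeric vectors.
#' @return nonnegative numeric vector.
#' @export
dk_metric <- function(k, s, t) {
  kf <- if (inherits(k, "kernel_model")) k$k else k
  val <- kf(s, s) + kf(t, t) - 2 * kf(s, t)
  if (any(val < -1e-10)) stop("kernel metric argument negative: invalid kernel")
  sqrt(pmax(val, 0))
}

## ---- entropy integral -------------------------------------------------------

# greedy covering number of a finite sampling at radius eps, from a full
# distance matrix: repeatedly pick the first uncovered point and cover its
# eps-ball. Upper bound on the minimal covering number of the sampling.
greedy_cover_count <- function(D, eps) {
  n <- nrow(D)
  uncovered <- rep(TRUE, n)
  cnt <- 0L
  while (any(uncovered)) {
    i <- which.max(uncovered)
    uncovered[D[i, ] <= eps] <- FALSE
    cnt <- cnt + 1L
  }
  cnt
}

#' Covering-number entropy integral
#'
#' Computes `J = integral_0^inf sqrt(log N(eps)) d(eps)`, where `N(eps)` is
#' the number of metric balls of radius eps needed to cover the domain.
#' Finiteness of J for the kernel metric is the hypothesis under which
#' Gaussian-process smoothing is consistent. Either an analytic covering
#' function `N_fn` is supplied, or `N` is estimated by greedy covering of a
#' finite dense sampling of the domain (an upper bound on the minimal cover,
#' hence an upper bound on J). The integrand is zero once `N = 1`; the
#' integral is a trapezoid sum over a log-spaced eps-grid.
#'
#' @param points numeric vector/matrix of domain samples (default 2000 points
#'   required when no `N_fn` is given).
#' @param metric function `(x, y) -> distance` vectorised over its first
#'   argument, or a precomputed distance matrix.
#' @param N_fn optional analytic covering-number function of eps.
#' @param eps_grid optional increasing grid; default 400 log-spaced points
#'   spanning `[diameter * 1e-4, diameter]` (or `(0, eps_max]` for `N_fn`).
#' @return nonnegative scalar estimate of J.
#' @export
covering_integral <- function(points = NULL, metric = NULL, N_fn = NULL,
                              eps_grid = NULL) {
  if (!is.null(N_fn)) {
    if (is.null(eps_grid)) {
      # find where N reaches 1, then integrate on a log grid from near 0
      hi <- 1
      while (N_fn(hi) > 1 && hi < 1e8) hi <- hi * 2
      eps_grid <- exp(seq(log(hi * 1e-8), log(hi), length.out = 4000))
    }
    Ns <- vapply(eps_grid, N_fn, numeric(1))
  } else {
    if (is.null(points)) stop("covering_integral needs points or N_fn")
    if (is.matrix(metric)) {
      D <- metric
    } else {
      pts <- if (is.matrix(points)) points else matrix(points, ncol = 1)
      n <- nrow(pts)
      if (n < 1) stop("empty domain sampling")
      if (n == 1) return(0)
      if (is.null(metric)) {
        D <- as.matrix(stats::dist(pts))
      } else if (ncol(pts) == 1) {
        D <- outer(drop(pts), drop(pts), metric)
      } else {
        D <- matrix(0, n, n)
        for (i in seq_len(n)) {
          for (j in seq_len(i - 1)) {
            D[i, j] <- D[j, i] <- metric(pts[i, ], pts[j, ])
          }
        }
      }
    }
    diam <- max(D)
    if (diam == 0) return(0)
    if (is.null(eps_grid)) {
      eps_grid <- exp(seq(log(diam * 1e-4), log(diam), length.out = 400))
    }
    Ns <- vapply(eps_grid, function(e) greedy_cover_count(D, e), integer(1))
  }
  g <- sqrt(pmax(log(Ns), 0))
  # trapezoid over the grid; left tail below the smallest grid point is
  # closed off with the integrand value there (rectangle), an upper piece
  sum(diff(eps_grid) * (g[-1] + g[-length(g)]) / 2) + eps_grid[1] * g[1]
}

## ---- GP regression ----------------------------------------------------------

gram <- function(kfun, x, y) outer(x, y, kfun)

# Cholesky with jitter escalation 0 -> 1e-10 -> 1e-8 -> 1e-6
chol_jitter <- function(B) {
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    R <- tryCatch(chol(B + diag(j, nrow(B))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("Gram matrix not positive definite beyond jitter ladder")
}

#' Fit a Gaussian-process regression
#'
#' Conditions a zero-mean Gaussian process with covariance `kernel` on noisy
#' observations `y_i = f(x_i) + noise`, noise variance `sigma2`. The
#' regularised Gram matrix `B = K(x, x) + sigma2 * I` is Cholesky-factored
#' once (with jitter escalation 1e-10 to 1e-6 on failure).
#'
#' @param x numeric vector of training inputs.
#' @param y numeric vector of observations.
#' @param kernel a `kernel_model`.
#' @param sigma2 observation noise variance (> 0).
#' @return object of class `gp_fit`.
#' @export
gp_fit <- function(x, y, kernel, sigma2) {
  stopifnot(inherits(kernel, "kernel_model"), sigma2 > 0,
            length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n == 0) {
    return(structure(list(x = x, y = y, kernel = kernel, sigma2 = sigma2,
                          R = NULL, alpha = numeric(0)), class = "gp_fit"))
  }
  B <- gram(kernel$k, x, x) + diag(sigma2, n)
  R <- chol_jitter(B)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  structure(list(x = x, y = y, kernel = kernel, sigma2 = sigma2,
                 R = R, alpha = alpha), class = "gp_fit")
}

# solve B z = M for a matrix M using the stored factor
gp_solve <- function(fit, M) backsolve(fit$R, forwardsolve(t(fit$R), M))

#' Gaussian-process posterior at query points
#'
#' Posterior mean `K(q, x) B^{-1} y` and covariance
#' `K(q, q) - K(q, x) B^{-1} K(x, q)` of the latent function at `xq`. With no
#' observations this is the prior (mean 0, covariance `K(q, q)`).
#'
#' @param fit a [gp_fit()].
#' @param xq numeric vector of query points.
#' @param full_cov return the full covariance matrix (default) or only its
#'   diagonal (the pointwise variance).
#' @return list(mean, cov) or list(mean, var).
#' @export
gp_posterior <- function(fit, xq, full_cov = TRUE) {
  xq <- as.numeric(xq)
  Kqq <- gram(fit$kernel$k, xq, xq)
  if (length(fit$x) == 0) {
    return(if (full_cov) list(mean = rep(0, length(xq)), cov = Kqq)
           else list(mean = rep(0, length(xq)), var = diag(Kqq)))
  }
  Kqx <- gram(fit$kernel$k, xq, fit$x)
  mu <- drop(Kqx %*% fit$alpha)
  V <- Kqq - Kqx %*% gp_solve(fit, t(Kqx))
  if (full_cov) list(mean = mu, cov = V)
  else list(mean = mu, var = pmax(diag(V), 0))
}

#' Posterior variance (and mean) of the derivative process
#'
#' The derivative of a GP with a twice-differentiable kernel is again a GP
#' with kernel `k_xy`; given n noisy observations its posterior variance at t
#' is `k_xy(t, t) - K_x(t, x) B^{-1} K_y(x, t)`, which is monotonically
#' nonincreasing as observations are appended. The posterior derivative mean
#' applies the same linear functional to the mean weights.
#'
#' @param fit a [gp_fit()] whose kernel has `kx`, `ky`, `kxy` derivatives.
#' @param t numeric vector of query points.
#' @return list(var, mean): derivative variance and posterior derivative mean.
#' @export
derivative_variance <- function(fit, t) {
  k <- fit$kernel
  if (is.null(k$kxy)) stop("kernel has no second mixed partial")
  prior <- k$kxy(t, t)
  if (length(fit$x) == 0) return(list(var = prior, mean = rep(0, length(t))))
  Kx <- outer(t, fit$x, k$kx)   # rows: d/dt k(t, x_j)
  v <- prior - rowSums(Kx * t(gp_solve(fit, t(Kx))))
  list(var = pmax(v, 0), mean = drop(Kx %*% fit$alpha))
}

#' Draw sample paths from a GP posterior
#'
#' @param fit a [gp_fit()].
#' @param xq evaluation grid.
#' @param n_draws number of paths.
#' @return matrix (n_draws x length(xq)) of sampled function values.
#' @export
gp_draw <- function(fit, xq, n_draws) {
  post <- gp_posterior(fit, xq, full_cov = TRUE)
  R <- chol_jitter((post$cov + t(post$cov)) / 2)
  Z <- matrix(stats::rnorm(n_draws * length(xq)), n_draws, length(xq))
  sweep(Z %*% R, 2, post$mean, "+")
}
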
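## End-to-end consistent ECT/SECT estimation: noisy arc-length-equispaced
## sampling of an embedded complex, componentwise Gaussian-process smoothing,
## constant-velocity reparametrisation, and the PL ECT of the smoothed shape.

# GP input for a location on an edge: loop edges live on [0, 2*pi) (periodic
# kernels), open edges on [0, 1].
edge_gp_input <- function(param, is_loop) if (is_loop) 2 * pi * param else param

#' Noisy observations of an embedded complex
#'
#' Samples `n` locations per edge, equally spaced in arc length (a compatible
#' subset: loop edges start at their vertex; open edges include both
#' endpoints), and perturbs every coordinate independently with centred
#' Gaussian noise.
#'
#' @param X an [embedded_complex()].
#' @param n samples per edge (>= 4).
#' @param sigma per-coordinate noise standard deviations (recycled to the
#'   dimension), all > 0. The simulation protocol of the reference experiment
#'   uses 0.002.
#' @param seed RNG seed; two calls with the same seed are identical.
#' @return object of class `noisy_observations`: per-edge data.frames with
#'   the location parameters, GP inputs, true and observed coordinates.
#' @export
sample_noisy <- function(X, n, sigma = 0.002, seed = 1) {
  stopifnot(inherits(X, "embedded_complex"))
  if (n < 4) stop("need at least 4 samples per edge")
  sigma <- rep(as.numeric(sigma), length.out = X$dimension)
  if (any(sigma <= 0)) stop("noise standard deviations must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))
  edges <- X$structure$edges
  obs <- list()
  for (r in seq_len(nrow(edges))) {
    e <- edges[r, ]
    cu <- X$curves[[e$edge_id]]
    cs <- cumulative_length(cu$points)
    L <- cs[length(cs)]
    is_loop <- identical(e$u, e$v)
    frac <- if (is_loop) (seq_len(n) - 1) / n else (seq_len(n) - 1) / (n - 1)
    if (L > 1e-12) {
      s <- L * frac
      par <- stats::approx(cs, cu$params, xout = s, ties = "ordered")$y
      truth <- interp_at_arclength(cu$points, s)
    } else {
      # degenerate (point-like) edge: fall back to parameter spacing
      par <- frac
      truth <- vapply(seq_len(X$dimension), function(j) {
        stats::approx(cu$params, cu$points[, j], xout = par,
                      ties = "ordered")$y
      }, numeric(n))
    }
    noise <- matrix(stats::rnorm(n * X$dimension), n) %*% diag(sigma, X$dimension)
    obs[[e$edge_id]] <- list(param = par,
                             input = edge_gp_input(par, is_loop),
                             is_loop = is_loop,
                             truth = truth, y = truth + noise)
  }
  structure(list(edges = obs, sigma = sigma, n = n, seed = seed,
                 dimension = X$dimension, complex = X),
            class = "noisy_observations")
}

#' Gaussian smoothing of a noisy embedding
#'
#' Fits one Gaussian-process posterior per coordinate and edge (noise variance
#' `sigma^2`) and evaluates the posterior means on `m_eval` dense parameters
#' per edge, returning the smoothed shape as an embedded complex. Loop edges
#' use the (periodic) kernel on `[0, 2*pi)`, so the first and last evaluation
#' agree; vertices shared by several edge ends take the average of the edge
#' estimates.
#'
#' @param obs a [sample_noisy()] result.
#' @param kernel a `kernel_model`; the sine-squared exponential kernel is the
#'   natural choice for closed curves.
#' @param m_eval dense evaluation points per edge (>= number of samples).
#' @return list(complex, fits): the smoothed [embedded_complex()] and the
#'   per-edge, per-coordinate [gp_fit()]s.
#' @export
smooth_embedding <- function(obs, kernel = kernel_sine_squared(), m_eval = 256) {
  stopifnot(inherits(obs, "noisy_observations"))
  if (m_eval < obs$n) stop("m_eval must be at least the number of samples")
  X <- obs$complex
  d <- obs$dimension
  curves <- list(); fits <- list()
  vert_acc <- matrix(0, nrow(X$vertex_coords), d,
                     dimnames = list(rownames(X$vertex_coords), NULL))
  vert_cnt <- stats::setNames(numeric(nrow(X$vertex_coords)),
                              rownames(X$vertex_coords))
  for (r in seq_len(nrow(X$structure$edges))) {
    e <- X$structure$edges[r, ]
    ob <- obs$edges[[e$edge_id]]
    u_eval <- seq(0, 1, length.out = m_eval)
    x_eval <- edge_gp_input(u_eval, ob$is_loop)
    # loops close exactly: parameters 0 and 1 are the same point of the
    # complex, so the last evaluation reuses input 0 (periodic kernel)
    if (ob$is_loop) x_eval[m_eval] <- 0
    pts <- matrix(0, m_eval, d)
    efits <- vector("list", d)
    for (j in seq_len(d)) {
      fit <- gp_fit(ob$input, ob$y[, j], kernel, obs$sigma[j]^2)
      pts[, j] <- gp_posterior(fit, x_eval, full_cov = FALSE)$mean
      efits[[j]] <- fit
    }
    if (ob$is_loop) {
      if (!kernel$periodic &&
          max(abs(kernel$k(0, ob$input) - kernel$k(2 * pi, ob$input))) > 1e-9) {
        stop("loop edges need a 2*pi-periodic kernel")
      }
      pts[m_eval, ] <- pts[1, ]
      vert_acc[e$u, ] <- vert_acc[e$u, ] + pts[1, ]
      vert_cnt[e$u] <- vert_cnt[e$u] + 1
    } else {
      vert_acc[e$u, ] <- vert_acc[e$u, ] + pts[1, ]
      vert_acc[e$v, ] <- vert_acc[e$v, ] + pts[m_eval, ]
      vert_cnt[e$u] <- vert_cnt[e$u] + 1
      vert_cnt[e$v] <- vert_cnt[e$v] + 1
    }
    curves[[e$edge_id]] <- list(pts = pts, u = u_eval)
    fits[[e$edge_id]] <- efits
  }
  vc <- vert_acc / pmax(vert_cnt, 1)
  sc <- list()
  for (eid in names(curves)) {
    e <- X$structure$edges[X$structure$edges$edge_id == eid, ]
    pts <- curves[[eid]]$pts
    pts[1, ] <- vc[e$u, ]; pts[nrow(pts), ] <- vc[e$v, ]
    sc[[eid]] <- sampled_curve(pts, curves[[eid]]$u)
  }
  list(complex = embedded_complex(X$structure, vc, sc, tol = 1e-6),
       fits = fits)
}

#' Estimate the ECT/SECT of a shape from noisy samples
#'
#' The full estimator: Gaussian smoothing of the observations, per-edge
#' constant-velocity reparametrisation of the posterior-mean curves, then the
#' exact PL ECT on the `m` interpolation points, plus the SECT. Distances to
#' a reference ECT/SECT field are attached when supplied.
#'
#' @param obs a [sample_noisy()] result.
#' @param kernel a `kernel_model`.
#' @param m interpolation fineness per edge; default `max(4 * n, 256)`.
#' @param directions a [direction_set()].
#' @param a bounding radius (should cover both estimate and reference).
#' @param reference optional list(ect =, sect =) reference fields.
#' @return object of class `ect_estimate`: smoothed complex, arc lengths,
#'   `ect`/`sect` fields and (optionally) `ect_distance`/`sect_distance`.
#' @export
estimate_ect <- function(obs, kernel = kernel_sine_squared(), m = NULL,
                         directions = direction_set(64), a = NULL,
                         reference = NULL) {
  if (is.null(m)) m <- max(4 * obs$n, 256)
  sm <- smooth_embedding(obs, kernel, m_eval = m)
  Xs <- sm$complex
  lengths <- vapply(Xs$curves, arc_length, numeric(1))
  # constant-velocity interpolation points define the PL ECT of the estimate
  cv <- lapply(Xs$curves, reparam_constant_velocity, n_out = m)
  Xcv <- embedded_complex(Xs$structure, Xs$vertex_coords, cv, tol = 1e-6)
  E <- ect_field(Xcv, eps = NULL, directions = directions, a = a)
  S <- sect_from_ect(E)
  out <- list(complex = Xcv, fits = sm$fits, lengths = lengths,
              ect = E, sect = S, m = m, n = obs$n)
  if (!is.null(reference)) {
    if (!is.null(reference$ect)) out$ect_distance <- ect_distance(E, reference$ect)
    if (!is.null(reference$sect)) out$sect_distance <- sect_distance(S, reference$sect)
  }
  structure(out, class = "ect_estimate")
}

#' @export
print.ect_estimate <- function(x, ...) {
  cat("<ect_estimate> n =", x$n, "samples, m =", x$m, "interpolation points\n")
  if (!is.null(x$sect_distance)) {
    cat("  SECT distance to reference:", format(x$sect_distance), "\n")
  }
  invisible(x)
}

# reference fields of the true shape from a 10x finer PL interpolation
reference_fields <- function(X, m, directions, a) {
  cv <- lapply(X$curves, reparam_constant_velocity, n_out = 10 * m)
  Xf <- embedded_complex(X$structure, X$vertex_coords, cv, tol = 1e-6)
  E <- ect_field(Xf, eps = NULL, directions = directions, a = a)
  list(ect = E, sect = sect_from_ect(E))
}

#' Consistency experiment for the SECT estimator
#'
#' For each sample size in `n_list` and each replicate: draw noisy samples of
#' the curve, fit the Gaussian smoothing, and record the ECT and SECT
#' distances between the posterior-mean estimate and the true shape's
#' reference fields (computed from a 10x finer PL interpolation of the
#' truth). Optionally draws posterior sample curves per fit and records the
#' mean and standard deviation of their SECT distances.
#'
#' @param X an [embedded_complex()] (typically a single closed curve).
#' @param n_list sample sizes, e.g. `c(20, 50, 100)`.
#' @param reps replicates per sample size.
#' @param n_posterior posterior draws per fit (0 to skip; the reference
#'   experiment uses 500).
#' @param sigma noise standard deviation (default 0.002).
#' @param seed base seed; replicate r at sample size n uses a seed derived
#'   from (seed, n, r) so that runs are reproducible and independent.
#' @param kernel a `kernel_model`.
#' @param directions a [direction_set()].
#' @param m interpolation fineness; default `max(4 * n, 256)` per fit.
#' @return data.frame with columns n, rep, distance_kind (ect|sect),
#'   point_estimate_distance, posterior_mean_distance, posterior_sd_distance.
#' @export
consistency_experiment <- function(X, n_list = c(20, 50, 100), reps = 5,
                                   n_posterior = 0, sigma = 0.002, seed = 1,
                                   kernel = kernel_sine_squared(),
                                   directions = direction_set(64), m = NULL) {
  a <- 1.1 * max_point_norm(X)
  m_ref <- if (is.null(m)) max(4 * max(n_list), 256) else m
  ref <- reference_fields(X, m_ref, directions, a)
  rows <- list()
  for (n in n_list) {
    for (r in seq_len(reps)) {
      sub_seed <- (as.integer(seed) * 1000L + as.integer(n) * 37L +
                     as.integer(r)) %% 2147483647L
      obs <- sample_noisy(X, n, sigma = sigma, seed = sub_seed)
      est <- estimate_ect(obs, kernel, m = m, directions = directions,
                          a = a, reference = ref)
      post <- list(ect = c(NA_real_, NA_real_), sect = c(NA_real_, NA_real_))
      if (n_posterior > 0) {
        pd <- posterior_sect_distances(est, obs, n_posterior, ref, directions, a)
        post <- pd
      }
      rows[[length(rows) + 1]] <- data.frame(
        n = n, rep = r, distance_kind = c("ect", "sect"),
        point_estimate_distance = c(est$ect_distance, est$sect_distance),
        posterior_mean_distance = c(post$ect[1], post$sect[1]),
        posterior_sd_distance = c(post$ect[2], post$sect[2]))
    }
  }
  do.call(rbind, rows)
}

# distances of posterior sample curves to the reference fields
posterior_sect_distances <- function(est, obs, n_posterior, ref, directions, a) {
  eid <- names(est$fits)[1]
  fits <- est$fits[[eid]]
  ob <- obs$edges[[eid]]
  m <- est$m
  u_eval <- seq(0, 1, length.out = m)
  x_eval <- edge_gp_input(u_eval, ob$is_loop)
  if (ob$is_loop) x_eval[m] <- 0
  draws <- lapply(fits, gp_draw, xq = x_eval, n_draws = n_posterior)
  de <- ds <- numeric(n_posterior)
  for (b in seq_len(n_posterior)) {
    pts <- vapply(draws, function(D) D[b, ], numeric(m))
    if (ob$is_loop) pts[m, ] <- pts[1, ]
    cu <- sampled_curve(pts, u_eval)
    A <- chain_subset_curve(cu, loop = ob$is_loop)
    E <- structure(list(directions = directions,
                        curves = lapply(seq_len(nrow(directions)), function(i) {
                          pl_ect(A, directions[i, ])
                        }),
                        a = a, chi = nrow(A$coords) - nrow(A$E)),
                   class = "ect_field")
    de[b] <- ect_distance(E, ref$ect)
    ds[b] <- sect_distance(sect_from_ect(E), ref$sect)
  }
  list(ect = c(mean(de), stats::sd(de)), sect = c(mean(ds), stats::sd(ds)))
}

# minimal compatible subset for one free-standing curve chain
chain_subset_curve <- function(cu, loop = FALSE) {
  n <- nrow(cu$points)
  if (loop) {
    coords <- cu$points[1:(n - 1), , drop = FALSE]
    E <- data.frame(i = 1:(n - 1), j = c(2:(n - 1), 1))
  } else {
    coords <- cu$points
    E <- data.frame(i = 1:(n - 1), j = 2:n)
  }
  E$length <- sqrt(rowSums((coords[E$j, , drop = FALSE] -
                            coords[E$i, , drop = FALSE])^2))
  structure(list(coords = coords, E = E, eps = max(E$length), eps_dense = NA),
            class = "compatible_subset")
}
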
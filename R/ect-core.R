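## Exact piecewise-linear Euler characteristic transform machinery.
##
## Convention: sublevel sets are {x : <x, v> <= t}; Euler characteristic curves
## are right-continuous step functions of t whose breakpoints sit exactly at
## the projection values of the sample points. The Euler characteristic of a
## piecewise-linear sublevel set is (#vertices below) - (#chords fully below),
## which is exact for linear edges because the projection is affine on each
## chord, so edge minima and maxima occur at endpoints.

#' Direction set on the unit sphere
#'
#' For d = 2 (the default), `m` evenly spaced angles `(cos, sin)(2*pi*j/m)`;
#' for general d, a seeded random sample of unit vectors. The supremum over
#' all directions in the ECT norm is approximated by a maximum over this
#' finite grid, which under-estimates the true supremum.
#'
#' @param m number of directions.
#' @param d ambient dimension (default 2).
#' @param seed RNG seed for the general-d fallback.
#' @return numeric matrix (m x d) with unit rows, class `direction_set`.
#' @export
direction_set <- function(m = 64, d = 2, seed = 1) {
  if (d == 2) {
    th <- 2 * pi * (seq_len(m) - 1) / m
    v <- cbind(cos(th), sin(th))
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    v <- matrix(stats::rnorm(m * d), m, d)
    v <- v / sqrt(rowSums(v^2))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(v, class = c("direction_set", "matrix"))
}

## ---- compatible subsets -----------------------------------------------------

#' Compatible (and eps-dense) subset of an embedded complex
#'
#' A compatible subset contains every 0-cell and at least one interior point
#' per 1-cell, so that removing it cuts the complex into disjoint open arcs.
#' This function subdivides each edge at equal-arc-length interior points
#' until every sub-arc has image length strictly below `eps`.
#'
#' @param X an [embedded_complex()].
#' @param eps positive subdivision target; every sub-arc image length < eps.
#' @return an object of class `compatible_subset`: `coords` (matrix of sample
#'   coordinates, vertices first), `locations` (data.frame edge_id/param, NA
#'   edge for vertices), `E` (data.frame i/j/length: the sub-edge multiset as
#'   index pairs with sub-arc image lengths), and `eps`.
#' @export
build_compatible_subset <- function(X, eps) {
  stopifnot(inherits(X, "embedded_complex"))
  if (!is.numeric(eps) || eps <= 0) stop("eps must be a positive real")
  vids <- X$structure$vertex_ids
  coords <- X$vertex_coords
  loc <- data.frame(edge_id = NA_character_, param = NA_real_,
                    id = vids, stringsAsFactors = FALSE)
  E <- list()
  vindex <- stats::setNames(seq_along(vids), vids)
  nxt <- length(vids)
  for (r in seq_len(nrow(X$structure$edges))) {
    e <- X$structure$edges[r, ]
    cu <- X$curves[[e$edge_id]]
    cs <- cumulative_length(cu$points)
    L <- cs[length(cs)]
    k <- max(2, ceiling(L / eps))
    if (L / k >= eps) k <- k + 1  # enforce strict sub-arc length < eps
    s_int <- L * seq_len(k - 1) / k
    ppars <- stats::approx(cs, cu$params, xout = s_int, ties = "ordered")$y
    ppts <- interp_at_arclength(cu$points, s_int)
    idx <- integer(k + 1)
    idx[1] <- vindex[[e$u]]
    idx[k + 1] <- vindex[[e$v]]
    if (k > 1) {
      idx[2:k] <- nxt + seq_len(k - 1)
      nxt <- nxt + (k - 1)
      coords <- rbind(coords, ppts)
      loc <- rbind(loc, data.frame(edge_id = e$edge_id, param = ppars,
                                   id = NA_character_, stringsAsFactors = FALSE))
    }
    E[[r]] <- data.frame(i = idx[-(k + 1)], j = idx[-1], length = L / k)
  }
  rownames(coords) <- NULL
  structure(list(coords = coords, locations = loc,
                 E = do.call(rbind, E), eps = eps,
                 eps_dense = TRUE),
            class = "compatible_subset")
}

# compatible subset that reuses a complex's own sample chains (no subdivision
# target): consecutive samples become the sub-edge multiset. Used for the
# "interpolation on the evaluation grid" ECT of the estimator.
chain_subset <- function(X) {
  vids <- X$structure$vertex_ids
  coords <- X$vertex_coords
  vindex <- stats::setNames(seq_along(vids), vids)
  nxt <- length(vids)
  E <- list(); loc <- data.frame(edge_id = NA_character_, param = NA_real_,
                                 id = vids, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(X$structure$edges))) {
    e <- X$structure$edges[r, ]
    cu <- X$curves[[e$edge_id]]
    n <- nrow(cu$points)
    seg <- sqrt(rowSums((cu$points[-1, , drop = FALSE] -
                         cu$points[-n, , drop = FALSE])^2))
    idx <- integer(n)
    idx[1] <- vindex[[e$u]]; idx[n] <- vindex[[e$v]]
    idx[2:(n - 1)] <- nxt + seq_len(n - 2)
    nxt <- nxt + (n - 2)
    coords <- rbind(coords, cu$points[2:(n - 1), , drop = FALSE])
    loc <- rbind(loc, data.frame(edge_id = e$edge_id,
                                 param = cu$params[2:(n - 1)],
                                 id = NA_character_, stringsAsFactors = FALSE))
    E[[r]] <- data.frame(i = idx[-n], j = idx[-1], length = seg)
  }
  rownames(coords) <- NULL
  structure(list(coords = coords, locations = loc, E = do.call(rbind, E),
                 eps = max(vapply(E, function(d) max(d$length), numeric(1))),
                 eps_dense = NA),
            class = "compatible_subset")
}

## ---- the PL ECT -------------------------------------------------------------

#' Exact piecewise-linear Euler characteristic curve in one direction
#'
#' For a compatible subset with sample coordinates `b_i` and sub-edge multiset
#' `E`, the PL Euler characteristic of the sublevel set at level t is
#' `#\{i : <b_i, v> <= t\} - #\{(i,j) in E : max(<b_i,v>, <b_j,v>) <= t\}`.
#' Breakpoints sit exactly at projection values; equal projections (ties at
#' symmetric directions) are merged by summing jumps, never perturbed.
#'
#' @param A a `compatible_subset` (or anything with `coords` and `E`).
#' @param v unit direction vector.
#' @param coords optional replacement coordinates for the subset's points.
#' @return a [step_function()].
#' @export
pl_ect <- function(A, v, coords = NULL) {
  if (is.null(coords)) coords <- A$coords
  p <- drop(coords %*% as.numeric(v))
  ep <- pmax(p[A$E$i], p[A$E$j])
  step_from_jumps(c(p, ep), c(rep(1, length(p)), rep(-1, length(ep))))
}

#' Euler characteristic transform field of an embedded complex
#'
#' Computes the exact PL ECT on an eps-dense compatible subset of `X`, one
#' Euler characteristic curve (step function) per direction, together with the
#' bounding radius `a` outside of which every curve is constant.
#'
#' @param X an [embedded_complex()].
#' @param eps subdivision density; `NULL` uses the complex's own sample chains
#'   as the interpolation points.
#' @param directions a [direction_set()] (default 64 planar directions).
#' @param a bounding radius; `NULL` uses `1.05 * max point norm`. Must exceed
#'   the maximum point norm of `X`.
#' @return object of class `ect_field`: list(directions, curves, a, chi).
#' @export
ect_field <- function(X, eps = NULL, directions = NULL, a = NULL) {
  stopifnot(inherits(X, "embedded_complex"))
  if (is.null(directions)) directions <- direction_set(64, X$dimension)
  mpn <- max_point_norm(X)
  if (is.null(a)) a <- 1.05 * mpn
  if (a < mpn) stop("bounding radius a is smaller than the shape's max norm")
  A <- if (is.null(eps)) chain_subset(X) else build_compatible_subset(X, eps)
  curves <- lapply(seq_len(nrow(directions)), function(i) {
    pl_ect(A, directions[i, ])
  })
  chi <- nrow(A$coords) - nrow(A$E)
  structure(list(directions = directions, curves = curves, a = a, chi = chi),
            class = "ect_field")
}

#' @export
print.ect_field <- function(x, ...) {
  cat("<ect_field>", nrow(x$directions), "directions | a =",
      format(x$a), "| chi =", x$chi, "\n")
  invisible(x)
}

# internal: check two fields share a direction grid; return common radius
common_frame <- function(E1, E2) {
  if (!isTRUE(all.equal(unclass(E1$directions), unclass(E2$directions),
                        tolerance = 1e-12))) {
    stop("fields must share the same direction set")
  }
  max(E1$a, E2$a)
}

#' Distance between two ECT fields
#'
#' Maximum over the (shared) direction grid of the exact L1 distance between
#' the two directional step functions over `[-a, a]`, where `a` is the larger
#' of the two bounding radii (step functions are constant beyond their own
#' bound, so re-bounding is exact). The max over a finite grid under-estimates
#' the supremum over the whole sphere.
#'
#' @param E1,E2 [ect_field()]s over the same direction set.
#' @return nonnegative scalar.
#' @export
ect_distance <- function(E1, E2) {
  a <- common_frame(E1, E2)
  d <- 0
  for (i in seq_along(E1$curves)) {
    d <- max(d, step_l1_distance(E1$curves[[i]], E2$curves[[i]], -a, a))
  }
  d
}

## ---- SECT -------------------------------------------------------------------

#' Smooth Euler characteristic transform from an ECT field
#'
#' Per direction, integrates the Euler characteristic curve minus its mean
#' over `[-a, a]` exactly; the result is piecewise linear with knots at the
#' step breakpoints and vanishes at both endpoints.
#'
#' @param E an [ect_field()].
#' @return object of class `sect_field`: list(directions, curves of
#'   [pl_function()], a).
#' @export
sect_from_ect <- function(E) {
  a <- E$a
  curves <- lapply(E$curves, function(sf) {
    ks <- sort(unique(c(-a, a, sf$breakpoints[sf$breakpoints > -a &
                                              sf$breakpoints < a])))
    left <- ks[-length(ks)]
    seg <- step_eval(sf, left) * diff(ks)
    total <- sum(seg)
    mean_ecc <- total / (2 * a)
    vals <- c(0, cumsum(seg - mean_ecc * diff(ks)))
    vals[length(vals)] <- 0  # exact by construction; clear rounding residue
    pl_function(ks, vals)
  })
  structure(list(directions = E$directions, curves = curves, a = a),
            class = "sect_field")
}

#' Distance between two SECT fields
#'
#' Maximum over directions of the exact L1 distance of the piecewise-linear
#' directional SECT curves.
#'
#' @param S1,S2 `sect_field`s (from [sect_from_ect()]) over the same
#'   direction set and radius.
#' @return nonnegative scalar.
#' @export
sect_distance <- function(S1, S2) {
  if (!isTRUE(all.equal(unclass(S1$directions), unclass(S2$directions),
                        tolerance = 1e-12))) {
    stop("fields must share the same direction set")
  }
  if (abs(S1$a - S2$a) > 1e-9) stop("SECT fields must share the radius a")
  max(vapply(seq_along(S1$curves), function(i) {
    pl_l1_distance(S1$curves[[i]], S2$curves[[i]])
  }, numeric(1)))
}

# L1 norm of one SECT field (max over directions)
sect_norm <- function(S) {
  zero <- pl_function(c(-S$a, S$a), c(0, 0))
  max(vapply(S$curves, function(p) pl_l1_distance(p, zero), numeric(1)))
}

#' Check the gluing identity for Euler characteristic curves
#'
#' When a shape Z is the union of V and W overlapping in a finite vertex set
#' S, inclusion-exclusion of sublevel Euler characteristics gives
#' `ECC_Z = ECC_V + ECC_W - ECC_S` for almost every filtration level. This
#' checks the identity for step functions: equality of interval values
#' everywhere except possibly at the finitely many breakpoints.
#'
#' Floating-point jitter in breakpoint locations is tolerated by measuring the
#' total length where the two sides disagree rather than demanding exact
#' breakpoint coincidence.
#'
#' @param E_V,E_W,E_S,E_Z [step_function()]s on a common interval.
#' @param tol maximal total length of disagreement (default 1e-7).
#' @return TRUE iff `E_Z = E_V + E_W - E_S` almost everywhere.
#' @export
glue_check <- function(E_V, E_W, E_S, E_Z, tol = 1e-7) {
  d <- step_combine(list(E_V, E_W, E_S, E_Z), c(1, 1, -1, -1))
  nb <- length(d$breakpoints)
  if (nb == 0) return(TRUE)
  if (abs(d$values[nb]) > 1e-9) return(FALSE)  # difference must die out
  bad <- abs(d$values[-nb]) > 1e-9
  sum(diff(d$breakpoints)[bad]) < tol
}
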
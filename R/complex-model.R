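#' @keywords internal
"_PACKAGE"

## ---- domain types -----------------------------------------------------------

#' Combinatorial structure of a finite one-dimensional CW complex
#'
#' A CW structure records the 0-cells (vertices) and 1-cells (edges) of a
#' topological graph. Loops (both endpoints equal) and parallel edges are
#' allowed, so the edge list is a multiset indexed by unique edge ids.
#'
#' @param vertex_ids character or integer vector of unique vertex identifiers.
#' @param edges data.frame with columns `edge_id`, `u`, `v` giving, for each
#'   1-cell, its identifier and the two endpoint vertex ids.
#' @return an object of class `cw_structure`.
#' @examples
#' cw_structure("p", data.frame(edge_id = "loop", u = "p", v = "p"))
#' @export
cw_structure <- function(vertex_ids, edges) {
  vertex_ids <- as.character(vertex_ids)
  if (anyDuplicated(vertex_ids)) stop("vertex ids must be unique")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("edge_id", "u", "v") %in% names(edges))) {
    stop("edges must have columns edge_id, u, v")
  }
  edges$edge_id <- as.character(edges$edge_id)
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  if (anyDuplicated(edges$edge_id)) stop("edge ids must be unique")
  bad <- setdiff(c(edges$u, edges$v), vertex_ids)
  if (length(bad)) stop("edge endpoint(s) not in vertex_ids: ",
                        paste(bad, collapse = ", "))
  structure(list(vertex_ids = vertex_ids, edges = edges),
            class = "cw_structure")
}

#' Sampled parametrised curve
#'
#' The discrete stand-in for a C^2 curve: a strictly increasing parameter grid
#' on the unit interval with one d-dimensional point per parameter. All smooth objects in
#' this package are represented by such dense polygonal chains; the
#' piecewise-linear approximation theory (see [pl_approx_bound()]) justifies
#' this with an explicit error bound.
#'
#' @param points numeric matrix (n x d) of sample coordinates, n >= 3.
#' @param params strictly increasing numeric vector in \[0, 1\] with endpoints
#'   0 and 1; defaults to a uniform grid.
#' @return an object of class `sampled_curve` with fields `params`, `points`
#'   and `dimension`.
#' @export
sampled_curve <- function(points, params = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 3) stop("a sampled curve needs at least 3 samples")
  if (!all(is.finite(points))) stop("curve coordinates must be finite")
  if (is.null(params)) params <- seq(0, 1, length.out = n)
  params <- as.numeric(params)
  if (length(params) != n) stop("params and points disagree in length")
  if (any(diff(params) <= 0)) stop("params must be strictly increasing")
  if (abs(params[1]) > 1e-12 || abs(params[n] - 1) > 1e-12) {
    stop("params must start at 0 and end at 1")
  }
  params[1] <- 0; params[n] <- 1
  structure(list(params = params, points = points, dimension = ncol(points)),
            class = "sampled_curve")
}

#' Embedded one-dimensional CW complex
#'
#' Couples a [cw_structure()] with an embedding: coordinates for every vertex
#' and one [sampled_curve()] per edge. Curve endpoints must match the
#' coordinates of the edge's endpoint vertices within `tol`.
#'
#' @param structure a [cw_structure()].
#' @param vertex_coords numeric matrix with one row per vertex, rownames the
#'   vertex ids.
#' @param curves named list of [sampled_curve()]s, names the edge ids.
#' @param tol absolute endpoint-matching tolerance (default 1e-9).
#' @return an object of class `embedded_complex`.
#' @export
embedded_complex <- function(structure, vertex_coords, curves, tol = 1e-9) {
  stopifnot(inherits(structure, "cw_structure"))
  vertex_coords <- as.matrix(vertex_coords)
  storage.mode(vertex_coords) <- "double"
  if (is.null(rownames(vertex_coords))) {
    if (nrow(vertex_coords) != length(structure$vertex_ids)) {
      stop("vertex_coords rows must correspond to vertex_ids")
    }
    rownames(vertex_coords) <- structure$vertex_ids
  }
  if (!setequal(rownames(vertex_coords), structure$vertex_ids)) {
    stop("vertex_coords rownames must equal the structure's vertex ids")
  }
  vertex_coords <- vertex_coords[structure$vertex_ids, , drop = FALSE]
  if (!setequal(names(curves), structure$edges$edge_id)) {
    stop("curves must be named by the structure's edge ids")
  }
  dims <- vapply(curves, function(cu) cu$dimension, integer(1))
  if (length(unique(c(dims, ncol(vertex_coords)))) != 1) {
    stop("all curves and vertex coordinates must share one dimension")
  }
  for (i in seq_len(nrow(structure$edges))) {
    e <- structure$edges[i, ]
    cu <- curves[[e$edge_id]]
    p0 <- cu$points[1, ]; p1 <- cu$points[nrow(cu$points), ]
    if (max(abs(p0 - vertex_coords[e$u, ])) > tol ||
        max(abs(p1 - vertex_coords[e$v, ])) > tol) {
      stop("curve endpoints of edge '", e$edge_id,
           "' do not match its vertex coordinates (tol = ", tol, ")")
    }
  }
  structure(list(structure = structure, vertex_coords = vertex_coords,
                 curves = curves, dimension = ncol(vertex_coords)),
            class = "embedded_complex")
}

#' @export
print.embedded_complex <- function(x, ...) {
  cat("<embedded_complex> d =", x$dimension, "|",
      length(x$structure$vertex_ids), "vertices,",
      nrow(x$structure$edges), "edges\n")
  invisible(x)
}

## ---- geometry of sampled curves --------------------------------------------

#' Polygonal arc length of a sampled curve
#'
#' Sum of Euclidean segment lengths of the sample chain; converges to the
#' arc length of the underlying curve as the sampling refines.
#'
#' @param curve a [sampled_curve()], or a plain numeric matrix of points.
#' @return nonnegative scalar.
#' @export
arc_length <- function(curve) {
  pts <- if (inherits(curve, "sampled_curve")) curve$points else as.matrix(curve)
  if (nrow(pts) < 2) stop("arc_length needs at least 2 points")
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

# cumulative chain length at each sample (first entry 0)
cumulative_length <- function(pts) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# linear interpolation of the chain at prescribed arc-length positions
interp_at_arclength <- function(pts, s_target) {
  cs <- cumulative_length(pts)
  L <- cs[length(cs)]
  s_target <- pmin(pmax(s_target, 0), L)
  out <- matrix(0, length(s_target), ncol(pts))
  for (j in seq_len(ncol(pts))) {
    out[, j] <- stats::approx(cs, pts[, j], xout = s_target,
                              ties = "ordered")$y
  }
  out
}

#' Constant-velocity resampling of a curve
#'
#' Returns a curve with `n_out` samples at uniform parameters whose points sit
#' at equal arc-length spacing along the input chain, i.e. the discrete
#' analogue of reparametrising to unit speed. The image of the polyline is
#' unchanged up to resampling and the endpoints are preserved exactly.
#'
#' @param curve a [sampled_curve()].
#' @param n_out number of output samples (>= 3).
#' @return a [sampled_curve()] with constant discrete speed.
#' @export
reparam_constant_velocity <- function(curve, n_out) {
  stopifnot(inherits(curve, "sampled_curve"), n_out >= 3)
  pts <- curve$points
  L <- arc_length(curve)
  if (L <= 0) stop("cannot reparametrise a zero-length (degenerate) curve")
  s <- seq(0, L, length.out = n_out)
  out <- interp_at_arclength(pts, s)
  out[1, ] <- pts[1, ]
  out[n_out, ] <- pts[nrow(pts), ]
  sampled_curve(out)
}

#' Maximum curvature estimate of a sampled curve
#'
#' Estimates the supremum of the curvature (the norm of the second derivative
#' under the arc-length parametrisation) by second-order central differences
#' on an arc-length-uniform resampling with spacing `L / max(200, n)`;
#' one-sided second differences are used at the chain ends. This is the
#' quantity `M` that controls all stability bounds in this package.
#'
#' @param curve a [sampled_curve()] with at least 5 samples.
#' @return nonnegative scalar estimate of the curvature bound.
#' @export
curvature_max <- function(curve) {
  stopifnot(inherits(curve, "sampled_curve"))
  n <- nrow(curve$points)
  if (n < 5) stop("curvature estimation needs at least 5 samples")
  m <- max(200, n)
  rc <- reparam_constant_velocity(curve, m)
  pts <- rc$points
  h <- arc_length(rc) / (m - 1)
  # stride the stencil so its span stays well above the input resolution:
  # second differences at the raw spacing amplify the chord "sawtooth" of the
  # underlying polyline into an O(1) relative error
  s <- max(1L, as.integer(floor(m / 400)))
  hs <- s * h
  i <- (s + 1):(m - s)
  dd <- pts[i + s, , drop = FALSE] - 2 * pts[i, , drop = FALSE] +
    pts[i - s, , drop = FALSE]
  kappa <- sqrt(rowSums(dd^2)) / hs^2
  # one-sided at the boundary (same stencil anchored at the first/last triple)
  k0 <- sqrt(sum((pts[1 + 2 * s, ] - 2 * pts[1 + s, ] + pts[1, ])^2)) / hs^2
  k1 <- sqrt(sum((pts[m, ] - 2 * pts[m - s, ] + pts[m - 2 * s, ])^2)) / hs^2
  max(kappa, k0, k1)
}

#' Discrete total variation of a directional projection
#'
#' For a unit direction `v`, computes the total variation of the projection
#' `t -> <v, curve(t)>` as the sum of absolute successive differences of the
#' projected samples. The L1 mass of an Euler characteristic curve between the
#' directional minimum and maximum is bounded above by this quantity.
#'
#' @param curve a [sampled_curve()].
#' @param v unit vector (checked to 1e-9).
#' @return nonnegative scalar.
#' @export
directional_variation <- function(curve, v) {
  stopifnot(inherits(curve, "sampled_curve"))
  v <- as.numeric(v)
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9) stop("v must be a unit vector")
  p <- drop(curve$points %*% v)
  sum(abs(diff(p)))
}

#' Hausdorff distance between two point samples
#'
#' Symmetric max-min Euclidean distance over the sample points:
#' `max(max_a min_b |a-b|, max_b min_a |a-b|)`.
#'
#' @param A,B numeric matrices of points (rows), or [sampled_curve()]s.
#' @return nonnegative scalar.
#' @export
hausdorff_distance <- function(A, B) {
  A <- if (inherits(A, "sampled_curve")) A$points else as.matrix(A)
  B <- if (inherits(B, "sampled_curve")) B$points else as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("hausdorff_distance needs nonempty inputs")
  # squared cross-distances via the usual expansion
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  cross <- outer(aa, bb, "+") - 2 * A %*% t(B)
  cross[cross < 0] <- 0
  d_ab <- max(sqrt(apply(cross, 1, min)))
  d_ba <- max(sqrt(apply(cross, 2, min)))
  max(d_ab, d_ba)
}

#' Upper estimate of the embedding metric between two complexes
#'
#' The metric on embeddings of a fixed CW structure combines the sup-distance
#' of constant-velocity representatives with per-edge arc-length differences.
#' The true metric is an infimum over all pairs of parametrising
#' homeomorphisms, which is not computable; this function fixes the edge
#' correspondence supplied by the caller, reparametrises every paired curve to
#' constant velocity on a common grid, tries both orientations of each pairing
#' and keeps the better, and returns
#' `max(sup-norm of pointwise differences, max |arc-length difference|)` --
#' an upper estimate of the metric.
#'
#' @param X,Y [embedded_complex()]es of the same dimension.
#' @param correspondence named character vector mapping X edge ids to Y edge
#'   ids; defaults to the identity on shared edge ids.
#' @param n_grid number of comparison samples per edge (default 512).
#' @return nonnegative scalar upper estimate.
#' @export
cw_distance_upper <- function(X, Y, correspondence = NULL, n_grid = 512) {
  stopifnot(inherits(X, "embedded_complex"), inherits(Y, "embedded_complex"))
  if (X$dimension != Y$dimension) stop("complexes must share dimension")
  ex <- X$structure$edges$edge_id
  if (is.null(correspondence)) {
    if (!setequal(ex, Y$structure$edges$edge_id)) {
      stop("no correspondence supplied and edge ids differ")
    }
    correspondence <- stats::setNames(ex, ex)
  }
  if (!setequal(names(correspondence), ex) ||
      !setequal(correspondence, Y$structure$edges$edge_id)) {
    stop("correspondence must biject X edges onto Y edges")
  }
  is_loop <- function(S, id) {
    e <- S$structure$edges[S$structure$edges$edge_id == id, ]
    identical(e$u, e$v)
  }
  for (eid in ex) {
    if (is_loop(X, eid) != is_loop(Y, correspondence[[eid]])) {
      stop("structure mismatch: edge '", eid,
           "' pairs a loop with a non-loop edge")
    }
  }
  sup_d <- 0; len_d <- 0
  for (eid in ex) {
    cx <- reparam_constant_velocity(X$curves[[eid]], n_grid)
    cy <- reparam_constant_velocity(Y$curves[[correspondence[[eid]]]], n_grid)
    len_d <- max(len_d, abs(arc_length(cx) - arc_length(cy)))
    fwd <- max(sqrt(rowSums((cx$points - cy$points)^2)))
    rev_pts <- cy$points[n_grid:1, , drop = FALSE]
    bwd <- max(sqrt(rowSums((cx$points - rev_pts)^2)))
    sup_d <- max(sup_d, min(fwd, bwd))
  }
  max(sup_d, len_d)
}

# maximum point norm over an embedded complex (vertices + all curve samples)
max_point_norm <- function(X) {
  m <- max(sqrt(rowSums(X$vertex_coords^2)))
  for (cu in X$curves) m <- max(m, max(sqrt(rowSums(cu$points^2))))
  m
}
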
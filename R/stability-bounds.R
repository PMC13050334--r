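## Closed-form stability bounds for the ECT of embedded one-dimensional
## shapes. The central result: if two embeddings of the same complex are
## within eps in the embedding metric (sup-distance + arc-length differences
## of constant-velocity representatives) and one has curvature bounded by M,
## their ECT distance is at most |Z0|*eps + sum_over_edges G(eps), where each
## edge is conceptually split into n near-straight pieces.

#' Number of near-straight pieces for one edge
#'
#' `max(ceil((M^2 L^3 / (24 eps))^(1/3)), ceil(L M / pi))`, floored at 1 so
#' that straight edges (M = 0) are handled.
#'
#' @param M curvature bound (>= 0).
#' @param L edge arc length (> 0).
#' @param eps perturbation size (> 0).
#' @return positive integer.
#' @export
edge_subdivision_count <- function(M, L, eps) {
  if (eps <= 0 || L <= 0 || M < 0) stop("need eps > 0, L > 0, M >= 0")
  as.integer(max(1, ceiling((M^2 * L^3 / (24 * eps))^(1 / 3)),
                 ceiling(L * M / pi)))
}

#' Per-edge stability term G(eps)
#'
#' `8*sqrt(L*n*eps) + n*eps` when `L/n > 2*eps`, else `11*n*eps`. Branch
#' predicates are strict exactly as in the bound's statement; at equality the
#' second branch applies.
#'
#' @param eps perturbation size (> 0).
#' @param L edge arc length (> 0).
#' @param n number of pieces (>= 1), e.g. from [edge_subdivision_count()].
#' @return positive scalar.
#' @export
edge_stability_term <- function(eps, L, n) {
  if (eps <= 0 || L <= 0 || n < 1) stop("need eps > 0, L > 0, n >= 1")
  if (L / n > 2 * eps) 8 * sqrt(L * n * eps) + n * eps else 11 * n * eps
}

#' ECT stability bound for an embedded complex
#'
#' Evaluates `|Z0|*eps + sum_lambda G_lambda(eps)` with the per-edge piece
#' counts computed from the curvature bound.
#'
#' @param M curvature bound of the reference embedding.
#' @param lengths numeric vector of per-edge arc lengths.
#' @param eps bound on the embedding metric between the two shapes.
#' @param n_vertices number of 0-cells |Z0|.
#' @return positive scalar bound on the ECT distance.
#' @export
ect_stability_bound <- function(M, lengths, eps, n_vertices) {
  if (n_vertices < 0) stop("n_vertices must be nonnegative")
  g <- vapply(lengths, function(L) {
    edge_stability_term(eps, L, edge_subdivision_count(M, L, eps))
  }, numeric(1))
  n_vertices * eps + sum(g)
}

#' Near-straight-curve ECT bound
#'
#' For a curve within eps of a straight chord of length L (arc length at most
#' L + eps, competitor arc length at most L + 2*eps), the ECT distance is at
#' most `8*sqrt(L*eps)` when `L > 2*eps` and `10*eps` otherwise.
#'
#' @param L chord length (> 0).
#' @param eps perturbation size (> 0).
#' @return positive scalar.
#' @export
near_straight_bound <- function(L, eps) {
  if (L <= 0 || eps <= 0) stop("need L > 0 and eps > 0")
  if (L > 2 * eps) 8 * sqrt(L * eps) else 10 * eps
}

#' Directional stability envelope f(theta)
#'
#' The four-term function of the angle theta between the chord and the
#' filtration hyperplane whose maximum over theta gives the near-straight
#' bound:
#' `sqrt((L+2e)^2 - max(0, L|cos| - 2e)^2) + sqrt((L+e)^2 - L^2 cos^2)
#'  - 2*max(0, L|sin| - 2e) + max(0, e - L|sin|)`.
#' Satisfies `f(-theta) = f(theta)` and `f(pi/2 - theta) = f(theta)`.
#'
#' @param theta numeric vector of angles (any reals).
#' @param L chord length.
#' @param eps perturbation size.
#' @return numeric vector of envelope values.
#' @export
stability_envelope <- function(theta, L, eps) {
  co <- abs(cos(theta)); si <- abs(sin(theta))
  sqrt((L + 2 * eps)^2 - pmax(0, L * co - 2 * eps)^2) +
    sqrt((L + eps)^2 - L^2 * co^2) -
    2 * pmax(0, L * si - 2 * eps) +
    pmax(0, eps - L * si)
}

#' Chord-length lower bound under a curvature constraint
#'
#' A unit-speed curve with curvature at most M cannot shortcut: over an arc of
#' length eps < pi/M, the chord between the endpoints is at least
#' `(2/M) * sin(M*eps/2)`, with equality on the circle of radius 1/M. A
#' slightly weaker polynomial form `eps - M^2 eps^3 / 24` is also returned.
#'
#' @param M curvature bound (> 0).
#' @param eps arc length, with `0 < eps < pi/M`.
#' @return list with elements `chord` (the sine bound) and `poly` (the cubic
#'   companion bound).
#' @export
chord_lower_bound <- function(M, eps) {
  if (M <= 0) stop("M must be positive (straight curves have chord = arc)")
  if (eps <= 0 || eps >= pi / M) {
    stop("eps must satisfy 0 < eps < pi/M")
  }
  list(chord = (2 / M) * sin(M * eps / 2),
       poly = eps - M^2 * eps^3 / 24)
}

#' Piecewise-linear interpolation error bound for the ECT
#'
#' For a shape of total arc length L and curvature bound M, the ECT of its
#' chord interpolation on an eps-dense compatible subset differs from the true
#' ECT by at most `M * L * eps / sqrt(12)`.
#'
#' @param M curvature bound (>= 0).
#' @param L total arc length.
#' @param eps subdivision density, with `eps < pi/M` when `M > 0`.
#' @return nonnegative scalar.
#' @export
pl_approx_bound <- function(M, L, eps) {
  if (eps <= 0 || L <= 0 || M < 0) stop("need eps > 0, L > 0, M >= 0")
  if (M > 0 && eps >= pi / M) stop("eps must satisfy eps < pi/M")
  M * L * eps / sqrt(12)
}

#' SECT-to-ECT Lipschitz factor
#'
#' If two shapes' ECTs on `[-a, a]` are delta apart, their SECTs are at most
#' `(2a + 1) * delta` apart.
#'
#' @param a bounding radius (> 0).
#' @return the factor `2a + 1`.
#' @export
sect_lipschitz_factor <- function(a) {
  if (a <= 0) stop("a must be positive")
  2 * a + 1
}

#' Evaluate all stability-bound quantities at once
#'
#' @param M curvature bound.
#' @param lengths per-edge arc lengths.
#' @param eps perturbation / subdivision size.
#' @param n_vertices number of 0-cells.
#' @param a optional bounding radius for the SECT factor.
#' @return a list (class `bound_report`) with per-edge piece counts and
#'   stability terms, the total ECT stability bound, the PL interpolation
#'   bound, the near-straight bound per edge, and the SECT factor.
#' @export
bound_report <- function(M, lengths, eps, n_vertices, a = NULL) {
  n_l <- vapply(lengths, edge_subdivision_count, integer(1), M = M, eps = eps)
  g_l <- mapply(edge_stability_term, L = lengths, n = n_l,
                MoreArgs = list(eps = eps))
  rep <- list(M = M, lengths = lengths, eps = eps, n_vertices = n_vertices,
              n_lambda = n_l, G_lambda = as.numeric(g_l),
              stability_bound = n_vertices * eps + sum(g_l),
              pl_bound = if (M == 0 || eps < pi / M)
                pl_approx_bound(M, sum(lengths), eps) else NA_real_,
              near_straight = vapply(lengths, near_straight_bound,
                                     numeric(1), eps = eps),
              sect_factor = if (!is.null(a)) sect_lipschitz_factor(a) else NULL)
  class(rep) <- "bound_report"
  rep
}

#' @export
print.bound_report <- function(x, ...) {
  cat("<bound_report> eps =", format(x$eps), " M =", format(x$M), "\n")
  cat("  per-edge pieces:", paste(x$n_lambda, collapse = ", "), "\n")
  cat("  stability bound:", format(x$stability_bound), "\n")
  if (!is.na(x$pl_bound)) cat("  PL interpolation bound:", format(x$pl_bound), "\n")
  invisible(x)
}
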
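## Exact piecewise-constant and piecewise-linear function arithmetic.
## Step functions carry Euler characteristic curves: right-continuous, value 0
## before the first breakpoint, `values[i]` on [breakpoints[i], breakpoints[i+1])
## and `values[last]` from the final breakpoint on. All integrals and L1
## distances are computed exactly by breakpoint merging -- no quadrature.

#' Right-continuous step function
#'
#' @param breakpoints strictly increasing numeric vector.
#' @param values numeric vector of the same length; `values[i]` is the value
#'   on `[breakpoints[i], breakpoints[i+1])`. The function is 0 before the
#'   first breakpoint (the empty sublevel set has Euler characteristic 0).
#' @return an object of class `step_function`.
#' @export
step_function <- function(breakpoints, values) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.numeric(values)
  if (length(breakpoints) != length(values)) {
    stop("breakpoints and values must have equal length")
  }
  if (length(breakpoints) && any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing")
  }
  structure(list(breakpoints = breakpoints, values = values),
            class = "step_function")
}

# step function built from (location, jump) pairs; equal locations are merged
# exactly and zero net jumps dropped, so ties at symmetric shapes are handled
# without perturbation.
step_from_jumps <- function(locations, jumps) {
  o <- order(locations)
  locations <- locations[o]; jumps <- jumps[o]
  grp <- c(TRUE, diff(locations) > 0)
  idx <- cumsum(grp)
  locs <- locations[grp]
  js <- as.numeric(rowsum(jumps, idx))
  keep <- js != 0
  # values are cumulative sums of the (merged) jumps
  vals <- cumsum(js[keep])
  # consecutive equal values can appear when a kept jump is cancelled later;
  # they are harmless but we compact them for canonical form
  locs <- locs[keep]
  if (length(locs) == 0) return(step_function(numeric(0), numeric(0)))
  dup <- c(TRUE, diff(c(0, vals))[-1] != 0)
  step_function(locs[dup], vals[dup])
}

#' Evaluate a step function
#'
#' @param sf a [step_function()].
#' @param t numeric vector of evaluation points.
#' @return numeric vector of values (0 left of the first breakpoint).
#' @export
step_eval <- function(sf, t) {
  idx <- findInterval(t, sf$breakpoints)
  c(0, sf$values)[idx + 1]
}

# linear combination sum_i w_i * sf_i, exact, via merged breakpoints
step_combine <- function(sfs, weights = rep(1, length(sfs))) {
  locs <- unlist(lapply(sfs, `[[`, "breakpoints"))
  jumps <- unlist(mapply(function(sf, w) w * diff(c(0, sf$values)),
                         sfs, weights, SIMPLIFY = FALSE))
  step_from_jumps(locs, jumps)
}

# exact integral of |sf1 - sf2| over [lo, hi]
step_l1_distance <- function(sf1, sf2, lo, hi) {
  stopifnot(hi > lo)
  cuts <- sort(unique(c(lo, hi,
                        sf1$breakpoints[sf1$breakpoints > lo & sf1$breakpoints < hi],
                        sf2$breakpoints[sf2$breakpoints > lo & sf2$breakpoints < hi])))
  left <- cuts[-length(cuts)]
  width <- diff(cuts)
  sum(abs(step_eval(sf1, left) - step_eval(sf2, left)) * width)
}

# exact integral of sf over [lo, hi]
step_integral <- function(sf, lo, hi) {
  cuts <- sort(unique(c(lo, hi,
                        sf$breakpoints[sf$breakpoints > lo & sf$breakpoints < hi])))
  left <- cuts[-length(cuts)]
  sum(step_eval(sf, left) * diff(cuts))
}

## ---- piecewise-linear functions (SECT curves) -------------------------------

#' Continuous piecewise-linear function
#'
#' Knots with values, linear in between; used for the smooth Euler
#' characteristic transform, which is the integrated, mean-centred ECC.
#'
#' @param knots strictly increasing numeric vector (length >= 2).
#' @param values numeric vector of the same length.
#' @return an object of class `pl_function`.
#' @export
pl_function <- function(knots, values) {
  knots <- as.numeric(knots); values <- as.numeric(values)
  if (length(knots) != length(values) || length(knots) < 2) {
    stop("need matching knots/values of length >= 2")
  }
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = knots, values = values), class = "pl_function")
}

#' Evaluate a piecewise-linear function
#'
#' @param pf a [pl_function()].
#' @param t numeric vector of evaluation points (clamped to the knot range).
#' @return numeric vector of values.
#' @export
pl_eval <- function(pf, t) {
  stats::approx(pf$knots, pf$values, xout = t, rule = 2, ties = "ordered")$y
}

# exact L1 distance of two piecewise-linear functions on the union of their
# knot ranges; the difference is linear between merged knots, so each segment
# integral is computed in closed form, splitting at interior sign changes.
pl_l1_distance <- function(p1, p2) {
  ks <- sort(unique(c(p1$knots, p2$knots)))
  v <- pl_eval(p1, ks) - pl_eval(p2, ks)
  total <- 0
  for (i in seq_len(length(ks) - 1)) {
    a <- v[i]; b <- v[i + 1]; w <- ks[i + 1] - ks[i]
    if (a * b >= 0) {
      total <- total + w * (abs(a) + abs(b)) / 2
    } else {
      # root of the linear interpolant splits the trapezoid into two triangles
      r <- a / (a - b)
      total <- total + w * (r * abs(a) + (1 - r) * abs(b)) / 2
    }
  }
  total
}
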
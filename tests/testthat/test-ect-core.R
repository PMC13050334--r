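test_that("step-function arithmetic and exact L1 distances match a quadrature oracle", {
  s1 <- step_function(c(-1, 0.25, 2), c(1, 3, 0))
  s2 <- step_function(c(-0.5, 1), c(2, 1))
  expect_identical(step_eval(s1, c(-2, -1, 0.3, 5)), c(0, 1, 3, 0))
  # |s1 - s2| piecewise: [-2,-1):0, [-1,-.5):1, [-.5,.25):1, [.25,1):1, [1,2):2, [2,3):1
  expect_equal(ect1d:::step_l1_distance(s1, s2, -2, 3), 0 + 0.5 + 0.75 + 0.75 + 2 + 1)
  expect_identical(ect1d:::step_l1_distance(s1, s1, -2, 3), 0)
  # combine: jump merging keeps values exact under ties
  comb <- ect1d:::step_combine(list(s1, s1, s2), c(1, -1, 1))
  expect_equal(step_eval(comb, c(-0.7, 0, 1.5)), step_eval(s2, c(-0.7, 0, 1.5)))
})

test_that("compatible subsets subdivide edges to the prescribed density", {
  # one vertex + one interior point is the minimal compatible subset of a loop
  A <- build_compatible_subset(make_circle(1, 2000), 7)
  expect_identical(nrow(A$coords), 2L)
  expect_identical(nrow(A$E), 2L)  # two parallel sub-edges
  # equal subdivision: ceil(2*pi / 0.1) = 63 sub-edges
  A <- build_compatible_subset(make_circle(1, 4000), 0.1)
  expect_identical(nrow(A$E), 63L)
  expect_true(all(A$E$length < 0.1))
  # unit segment at eps = 0.3: four sub-edges of length 1/4
  A <- build_compatible_subset(make_segment(n = 101), 0.3)
  expect_identical(nrow(A$E), 4L)
  expect_equal(A$E$length, rep(0.25, 4))
  expect_error(build_compatible_subset(make_circle(1, 100), -1), "positive")
})

test_that("the PL ECT counts vertices minus submerged chords exactly", {
  # triangle: 3 vertices, 3 chords; chi of the full cycle is 0
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  A <- structure(list(coords = tri,
                      E = data.frame(i = 1:3, j = c(2, 3, 1), length = 1)),
                 class = "compatible_subset")
  for (v in list(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))) {
    sf <- pl_ect(A, v)
    expect_identical(step_eval(sf, max(tri %*% v)), 0)
  }
  # segment sampled at x = 0, 0.5, 1; direction (1, 0): 2 vertices - 1 chord at t = 0.6
  seg <- structure(list(coords = cbind(c(0, 0.5, 1), 0),
                        E = data.frame(i = 1:2, j = 2:3, length = 0.5)),
                   class = "compatible_subset")
  sf <- pl_ect(seg, c(1, 0))
  expect_identical(step_eval(sf, 0.6), 1)
  expect_identical(step_eval(sf, -0.01), 0)   # below the minimum projection
  expect_identical(step_eval(sf, 1), 1)       # terminal: chi of the interval
})

test_that("ECT fields have the right boundary and terminal values", {
  E <- ect_field(make_circle(1, 800), eps = 0.2, directions = direction_set(16))
  for (sf in E$curves) {
    expect_identical(step_eval(sf, E$a), 0)        # chi(circle) = 0
    expect_identical(step_eval(sf, -E$a), 0)
    expect_identical(step_eval(sf, 0), 1)          # half circle: an arc
  }
  Eseg <- ect_field(make_segment(n = 64), eps = 0.2,
                    directions = direction_set(16))
  for (sf in Eseg$curves) expect_identical(step_eval(sf, Eseg$a), 1)
  # terminal value equals |A| - |E| for any subdivision
  expect_identical(Eseg$chi, 1L)
  expect_identical(E$chi, 0L)
  expect_error(ect_field(make_circle(1, 100), eps = 0.5, a = 0.5), "radius")
})

test_that("PL circle ECT converges monotonically to the analytic field", {
  # direction count coprime to the subdivision counts, so no direction
  # accidentally aligns with a subdivision vertex
  dirs <- direction_set(37)
  ref <- analytic_circle_ect(1, dirs, a = 1.05)
  eps_seq <- c(0.4, 0.2, 0.1, 0.05)
  d <- vapply(eps_seq, function(eps) {
    ect_distance(ect_field(make_circle(1, 6000), eps = eps,
                           directions = dirs, a = 1.05), ref)
  }, numeric(1))
  expect_true(all(diff(d) <= 1e-12))
  # each within the PL interpolation bound M * L * eps / sqrt(12)
  bounds <- vapply(eps_seq, pl_approx_bound, numeric(1), M = 1, L = 2 * pi)
  expect_true(all(d <= bounds))
})

test_that("ECT distance separates the wave from the line but Hausdorff does not", {
  wl <- make_wave_and_line(0.05)
  Aw <- ect1d:::chain_subset(wl$wave)
  Al <- ect1d:::chain_subset(wl$line)
  ew <- pl_ect(Aw, c(0, 1)); el <- pl_ect(Al, c(0, 1))
  expect_gte(ect1d:::step_l1_distance(ew, el, -1.2, 1.2), 1)
  expect_lte(hausdorff_distance(
    reparam_constant_velocity(wl$line$curves$e1, 2000),
    wl$wave$curves$e1), 0.06)
  # boundary case: large amplitude, few oscillations, still computable
  wl2 <- make_wave_and_line(0.49, oscillations = 2)
  expect_gte(ect1d:::step_l1_distance(
    pl_ect(ect1d:::chain_subset(wl2$wave), c(0, 1)),
    pl_ect(ect1d:::chain_subset(wl2$line), c(0, 1)), -1.5, 1.5), 0)
})

test_that("degenerate one-point shapes separate by their offset in the direction grid", {
  p1 <- structure(list(coords = rbind(c(0, 0)),
                       E = data.frame(i = integer(0), j = integer(0),
                                      length = numeric(0))),
                  class = "compatible_subset")
  p2 <- structure(list(coords = rbind(c(0.3, 0)),
                       E = p1$E), class = "compatible_subset")
  dirs <- direction_set(8)  # includes (1, 0)
  d <- max(vapply(seq_len(8), function(i) {
    ect1d:::step_l1_distance(pl_ect(p1, dirs[i, ]), pl_ect(p2, dirs[i, ]),
                             -1, 1)
  }, numeric(1)))
  expect_equal(d, 0.3, tolerance = 1e-12)
})

test_that("SECT integrates the mean-centred ECC exactly and vanishes at both ends", {
  # single point at the origin, a = 1: ECC = 1_{t >= 0}, mean 1/2
  Ep <- structure(list(directions = direction_set(4),
                       curves = replicate(4, step_function(0, 1),
                                          simplify = FALSE),
                       a = 1, chi = 1), class = "ect_field")
  S <- sect_from_ect(Ep)
  expect_equal(pl_eval(S$curves[[1]], 0), -0.5)
  expect_equal(pl_eval(S$curves[[1]], c(-1, 1)), c(0, 0))
  expect_equal(pl_eval(S$curves[[1]], -0.5), -0.25)

  # all-zero ECT gives an all-zero SECT
  E0 <- structure(list(directions = direction_set(4),
                       curves = replicate(4, step_function(numeric(0), numeric(0)),
                                          simplify = FALSE),
                       a = 1, chi = 0), class = "ect_field")
  S0 <- sect_from_ect(E0)
  expect_true(all(vapply(S0$curves, function(p) max(abs(p$values)), numeric(1)) == 0))

  # endpoints vanish for a real shape
  E <- ect_field(random_fourier(9, n = 300), eps = 0.1,
                 directions = direction_set(16))
  S <- sect_from_ect(E)
  for (p in S$curves) {
    expect_equal(p$values[1], 0)
    expect_equal(p$values[length(p$values)], 0)
  }
})

test_that("SECT distances are exact: scaling and quadrature oracle", {
  E <- ect_field(random_fourier(10, n = 300), eps = 0.15,
                 directions = direction_set(8))
  S <- sect_from_ect(E)
  S2 <- S
  S2$curves <- lapply(S$curves, function(p) pl_function(p$knots, 2 * p$values))
  expect_equal(sect_distance(S, S2), ect1d:::sect_norm(S), tolerance = 1e-12)

  F2 <- ect_field(make_circle(0.8, 300), eps = 0.15,
                  directions = direction_set(8), a = E$a)
  T2 <- sect_from_ect(F2)
  d_exact <- sect_distance(S, T2)
  d_quad <- max(vapply(1:8, function(i) {
    pl_l1_quadrature(S$curves[[i]], T2$curves[[i]])
  }, numeric(1)))
  expect_equal(d_exact, d_quad, tolerance = 1e-6)
})

test_that("gluing identity holds a.e. for split segments and split circles", {
  # V = W = S = Z = a single point: 1 = 1 + 1 - 1
  pt <- step_function(0, 1)
  expect_true(glue_check(pt, pt, pt, pt))

  # two segments glued at a shared endpoint vs their union
  dirs <- direction_set(8)
  segA <- cbind(seq(0, 0.5, length.out = 26), 0.3 * seq(0, 0.5, length.out = 26))
  segB <- cbind(seq(0.5, 1, length.out = 26),
                0.15 + 0.1 * (seq(0.5, 1, length.out = 26) - 0.5))
  whole <- rbind(segA, segB[-1, ])
  for (i in seq_len(8)) {
    v <- dirs[i, ]
    EV <- pl_ect(ect1d:::chain_subset_curve(sampled_curve(segA)), v)
    EW <- pl_ect(ect1d:::chain_subset_curve(sampled_curve(segB)), v)
    ES <- ect1d:::step_from_jumps(sum(segA[26, ] * v), 1)
    EZ <- pl_ect(ect1d:::chain_subset_curve(sampled_curve(whole)), v)
    expect_true(glue_check(EV, EW, ES, EZ))
  }

  # circle split into two arcs glued at two points
  th1 <- seq(0, pi, length.out = 101); th2 <- seq(pi, 2 * pi, length.out = 101)
  arc <- function(th) cbind(cos(th), sin(th))
  for (i in seq_len(8)) {
    v <- dirs[i, ]
    EV <- pl_ect(ect1d:::chain_subset_curve(sampled_curve(arc(th1))), v)
    EW <- pl_ect(ect1d:::chain_subset_curve(sampled_curve(arc(th2))), v)
    ES <- ect1d:::step_from_jumps(drop(rbind(c(1, 0), c(-1, 0)) %*% v), c(1, 1))
    EZ <- pl_ect(ect1d:::chain_subset(make_circle(1, 201)), v)
    expect_true(glue_check(EV, EW, ES, EZ))
  }
})

test_that("segment decomposition: PL ECT equals chord ECTs minus weighted point ECTs", {
  # independent right-hand-side implementation: sum over chords of the ECT of
  # a segment (1 from min projection on) minus (degree - 1) point ECTs
  rhs_ect <- function(A, v) {
    p <- drop(A$coords %*% v)
    chord_locs <- pmin(p[A$E$i], p[A$E$j])
    deg <- tabulate(c(A$E$i, A$E$j), nbins = nrow(A$coords))
    ect1d:::step_combine(list(
      ect1d:::step_from_jumps(chord_locs, rep(1, length(chord_locs))),
      ect1d:::step_from_jumps(p, deg - 1)), c(1, -1))
  }
  set.seed(99)
  shapes <- list(build_compatible_subset(random_fourier(12, n = 300), 0.4),
                 build_compatible_subset(make_segment(n = 40), 0.21),
                 build_compatible_subset(make_circle(1.3, 300), 0.5))
  dirs <- direction_set(16)
  for (A in shapes) {
    for (i in seq_len(16)) {
      v <- dirs[i, ]
      lhs <- pl_ect(A, v)
      rhs <- rhs_ect(A, v)
      dd <- ect1d:::step_combine(list(lhs, rhs), c(1, -1))
      expect_true(length(dd$values) == 0 || all(abs(dd$values) < 1e-9))
    }
  }
})

test_that("ECCs are equivariant under joint rotation of shape and directions", {
  X <- random_fourier(13, n = 250)
  dirs <- direction_set(12)
  E1 <- ect_field(X, eps = 0.2, directions = dirs, a = 2)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Xr_curves <- lapply(X$curves, function(cu) sampled_curve(cu$points %*% t(R), cu$params))
  Xr <- embedded_complex(X$structure, X$vertex_coords %*% t(R), Xr_curves)
  dirs_r <- structure(unclass(dirs) %*% t(R), class = class(dirs))
  E2 <- ect_field(Xr, eps = 0.2, directions = dirs_r, a = 2)
  disagreement_measure <- function(dd) {
    nb <- length(dd$breakpoints)
    if (nb < 2) return(0)
    sum(diff(dd$breakpoints)[abs(dd$values[-nb]) > 1e-9])
  }
  for (i in seq_len(12)) {
    dd <- ect1d:::step_combine(list(E1$curves[[i]], E2$curves[[i]]), c(1, -1))
    # rotation only jitters breakpoint locations at machine precision
    if (length(dd$values)) expect_lt(abs(dd$values[length(dd$values)]), 1e-9)
    expect_lt(disagreement_measure(dd), 1e-7)
  }
})

test_that("the L1 mass of an ECC is bounded by the directional variation", {
  set.seed(7)
  for (s in 1:25) {
    cu <- if (s %% 2) random_open_curve(s) else random_fourier(s, n = 250)$curves$e1
    A <- ect1d:::chain_subset_curve(cu, loop = s %% 2 == 0)
    for (r in 1:2) {
      v <- random_direction()
      sf <- pl_ect(A, v)
      p <- drop(A$coords %*% v)
      mass <- ect1d:::step_l1_distance(sf, step_function(numeric(0), numeric(0)),
                                       min(p), max(p))
      expect_lte(mass, directional_variation(cu, v) + 1e-9)
    }
  }
})
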
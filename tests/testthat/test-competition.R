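test_that("layer gate admits pairs within 2 m of vertical separation", {
  expect_true(layer_gate(3.0, 4.9))
  expect_false(layer_gate(3.0, 5.1))
  for (x in c(0, 0.5, 7)) expect_true(layer_gate(x, x))
  expect_true(layer_gate(1, 3))          # boundary included
  expect_error(layer_gate(-1, 2), "nonnegative")
})

test_that("disc overlap area covers all three regimes with the right values", {
  expect_equal(pair_overlap_area(1, 1, 2), 0)            # tangent
  expect_equal(pair_overlap_area(1, 1, 5), 0)            # disjoint
  expect_equal(pair_overlap_area(1, 0.5, 0.1), pi * 0.25)  # contained
  expect_equal(pair_overlap_area(0.5, 1, 0.1), pi * 0.25)  # smaller subject
  expect_equal(pair_overlap_area(1, 1, 1), 2 * pi / 3 - sqrt(3) / 2,
               tolerance = 1e-12)                          # symmetric lens
  expect_equal(pair_overlap_area(2, 2, 0), pi * 4)         # concentric
  expect_error(pair_overlap_area(-1, 1, 1), "nonnegative")
})

test_that("overlap area is symmetric, bounded, and continuous across regimes", {
  set.seed(31)
  r1 <- runif(1000, 0, 4); r2 <- runif(1000, 0, 4)
  d <- runif(1000, 0, 9)
  a12 <- pair_overlap_area(r1, r2, d)
  a21 <- pair_overlap_area(r2, r1, d)
  expect_equal(a12, a21, tolerance = 1e-12)
  expect_true(all(a12 <= pi * pmin(r1, r2)^2 + 1e-12))
  expect_true(all(a12 >= 0))
  # continuity: the lens formula meets the disjoint and containment limits
  at_outer <- pair_overlap_area(r1, r2, r1 + r2)
  expect_true(all(abs(at_outer) < 1e-6))
  at_inner <- pair_overlap_area(r1, r2, abs(r1 - r2))
  expect_true(all(abs(at_inner - pi * pmin(r1, r2)^2) < 1e-6))
})

test_that("overlap area agrees with Monte-Carlo estimates", {
  set.seed(32)
  for (i in 1:12) {
    r1 <- runif(1, 0.3, 3); r2 <- runif(1, 0.3, 3)
    d <- runif(1, 0, (r1 + r2) * 1.1)
    exact <- pair_overlap_area(r1, r2, d)
    mc <- mc_overlap_area(r1, r2, d, n_samples = 1e6)
    if (exact > 0.05) expect_lt(abs(mc - exact) / exact, 0.02)
    else expect_lt(abs(mc - exact), 0.01)
  }
})

make_layers <- function(lcl, base_cr, beta = 0.6) {
  k <- 1:10
  list(ch = 0.1 * k * lcl, cr = base_cr * (0.1 * k)^beta)
}

test_that("total overlap sums gated pairs and scales like an area", {
  subject <- make_layers(5, 1)
  expect_equal(total_overlap(subject, list(), 5), 0)   # no competitors
  # one competitor with exactly one layer inside the gate
  comp <- list(ch = c(0.4, 100, 200, 300, 400, 500, 600, 700, 800, 900),
               cr = c(1, rep(1, 9)), dist = 1)
  subject2 <- list(ch = rep(1, 10), cr = rep(1, 10))
  ao <- total_overlap(subject2, list(comp), 1)
  expect_equal(ao, 2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-9)
  # doubling radii and distance quadruples the total overlap
  subject3 <- make_layers(6, 1.2)
  comp3 <- list(ch = make_layers(5.5, 1)$ch, cr = make_layers(5.5, 1)$cr,
                dist = 1.5)
  ao1 <- total_overlap(subject3, list(comp3), 7)
  comp3x2 <- list(ch = comp3$ch, cr = 2 * comp3$cr, dist = 3)
  subject3x2 <- list(ch = subject3$ch, cr = 2 * subject3$cr)
  expect_equal(total_overlap(subject3x2, list(comp3x2), 7), 4 * ao1,
               tolerance = 1e-12)
  # zero-radius competitor layers contribute nothing
  comp0 <- list(ch = comp3$ch, cr = comp3$cr * 0, dist = 0.5)
  expect_equal(total_overlap(subject3, list(comp0), 7), 0)
})

test_that("layer competition index matches hand evaluation and is monotone", {
  expect_equal(cpci(make_layers(5, 1), list(), 4), 0)  # isolated tree
  # two identical trees, one gated layer pair, CR = 1 m, equal CH, dist 1 m
  subject <- list(ch = rep(1, 10), cr = rep(1, 10))
  comp <- list(ch = c(1, rep(1e3, 9)), cr = rep(1, 10), dist = 1)
  expect_equal(cpci(subject, list(comp), 1),
               (2 * pi / 3 - sqrt(3) / 2) / pi, tolerance = 1e-9)
  # growing the competitor radius never decreases the index
  vals <- vapply(seq(0.2, 2.5, by = 0.1), function(rj) {
    comp_r <- list(ch = c(1, rep(1e3, 9)), cr = c(rj, rep(0, 9)), dist = 1)
    cpci(subject, list(comp_r), 1)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  # zero subject radius: index defined as zero
  subject0 <- list(ch = rep(1, 10), cr = rep(0, 10))
  expect_equal(cpci(subject0, list(comp), 1), 0)
})

test_that("directional allocation splits the index as specified", {
  expect_equal(directional_cpci(2, c(1, 1, 1, 1)),
               c(E = 1.5, W = 1.5, S = 1.5, N = 1.5))
  expect_equal(unname(directional_cpci(1, c(2, 1, 1, 0))),
               c(0.5, 0.75, 0.75, 1.0))
  expect_equal(unname(directional_cpci(1, c(0, 0, 0, 0))), rep(0, 4))
  expect_error(directional_cpci(1, c(-1, 1, 1, 1)), "negative")
  # shares always sum to three times the index; larger radii get less
  set.seed(33)
  for (i in 1:50) {
    r <- runif(4, 0, 3)
    cp <- runif(1, 0, 2)
    s <- directional_cpci(cp, r)
    expect_equal(sum(s), 3 * cp, tolerance = 1e-12)
    expect_equal(order(s), order(-r))
  }
})

test_that("stand-level competition table is structurally consistent", {
  stand <- make_test_stand(n_trees = 25L, seed = 9L)
  pr <- crown_profiles(stand)
  tab <- compute_cpci(stand, pr)
  expect_equal(nrow(tab), 25L * 10L)
  expect_true(all(tab$ao_m2 >= 0))
  expect_true(all(tab$cpci >= 0))
  sums <- tab$cpci_E + tab$cpci_W + tab$cpci_S + tab$cpci_N
  expect_equal(sums, 3 * tab$cpci, tolerance = 1e-12)
})
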
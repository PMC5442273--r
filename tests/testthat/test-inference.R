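# helper: trapezoid clipped at 1 — closed-form centroid (moment/area)
trap_centroid <- function(a, b, c, d) {
  pieces <- rbind(
    c((b - a) / 2, (a + 2 * b) / 3),          # rising ramp
    c(c - b, (b + c) / 2),                    # plateau
    c((d - c) / 2, (2 * c + d) / 3)           # falling ramp
  )
  sum(pieces[, 1] * pieces[, 2]) / sum(pieces[, 1])
}

test_that("firing strength is MIN over antecedent degrees", {
  sys <- oral_fis()
  deg <- function(mda, donors) {
    list(MDA = setNames(mda, term_labels),
         DONORS_PROTONS = setNames(donors, term_labels))
  }
  # (FM, fm) rule is #21; degrees 1/1 -> 1
  s <- firing_strengths(sys, deg(c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 0)))
  expect_equal(s[21], 1)
  expect_equal(sum(s > 0), 1)
  s2 <- firing_strengths(sys, deg(c(0, 0, 0, 0, 0.6), c(0.3, 0, 0, 0, 0)))
  expect_equal(s2[21], 0.3)
  s3 <- firing_strengths(sys, deg(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1)))
  expect_equal(s3, rep(0, 25))  # zero antecedent annihilates
  expect_error(firing_strengths(sys, deg(rep(1, 5), rep(1, 5))["MDA"]),
               "missing")
})

test_that("aggregation is pointwise MAX of MIN-clipped consequents", {
  sys <- oral_fis()
  zero <- aggregate_curve(sys, rep(0, 25))
  expect_equal(zero$mu, rep(0, sys$options$resolution))
  # a single fully fired rule reproduces its consequent term exactly
  s <- rep(0, 25); s[21] <- 1  # consequent FM
  one <- aggregate_curve(sys, s)
  expect_equal(one$mu, membership(sys$output$terms$FM, one$x))
  # two adjacent consequents clipped at 0.5: direct dense evaluation
  s2 <- rep(0, 25); s2[21] <- 0.5; s2[23] <- 0.5  # FM and M
  two <- aggregate_curve(sys, s2)
  ref <- pmax(pmin(0.5, membership(sys$output$terms$FM, two$x)),
              pmin(0.5, membership(sys$output$terms$M, two$x)))
  expect_equal(two$mu, ref)
  expect_error(aggregate_curve(sys, rep(0.5, 24)), "one firing strength per rule")
})

test_that("centroid defuzzification matches closed forms and is scale invariant", {
  x <- seq(1, 10, length.out = 100001)
  # symmetric triangle centred at 5.5
  mu_tri <- membership(mf_triangle(4, 5.5, 7), x)
  expect_equal(defuzz_centroid(x, mu_tri), 5.5, tolerance = 1e-6)
  # the default FM risk trapezoid clipped at 1: closed-form moment 9.125
  mu_trap <- membership(mf_trapezoid(7.75, 8.875, 10, 10), x)
  expect_equal(trap_centroid(7.75, 8.875, 10, 10), 9.125)
  expect_equal(defuzz_centroid(x, mu_trap), 9.125, tolerance = 1e-3)
  expect_equal(defuzz_centroid(x, 0.37 * mu_trap),
               defuzz_centroid(x, mu_trap))  # scaling does not move the centroid
  expect_error(defuzz_centroid(x, numeric(length(x))), "no rule fired")
})

test_that("bisector and mean-of-maximum defuzzifiers behave sanely", {
  x <- seq(1, 10, length.out = 10001)
  mu <- membership(mf_triangle(4, 5.5, 7), x)
  expect_equal(defuzz_bisector(x, mu), 5.5, tolerance = 1e-3)
  expect_equal(defuzz_mom(x, mu), 5.5, tolerance = 1e-3)
  sys_mom <- oral_fis(defuzz = "mom")
  r <- risk_score(sys_mom, 6.7, 38.5)$risk
  expect_gte(r, 8.875)  # plateau of the FM risk term
  expect_lte(r, 10)
})

test_that("corner inference fires exactly one rule and hits the FM centroid", {
  sys <- oral_fis()
  tr <- infer(sys, c(MDA = 6.7, DONORS_PROTONS = 38.5))
  expect_equal(sum(tr$firing > 0), 1)
  expect_equal(tr$firing[21], 1)  # (MDA=FM, DONORS=fm) -> RISK=FM
  expect_equal(tr$crisp, trap_centroid(7.75, 8.875, 10, 10), tolerance = 3e-3)
  expect_error(infer(sys, c(MDA = 5)), "missing input")
  expect_error(infer(sys, c(MDA = NaN, DONORS_PROTONS = 40)), "finite")
})

test_that("trace is self-consistent and crisp output stays in the risk universe", {
  sys <- oral_fis()
  pts <- random_inputs(25, seed = 11)
  for (i in seq_len(nrow(pts))) {
    tr <- infer(sys, c(MDA = pts$MDA[i], DONORS_PROTONS = pts$DONORS_PROTONS[i]))
    expect_equal(defuzz_centroid(tr$curve$x, tr$curve$mu), tr$crisp)
    expect_gte(tr$crisp, 1); expect_lte(tr$crisp, 10)
  }
})

test_that("batch inference equals the scalar path", {
  sys <- oral_fis()
  pts <- random_inputs(40, seed = 7)
  batch <- infer_batch(sys, pts, chunk_size = 16L)
  scalar <- vapply(seq_len(nrow(pts)), function(i) {
    infer(sys, c(MDA = pts$MDA[i], DONORS_PROTONS = pts$DONORS_PROTONS[i]))$crisp
  }, numeric(1))
  expect_equal(batch, scalar, tolerance = 1e-12)
  expect_identical(infer_batch(sys, pts[0, ]), numeric(0))
})

test_that("the engine agrees with the brute-force oracle", {
  sys <- oral_fis()
  pts <- random_inputs(30, seed = 2024)
  engine <- infer_batch(sys, pts)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    oracle_infer(sys, pts$MDA[i], pts$DONORS_PROTONS[i])
  }, numeric(1))
  expect_equal(engine, oracle, tolerance = 1e-6)
})

test_that("crisp output converges under grid refinement", {
  pts <- random_inputs(5, seed = 3)
  res_levels <- c(251L, 501L, 1001L, 2001L)
  out <- sapply(res_levels, function(r) infer_batch(oral_fis(resolution = r), pts))
  step <- abs(out[, -1] - out[, -length(res_levels)])
  worst <- apply(step, 2, max)   # max refinement change per doubling
  expect_true(all(worst[-1] <= worst[1]))  # refinement error shrinks
  expect_lt(max(abs(out[, 3] - out[, 4])), 1e-3)  # 1001 vs 2001 within 1e-3
})

test_that("engine options are validated", {
  expect_error(fis_options(resolution = 51), ">= 101")
  expect_error(oral_fis(defuzz = "sugeno"))
})
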
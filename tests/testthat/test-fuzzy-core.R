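test_that("membership evaluation is piecewise linear with closed plateaus", {
  tri <- mf_triangle(0, 1, 2)
  expect_equal(membership(tri, 1), 1)
  expect_equal(membership(tri, 0.25), 0.25) # line through (0,0)-(1,1)
  expect_equal(membership(tri, c(-1, 0, 2, 3)), c(0, 0, 0, 0))
  trap <- mf_trapezoid(0, 1, 3, 4)
  expect_equal(membership(trap, 2), 1)
  expect_equal(membership(trap, c(0.5, 3.5)), c(0.5, 0.5))
  # linearity on the ramps against a dense reference line
  xs <- seq(0, 1, length.out = 101)
  expect_equal(membership(tri, xs), xs, tolerance = 1e-12)
})

test_that("zero-width ramps act as steps attaining the plateau value", {
  left_shoulder <- mf_trapezoid(0, 0, 1, 2)  # zero-width rising ramp
  expect_equal(membership(left_shoulder, 0), 1)
  right_shoulder <- mf_trapezoid(8, 9, 10, 10) # zero-width falling ramp
  expect_equal(membership(right_shoulder, 10), 1)
  spike <- mf_trapezoid(0, 0, 0, 1)  # degenerate fm at zero shoulder width
  expect_equal(membership(spike, 0), 1)
  expect_equal(membership(spike, 0.5), 0.5)
})

test_that("malformed knots are rejected", {
  expect_error(new_mf("triangle", c(0, 2, 1)), "non-decreasing")
  expect_error(new_mf("triangle", c(0, 1)), "3 finite knots")
  expect_error(new_mf("trapezoid", c(0, 1, 2)), "4 finite knots")
  expect_error(new_mf("trapezoid", c(0, 1, NA, 2)), "finite")
  expect_error(membership(mf_triangle(0, 1, 2), "a"), "numeric")
})

test_that("standard partition lays out the documented knots", {
  v <- standard_partition("RISK", 1, 10, shoulder_fraction = 1 / 8)
  expect_equal(v$terms$Md$knots, c(3.25, 5.5, 7.75))
  expect_equal(v$terms$fm$knots, c(1, 1, 1 + 9 / 8, 3.25))
  expect_equal(v$terms$FM$knots, c(7.75, 10 - 9 / 8, 10, 10))
  # zero shoulder degenerates the end trapezoid to a spike-edged shape
  v0 <- standard_partition("X", 0, 4, shoulder_fraction = 0)
  expect_equal(v0$terms$fm$knots, c(0, 0, 0, 1))
  expect_equal(membership(v0$terms$fm, 0), 1)
  expect_error(standard_partition("X", 0, 1, shoulder_fraction = 0.25),
               "0, 0.25")
  expect_error(standard_partition("X", 0, 1, shoulder_fraction = -0.1),
               "0, 0.25")
})

test_that("partitions cover the universe and sum to one on the interior", {
  for (uni in list(c(1.1, 6.7), c(38.5, 58.25), c(1, 10))) {
    v <- standard_partition("V", uni[1], uni[2])
    grid <- seq(uni[1], uni[2], length.out = 2001)
    deg <- sapply(v$terms, membership, x = grid)
    expect_true(all(deg >= 0 & deg <= 1))
    expect_true(min(apply(deg, 1, max)) > 0)  # coverage
    # partition of unity between the first and third interior breakpoints
    c1 <- uni[1] + (uni[2] - uni[1]) / 4
    c3 <- uni[1] + 3 * (uni[2] - uni[1]) / 4
    interior <- grid >= c1 & grid <= c3
    expect_equal(rowSums(deg[interior, ]), rep(1, sum(interior)),
                 tolerance = 1e-9)
  }
})

test_that("fuzzify at the universe bounds activates only the end trapezoid", {
  mda <- standard_partition("MDA", 1.1, 6.7, units = "nmol/ml")
  expect_equal(fuzzify(mda, 6.7),
               c(fm = 0, m = 0, Md = 0, M = 0, FM = 1))
  expect_equal(fuzzify(mda, 1.1),
               c(fm = 1, m = 0, Md = 0, M = 0, FM = 0))
  d <- fuzzify(mda, 4.321)
  expect_true(all(d >= 0 & d <= 1) && any(d > 0))
})

test_that("out-of-universe inputs are clamped with a warning, or rejected in strict mode", {
  mda <- standard_partition("MDA", 1.1, 6.7)
  expect_warning(d <- fuzzify(mda, 7.5), "clamped")
  expect_equal(unname(d["FM"]), 1)
  expect_error(fuzzify(mda, 7.5, strict = TRUE), "strict")
  expect_error(fuzzify(mda, NaN), "finite")
  expect_error(fuzzify(mda, Inf), "finite")
})

test_that("invalid variable partitions are rejected", {
  terms_ok <- standard_partition("V", 0, 1)$terms
  expect_error(linguistic_variable("V", 1, 0, terms = terms_ok), "lower < upper")
  # non-increasing peaks
  bad <- terms_ok
  bad$Md <- mf_triangle(0.0, 0.05, 0.5)
  expect_error(linguistic_variable("V", 0, 1, terms = bad), "strictly increase")
  # coverage hole
  holey <- list(fm = mf_trapezoid(0, 0, 0.05, 0.1),
                m = mf_triangle(0.1, 0.2, 0.3),
                Md = mf_triangle(0.3, 0.4, 0.45),
                M = mf_triangle(0.6, 0.7, 0.8),
                FM = mf_trapezoid(0.8, 0.9, 1, 1))
  expect_error(linguistic_variable("V", 0, 1, terms = holey), "cover")
})

test_that("the FIS config round-trips through JSON losslessly", {
  sys <- oral_fis(resolution = 501L)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  fis_write(sys, p1)
  back <- fis_read(p1)
  expect_equal(back$inputs, sys$inputs)
  expect_equal(back$output, sys$output)
  expect_equal(back$rules, sys$rules)
  expect_equal(back$options, sys$options)
  fis_write(back, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical rewrite
  # the reread system infers identically
  expect_equal(risk_score(back, 5.1, 44.2)$risk,
               risk_score(sys, 5.1, 44.2)$risk)
})
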
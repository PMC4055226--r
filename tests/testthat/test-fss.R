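test_that("fuzzy soft set construction validates its invariants", {
  expect_s3_class(fuzzy_soft_set(matrix(0.5, 2, 2)), "fuzzy_soft_set")
  expect_error(fuzzy_soft_set(matrix(1.2, 1, 1)), "outside \\[0, 1\\]")
  expect_error(fuzzy_soft_set(matrix(0.5, 2, 2), objects = c("a", "a")),
               "duplicate object")
  expect_error(fuzzy_soft_set(matrix(0.5, 2, 2),
                              parameters = c("e", "e")),
               "duplicate parameter")
  expect_error(fuzzy_soft_set(matrix(0.5, 2, 2), objects = "a"),
               "label lengths")
})

test_that("fuzzy soft subset test matches the pointwise definition", {
  t2 <- fixture_fss("table2")
  expect_true(is_fuzzy_subset(t2, t2))
  expect_true(is_fuzzy_subset(select_parameters(t2, "e1"), t2))

  f <- fuzzy_soft_set(matrix(0.5, 1, 1), "h1", "e1")
  g <- fuzzy_soft_set(matrix(0.4, 1, 1), "h1", "e1")
  expect_false(is_fuzzy_subset(f, g))
  expect_true(is_fuzzy_subset(g, f))

  other <- fuzzy_soft_set(matrix(0.5, 1, 1), "zz", "e1")
  expect_error(is_fuzzy_subset(f, other), "different object universes")
})

test_that("subset test is a partial order on random sets", {
  set.seed(41)
  for (rep in 1:30) {
    f <- synth_fss(4, 3, seed = rep)
    shrink <- function(x, fac) fuzzy_soft_set(memberships(x) * fac,
                                              fss_objects(x),
                                              fss_parameters(x))
    g <- shrink(f, 0.8)
    h <- shrink(f, 0.6)
    expect_true(is_fuzzy_subset(h, g))
    expect_true(is_fuzzy_subset(g, f))
    expect_true(is_fuzzy_subset(h, f))  # transitivity
    # mutual containment implies equality (oracle: matrix comparison)
    if (is_fuzzy_subset(f, g) && is_fuzzy_subset(g, f)) {
      expect_equal(memberships(f), memberships(g))
    }
  }
})

test_that("AND-product reproduces the medical diagnosis table", {
  med <- medical_fss()
  expect_identical(fss_parameters(med),
                   c("(e1,s1)", "(e1,s2)", "(e1,s3)",
                     "(e2,s1)", "(e2,s2)", "(e2,s3)",
                     "(e4,s1)", "(e4,s2)", "(e4,s3)"))
  expect_equal(unname(memberships(med)[, "(e1,s1)"]), c(0.6, 0.2, 0.3, 0.4))
  expect_equal(unname(memberships(med)[, "(e4,s2)"]), c(0.8, 0.3, 0.4, 0.7))
  table9 <- matrix(c(0.6, 0.6, 0.4, 0,   0,   0,   0.6, 0.8, 0.4,
                     0.2, 0.2, 0.2, 0,   0,   0,   0.8, 0.3, 0.6,
                     0.3, 0.3, 0.3, 0.7, 0.4, 0.7, 0.8, 0.4, 0.7,
                     0.4, 0.4, 0.3, 0,   0,   0,   0.6, 0.7, 0.3),
                   4, 9, byrow = TRUE)
  expect_equal(unname(memberships(med)), table9)
})

test_that("AND-product is a pointwise minimum and checks universes", {
  set.seed(42)
  f <- synth_fss(3, 2, seed = 11)
  g <- synth_fss(3, 3, seed = 12)
  prod <- and_product(f, g)
  for (a in fss_parameters(f)) {
    for (b in fss_parameters(g)) {
      col <- memberships(prod)[, sprintf("(%s,%s)", a, b)]
      expect_true(all(col <= memberships(f)[, a]))
      expect_true(all(col <= memberships(g)[, b]))
      expect_equal(unname(col),
                   unname(pmin(memberships(f)[, a], memberships(g)[, b])))
    }
  }
  one <- select_parameters(f, "e1")
  self <- and_product(one, one)
  expect_equal(unname(memberships(self)), unname(memberships(one)))

  h <- fuzzy_soft_set(matrix(0.5, 2, 2))
  expect_error(and_product(f, h), "different object universes")
})

test_that("level soft sets reproduce the worked thresholds", {
  t3 <- fixture_fss("table3")
  l63 <- level_soft_set(t3, 0.63)
  expect_equal(unname(l63$choice_values), c(3, 3, 2))
  expect_equal(unname(l63$indicator),
               matrix(c(1, 1, 0, 0, 1,
                        0, 1, 1, 1, 0,
                        1, 0, 1, 0, 0), 3, 5, byrow = TRUE))
  l34 <- level_soft_set(t3, 0.34)
  expect_equal(unname(l34$choice_values), c(4, 5, 5))

  l0 <- level_soft_set(t3, 0)
  expect_true(all(l0$indicator == 1))
  expect_equal(unname(l0$choice_values), rep(5, 3))
  expect_error(level_soft_set(t3, 1.5), "threshold")
})

test_that("choice values are non-increasing in the threshold", {
  set.seed(7)
  for (rep in 1:25) {
    f <- synth_fss(sample(2:6, 1), sample(2:7, 1), seed = 100 + rep)
    ts <- sort(runif(2))
    cv_lo <- level_soft_set(f, ts[1])$choice_values
    cv_hi <- level_soft_set(f, ts[2])$choice_values
    expect_true(all(cv_lo >= cv_hi))
  }
})

test_that("membership spreads match the worked table", {
  t3 <- fixture_fss("table3")
  r <- membership_ranges(t3)
  expect_equal(unname(r$alpha), c(0.29, 0.31, 0.44, 0.32, 0.32))
  expect_equal(unname(r$beta), c(0.53, 0.39, 0.37))

  const <- fuzzy_soft_set(matrix(0.4, 3, 4))
  rc <- membership_ranges(const)
  expect_equal(unname(rc$alpha), rep(0, 4))
  expect_equal(unname(rc$beta), rep(0, 3))
})

test_that("significant figures are counted from the written form", {
  expect_equal(max_significant_figures(fixture_fss("table3")), 2L)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("object,e1,e2", "x1,0.5,0.25"), tmp)
  expect_equal(max_significant_figures(read_fss(tmp)), 2L)

  writeLines(c("object,e1", "x1,1"), tmp)
  expect_equal(max_significant_figures(read_fss(tmp)), 1L)

  bare <- fuzzy_soft_set(matrix(0.5, 1, 1))
  expect_error(max_significant_figures(bare), "significant figures")
  expect_equal(max_significant_figures(bare, override = 3), 3L)
})

test_that("round_sig rounds half away from zero", {
  expect_equal(round_sig(0.626, 2), 0.63)
  expect_equal(round_sig(0.336, 2), 0.34)
  expect_equal(round_sig(0, 5), 0)
  expect_equal(round_sig(0.65, 1), 0.7)   # signif() would round to even
  expect_equal(round_sig(0.04251, 2), 0.043)
  expect_error(round_sig(-0.1, 2), "non-negative")
  expect_error(round_sig(0.5, 0), "positive integer")
})

test_that("the performance measure uses unordered membership pairs", {
  t3 <- fixture_fss("table3")
  expect_equal(round(performance_measure(t3, "x2"), 4), 3.7202)
  expect_equal(round(performance_measure(t3, "x3"), 4), 3.6462)

  f <- fuzzy_soft_set(matrix(c(0.2, 0.6), 1, 2), "a", c("e1", "e2"))
  expect_equal(performance_measure(f, "a"), 1 / 0.4 + 0.8)

  flat <- fuzzy_soft_set(matrix(0.5, 1, 3), "a", c("e1", "e2", "e3"))
  expect_error(performance_measure(flat, "a"), "all equal")
  narrow <- fuzzy_soft_set(matrix(0.5, 1, 1), "a", "e1")
  expect_error(performance_measure(narrow, "a"), "at least two")
  expect_error(performance_measure(t3, "nope"), "unknown object")
})
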
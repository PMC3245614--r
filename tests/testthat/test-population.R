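mkProfile <- function(normalized, id = "n") {
  new("ShellProfile", nucleusId = id, dapiPct = rep(20, 5),
      probePct = rep(20, 5), normalized = normalized)
}

test_that("aggregation gives the closed-form mean and SEM", {
  p1 <- mkProfile(c(1, 1, 1, 1, 1), "a")
  p2 <- mkProfile(c(2, 1, 1, 1, 1), "b")
  expect_warning(r <- aggregateProfiles(list(p1, p2), "toy"), "> 50")
  expect_equal(unname(shellMeans(r)[1]), 1.5)
  expect_equal(unname(shellSEM(r)[1]), 0.5)  # sd(c(1,2))/sqrt(2)
  expect_equal(unname(shellSEM(r)[2:5]), rep(0, 4))

  same <- suppressWarnings(aggregateProfiles(list(p1, p1, p1), "same"))
  expect_equal(unname(shellMeans(same)), normalizedProfile(p1))
  expect_equal(unname(shellSEM(same)), rep(0, 5))

  expect_error(aggregateProfiles(list(p1), "one"), "at least 2")
})

test_that("shell-wise Welch test matches the hand-computed oracle", {
  a <- suppressWarnings(aggregateProfiles(
    lapply(1:3, function(i) mkProfile(rep(i, 5), paste0("a", i))), "a"))
  b <- suppressWarnings(aggregateProfiles(
    lapply(4:6, function(i) mkProfile(rep(i, 5), paste0("b", i))), "b"))
  cmp <- compareShells(a, b)
  ## {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3), Welch-Satterthwaite df = 4
  expect_equal(cmp$t, rep(-3.674235, 5), tolerance = 1e-6)
  expect_equal(cmp$df, rep(4, 5), tolerance = 1e-9)
  expect_equal(cmp$p, rep(0.021312, 5), tolerance = 1e-4)
  expect_true(all(cmp$significant))
})

test_that("Welch implementation agrees with stats::t.test on random cohorts", {
  set.seed(77)
  for (i in 1:5) {
    x <- matrix(rnorm(40, mean = 1, sd = 0.3), 8, 5)
    y <- matrix(rnorm(60, mean = 1.2, sd = 0.6), 12, 5)
    a <- new("PopulationResult", condition = "a", profiles = x,
             mean = colMeans(x), sem = apply(x, 2, sd) / sqrt(8))
    b <- new("PopulationResult", condition = "b", profiles = y,
             mean = colMeans(y), sem = apply(y, 2, sd) / sqrt(12))
    cmp <- compareShells(a, b)
    for (k in 1:5) {
      tt <- t.test(x[, k], y[, k])          # Welch by default
      expect_equal(cmp$t[k], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(cmp$df[k], unname(tt$parameter), tolerance = 1e-12)
      expect_equal(cmp$p[k], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("comparison is symmetric and the identity comparison is null", {
  set.seed(5)
  x <- matrix(rnorm(50, 1, 0.2), 10, 5)
  a <- new("PopulationResult", condition = "a", profiles = x,
           mean = colMeans(x), sem = apply(x, 2, sd) / sqrt(10))
  self <- compareShells(a, a)
  expect_equal(self$t, rep(0, 5))
  expect_equal(self$p, rep(1, 5))

  y <- x + 0.3
  b <- new("PopulationResult", condition = "b", profiles = y,
           mean = colMeans(y), sem = apply(y, 2, sd) / sqrt(10))
  ab <- compareShells(a, b)
  ba <- compareShells(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("zero-variance cohorts follow the degenerate conventions", {
  flat1 <- suppressWarnings(aggregateProfiles(
    list(mkProfile(rep(1, 5), "a"), mkProfile(rep(1, 5), "b")), "flat1"))
  cmpEq <- compareShells(flat1, flat1)
  expect_equal(cmpEq$p, rep(1, 5))
  expect_true(all(cmpEq$degenerate))

  flat2 <- suppressWarnings(aggregateProfiles(
    list(mkProfile(rep(2, 5), "a"), mkProfile(rep(2, 5), "b")), "flat2"))
  cmpNe <- compareShells(flat1, flat2)
  expect_equal(cmpNe$p, rep(0, 5))
  expect_true(all(cmpNe$degenerate))
})

test_that("Bonferroni correction inflates P across the five shells", {
  set.seed(8)
  x <- matrix(rnorm(50, 1.0, 0.3), 10, 5)
  y <- matrix(rnorm(50, 1.4, 0.3), 10, 5)
  a <- new("PopulationResult", condition = "a", profiles = x,
           mean = colMeans(x), sem = apply(x, 2, sd) / sqrt(10))
  b <- new("PopulationResult", condition = "b", profiles = y,
           mean = colMeans(y), sem = apply(y, 2, sd) / sqrt(10))
  plain <- compareShells(a, b)
  bonf <- compareShells(a, b, correction = "bonferroni")
  expect_equal(bonf$p, pmin(1, plain$p * 5))
})

test_that("radial position classification uses the profile center of mass", {
  expect_identical(as.character(classifyPosition(c(5, 0, 0, 0, 0))),
                   "peripheral")
  expect_equal(attr(classifyPosition(c(5, 0, 0, 0, 0)), "centerOfMass"), 1)
  expect_identical(as.character(classifyPosition(c(0, 0, 0, 0, 5))),
                   "interior")
  expect_equal(attr(classifyPosition(c(0, 0, 0, 0, 5)), "centerOfMass"), 5)
  cls <- classifyPosition(c(1, 1, 1, 1, 1))
  expect_identical(as.character(cls), "intermediate")
  expect_equal(attr(cls, "centerOfMass"), 3)
  expect_error(classifyPosition(c(0, 0, 0, 0, 0)), "classification error")
})

test_that("opposed radial laws are detected end to end in small cohorts", {
  rp <- cohortResult("peripheral", seed = 101, n = 20L)
  ri <- cohortResult("interior", seed = 102, n = 20L)
  cmp <- compareShells(rp, ri)
  expect_true(cmp$significant[1])
  expect_true(cmp$significant[5])
  ## opposite sides of a uniform profile (full three-way labeling at the
  ## conventional cohort size n = 50 is exercised elsewhere)
  expect_lt(attr(classifyPosition(rp), "centerOfMass"), 3)
  expect_gt(attr(classifyPosition(ri), "centerOfMass"), 3.6)
  ## identical-law pair: mostly quiet
  r1 <- cohortResult("intermediate", seed = 103, n = 20L)
  r2 <- cohortResult("intermediate", seed = 104, n = 20L)
  expect_gte(sum(!compareShells(r1, r2)$significant), 4L)
})
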
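test_that("shell areas are equal within one pixel and cover the mask exactly", {
  set.seed(31)
  for (i in 1:40) {
    msk <- maskFromArray(ellipseMask(a = runif(1, 6, 16), b = runif(1, 5, 12),
                                     irregular = runif(1, 0, 0.25),
                                     phases = runif(3, 0, 2 * pi)))
    p <- buildShells(msk)
    expect_equal(nShells(p), 5L)
    expect_lte(max(shellAreas(p)) - min(shellAreas(p)), 1L)
    lab <- shellLabels(p)
    expect_identical(lab > 0L, maskArray(msk))
    expect_identical(sum(shellAreas(p)), nucleusArea(msk))
  }
})

test_that("circular masks produce the analytic equal-area annulus radii", {
  R <- 15
  n <- 41L
  disc <- outer((1:n) - 21, rep(1, n))^2 + outer(rep(1, n), (1:n) - 21)^2
  disc <- sqrt(disc) <= R
  msk <- maskFromArray(disc)
  p <- buildShells(msk)
  radius <- sqrt(outer((1:n) - 21, rep(1, n))^2 +
                 outer(rep(1, n), (1:n) - 21)^2)
  for (k in 1:4) {
    ## outer edge of shell k+1 == inner edge of shell k ~ R*sqrt(1 - k/5)
    expected <- R * sqrt(1 - k / 5)
    observed <- max(radius[shellLabels(p) == k + 1L])
    expect_lt(abs(observed - expected), 1)
  }
})

test_that("a five-pixel mask yields one pixel per shell", {
  m <- matrix(FALSE, 9, 9)
  m[5, 4:6] <- TRUE
  m[4:6, 5] <- TRUE                      # plus-shape, 5 px
  p <- buildShells(maskFromArray(m))
  expect_identical(shellAreas(p), rep(1L, 5))
  expect_identical(shellLabels(p)[5, 5], 5L)   # center is the interior shell
})

test_that("too-small masks and z-stacks are rejected", {
  m <- matrix(FALSE, 9, 9)
  m[4:5, 4:5] <- TRUE
  expect_error(buildShells(maskFromArray(m)), "partition error")
  img3 <- makeNucleus(smallScene3d(), 1)
  expect_error(buildShells(segmentNucleus(img3)), "2D masks")
})

test_that("probe identical to DAPI gives a flat normalized profile of 1", {
  img <- makeNucleus(smallScene2d(), 1)
  same <- NucleusImage(dapi = dapi(img), probe = dapi(img),
                       spacing = spacing(img), id = "same")
  part <- buildShells(segmentNucleus(same))
  for (bg in c(FALSE, TRUE)) {
    prof <- measureShells(same, part, backgroundSubtract = bg)
    expect_equal(normalizedProfile(prof), rep(1, 5), tolerance = 1e-6)
    expect_equal(sum(dapiPct(prof)), 100, tolerance = 1e-6)
    expect_equal(sum(probePct(prof)), 100, tolerance = 1e-6)
  }
})

test_that("normalization follows the percentage-ratio formula", {
  msk <- maskFromArray(ellipseMask())
  part <- buildShells(msk)
  lab <- shellLabels(part)
  targetProbe <- c(30, 20, 20, 15, 15)
  d <- matrix(0, nrow(lab), ncol(lab))
  p <- matrix(0, nrow(lab), ncol(lab))
  for (k in 1:5) {
    d[lab == k] <- 20 / shellAreas(part)[k]
    p[lab == k] <- targetProbe[k] / shellAreas(part)[k]
  }
  img <- NucleusImage(dapi = d, probe = p, spacing = c(0.2, 0.2))
  prof <- measureShells(img, part)
  expect_equal(probePct(prof), targetProbe, tolerance = 1e-9)
  expect_equal(dapiPct(prof), rep(20, 5), tolerance = 1e-9)
  expect_equal(normalizedProfile(prof), c(1.5, 1, 1, 0.75, 0.75),
               tolerance = 1e-9)
})

test_that("a territory placed against the envelope loads shell 1 most", {
  cfg <- smallScene2d(radialLaw = "custom", radialShape = c(150, 8),
                      noiseSd = 0, baselineLevel = 0, territoryRadius = 0.6,
                      territoriesPerNucleus = 1L)
  img <- makeNucleus(cfg, 1)
  prof <- measureShells(img, buildShells(segmentNucleus(img)))
  expect_identical(which.max(normalizedProfile(prof)), 1L)
})

test_that("zero probe signal and degenerate DAPI are profile errors", {
  img <- makeNucleus(smallScene2d(noiseSd = 0, baselineLevel = 0), 1)
  part <- buildShells(segmentNucleus(img))
  none <- NucleusImage(dapi = dapi(img), probe = dapi(img) * 0,
                       spacing = spacing(img))
  expect_error(measureShells(none, part), "no probe signal")
  holes <- dapi(img)
  holes[shellLabels(part) == 3L] <- 0
  degen <- NucleusImage(dapi = holes, probe = probe(img),
                        spacing = spacing(img))
  expect_error(measureShells(degen, part), "degenerate DAPI")
})

test_that("rotating by 90 degrees preserves areas, and profiles for symmetric images", {
  rot90 <- function(m) t(m)[ncol(m):1, ]
  img <- makeNucleus(smallScene2d(), 1)
  msk <- segmentNucleus(img)
  p1 <- buildShells(msk)
  rimg <- NucleusImage(dapi = rot90(dapi(img)), probe = rot90(probe(img)),
                       spacing = spacing(img))
  p2 <- buildShells(segmentNucleus(rimg))
  expect_identical(shellAreas(p1), shellAreas(p2))

  ## rotation-symmetric image: centered disc, radial intensity gradient
  n <- 41L
  radius <- sqrt(outer((1:n) - 21, rep(1, n))^2 +
                 outer(rep(1, n), (1:n) - 21)^2)
  disc <- radius <= 15
  grad <- (20 - radius) * disc
  img <- NucleusImage(dapi = disc * 1, probe = grad, spacing = c(0.2, 0.2))
  prof <- measureShells(img, buildShells(maskFromArray(disc)))
  rimgS <- NucleusImage(dapi = rot90(disc * 1), probe = rot90(grad),
                        spacing = c(0.2, 0.2))
  profR <- measureShells(rimgS, buildShells(maskFromArray(rot90(disc))))
  expect_equal(normalizedProfile(prof), normalizedProfile(profR),
               tolerance = 1e-6)
})

test_that("sort-and-split banding matches a brute-force oracle on small masks", {
  set.seed(99)
  for (i in 1:10) {
    m <- ellipseMask(rows = 20L, cols = 20L, a = runif(1, 4, 7),
                     b = runif(1, 3, 6), irregular = runif(1, 0, 0.2),
                     phases = runif(3, 0, 2 * pi))
    if (sum(m) < 5) next
    ## brute force: per-pixel min distance to any background pixel, then the
    ## same (distance, index) ordering and consecutive equal split
    fgIdx <- which(m)
    bg <- which(!m, arr.ind = TRUE)
    fgPos <- which(m, arr.ind = TRUE)
    dist <- vapply(seq_len(nrow(fgPos)), function(j)
      sqrt(min((bg[, 1] - fgPos[j, 1])^2 + (bg[, 2] - fgPos[j, 2])^2)),
      numeric(1))
    ord <- order(dist, fgIdx)
    n <- length(fgIdx)
    sizes <- rep(n %/% 5, 5)
    if (n %% 5) sizes[seq_len(n %% 5)] <- sizes[seq_len(n %% 5)] + 1L
    expected <- integer(n)
    expected[ord] <- rep(1:5, times = sizes)
    p <- buildShells(maskFromArray(m))
    expect_identical(as.integer(shellLabels(p)[fgIdx]), expected)
  }
})

test_that("profile center of mass tracks the radial law monotonically", {
  means <- c(0.15, 0.35, 0.55, 0.75, 0.92)
  com <- vapply(seq_along(means), function(i) {
    ab <- c(means[i], 1 - means[i]) * 30          # concentrated Beta
    r <- cohortResult("custom", seed = 400 + i, n = 20L,
                      label = paste0("m", i), radialShape = ab)
    attr(classifyPosition(r), "centerOfMass")
  }, numeric(1))
  expect_true(all(diff(com) < 0))    # outward placement -> peripheral shells
})
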
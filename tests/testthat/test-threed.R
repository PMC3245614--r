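test_that("noise-free blobs are segmented with ground-truth centroids", {
  cfg <- smallScene3d(noiseSd = 0, baselineLevel = 0)
  img <- makeNucleus(cfg, 1)
  msk <- segmentNucleus(img)
  terrs <- segmentTerritories(img, msk)
  expect_length(terrs, 2L)
  gt <- groundTruth(img)
  sp <- spacing(img)
  cent <- t(vapply(terrs, function(v) (colMeans(v) - 0.5) * sp, numeric(3)))
  ## match each component to its nearest ground-truth territory
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((cent[, 2] - gt$x_um[i])^2 + (cent[, 1] - gt$y_um[i])^2 +
              (cent[, 3] - gt$z_um[i])^2)
    expect_lt(min(d), max(sp))          # within one voxel
  }
})

test_that("components below the minimum volume are filtered out", {
  cfg <- smallScene3d(noiseSd = 0, baselineLevel = 0,
                      territoriesPerNucleus = 1L,
                      radialLaw = "custom", radialShape = c(1e-9, 1e9))
  img <- makeNucleus(cfg, 1)
  msk <- segmentNucleus(img)
  ## add a bright speck far from the main blob, inside the mask
  p <- probe(img)
  vox <- which(maskArray(msk) & p < 0.01, arr.ind = TRUE)
  speck <- vox[which.max(vox[, 1]), , drop = FALSE]
  p[speck] <- 1
  spiked <- NucleusImage(dapi = dapi(img), probe = p, spacing = spacing(img))
  terrs <- suppressWarnings(
    segmentTerritories(spiked, msk, minVolume = 20L, expectedCount = NA))
  expect_length(terrs, 1L)               # the speck is gone
  few <- suppressWarnings(
    segmentTerritories(spiked, msk, minVolume = 1L, smoothSigma = 0,
                       expectedCount = NA))
  expect_gte(length(few), 2L)            # kept when the filter is off
  expect_error(segmentTerritories(img, msk, minVolume = 10^6),
               "territory-detection failure")
})

test_that("a constant probe channel is a territory-detection failure", {
  img <- makeNucleus(smallScene3d(noiseSd = 0), 1)
  msk <- segmentNucleus(img)
  flat <- NucleusImage(dapi = dapi(img),
                       probe = array(0, dim(dapi(img))),
                       spacing = spacing(img))
  expect_error(segmentTerritories(flat, msk), "no probe contrast")
})

test_that("a center-placed territory returns the smallest semi-axis", {
  cfg <- smallScene3d(noiseSd = 0, baselineLevel = 0,
                      nucleusIrregularity = 0, territoriesPerNucleus = 1L,
                      radialLaw = "custom", radialShape = c(1e-9, 1e9))
  img <- makeNucleus(cfg, 1)
  rec <- territoryDistances(img, expectedCount = 1L)
  voxDiag <- sqrt(sum(spacing(img)^2))
  expect_lt(abs(rec$d_raw_um - 1.8), voxDiag)   # axial semi-axis, 1.8 um
  ## normalizations against the fitted axes are in [0, 1)
  expect_gte(rec$d_norm_avg, 0)
  expect_lt(rec$d_norm_avg, 1)
  expect_lt(rec$d_norm_major, rec$d_norm_avg)
})

test_that("distances scale linearly with voxel spacing", {
  cfg <- smallScene3d(noiseSd = 0, baselineLevel = 0)
  img <- makeNucleus(cfg, 1)
  msk <- segmentNucleus(img)
  terr <- segmentTerritories(img, msk)[[1]]
  r1 <- distanceToPeriphery(terr, msk)
  doubled <- new("NucleusMask", mask = maskArray(msk),
                 area = nucleusArea(msk), centroid = nucleusCentroid(msk),
                 axes = nucleusAxes(msk) * 2, spacing = spacing(msk) * 2,
                 threshold = segThreshold(msk))
  r2 <- distanceToPeriphery(terr, doubled)
  expect_equal(r2$d_raw_um, 2 * r1$d_raw_um, tolerance = 1e-12)
  expect_equal(r2$d_norm_avg, r1$d_norm_avg, tolerance = 1e-12)
})

test_that("distance equals brute-force boundary-voxel minimization", {
  cfg <- sceneConfig(imageShape = c(32L, 32L, 20L), pixelSize = 0.25,
                     zStep = 0.2, nucleusAxes = c(2.8, 2.2, 1.4),
                     noiseSd = 0, nucleusIrregularity = 0.05,
                     territoryRadius = 0.5, nNuclei = 2L, seed = 77L)
  for (i in 1:2) {
    img <- makeNucleus(cfg, i)
    msk <- segmentNucleus(img)
    terrs <- suppressWarnings(segmentTerritories(img, msk, minVolume = 5L,
                                                 expectedCount = NA))
    m <- maskArray(msk)
    d <- dim(m)
    sp <- spacing(img)
    for (terr in terrs) {
      rec <- distanceToPeriphery(terr, msk)
      ctr <- (colMeans(terr) - 0.5) * sp
      ## independent plain-loop oracle with its own boundary detection
      best <- Inf
      for (v in seq_len(prod(d))) {
        if (!m[v]) next
        pos <- arrayInd(v, d)
        boundary <- FALSE
        for (ax in 1:3) {
          for (dlt in c(-1L, 1L)) {
            nb <- pos
            nb[ax] <- nb[ax] + dlt
            if (nb[ax] < 1L || nb[ax] > d[ax] || !m[nb]) boundary <- TRUE
          }
        }
        if (!boundary) next
        dist <- sqrt(sum(((pos - 0.5) * sp - ctr)^2))
        if (dist < best) best <- dist
      }
      expect_equal(rec$d_raw_um, best, tolerance = 1e-12)
    }
  }
})

test_that("a centroid outside the nucleus mask is an invalid-geometry error", {
  img <- makeNucleus(smallScene3d(noiseSd = 0), 1)
  msk <- segmentNucleus(img)
  corner <- which(!maskArray(msk), arr.ind = TRUE)[1, , drop = FALSE]
  expect_error(distanceToPeriphery(corner, msk), "invalid geometry")
})

test_that("frequency curves bin distances with conservation", {
  recs <- data.frame(d_raw_um = c(2.0), d_norm_avg = 0.2, d_norm_major = 0.1)
  cv <- frequencyCurve(recs, "raw", binWidth = 1)
  expect_equal(cv$frequency[cv$bin_lo == 2], 1)
  expect_equal(sum(cv$frequency), 1)

  recs <- data.frame(d_raw_um = c(0.1, 0.6, 0.6, 2.4),
                     d_norm_avg = c(0.01, 0.05, 0.05, 0.2),
                     d_norm_major = c(0.01, 0.04, 0.04, 0.15))
  cv <- frequencyCurve(recs, "raw")     # default 0.5 um bins
  expect_equal(sum(cv$frequency), 4)
  expect_equal(cv$frequency[1], 1)
  expect_equal(cv$frequency[2], 2)
  expect_error(frequencyCurve(recs, "raw", binWidth = 0), "binWidth")
})

test_that("condition ordering of median distances survives both normalizations", {
  mkCohort <- function(law, seed) {
    cfg <- sceneConfig(imageShape = c(96L, 96L, 40L), radialLaw = law,
                       nNuclei = 8L, seed = seed)
    do.call(rbind, lapply(makePopulation(cfg), function(im)
      suppressWarnings(territoryDistances(im))))
  }
  peri <- mkCohort("peripheral", 301)
  inte <- mkCohort("interior", 302)
  for (col in c("d_raw_um", "d_norm_avg", "d_norm_major"))
    expect_lt(median(peri[[col]]), median(inte[[col]]))
})
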
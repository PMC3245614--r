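# Small-scene configs used across the suite; cohort-scale tests use the
# package defaults instead, which are the emulated study conditions.

smallScene2d <- function(...) {
  args <- utils::modifyList(
    list(imageShape = c(96L, 96L), pixelSize = 0.2,
         nucleusAxes = c(7, 4.5), nNuclei = 5L, seed = 42L),
    list(...))
  do.call(sceneConfig, args)
}

smallScene3d <- function(...) {
  args <- utils::modifyList(
    list(imageShape = c(64L, 64L, 32L), pixelSize = 0.2, zStep = 0.2,
         nucleusAxes = c(4.5, 3.5, 1.8), nNuclei = 3L, seed = 42L),
    list(...))
  do.call(sceneConfig, args)
}

# Direct elliptical test mask (bypasses the generator) with optional Fourier
# boundary perturbation; used by shell-partition property tests.
ellipseMask <- function(rows = 40L, cols = 40L, a = 14, b = 9,
                        irregular = 0, phases = c(0, 0, 0)) {
  cy <- rows / 2 + 0.5
  cx <- cols / 2 + 0.5
  u <- outer(rep(1, rows), (seq_len(cols) - cx) / a)
  v <- outer((seq_len(rows) - cy) / b, rep(1, cols))
  theta <- atan2(v, u)
  g <- 1
  if (irregular > 0)
    for (k in 1:3)
      g <- g + irregular / (k + 1) * cos((k + 1) * theta + phases[k])
  sqrt(u^2 + v^2) <= g
}

maskFromArray <- function(m, spacing = c(0.2, 0.2)) {
  img <- NucleusImage(dapi = m * 1, probe = m * 1, spacing = spacing)
  segmentNucleus(img, mask = m)
}

# Cohort -> PopulationResult under the study analysis settings.
cohortResult <- function(law, seed, n = 50L, label = law, ...) {
  cfg <- sceneConfig(radialLaw = law, nNuclei = n, seed = seed, ...)
  suppressWarnings(aggregateProfiles(
    shellProfiles(makePopulation(cfg), backgroundSubtract = TRUE), label))
}
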
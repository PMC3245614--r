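#' Radial placement laws
#'
#' Territory centers are placed at a normalized radial coordinate r in [0,1]
#' (0 = nuclear center, 1 = nuclear boundary) drawn from a Beta distribution.
#' r is the elliptical scale coordinate: the point lies on the nuclear
#' boundary contour shrunk by the factor r, so r has the same meaning along
#' every direction regardless of the axis ratio.
#'
#' The named laws are Beta(8,2) (peripheral, mean r = 0.8), Beta(7,3)
#' (intermediate, mean 0.7) and Beta(2,8) (interior, mean 0.2). Under
#' five equal-area shells these place the expected signal center of mass in
#' shells 1-2, near shell 3, and in shell 5 respectively (closed-form Beta
#' probabilities over the equal-area band edges r = sqrt(1 - k/5)).
#'
#' @param law one of \code{"peripheral"}, \code{"intermediate"},
#'   \code{"interior"}.
#' @return \code{radialLawShape}: numeric \code{c(alpha, beta)}.
#' @examples
#' radialLawShape("peripheral")
#' @export
radialLawShape <- function(law = c("peripheral", "intermediate", "interior")) {
  law <- match.arg(law)
  switch(law,
         peripheral   = c(8, 2),
         intermediate = c(7, 3),
         interior     = c(2, 8))
}

#' @rdname radialLawShape
#' @param n number of draws.
#' @param config a \code{\linkS4class{SceneConfig}} whose \code{radialShape}
#'   defines the Beta law.
#' @return \code{sampleRadialLaw}: numeric vector of n draws in [0,1]. Uses
#'   the current RNG stream (callers control seeding).
#' @export
sampleRadialLaw <- function(n, config) {
  stats::rbeta(n, config@radialShape[1], config@radialShape[2])
}

## Evaluate an expression under a temporary RNG state, restoring the caller's
## stream afterwards so generator calls do not perturb user code.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-nucleus sub-seed: exact in double arithmetic for any
## 32-bit config seed and index, kept below 2^31 for set.seed().
.nucleusSeed <- function(seed, index) {
  (abs(seed) * 20011 + index * 7919) %% 2147483647
}
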
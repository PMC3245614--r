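#' @include AllClasses.R shells.R
NULL

#' Aggregate shell profiles for one condition
#'
#' Per-shell mean and standard error of the mean (sample SD / sqrt(n)) of the
#' normalized shell values across the nuclei of one condition — the summary
#' plotted as a shell histogram with SEM error bars. The per-nucleus values
#' are retained for shell-wise condition comparisons.
#'
#' A cohort below 50 nuclei triggers a warning (not an error): the erosion
#' analysis is conventionally run on populations of more than 50 images, and
#' smaller cohorts give unstable shell means.
#'
#' @param profiles list of \code{\linkS4class{ShellProfile}} (>= 2), all with
#'   the same number of shells.
#' @param condition condition label.
#' @return A \code{\linkS4class{PopulationResult}}.
#' @examples
#' imgs <- makePopulation(sceneConfig(nNuclei = 3, seed = 8))
#' res <- suppressWarnings(aggregateProfiles(shellProfiles(imgs), "demo"))
#' shellMeans(res)
#' @export
aggregateProfiles <- function(profiles, condition = "condition") {
  if (length(profiles) < 2L)
    stop("aggregation error: at least 2 profiles are required")
  k <- unique(vapply(profiles, function(p) length(p@normalized), integer(1)))
  if (length(k) != 1L)
    stop("aggregation error: profiles have differing shell counts")
  if (length(profiles) < 50L)
    warning("cohort has ", length(profiles),
            " nuclei; shell analyses are conventionally run on > 50")
  m <- do.call(rbind, lapply(profiles, function(p) p@normalized))
  rownames(m) <- vapply(profiles, function(p) p@nucleusId, character(1))
  colnames(m) <- paste0("shell", seq_len(k))
  new("PopulationResult", condition = as.character(condition), profiles = m,
      mean = colMeans(m),
      sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
}

## Welch's unequal-variance two-tailed t-test with Welch-Satterthwaite df.
## Degenerate zero-variance cohorts follow the documented conventions:
## equal means -> t = 0, P = 1; unequal means -> P = 0 limit, flagged.
.welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    if (dm == 0) return(c(t = 0, df = NA_real_, p = 1, degenerate = 1))
    return(c(t = sign(dm) * Inf, df = NA_real_, p = 0, degenerate = 1))
  }
  tt <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = 0)
}

#' Compare two conditions shell-by-shell
#'
#' For each shell, an unpaired two-tailed Welch t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) on the per-nucleus normalized
#' values of the two conditions. By convention the per-shell P values are
#' not corrected for testing across the five shells — each shell is marked
#' significant on its own P < alpha, the way shell histograms are
#' conventionally annotated; a Bonferroni option is available.
#'
#' @param a,b \code{\linkS4class{PopulationResult}} objects with the same
#'   number of shells.
#' @param alpha significance level for the per-shell flag.
#' @param correction \code{"none"} (default) or \code{"bonferroni"}.
#' @return \code{data.frame} with one row per shell: \code{shell}, \code{t},
#'   \code{df}, \code{p}, \code{significant}, \code{degenerate}. \code{t} is
#'   positive where condition \code{a} exceeds \code{b}; swapping the
#'   arguments flips the sign of \code{t} and leaves \code{p} unchanged.
#' @examples
#' imgs <- makePopulation(sceneConfig(nNuclei = 4, seed = 9))
#' r <- suppressWarnings(aggregateProfiles(shellProfiles(imgs), "x"))
#' compareShells(r, r)$p   # identity comparison: P = 1 everywhere
#' @export
compareShells <- function(a, b, alpha = 0.05,
                          correction = c("none", "bonferroni")) {
  stopifnot(is(a, "PopulationResult"), is(b, "PopulationResult"))
  correction <- match.arg(correction)
  if (ncol(a@profiles) != ncol(b@profiles))
    stop("conditions have differing shell counts")
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)")
  k <- ncol(a@profiles)
  res <- t(vapply(seq_len(k), function(j)
    .welch(a@profiles[, j], b@profiles[, j]), numeric(4)))
  p <- res[, "p"]
  if (correction == "bonferroni") p <- pmin(1, p * k)
  data.frame(shell = seq_len(k), t = res[, "t"], df = res[, "df"], p = p,
             significant = p < alpha, degenerate = res[, "degenerate"] == 1)
}

#' Classify the radial position of a condition
#'
#' Summarizes a mean normalized shell profile into one of the verbal radial
#' categories by its center of mass over shells,
#' \code{c = sum(k * mean_k) / sum(mean_k)} with shell 1 at the periphery:
#' \code{c <= peripheralMax} is \code{"peripheral"},
#' \code{c >= interiorMin} is \code{"interior"}, anything between is
#' \code{"intermediate"}. The thresholds (defaults 2.4 and 3.6, symmetric
#' about the uniform-profile value 3) are a convention of this package, not
#' a community standard; they are exposed as parameters.
#'
#' @param result a \code{\linkS4class{PopulationResult}} or a numeric mean
#'   profile.
#' @param peripheralMax,interiorMin classification thresholds on the center
#'   of mass.
#' @return Character label, with the center of mass in attribute
#'   \code{"centerOfMass"}.
#' @examples
#' classifyPosition(c(5, 0, 0, 0, 0))   # peripheral, c = 1
#' classifyPosition(c(1, 1, 1, 1, 1))   # intermediate, c = 3
#' @export
classifyPosition <- function(result, peripheralMax = 2.4, interiorMin = 3.6) {
  m <- if (is(result, "PopulationResult")) shellMeans(result)
       else as.numeric(result)
  if (all(m == 0))
    stop("classification error: all-zero mean profile")
  if (any(m < 0))
    stop("classification error: negative mean profile values")
  com <- sum(seq_along(m) * m) / sum(m)
  label <- if (com <= peripheralMax) "peripheral"
           else if (com >= interiorMin) "interior"
           else "intermediate"
  structure(label, centerOfMass = com)
}

#' Tabulate a condition comparison
#'
#' Combines the per-condition summaries and the shell-wise tests into one
#' long-format table for CSV interchange.
#'
#' @param a,b \code{\linkS4class{PopulationResult}} objects.
#' @param comparison output of \code{\link{compareShells}(a, b)}; computed if
#'   missing.
#' @param alpha significance level, used only if \code{comparison} is missing.
#' @return \code{data.frame} with columns \code{condition}, \code{shell},
#'   \code{mean}, \code{sem}, \code{t}, \code{df}, \code{p},
#'   \code{significant} (test columns repeated for both conditions; \code{t}
#'   signed as a vs b).
#' @export
comparisonTable <- function(a, b, comparison = NULL, alpha = 0.05) {
  if (is.null(comparison)) comparison <- compareShells(a, b, alpha = alpha)
  one <- function(r) data.frame(condition = conditionName(r),
                                shell = seq_along(shellMeans(r)),
                                mean = shellMeans(r), sem = shellSEM(r))
  cbind(rbind(one(a), one(b)),
        comparison[rep(seq_len(nrow(comparison)), 2),
                   c("t", "df", "p", "significant")],
        row.names = NULL)
}
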
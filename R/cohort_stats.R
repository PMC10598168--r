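## Cohort statistics: vertex-wise and patch-averaged Bland-Altman agreement,
## paired t test, sagittal landmark angle, and permutation-based statistical
## parametric mapping of JSW against joint angulation.

asFieldMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(stackFields(x))
  stop("stacked fields must be a matrix or a list of ScalarFields")
}

#' Vertex-wise and patch-averaged Bland-Altman agreement maps
#'
#' Given two paired sets of maps (subjects in columns), computes the
#' vertex-wise bias (mean of B - A) and 95 percent limits of agreement
#' (1.96 x the n-1 sample SD of B - A); vertices valid in fewer than two
#' pairs are masked. Patch summaries reduce each subject's field to an
#' area-weighted patch mean first, then apply Bland-Altman to those
#' scalars (the headline summary); area-weighted surface averages of the
#' vertex-wise bias and LOA fields are also reported.
#'
#' @param fieldsA,fieldsB numeric matrices (vertices x subjects, NA =
#'   masked) or lists of ScalarFields, paired by column.
#' @param patch optional \linkS4class{JointPatch} hosting the fields; used
#'   for area weighting. Unweighted means are used when omitted.
#' @return a \linkS4class{BlandAltmanMap}
#' @export
blandAltmanMap <- function(fieldsA, fieldsB, patch = NULL) {
  A <- asFieldMatrix(fieldsA)
  B <- asFieldMatrix(fieldsB)
  if (!all(dim(A) == dim(B))) {
    bad <- which(dim(A) != dim(B))[1]
    stop(sprintf(
      "shape mismatch between paired field sets (%s: %d vs %d)",
      c("vertices", "subject")[bad], dim(A)[bad], dim(B)[bad]))
  }
  for (j in seq_len(ncol(A))) {
    if (sum(!is.na(A[, j])) == 0 || sum(!is.na(B[, j])) == 0)
      stop(sprintf("subject %d has an empty field", j))
  }
  D <- B - A
  nv <- rowSums(!is.na(D))
  ok <- nv >= 2
  bias <- ifelse(ok, rowMeans(D, na.rm = TRUE), NA_real_)
  sdv <- apply(D, 1, stats::sd, na.rm = TRUE)
  loa <- ifelse(ok, 1.96 * sdv, NA_real_)
  w <- if (!is.null(patch)) {
    vertexAreas(if (is(patch, "JointPatch")) patch@mesh else patch)
  } else rep(1, nrow(A))
  wmean <- function(x, keep) sum(w[keep] * x[keep]) / sum(w[keep])
  perSubjMean <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      keep <- !is.na(M[, j])
      if (!any(keep)) NA_real_ else wmean(M[, j], keep)
    }, 1)
  }
  dm <- perSubjMean(B) - perSubjMean(A)
  dm <- dm[is.finite(dm)]
  patchBias <- mean(dm)
  patchLoa <- if (length(dm) >= 2) 1.96 * stats::sd(dm) else NA_real_
  new("BlandAltmanMap",
      bias = ScalarField(bias, mask = ok),
      loa = ScalarField(loa, mask = ok),
      patchBias = patchBias, patchLoa = patchLoa,
      surfaceBias = if (any(ok)) wmean(bias, ok) else NA_real_,
      surfaceLoa = if (any(ok)) wmean(loa, ok) else NA_real_)
}

#' Paired Student t test on a vector of differences
#'
#' t = mean / (sd / sqrt(n)) with a two-sided p from the t distribution on
#' n - 1 degrees of freedom. Zero variance with zero mean gives t = 0,
#' p = 1; zero variance with nonzero mean gives p = 0 with a warning.
#'
#' @param differences numeric vector of paired differences (n >= 2, finite).
#' @return a \linkS4class{TTestResult}
#' @export
pairedT <- function(differences) {
  d <- as.numeric(differences)
  if (length(d) < 2) stop("need at least 2 differences")
  if (any(!is.finite(d))) stop("differences must be finite")
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with nonzero mean: p = 0 by convention")
      t <- sign(m) * Inf; p <- 0
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  new("TTestResult", meanDiff = m, sdDiff = s, t = t, df = n - 1, p = p)
}

setMethod("show", "TTestResult", function(object) {
  cat(sprintf(
    "Paired t test: mean %.4g +/- SD %.4g, t = %.4f (df %g), p = %.4g\n",
    object@meanDiff, object@sdDiff, object@t, object@df, object@p))
})

#' Sagittal joint angle from three landmarks
#'
#' Both limb segments (tibial shaft centre to talar dome centre; talar
#' head centre to dome centre) are projected onto the plane orthogonal to
#' the sagittal normal; the angle at the dome centre between them is
#' returned in degrees, in (0, 180]. Collinear landmarks give 180.
#'
#' @param tibiaShaftCentre,domeCentre,headCentre numeric(3) landmarks (mm).
#' @param sagittalNormal unit normal of the sagittal plane (default x axis,
#'   the scanner left-right direction).
#' @return angle in degrees
#' @export
sagittalAngle <- function(tibiaShaftCentre, domeCentre, headCentre,
                          sagittalNormal = c(1, 0, 0)) {
  nrm <- sagittalNormal / sqrt(sum(sagittalNormal^2))
  u <- as.numeric(tibiaShaftCentre - domeCentre)
  v <- as.numeric(headCentre - domeCentre)
  if (sum(u^2) < 1e-18 || sum(v^2) < 1e-18)
    stop("degenerate landmarks: points coincide")
  u <- u - sum(u * nrm) * nrm
  v <- v - sum(v * nrm) * nrm
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  if (lu < 1e-12 || lv < 1e-12)
    stop("degenerate landmarks: segment vanishes after sagittal projection")
  acos(pmin(1, pmax(-1, sum(u * v) / (lu * lv)))) * 180 / pi
}

#' Vertex-wise F map of a covariate with max-statistic permutation control
#'
#' Per vertex, the F statistic (1 and n - 2 df) for the slope in the linear
#' model value = b0 + b1 * covariate + error. Family-wise control follows
#' the maximum-statistic permutation scheme: the covariate is permuted
#' \code{nPermutations} times, the maximum F over valid vertices recorded,
#' and \code{pCorrected(v) = (1 + #\{max F >= F(v)\}) / (nPermutations + 1)}
#' (the observed statistic counts itself, so p never reaches zero).
#' Deterministic given the seed.
#'
#' @param fields numeric matrix (vertices x subjects; NA = masked) or list
#'   of ScalarFields.
#' @param covariate per-subject covariate (e.g. plantarflexion angle, deg).
#' @param nPermutations number of random permutations (default 999).
#' @param seed integer RNG seed. @param alpha significance level (0.05).
#' @return an \linkS4class{SPMResult}
#' @export
spmFMap <- function(fields, covariate, nPermutations = 999, seed = 1,
                    alpha = 0.05) {
  Y <- asFieldMatrix(fields)
  n <- ncol(Y)
  if (n < 3) stop("need at least 3 subjects")
  if (length(covariate) != n)
    stop("covariate length must equal the number of subjects")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  valid <- rowSums(is.na(Y)) == 0 & apply(Y, 1, function(r) all(is.finite(r)))
  if (!any(valid)) stop("no vertex is valid in all subjects")
  xc <- covariate - mean(covariate)
  Sxx <- sum(xc^2)
  Yv <- Y[valid, , drop = FALSE]
  Yc <- Yv - rowMeans(Yv)
  SST <- rowSums(Yc^2)
  fstat <- function(cross) {
    # cross: valid vertices x permutations; SST recycles down columns
    SSR <- cross^2 / Sxx
    SSE <- pmax(SST - SSR, 0)
    f <- SSR * (n - 2) / pmax(SSE, pmax(SST, 1e-300) * 1e-12)
    f[SST < 1e-24, ] <- 0
    f
  }
  Fv <- fstat(Yc %*% xc)[, 1]
  set.seed(seed)
  P <- vapply(seq_len(nPermutations), function(b) sample(xc), numeric(n))
  crossP <- Yc %*% P                      # valid vertices x permutations
  maxF <- apply(fstat(crossP), 2, max)
  pCorr <- (1 + vapply(Fv, function(f) sum(maxF >= f), 1)) /
    (nPermutations + 1)
  full <- function(x) {
    out <- rep(NA_real_, nrow(Y)); out[valid] <- x; out
  }
  pUnc <- stats::pf(Fv, 1, n - 2, lower.tail = FALSE)
  sig <- rep(FALSE, nrow(Y))
  sig[valid] <- pCorr < alpha
  new("SPMResult",
      F = ScalarField(full(Fv), mask = valid),
      pCorrected = ScalarField(full(pCorr), mask = valid),
      pUncorrected = ScalarField(full(pUnc), mask = valid),
      significant = sig, nPermutations = as.integer(nPermutations),
      alpha = alpha)
}

#' Load the shipped ankle cohort demographics table
#'
#' Per-participant age (years), sex, analysed side, metalwork status,
#' prior operation, interval between imaging visits (days) and sagittal
#' talocrural angle difference between visits (degrees) for the 23-person
#' repeat weight-bearing CT cohort used as the package's worked example.
#'
#' @return a data.frame with one row per participant
#' @export
ankleCohort <- function() {
  read.csv(system.file("extdata", "ankle_cohort_demographics.csv",
                       package = "jsmap"), stringsAsFactors = FALSE)
}

#' Summarise a cohort demographics table
#'
#' Arithmetic mean, n-1 SD and range for age, interval and angle
#' difference; counts by sex, side and metalwork status. A single-row
#' table reports SDs as NA.
#'
#' @param table data.frame with columns \code{age}, \code{sex},
#'   \code{side}, \code{interval_days}, \code{angle_delta_deg} and
#'   optionally \code{metalwork}.
#' @return a list of summary statistics
#' @export
cohortSummary <- function(table) {
  if (nrow(table) == 0) stop("empty cohort table")
  numCols <- c("age", "interval_days", "angle_delta_deg")
  for (cn in intersect(numCols, names(table))) {
    bad <- which(!is.finite(as.numeric(table[[cn]])))
    if (length(bad))
      stop(sprintf("missing numeric value in column '%s', row %d",
                   cn, bad[1]))
  }
  summ <- function(x) {
    list(mean = mean(x),
         sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
         min = min(x), max = max(x), n = length(x))
  }
  out <- list(n = nrow(table))
  for (cn in intersect(numCols, names(table)))
    out[[cn]] <- summ(as.numeric(table[[cn]]))
  for (cn in intersect(c("sex", "side", "metalwork"), names(table)))
    out[[paste0(cn, "_counts")]] <- table(table[[cn]])
  out
}
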
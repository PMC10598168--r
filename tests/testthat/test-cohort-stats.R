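test_that("blandAltmanMap degenerate and uniform-offset cases", {
  set.seed(2)
  A <- matrix(rnorm(50 * 8, 2, 0.3), 50, 8)
  ba0 <- blandAltmanMap(A, A)
  expect_true(all(fieldValues(ba0@bias) == 0))
  expect_true(all(fieldValues(ba0@loa) == 0))
  expect_equal(ba0@patchBias, 0)
  expect_equal(ba0@patchLoa, 0)
  ba <- blandAltmanMap(A, A + 0.2)
  expect_equal(fieldValues(ba@bias), rep(0.2, 50))
  expect_equal(max(fieldValues(ba@loa)), 0, tolerance = 1e-12)
  expect_equal(ba@patchBias, 0.2)
})

test_that("blandAltmanMap uses the n-1 SD and honours symmetry and scaling", {
  set.seed(3)
  A <- matrix(rnorm(30 * 6), 30, 6)
  B <- matrix(rnorm(30 * 6), 30, 6)
  ba <- blandAltmanMap(A, B)
  # n-1 denominator, vertex by vertex
  expect_equal(fieldValues(ba@loa),
               1.96 * apply(B - A, 1, sd))
  # antisymmetric bias, swap-invariant LOA
  ba2 <- blandAltmanMap(B, A)
  expect_equal(fieldValues(ba2@bias), -fieldValues(ba@bias))
  expect_equal(fieldValues(ba2@loa), fieldValues(ba@loa))
  # scaling all differences by c scales bias and LOA by c
  c0 <- 3.5
  ba3 <- blandAltmanMap(A, A + c0 * (B - A))
  expect_equal(fieldValues(ba3@bias), c0 * fieldValues(ba@bias))
  expect_equal(fieldValues(ba3@loa), c0 * fieldValues(ba@loa))
})

test_that("blandAltmanMap masks thin vertices and reports shape mismatches", {
  A <- matrix(rnorm(10 * 4), 10, 4)
  B <- A + 0.1
  A[1, 2:4] <- NA   # vertex 1 valid in only one pair
  ba <- blandAltmanMap(A, B)
  expect_false(fieldMask(ba@bias)[1])
  expect_true(all(fieldMask(ba@bias)[-1]))
  expect_error(blandAltmanMap(A, B[, 1:3]), "mismatch")
})

test_that("vertex LOA of two noisy visits matches the closed form", {
  # difference of two independent noises: SD = sqrt(2) * sigma
  sigma <- 0.1
  loas <- vapply(1:200, function(s) {
    A <- simulateMeasuredFields(rep(2, 40), 23, sigma, seed = 2 * s)
    B <- simulateMeasuredFields(rep(2, 40), 23, sigma, seed = 2 * s + 1)
    mean(fieldValues(blandAltmanMap(A, B)@loa))
  }, 1)
  expect_equal(mean(loas), 1.96 * sqrt(2) * sigma, tolerance = 0.05)
})

test_that("pairedT matches its closed form and conventions", {
  r <- pairedT(c(1, 2, 3))
  expect_equal(r@t, 3.4641, tolerance = 1e-4)
  expect_equal(r@df, 2)
  expect_equal(r@p, 0.0742, tolerance = 5e-4)
  # cross-check against the stock implementation
  tt <- t.test(c(1, 2, 3))
  expect_equal(r@t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r@p, tt$p.value, tolerance = 1e-10)
  r0 <- pairedT(c(0, 0, 0))
  expect_equal(r0@t, 0); expect_equal(r0@p, 1)
  rs <- pairedT(c(-1, 1))
  expect_equal(rs@t, 0); expect_equal(rs@p, 1)
  expect_warning(pairedT(c(2, 2, 2)), "zero variance")
  expect_error(pairedT(c(1)), "at least 2")
  expect_error(pairedT(c(1, NA)), "finite")
})

test_that("sagittalAngle projects and measures landmark angles", {
  expect_equal(sagittalAngle(c(0, 0, 10), c(0, 0, 0), c(0, 5, 0)), 90)
  expect_equal(sagittalAngle(c(0, 1, 1), c(0, 0, 0), c(0, 1, 0)), 45)
  # collinear landmarks with the dome in the middle
  expect_equal(sagittalAngle(c(0, -3, 0), c(0, 0, 0), c(0, 7, 0)), 180)
  # the out-of-plane component is discarded before measuring
  expect_equal(sagittalAngle(c(9, 0, 10), c(0, 0, 0), c(-4, 5, 0)), 90)
  expect_error(sagittalAngle(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "degenerate")
  expect_error(sagittalAngle(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("spmFMap agrees with the paired single-vertex F and validates input", {
  set.seed(11)
  n <- 23
  Y <- matrix(rnorm(5 * n, 2, 0.2), 5, n)
  ang <- rnorm(n, 0, 9)
  r <- spmFMap(Y, ang, nPermutations = 99, seed = 1)
  # F equals the squared t of the regression slope, vertex by vertex
  for (v in 1:5) {
    tv <- summary(lm(Y[v, ] ~ ang))$coefficients[2, "t value"]
    expect_equal(fieldValues(r@F)[v], tv^2, tolerance = 1e-9)
  }
  expect_error(spmFMap(Y, rep(1, n), nPermutations = 99), "constant")
  expect_error(spmFMap(Y[, 1:2], ang[1:2]), "at least 3")
  # constant fields across subjects: F = 0, nothing significant
  r0 <- spmFMap(matrix(2, 10, n), ang, nPermutations = 99, seed = 1)
  expect_true(all(fieldValues(r0@F) == 0))
  expect_false(any(r0@significant))
})

test_that("null per-vertex parametric p values are uniform", {
  set.seed(21)
  n <- 20
  Y <- matrix(rnorm(10000 * n), 10000, n)
  x <- rnorm(n)
  r <- spmFMap(Y, x, nPermutations = 9, seed = 1)
  ks <- suppressWarnings(ks.test(fieldValues(r@pUncorrected), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p values depend only on the F-field ordering", {
  set.seed(31)
  Y <- matrix(rnorm(50 * 12, 2, 0.1), 50, 12)
  x <- rnorm(12, 0, 9)
  r <- spmFMap(Y, x, nPermutations = 199, seed = 7)
  # a strictly monotone transform of the data scale (here: affine) leaves
  # the permutation p values unchanged
  r2 <- spmFMap(3 * Y + 10, x, nPermutations = 199, seed = 7)
  expect_equal(fieldValues(r@pCorrected), fieldValues(r2@pCorrected))
  expect_equal(fieldValues(r@F), fieldValues(r2@F), tolerance = 1e-9)
  # p values respect the permutation floor
  expect_gte(min(fieldValues(r@pCorrected)), 1 / 200)
  # determinism given the seed
  r3 <- spmFMap(Y, x, nPermutations = 199, seed = 7)
  expect_identical(fieldValues(r3@pCorrected), fieldValues(r@pCorrected))
})

test_that("the shipped cohort table summarises to the published demographics", {
  tab <- ankleCohort()
  expect_equal(nrow(tab), 23)
  s <- cohortSummary(tab)
  expect_equal(round(s$interval_days$mean, 1), 74.0)
  expect_equal(round(s$age$mean, 1), 52.7)
  expect_equal(c(s$age$min, s$age$max), c(23, 74))
  expect_equal(unname(s$sex_counts[c("Female", "Male")]), c(16, 7),
               ignore_attr = TRUE)
  expect_equal(unname(s$side_counts[c("Left", "Right")]), c(13, 10),
               ignore_attr = TRUE)
  expect_equal(unname(s$metalwork_counts[c("None", "Yes", "Opposite")]),
               c(12, 7, 4), ignore_attr = TRUE)
})

test_that("cohortSummary handles single rows and missing cells", {
  tab <- ankleCohort()
  s1 <- cohortSummary(tab[1, ])
  expect_true(is.na(s1$age$sd))
  expect_equal(s1$age$mean, tab$age[1])
  bad <- tab
  bad$interval_days[5] <- NA
  expect_error(cohortSummary(bad), "row 5")
  expect_error(cohortSummary(tab[0, ]), "empty")
})
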
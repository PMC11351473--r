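test_that("SRSS combines importances by root sum of squares", {
  impA <- c(x = 3, y = 0, z = 5)
  impB <- c(x = 4, y = 2, z = 12)
  tab <- srssRank(impA, impB)
  expect_s3_class(tab, "ImportanceTable")
  expect_equal(tab$srss[tab$variable == "x"], 5)   # 3-4-5 triangle
  expect_equal(tab$srss[tab$variable == "z"], 13)  # 5-12-13 triangle
  expect_equal(tab$variable, c("z", "x", "y"))     # descending srss
  # one species contributing zero leaves ordering to the other
  tab2 <- srssRank(c(a = 2, b = 7), c(a = 0, b = 0))
  expect_equal(tab2$variable, c("b", "a"))
  # ties break alphabetically
  tab3 <- srssRank(c(b = 1, a = 1), c(a = 1, b = 1))
  expect_equal(tab3$variable, c("a", "b"))
  expect_error(srssRank(c(a = 1), c(b = 1)), "different variables")
  expect_error(srssRank(c(a = -1), c(a = 1)), "non-negative")
})

test_that("PCA on perfectly correlated pairs gives eigenvalues (2, 0)", {
  set.seed(4)
  x <- rnorm(50)
  lam <- pcaFit(cbind(u = x, v = 2 * x + 3))$eigenvalues
  expect_equal(lam, c(2, 0), tolerance = 1e-12)
})

test_that("PCA eigenvalues sum to the variable count, identity gives all ~1", {
  set.seed(5)
  x <- matrix(rnorm(4000), 1000, 4, dimnames = list(NULL, letters[1:4]))
  p <- pcaFit(x)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-12)
  expect_true(all(abs(p$eigenvalues - 1) < 0.2))
  expect_equal(sum(p$varianceFraction), 100, tolerance = 1e-12)
})

test_that("PCA matches a direct eigen-solve of the correlation matrix", {
  set.seed(6)
  n <- 300
  z <- rnorm(n)
  x <- cbind(a = z + rnorm(n, sd = 0.3), b = z + rnorm(n, sd = 0.3),
             c = rnorm(n), d = -z + rnorm(n, sd = 0.5))
  p <- pcaFit(x)
  ref <- eigen(cor(x), symmetric = TRUE)
  expect_equal(p$eigenvalues, ref$values, tolerance = 1e-8)
  for (k in 1:4)  # loadings agree up to sign
    expect_lt(min(sum(abs(p$loadings[, k] - ref$vectors[, k])),
                  sum(abs(p$loadings[, k] + ref$vectors[, k]))), 1e-6)
  # projecting the calibration rows reproduces the stored scores
  expect_equal(projectScores(p, x), p$scores, tolerance = 1e-12)
  # cos2 of each variable over all PCs sums to 1; first-two slice is <= 1
  expect_true(all(rowSums(p$cos2) <= 1 + 1e-9))
})

test_that("stop decision honours both the variance and eigenvalue rules", {
  expect_false(stopDecision(56.86, 1.01))
  expect_true(stopDecision(60.87, 0.98))
  expect_true(stopDecision(86.0, 1.5))    # cumulative rule alone
  expect_false(stopDecision(85.0, 1.5))   # strictly greater than 85
  expect_true(stopDecision(50, NA))       # < 3 variables left
  expect_true(stopDecision(50, 0.9999999))
})

test_that("elimination removes lowest-SRSS variables until a round passes", {
  set.seed(9)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  bg <- cbind(a = z1 + rnorm(n, sd = 0.1), b = z1 + rnorm(n, sd = 0.1),
              c = z2 + rnorm(n, sd = 0.1), d = z2 + rnorm(n, sd = 0.1),
              e = rnorm(n))
  imp <- srssRank(c(a = 40, b = 30, c = 20, d = 8, e = 2),
                  c(a = 35, b = 25, c = 22, d = 9, e = 3))
  res <- eliminateAndSelect(bg, imp)
  expect_s3_class(res$log, "data.frame")
  expect_equal(sum(res$log$selected), 1)           # exactly one selected round
  expect_true(res$log$selected[nrow(res$log)])     # ...and it is the last
  expect_equal(res$log$round, seq_len(nrow(res$log)))
  # removals follow ascending SRSS order
  removed <- res$log$removed[-1]
  expect_equal(removed, rev(imp$variable)[seq_along(removed)])
  # re-running is byte-identical
  expect_identical(res, eliminateAndSelect(bg, imp))
  # selected set satisfies the stopping rule it reported
  lastRow <- res$log[nrow(res$log), ]
  expect_true(res$forced ||
                stopDecision(lastRow$cumulative12, lastRow$lambda3))
})

test_that("elimination refuses impossible inputs and flags forced stops", {
  set.seed(10)
  bg <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, letters[1:4]))
  imp <- srssRank(setNames(4:1, letters[1:4]), setNames(4:1, letters[1:4]))
  expect_error(eliminateAndSelect(bg[, 1:3], imp), "missing variable")
  expect_error(eliminateAndSelect(bg, imp, minVars = 4), "more than minVars")
  # 4 near-independent variables can never satisfy the rule -> forced at 3
  resF <- eliminateAndSelect(bg, imp, cumThreshold = 99.9,
                             eigThreshold = 1e-9, minVars = 3)
  expect_true(resF$forced)
  expect_equal(length(resF$selected), 3)
})

test_that("occupancy grids are normalized and respect the delta limit", {
  set.seed(11)
  bg <- cbind(Dim1 = rnorm(2000), Dim2 = rnorm(2000))
  occ <- cbind(Dim1 = rnorm(60, 1, 0.2), Dim2 = rnorm(60, -0.5, 0.2))
  es <- buildEnvSpace(bg, occ, r = 80, species = "sp")
  z <- occupancy(es)
  expect_equal(sum(z), 1, tolerance = 1e-12)
  expect_true(all(z >= 0))
  # the occupied mass concentrates near the occurrence centroid
  i <- which(z == max(z), arr.ind = TRUE)[1, ]
  expect_lt(abs(es@xGrid[i[1]] - 1), 0.5)
  expect_lt(abs(es@yGrid[i[2]] + 0.5), 0.5)
  # fewer than 5 occurrences is an error
  expect_error(buildEnvSpace(bg, occ[1:4, ]), "at least 5")
})

test_that("availability correction cancels for background-shaped occurrences", {
  # occurrences drawn as a subsample of the background: corrected occupancy
  # should be much flatter than the uncorrected one
  set.seed(13)
  bg <- cbind(Dim1 = rnorm(4000, sd = 1.5), Dim2 = rnorm(4000, sd = 0.8))
  occ <- bg[sample(4000, 400), ]
  esc <- buildEnvSpace(bg, occ, r = 60)
  esu <- buildEnvSpace(bg, occ, r = 60, corrected = FALSE)
  zc <- occupancy(esc); zu <- occupancy(esu)
  # on high-availability cells the corrected occupancy is near-constant
  # (o/e cancels) while the uncorrected one still tracks availability
  core <- esc@envDensity > 0.5 * max(esc@envDensity)
  cv <- function(z) stats::sd(z[core]) / mean(z[core])
  expect_lt(cv(zc), cv(zu))
  expect_lt(cv(zc), 0.5)
})

test_that("Schoener's D is stable under grid refinement", {
  set.seed(14)
  bg <- cbind(Dim1 = rnorm(3000), Dim2 = rnorm(3000))
  oa <- cbind(Dim1 = rnorm(80, 0.8, 0.3), Dim2 = rnorm(80, 0, 0.3))
  ob <- cbind(Dim1 = rnorm(80, 0.2, 0.3), Dim2 = rnorm(80, 0.3, 0.3))
  d10 <- schoenersD(buildEnvSpace(bg, oa, r = 50),
                    buildEnvSpace(bg, ob, r = 50))
  d100 <- schoenersD(buildEnvSpace(bg, oa, r = 100),
                     buildEnvSpace(bg, ob, r = 100))
  expect_lt(abs(d10 - d100), 0.05)
})

test_that("Schoener's D matches hand cases and is a bounded symmetric index", {
  u <- matrix(0.25, 2, 2)
  expect_equal(schoenersD(u, u), 1)
  a <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 0.5, 0.5), 2, 2)
  expect_equal(schoenersD(a, b), 0)
  expect_equal(schoenersD(a, u), 0.5)
  expect_warning(schoenersD(2 * a, u), "normaliz")
  set.seed(15)
  for (i in 1:25) {
    x <- matrix(runif(36), 6, 6); x <- x / sum(x)
    y <- matrix(runif(36), 6, 6); y <- y / sum(y)
    d <- schoenersD(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, schoenersD(y, x))
    expect_equal(schoenersD(x, x), 1)
  }
  expect_error(schoenersD(a, matrix(1, 3, 3)), "dimension")
})

test_that("density contours rank cells and count breadth correctly", {
  # uniform mass over k cells: the 50% contour holds ceiling(k/2) cells
  z <- matrix(0, 5, 5); z[1:10] <- 0.1
  ct <- nicheContours(z, levels = c(0.5, 1))
  expect_equal(attr(ct$q0.5, "breadth"), 5)
  expect_equal(attr(ct$q1, "breadth"), 10)
  expect_true(all(z[ct$q0.5] > 0))
  # all mass in one cell: every contour is that single cell
  z1 <- matrix(0, 4, 4); z1[7] <- 1
  expect_equal(nicheBreadth(z1, 0.5), 1)
  expect_equal(nicheBreadth(z1, 1), 1)
  # graded mass: the 50% contour is the minimal top-density set
  z2 <- matrix(c(0.4, 0.3, 0.2, 0.1), 2, 2)
  expect_equal(nicheBreadth(z2, 0.5), 2)   # 0.4 + 0.3 >= 0.5
  expect_equal(nicheBreadth(z2, 0.7), 2)
  expect_equal(nicheBreadth(z2, 0.71), 3)
})

test_that("1-d variable overlap recovers peaks and matches D conventions", {
  set.seed(16)
  bgv <- runif(3000, -4, 4)
  a <- rnorm(300, 0, 0.5)
  ov <- variableOverlap1d(a, a, bgv)
  expect_equal(ov$D, 1, tolerance = 1e-12)
  expect_equal(ov$peaksA$location[1], 0, tolerance = 0.15)
  # bimodal species: two peaks near -2 and 2
  b <- c(rnorm(200, -2, 0.3), rnorm(200, 2, 0.3))
  ov2 <- variableOverlap1d(a, b, bgv)
  locs <- sort(ov2$peaksB$location[1:2])
  expect_equal(locs, c(-2, 2), tolerance = 0.25)
  expect_lt(ov2$D, 0.6)
  # disjoint supports: D near zero
  ov3 <- variableOverlap1d(rnorm(100, -3, 0.1), rnorm(100, 3, 0.1), bgv)
  expect_lt(ov3$D, 0.05)
  expect_error(variableOverlap1d(1:3, a, bgv), "at least 5")
})
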
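test_that("feature construction scales, counts and prunes as specified", {
  v <- matrix(seq(0, 10, length.out = 21), ncol = 1,
              dimnames = list(NULL, "v"))
  fs <- buildFeatures(v, classes = "linear")
  expect_equal(unname(featureDesign(fs, matrix(5, 1, 1,
                                               dimnames = list(NULL, "v")))[1, 1]),
               0.5)
  # two layers, linear + quadratic + product -> 2 + 2 + 1 = 5 features
  v2 <- cbind(v, w = rev(v[, 1])); colnames(v2) <- c("v", "w")
  fs2 <- buildFeatures(v2, classes = c("linear", "quadratic", "product"))
  expect_equal(length(fs2$defs), 5)
  # all features within [0, 1] on the pool
  D <- featureDesign(fs2, v2)
  expect_true(all(D >= 0 & D <= 1))
  # constant layer: only a linear feature, with a warning
  v3 <- cbind(v, k = 1); colnames(v3) <- c("v", "k")
  expect_warning(fs3 <- buildFeatures(v3, classes = c("linear", "quadratic")),
                 "constant")
  kinds <- vapply(fs3$defs, function(d) d$kind, "")
  expect_equal(sum(kinds == "quadratic"), 1)  # only for v, not k
})

test_that("hinge features vanish outside their knot and clamp beyond range", {
  v <- matrix(0:10, ncol = 1, dimnames = list(NULL, "v"))
  fs <- buildFeatures(v, classes = c("linear", "hinge"), nHingeKnots = 3)
  hidx <- which(vapply(fs$defs, function(d)
    d$kind == "hinge" && !d$reverse, TRUE))
  D <- featureDesign(fs, v, which = hidx)
  expect_true(all(D >= 0 & D <= 1))
  # at the layer minimum every forward hinge is 0; at the maximum, 1
  expect_true(all(D[1, ] == 0))
  expect_true(all(D[11, ] == 1))
  # values beyond the training range clamp
  far <- matrix(c(-5, 50), ncol = 1, dimnames = list(NULL, "v"))
  Dfar <- featureDesign(fs, far, which = hidx)
  expect_equal(unname(Dfar[1, ]), rep(0, length(hidx)))
  expect_equal(unname(Dfar[2, ]), rep(1, length(hidx)))
})

test_that("a one-feature fit matches an exhaustive grid-search oracle", {
  set.seed(4)
  bgv <- matrix(rep(c(0, 1), each = 200), ncol = 1,
                dimnames = list(NULL, "v"))
  prv <- matrix(rep(1, 50), ncol = 1, dimnames = list(NULL, "v"))
  fs <- buildFeatures(rbind(prv, bgv), classes = "linear")
  Fp <- featureDesign(fs, prv); Fb <- featureDesign(fs, bgv)
  fit <- fitMaxent(Fp, Fb, fs)
  grid <- seq(-2, 10, by = 1e-4)
  oracle <- grid[which.max(vapply(grid, maxentObjective1d, 0,
                                  Fpr = Fp, Fbg = Fb, beta = fit@beta))]
  expect_lt(abs(fit@coefficients[1] - oracle), 1e-3)
  expect_gt(fit@coefficients[1], 0)
  # q concentrates on the v = 1 cells
  q <- exp(maxentScores(fit, bgv, type = "eta") - fit@logZ)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_gt(sum(q[bgv == 1]), 0.9)
})

test_that("uninformative presences give near-uniform logistic output", {
  set.seed(9)
  bgv <- matrix(runif(500), ncol = 1, dimnames = list(NULL, "v"))
  prv <- bgv[sample(500, 120), , drop = FALSE]
  fs <- buildFeatures(rbind(prv, bgv), classes = c("linear", "quadratic"))
  fit <- fitMaxent(featureDesign(fs, prv), featureDesign(fs, bgv), fs)
  out <- maxentScores(fit, bgv)
  expect_true(all(abs(out - 0.5) < 0.05))
})

test_that("an overwhelming penalty shrinks every coefficient to zero", {
  set.seed(2)
  bgv <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "v"))
  prv <- matrix(rnorm(40, 1), ncol = 1, dimnames = list(NULL, "v"))
  fs <- buildFeatures(rbind(prv, bgv), classes = c("linear", "quadratic"))
  fit <- fitMaxent(featureDesign(fs, prv), featureDesign(fs, bgv), fs,
                   betaMultiplier = 1e6)
  expect_true(all(fit@coefficients == 0))
  expect_equal(trainingGain(fit), 0)
})

test_that("the regularized gain is non-decreasing along the fit trace", {
  sc <- smallScene(seed = 5, nRows = 40, nCols = 40, nA = 80,
                   nBackground = 600)
  pv <- extractValues(sc$env, sc$occA, quiet = TRUE)
  bv <- extractValues(sc$env, sc$background, quiet = TRUE)
  fs <- buildFeatures(rbind(pv, bv), classes = c("linear", "quadratic", "hinge"))
  fit <- fitMaxent(featureDesign(fs, pv), featureDesign(fs, bv), fs)
  expect_true(all(fit@gainTrace$gain >= 0))
  expect_equal(sum(fit@gainTrace$gain), trainingGain(fit), tolerance = 1e-8)
})

test_that("logistic output follows q e^H / (1 + q e^H)", {
  # uniform q over n background cells -> logistic exactly 0.5
  bgv <- matrix(1:100, ncol = 1, dimnames = list(NULL, "v"))
  fs <- buildFeatures(bgv, classes = "linear")
  fit <- fitMaxent(featureDesign(fs, bgv[1:10, , drop = FALSE] * 0 + 50),
                   featureDesign(fs, bgv), fs, betaMultiplier = 1e9)
  expect_true(all(abs(maxentScores(fit, bgv) - 0.5) < 1e-12))
  # doubling q at one cell relative to uniform gives logistic 2/3 there:
  # with lambda = 0, q is uniform; construct the check arithmetically
  n <- 100
  q <- rep(1 / n, n); q[1] <- 2 / n; q <- q / sum(q)
  H <- -sum(q * log(q))
  expect_equal(q[1] * exp(H) / (1 + q[1] * exp(H)), 2 / 3,
               tolerance = 0.02)
})

test_that("nodata cells propagate through logistic prediction", {
  vals <- matrix(runif(100), 10, 10); vals[3, 4] <- NA
  st <- envStack(v = rasterGrid(vals, name = "v"))
  occ <- sampleBackground(st, 20, seed = 1)
  fit <- suppressWarnings(
    replicateProtocol(occ, NULL, st, nRep = 1, trainFrac = 1, seed = 1))
  out <- gridValues(fit$meanMap)
  expect_true(is.na(out[3, 4]))
  expect_true(all(!is.na(out[-((4 - 1) * 10 + 3)])))
  expect_error(predictLogistic(fit$models[[1]],
                               envStack(w = rasterGrid(vals, name = "w"))),
               "v")
})

test_that("AUC, TSS and threshold sweeps match hand-computed cases", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucScore(0.5, 0.5), 0.5)
  expect_equal(aucScore(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_equal(maxTSS(c(0.9, 0.8), c(0.1, 0.2))$tss, 1.0)
  expect_equal(maxTSS(c(0.9, 0.4), c(0.6, 0.1))$tss, 0.5)
  expect_equal(maxTSS(c(0.3, 0.7), c(0.3, 0.7))$tss, 0)
  # sss threshold: ties resolve to the lower threshold
  expect_equal(sssThreshold(c(0.9, 0.4), c(0.6, 0.1)), 0.4)
})

test_that("sweeps agree with O(n^2) brute force on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(1:50, 1); n <- sample(1:50, 1)
    pres <- round(runif(m), 2); bg <- round(runif(n), 2)  # force ties
    expect_equal(aucScore(pres, bg), bruteAUC(pres, bg))
    bt <- bruteSweep(pres, bg, "tss")
    got <- maxTSS(pres, bg)
    expect_equal(got$tss, bt$best)
    expect_equal(got$threshold, bt$threshold)
    bs <- bruteSweep(pres, bg, "ss")
    expect_equal(sssThreshold(pres, bg), bs$threshold)
  }
})

test_that("replicate protocol is deterministic and mean map is exact for one replicate", {
  sc <- smallScene(seed = 2, nRows = 40, nCols = 40, nA = 60,
                   nBackground = 500)
  r1 <- replicateProtocol(sc$occA, sc$background, sc$env, nRep = 2, seed = 7)
  r2 <- replicateProtocol(sc$occA, sc$background, sc$env, nRep = 2, seed = 7)
  expect_identical(gridValues(r1$meanMap), gridValues(r2$meanMap))
  expect_identical(r1$eval$testAUC, r2$eval$testAUC)
  # single replicate at trainFrac 1: mean map equals the model's own map
  r3 <- replicateProtocol(sc$occA, sc$background, sc$env, nRep = 1,
                          trainFrac = 1, seed = 3)
  single <- predictLogistic(r3$models[[1]], sc$env)
  expect_equal(gridValues(r3$meanMap), gridValues(single))
})

test_that("jackknife ranks an informative layer above pure noise", {
  set.seed(12)
  spec <- landscapeSpec(nRows = 50, nCols = 50, nContinuous = 2,
                        nDistance = 0, targetCorrelation = diag(2), seed = 21)
  st <- generateEnvStack(spec)
  niche <- nicheParams(c(env1 = 0.8), c(env1 = 0.4))  # env2 is pure noise
  occ <- simulateOccurrences(st, niche, 120, seed = 5)
  bg <- sampleBackground(st, 1000, seed = 6)
  pv <- extractValues(st, occ, quiet = TRUE)
  bv <- extractValues(st, bg, quiet = TRUE)
  jk <- jackknifeImportance(pv, bv)
  gOnly <- setNames(jk$gainOnly, jk$variable)
  expect_gt(gOnly["env1"], gOnly["env2"])
  # dropping the informative variable costs gain; dropping noise does not
  gWithout <- setNames(jk$gainWithout, jk$variable)
  expect_lt(gWithout["env1"], attr(jk, "fullGain") - 0.05)
  # a duplicated informative layer makes each copy individually redundant
  st2 <- envStack(env1 = getLayer(st, "env1"),
                  env1b = rasterGrid(gridValues(getLayer(st, "env1")),
                                     name = "env1b"),
                  env2 = getLayer(st, "env2"))
  pv2 <- extractValues(st2, occ, quiet = TRUE)
  bv2 <- extractValues(st2, bg, quiet = TRUE)
  jk2 <- jackknifeImportance(pv2, bv2)
  full2 <- attr(jk2, "fullGain")
  gw2 <- setNames(jk2$gainWithout, jk2$variable)
  expect_lt(abs(full2 - gw2["env1"]), 0.05)
  expect_lt(abs(full2 - gw2["env1b"]), 0.05)
})

test_that("all-noise layers produce near-zero gains", {
  set.seed(15)
  pv <- matrix(runif(120 * 2), 120, 2, dimnames = list(NULL, c("a", "b")))
  bv <- matrix(runif(800 * 2), 800, 2, dimnames = list(NULL, c("a", "b")))
  jk <- jackknifeImportance(pv, bv)
  expect_true(all(jk$gainOnly < 0.05))
  expect_lt(attr(jk, "fullGain"), 0.05)
})

test_that("percent contribution attributes gain to the signal variable", {
  # single-variable model -> 100%
  set.seed(18)
  bgv <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "v"))
  prv <- matrix(rnorm(60, 1.2, 0.5), ncol = 1, dimnames = list(NULL, "v"))
  fs <- buildFeatures(rbind(prv, bgv), classes = c("linear", "quadratic"))
  fit <- fitMaxent(featureDesign(fs, prv), featureDesign(fs, bgv), fs)
  pc <- percentContribution(fit)
  expect_equal(unname(pc["v"]), 100)
  expect_equal(sum(pc), 100)
})

test_that("two equally informative variables split contribution evenly", {
  shares <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 1500; m <- 200
    bgv <- cbind(a = rnorm(n), b = rnorm(n))
    prv <- cbind(a = rnorm(m, 1.5, 0.6), b = rnorm(m, 1.5, 0.6))
    fs <- buildFeatures(rbind(prv, bgv), classes = c("linear", "quadratic"))
    fit <- fitMaxent(featureDesign(fs, prv), featureDesign(fs, bgv), fs)
    percentContribution(fit)["a"]
  })
  expect_lt(abs(mean(shares) - 50), 10)
})
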
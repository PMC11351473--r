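#' Logistic or raw scores at covariate values
#'
#' @param model a [MaxEntModel-class].
#' @param values covariate matrix (named columns).
#' @param type "logistic" (default) or "eta" (the linear predictor).
#' @return numeric vector of scores.
#' @export
maxentScores <- function(model, values, type = c("logistic", "eta")) {
  type <- match.arg(type)
  eta <- maxentEta(model, as.matrix(values))
  if (type == "eta") return(eta)
  qeh <- exp(eta - model@logZ + model@entropy)
  qeh / (1 + qeh)
}

#' Rank-based AUC of presence vs background scores
#'
#' Mann-Whitney AUC: the probability a random presence outscores a random
#' background point, ties counted half. Identical constant scores give 0.5.
#'
#' @param presence,background numeric score vectors (each non-empty).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(presence, background) {
  if (!length(presence) || !length(background))
    stop("both score vectors must be non-empty")
  r <- rank(c(presence, background))
  m <- length(presence); n <- length(background)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# sensitivity/specificity sweep over all distinct score values
# (prediction positive when score >= threshold)
sensSpecSweep <- function(presence, background) {
  th <- sort(unique(c(presence, background)))
  sens <- vapply(th, function(t) mean(presence >= t), 0)
  spec <- vapply(th, function(t) mean(background < t), 0)
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Maximum true skill statistic over thresholds
#'
#' TSS(theta) = sensitivity + specificity - 1, evaluated at every distinct
#' score; returns the maximum, its threshold (lowest on ties) and the
#' conventional qualitative band (poor 0.2-0.5, effective 0.5-0.8,
#' excellent > 0.8).
#'
#' @inheritParams aucScore
#' @return list: `tss`, `threshold`, `rating`.
#' @export
maxTSS <- function(presence, background) {
  sw <- sensSpecSweep(presence, background)
  tss <- sw$sensitivity + sw$specificity - 1
  best <- which(tss == max(tss))[1L]   # sweep ascending: lowest theta first
  rating <- if (tss[best] > 0.8) "excellent"
            else if (tss[best] >= 0.5) "effective"
            else if (tss[best] >= 0.2) "poor"
            else "no skill"
  list(tss = tss[best], threshold = sw$threshold[best], rating = rating)
}

#' Maximum training sensitivity plus specificity threshold
#'
#' The logistic threshold maximizing sensitivity + specificity on training
#' presences vs background; ties resolve to the lowest threshold (largest
#' suitable area). Used to binarize suitability maps.
#'
#' @inheritParams aucScore
#' @return the threshold value.
#' @export
sssThreshold <- function(presence, background) {
  sw <- sensSpecSweep(presence, background)
  ss <- sw$sensitivity + sw$specificity
  sw$threshold[which(ss == max(ss))[1L]]
}

#' Replicated subsample fitting protocol
#'
#' Fits `nRep` models on independent random `trainFrac` subsamples of the
#' presences (each against the full background), evaluates each on its
#' held-out test split, and averages the logistic maps cell-wise into the
#' final suitability map. Feature classes default to the presence-count
#' rule of [autoFeatureClasses()]; feature scaling is derived once from the
#' full presence + background pool.
#'
#' @param occ presence [OccurrenceSet-class] (already thinned).
#' @param background background [OccurrenceSet-class]; if NULL, all valid
#'   cells up to `maxBackground` are used (a seeded uniform sample beyond
#'   that).
#' @param stack covariate [EnvStack-class].
#' @param nRep number of replicates (default 10).
#' @param trainFrac training fraction (default 0.8).
#' @param seed master seed for the subsampling.
#' @param classes feature classes; NULL = automatic.
#' @param nHingeKnots hinge knots per variable/direction.
#' @param betaMultiplier L1 penalty multiplier.
#' @param maxBackground cap on background cells when `background` is NULL.
#' @return list of class "ReplicateResult": `models`, `meanMap`
#'   ([RasterGrid-class]), `eval` (per-replicate train/test AUC, mean AUC,
#'   max TSS and threshold, sss threshold, percent contributions),
#'   `presValues`, `bgValues`, `features`.
#' @export
replicateProtocol <- function(occ, background, stack, nRep = 10,
                              trainFrac = 0.8, seed = 1L, classes = NULL,
                              nHingeKnots = 8, betaMultiplier = 1,
                              maxBackground = 10000) {
  presValues <- extractValues(stack, occ, quiet = TRUE)
  m <- nrow(presValues)
  if (is.null(background)) {
    vals <- stackValues(stack)
    if (nrow(vals) > maxBackground) {
      set.seed(seed)
      vals <- vals[sample(nrow(vals), maxBackground), , drop = FALSE]
    }
    bgValues <- vals
  } else {
    bgValues <- extractValues(stack, background, quiet = TRUE)
  }
  if (m < 5) {
    warning(sprintf("only %d presences: replicate count reduced to keep test sets non-empty", m))
    nRep <- min(nRep, max(m - 1L, 1L))
  }
  if (is.null(classes)) classes <- autoFeatureClasses(m)
  features <- buildFeatures(rbind(presValues, bgValues), classes = classes,
                            nHingeKnots = nHingeKnots)
  Fpr <- featureDesign(features, presValues)
  Fbg <- featureDesign(features, bgValues)

  nTrain <- max(1L, min(m - if (trainFrac < 1) 1L else 0L,
                        round(trainFrac * m)))
  set.seed(seed)
  repSeeds <- sample.int(2147483646L, nRep)
  models <- vector("list", nRep)
  trainAUC <- testAUC <- numeric(nRep)
  mapSum <- NULL
  for (k in seq_len(nRep)) {
    set.seed(repSeeds[k])
    tr <- sample.int(m, nTrain)
    te <- setdiff(seq_len(m), tr)
    fit <- fitMaxent(Fpr[tr, , drop = FALSE], Fbg, features,
                     betaMultiplier = betaMultiplier, seed = repSeeds[k])
    models[[k]] <- fit
    etaBg <- as.vector(Fbg %*% fit@coefficients)
    etaTr <- as.vector(Fpr[tr, , drop = FALSE] %*% fit@coefficients)
    trainAUC[k] <- aucScore(etaTr, etaBg)
    testAUC[k] <- if (length(te))
      aucScore(as.vector(Fpr[te, , drop = FALSE] %*% fit@coefficients), etaBg)
    else NA_real_
    logi <- predictLogistic(fit, stack)
    mapSum <- if (is.null(mapSum)) gridValues(logi) else
      mapSum + gridValues(logi)
  }
  ref <- stack@layers[[1L]]
  meanMap <- rasterGrid(mapSum / nRep, xOrigin = ref@xOrigin,
                        yOrigin = ref@yOrigin, cellSize = ref@cellSize,
                        nodata = ref@nodata,
                        name = paste0(occ@species, "_suitability"))
  # threshold and TSS on the mean map: training presences vs background
  presScores <- meanMapScores(meanMap, stack, presValues, bgValues,
                              models, nRep)
  tssRes <- maxTSS(presScores$presence, presScores$background)
  theta <- sssThreshold(presScores$presence, presScores$background)
  contrib <- replicateContribution(models)
  eval <- list(
    trainAUC = trainAUC, testAUC = testAUC,
    meanTrainAUC = mean(trainAUC), meanTestAUC = mean(testAUC, na.rm = TRUE),
    maxTSS = tssRes$tss, tssThreshold = tssRes$threshold,
    tssRating = tssRes$rating, sssThreshold = theta,
    contribution = contrib
  )
  structure(list(models = models, meanMap = meanMap, eval = eval,
                 presValues = presValues, bgValues = bgValues,
                 features = features, species = occ@species),
            class = "ReplicateResult")
}

# mean-map logistic scores at presence and background covariate rows
meanMapScores <- function(meanMap, stack, presValues, bgValues, models, nRep) {
  pres <- bg <- 0
  for (fit in models) {
    pres <- pres + maxentScores(fit, presValues)
    bg <- bg + maxentScores(fit, bgValues)
  }
  list(presence = pres / nRep, background = bg / nRep)
}

# replicate-mean percent contribution
replicateContribution <- function(models) {
  tabs <- lapply(models, percentContribution)
  vars <- names(tabs[[1L]])
  mat <- matrix(vapply(tabs, function(t) t[vars], numeric(length(vars))),
                nrow = length(vars), dimnames = list(vars, NULL))
  out <- rowMeans(mat)
  100 * out / sum(out)
}

#' Percent contribution per variable
#'
#' Credits each accepted coordinate-descent update's gain increment to the
#' updated feature's source variable(s) (product features split evenly),
#' floors negatives at zero and normalizes to sum 100. Path-dependent, as in
#' the original MaxEnt tool; see [permutationImportance()] for an
#' order-independent alternative.
#'
#' @param model a [MaxEntModel-class].
#' @return named numeric vector summing to 100.
#' @export
percentContribution <- function(model) {
  vars <- model@features$variables
  acc <- stats::setNames(numeric(length(vars)), vars)
  tr <- model@gainTrace
  for (i in seq_len(nrow(tr))) {
    d <- model@features$defs[[tr$feature[i]]]
    share <- tr$gain[i] / length(d$vars)
    for (v in d$vars) acc[v] <- acc[v] + share
  }
  acc[acc < 0] <- 0
  if (sum(acc) <= 0) {
    warning("zero total gain: contributions undefined, reporting uniform")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * acc / sum(acc)
}

#' Permutation importance per variable
#'
#' Drop in training AUC when a variable's values are permuted jointly across
#' presence and background rows; negatives floored at 0 and normalized to
#' sum 100.
#'
#' @param model a [MaxEntModel-class].
#' @param presValues,bgValues covariate matrices used in fitting.
#' @param seed RNG seed for the permutation.
#' @return named numeric vector summing to 100.
#' @export
permutationImportance <- function(model, presValues, bgValues, seed = 1L) {
  vars <- model@features$variables
  base <- aucScore(maxentScores(model, presValues, type = "eta"),
                   maxentScores(model, bgValues, type = "eta"))
  set.seed(seed)
  drop <- stats::setNames(numeric(length(vars)), vars)
  all <- rbind(presValues, bgValues)
  m <- nrow(presValues)
  for (v in vars) {
    perm <- all
    perm[, v] <- sample(perm[, v])
    auc <- aucScore(maxentScores(model, perm[seq_len(m), , drop = FALSE],
                                 type = "eta"),
                    maxentScores(model, perm[-seq_len(m), , drop = FALSE],
                                 type = "eta"))
    drop[v] <- base - auc
  }
  drop[drop < 0] <- 0
  if (sum(drop) <= 0) return(stats::setNames(rep(100 / length(vars),
                                                 length(vars)), vars))
  100 * drop / sum(drop)
}

#' Jackknife variable importance
#'
#' For each variable, the regularized training gain of a model using only
#' that variable and of a model using all variables except it, alongside the
#' full-model gain.
#'
#' @param presValues,bgValues covariate matrices (named columns).
#' @param classes feature classes (NULL = automatic by presence count).
#' @param nHingeKnots,betaMultiplier passed to the fits.
#' @return data.frame (variable, gainOnly, gainWithout) with attribute
#'   `fullGain`.
#' @export
jackknifeImportance <- function(presValues, bgValues, classes = NULL,
                                nHingeKnots = 8, betaMultiplier = 1) {
  vars <- colnames(presValues)
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  if (is.null(classes)) classes <- autoFeatureClasses(nrow(presValues))
  gainFor <- function(sub) {
    fs <- buildFeatures(rbind(presValues[, sub, drop = FALSE],
                              bgValues[, sub, drop = FALSE]),
                        classes = classes, nHingeKnots = nHingeKnots)
    fit <- fitMaxent(featureDesign(fs, presValues[, sub, drop = FALSE]),
                     featureDesign(fs, bgValues[, sub, drop = FALSE]),
                     fs, betaMultiplier = betaMultiplier)
    trainingGain(fit)
  }
  full <- gainFor(vars)
  only <- vapply(vars, function(v) gainFor(v), 0)
  without <- vapply(vars, function(v) gainFor(setdiff(vars, v)), 0)
  out <- data.frame(variable = vars, gainOnly = only, gainWithout = without,
                    row.names = NULL)
  attr(out, "fullGain") <- full
  out
}
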
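# Small in-code fixtures shared across test files.

# tiny fully valid grid with deterministic values
tinyGrid <- function(nr = 4, nc = 5, cellSize = 30, name = "tiny") {
  rasterGrid(matrix(seq_len(nr * nc), nr, nc), cellSize = cellSize,
             name = name)
}

# small stack of k analytic layers on an nr x nc grid
tinyStack <- function(nr = 10, nc = 10, cellSize = 30) {
  a <- matrix(rep(seq_len(nc), each = nr), nr, nc)        # column gradient
  b <- matrix(rep(seq_len(nr), times = nc), nr, nc)       # row gradient
  envStack(
    A = rasterGrid(a, cellSize = cellSize, name = "A"),
    B = rasterGrid(2 * a + 1, cellSize = cellSize, name = "B"),
    C = rasterGrid(b, cellSize = cellSize, name = "C")
  )
}

# small synthetic scene used by slower integration tests
smallScene <- function(seed = 1, nRows = 60, nCols = 60, nA = 150, nB = 40,
                       nBackground = 1500) {
  spec <- landscapeSpec(nRows = nRows, nCols = nCols, nContinuous = 4,
                        nDistance = 1, seed = seed)
  env <- generateEnvStack(spec)
  nicheA <- nicheParams(c(env1 = 0.8, env3 = -0.5),
                        c(env1 = 0.5, env3 = 0.6))
  nicheB <- nicheParams(c(env1 = 0.4, env3 = 0.1),
                        c(env1 = 0.25, env3 = 0.3))
  occA <- simulateOccurrences(env, nicheA, nA, seed = seed + 1,
                              species = "A")
  occB <- simulateOccurrences(env, nicheB, nB, seed = seed + 2,
                              species = "B")
  bg <- sampleBackground(env, nBackground, seed = seed + 3)
  list(env = env, occA = occA, occB = occB, background = bg,
       nicheA = nicheA, nicheB = nicheB)
}

# exhaustive 1-parameter objective for the grid-search oracle
maxentObjective1d <- function(lambda, Fpr, Fbg, beta) {
  mean(Fpr * lambda) - log(mean(exp(Fbg * lambda))) - beta * abs(lambda)
}

# brute-force AUC over all presence x background pairs
bruteAUC <- function(pres, bg) {
  wins <- outer(pres, bg, function(p, b) (p > b) + 0.5 * (p == b))
  mean(wins)
}

# brute-force TSS / sens+spec sweep over all candidate thresholds
bruteSweep <- function(pres, bg, stat = c("tss", "ss")) {
  stat <- match.arg(stat)
  th <- sort(unique(c(pres, bg)))
  val <- sapply(th, function(t) {
    sens <- mean(pres >= t); spec <- mean(bg < t)
    if (stat == "tss") sens + spec - 1 else sens + spec
  })
  list(best = max(val), threshold = th[which(val == max(val))[1L]])
}
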
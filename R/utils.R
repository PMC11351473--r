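#' Derive per-stage seeds from one master seed
#'
#' Expands a single integer seed into named, deterministic, well-separated
#' stage seeds so each pipeline stage is independently reproducible. All
#' derived seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @return named integer vector of stage seeds.
#' @export
stageSeeds <- function(seed) {
  stages <- c("landscape", "occA", "occB", "background", "replicatesA",
              "replicatesB", "screening", "niche")
  out <- (as.integer(seed) * 2654435761 + 1000003 * seq_along(stages)) %% 2147483647L
  out <- as.integer(abs(out))
  names(out) <- stages
  out
}

# internal: consistent log messages
logMsg <- function(fmt, ...) message(sprintf(fmt, ...))
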
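#' @import methods
#' @importFrom stats fft mvfft rnorm runif rpois rbinom pnorm dnorm sd setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib SeizureMViT, .registration = TRUE
NULL

# Condition helpers: config errors (bad user input / invalid configuration)
# and data errors (unreadable or inconsistent data) carry distinct classes so
# the command-line wrapper can map them to exit codes.
stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("mvitConfigError", "error", "condition")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("mvitDataError", "error", "condition")))
}

#' Derive an independent seed stream from a master seed and integer indices
#'
#' Deterministically mixes a master seed with a tuple of non-negative integer
#' indices (subject, clip, channel, purpose, ...) into a seed in
#' `[0, 2^31 - 2]`. All arithmetic stays below 2^53 so the result is exact in
#' double precision and identical across platforms. Used so that every
#' (subject, clip, channel) of the synthetic generator has its own
#' reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param ... non-negative integer indices identifying the stream.
#' @return an integer seed.
#' @export
mixSeed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in idx) {
    h <- (h * 48271 + (as.numeric(k) %% m) * 16807 + 11) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
localSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

readJson <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
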
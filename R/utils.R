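## internal helpers shared across modules

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-sample random seed from a master seed and a sample id
#'
#' Polynomial rolling hash of the sample id folded into the master seed,
#' reduced modulo 2^31 - 1 so the result is a valid 32-bit integer seed.
#' Deterministic, and distinct ids give (with overwhelming probability)
#' distinct seeds, so samples are reproducible independently of one another.
#'
#' @param master_seed integer master seed.
#' @param sample_id character scalar.
#' @return integer seed in [1, 2^31 - 2].
#' @export
sample_seed <- function(master_seed, sample_id) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            is.character(sample_id), length(sample_id) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(sample_id)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(max(1, h))
}

## stop() with a consistent prefix-free message built from sprintf parts
fail <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

## weighted/unweighted mean that returns NA (not NaN) on empty input
mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
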
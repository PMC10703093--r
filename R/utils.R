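#' @useDynLib amsf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

# Run expr with the global RNG temporarily seeded, restoring prior RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a role-specific sub-seed from a global seed
#'
#' One global seed fans out deterministically to the independent sources of
#' randomness in a run (dataset noise, split, parameter initialization,
#' batch shuffling) by hashing the seed together with a short role string.
#' The result always lies in `[1, 2^31 - 2]` so it is a valid R seed.
#'
#' @param seed integer global seed.
#' @param role character scalar naming the consumer, e.g. `"split"`,
#'   `"init"`, `"noise"`, `"shuffle"`.
#' @return a single integer seed.
#' @examples
#' deriveSeed(7, "split")
#' @export
deriveSeed <- function(seed, role) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(role),
            length(role) == 1L)
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(role)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# consistent error helpers -------------------------------------------------

stopDegenerate <- function(...) stop("degenerate input: ", ..., call. = FALSE)
stopConfig     <- function(...) stop("config error: ", ..., call. = FALSE)
stopShape      <- function(...) stop("shape error: ", ..., call. = FALSE)
stopParam      <- function(...) stop("parameter error: ", ..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
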
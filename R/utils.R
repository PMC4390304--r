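#' Derive a per-task RNG seed from a master seed and a counter
#'
#' All Monte Carlo machinery in the package draws sample `i` under the seed
#' `derive_seed(master, i)`, so any single null sample can be reproduced in
#' isolation (e.g. by calling [permute_track_global()] with that seed).  The
#' scheme is a fixed integer hash reduced modulo 2^31 - 1; it is documented
#' here as part of the package contract and will not change between versions.
#'
#' @param master Master seed, a non-negative integer.
#' @param counter Task counter (sample index), a non-negative integer.
#' @return A numeric scalar in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(42, 1)
#' @export
derive_seed <- function(master, counter) {
  master <- as.double(master)
  counter <- as.double(counter)
  if (any(is.na(master)) || any(is.na(counter)) || master < 0 || counter < 0) {
    stop("derive_seed() needs non-negative integer 'master' and 'counter'")
  }
  lo <- master %% 65536
  hi <- (master %/% 65536) %% 65536
  # all terms stay below 2^53, so the double arithmetic is exact
  (lo * 40503 + hi * 30269 + counter * 2654435761) %% 2147483647
}

# sprintf-style stop/warning without call context noise
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
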
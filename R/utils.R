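#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline (generator, per-region bootstrap, per-grid-point
#' trial simulation) each get their own RNG stream so that adding a region or
#' grid point does not perturb the results of the others. The sub-seed is a
#' 32-bit FNV-1a hash of the stage labels folded into the master seed,
#' reduced below 2^31 so it is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stage
#'   (e.g. `"bootstrap"`, a region name, a grid index).
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1L)), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h <- bitwXor32(h, abs(master) %% 4294967296)
  as.integer(h %% 2147483647)
}

# 32-bit xor on doubles carrying integer values (R's bitwXor needs ints)
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

# Run code with a local RNG state: seeds deterministically, then restores
# whatever state the caller had.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Truncated normal draws via inverse-CDF so they are cheap and seed-stable.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rnorm runif rbinom sd pnorm qnorm pt var coef
#' @importFrom utils read.csv write.csv
NULL
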
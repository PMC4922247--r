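#' @useDynLib fieldscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm logLik median optim pnorm qnorm quantile rbinom
#'   rgamma rlnorm rnorm runif sd setNames var qt pchisq dgamma rexp
#' @importFrom utils head read.csv tail write.csv
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-unit sub-seed from a master seed; stays inside 32-bit range.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

# Normal draw truncated below at `lower` (resampling; fine for mild truncation).
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out >= upper)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mean, lower + sd * 1e-3), upper - sd * 1e-3)
  out
}

# Even-odd ray-casting point-in-polygon test. `poly` is an n x 2 matrix of
# vertices (open ring; closure implied).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# FNV-1a hash of a serialized R object, as a hex string (used for run manifests).
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
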
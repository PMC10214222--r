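# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can distinguish user error
# from numerical failure.
nf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "nichefab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

nf_format_error     <- function(msg) nf_stop(msg, "nichefab_format_error")
nf_validation_error <- function(msg) nf_stop(msg, "nichefab_validation_error")
nf_envelope_error   <- function(msg) nf_stop(msg, "nichefab_envelope_error")
nf_domain_error     <- function(msg) nf_stop(msg, "nichefab_domain_error")
nf_config_error     <- function(msg) nf_stop(msg, "nichefab_config_error")
nf_geometry_error   <- function(msg) nf_stop(msg, "nichefab_geometry_error")
nf_solver_error     <- function(msg) nf_stop(msg, "nichefab_solver_error")
nf_packing_error    <- function(msg) nf_stop(msg, "nichefab_packing_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Classic histogram Otsu threshold on a numeric vector. Returns the
# threshold value; voxels strictly above it belong to the bright class.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) nf_validation_error("no finite values to threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Squared Euclidean distance from points (n x 2) to a polyline (m x 2).
dist2_to_polyline <- function(pts, path) {
  stopifnot(ncol(pts) == 2L, ncol(path) == 2L, nrow(path) >= 1L)
  if (nrow(path) == 1L) {
    return((pts[, 1] - path[1, 1])^2 + (pts[, 2] - path[1, 2])^2)
  }
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]
    b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      cand <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      cand <- (pts[, 1] - (a[1] + t * ab[1]))^2 +
              (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, cand)
  }
  d2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
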
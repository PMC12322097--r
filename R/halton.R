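#' Quasi-random standard-normal draws from scrambled Halton sequences
#'
#' Generates `n` points of a `dim`-dimensional Halton sequence (prime bases,
#' first 50 points dropped), randomised by a seeded Cranley-Patterson rotation
#' (a uniform shift modulo 1 per dimension), and maps them to standard normals
#' by the inverse CDF.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (up to 25).
#' @param seed Integer seed for the rotation; the sequence is deterministic
#'   given `(n, dim, seed)`.
#' @return An `n` x `dim` matrix of standard-normal quasi-random draws.
#' @export
halton_normal <- function(n, dim, seed = 1L) {
  u <- halton_uniform(n, dim, seed)
  stats::qnorm(u)
}

halton_uniform <- function(n, dim, seed = 1L, skip = 50L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
              53, 59, 61, 67, 71, 73, 79, 83, 89, 97)
  if (dim > length(primes)) stop("at most ", length(primes), " Halton dimensions")
  shift <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    stats::runif(dim)
  })
  idx <- (skip + 1L):(skip + n)
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    h <- radical_inverse(idx, primes[d])
    out[, d] <- (h + shift[d]) %% 1
  }
  eps <- 1e-10
  pmin(pmax(out, eps), 1 - eps)
}

radical_inverse <- function(i, base) {
  r <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

# Per-respondent slices of a single Halton stream: respondent n takes rows
# (n-1)*R + 1 .. n*R. Returns xi as an (N, Krand, R) array (or NULL) and eta
# as an N x R matrix (or NULL).
make_draws <- function(N, R, Krand, latent = FALSE, seed = 1L) {
  dim <- Krand + as.integer(latent)
  if (dim == 0L || R < 1L) return(list(xi = NULL, eta = NULL, R = R))
  H <- halton_normal(N * R, dim, seed = seed)
  # rows are ordered draw-fastest within respondent: reshape R x N, transpose
  xi <- NULL
  if (Krand > 0L) {
    xi <- array(0, c(N, Krand, R))
    for (k in seq_len(Krand)) xi[, k, ] <- t(matrix(H[, k], nrow = R))
  }
  eta <- NULL
  if (latent) eta <- t(matrix(H[, dim], nrow = R))
  list(xi = xi, eta = eta, R = R)
}
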
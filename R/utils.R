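#' @useDynLib gustaquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats median sd quantile rnorm rpois runif rlnorm dnorm pchisq
#'   pnorm pt lm coef resid anova aov complete.cases setNames pf rbinom
#' @importFrom utils write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gq <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_gq(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state so that simulations are reproducible without perturbing the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 1D Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve a 3D array along dimension d with a symmetric kernel, reflecting
# at the edges.  Implemented as a dense banded-matrix product, which is fast
# for the slice sizes used here.
conv_along <- function(arr, d, kernel) {
  if (length(kernel) == 1L) return(arr)
  n <- dim(arr)[d]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_along(kernel)) {
      src <- i + j - r - 1L
      # half-sample symmetric reflection
      while (src < 1L || src > n) {
        if (src < 1L) src <- 1L - src
        if (src > n) src <- 2L * n + 1L - src
      }
      K[i, src] <- K[i, src] + kernel[j]
    }
  }
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(arr, perm)
  dims <- dim(ap)
  m <- K %*% matrix(ap, nrow = dims[1])
  dim(m) <- dims
  aperm(m, order(perm))
}

# Separable 3D Gaussian blur; sigma is per-dimension in voxels (y, x, z order).
blur3d <- function(arr, sigma) {
  for (d in 1:3) {
    if (sigma[d] > 0) arr <- conv_along(arr, d, gauss_kernel(sigma[d]))
  }
  arr
}

# Holm-Sidak step-down adjustment of a vector of p-values.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}
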
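#' Eigenvalues of the finite-bath sphere diffusion problem
#'
#' Computes the first `n_roots` non-zero positive roots \eqn{q_n} of the
#' transcendental equation
#' \deqn{\tan q_n = \frac{3 q_n}{3 + \alpha q_n^2},}
#' which sets the decay rates of the limited-volume uptake series. Exactly one
#' root lies in each interval \eqn{(n\pi, n\pi + \pi/2)}: the left side rises
#' from 0 to \eqn{+\infty} across the interval while the right side is
#' positive, bounded and decreasing, so bisection on the bracket is guaranteed
#' to converge.
#'
#' @param alpha Ratio of liquid volume to granule volume (dimensionless,
#'   \eqn{\ge 0}). `alpha = 0` reduces the equation to \eqn{\tan q = q}; large
#'   `alpha` pushes the roots towards \eqn{n\pi}.
#' @param n_roots Number of roots to return (\eqn{\ge 1}).
#' @param residual_tol Maximum allowed residual
#'   \eqn{|\tan q_n - 3q_n/(3+\alpha q_n^2)|} at each returned root.
#'
#' @return A tibble of class `root_spectrum` with columns `n`, `root` and
#'   `residual`, carrying `alpha` and `residual_tol` as attributes. Roots are
#'   strictly increasing.
#'
#' @examples
#' compute_roots(4, 5)
#' # alpha = 0 recovers the classic first root of tan q = q:
#' compute_roots(0, 1)$root  # 4.493409...
#' @export
compute_roots <- function(alpha, n_roots, residual_tol = 1e-12) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(n_roots), length(n_roots) == 1L, n_roots >= 1)
  n_roots <- as.integer(n_roots)
  g <- function(q) tan(q) - 3 * q / (3 + alpha * q^2)
  n <- seq_len(n_roots)
  # bisection, vectorised across all brackets at once; g < 0 at n*pi+,
  # g -> +Inf at n*pi + pi/2-, so the sign of g(mid) steers each bracket
  lo <- n * pi
  hi <- n * pi + pi / 2
  eps <- pmax(1e-13, 4 * .Machine$double.eps * hi)
  lo <- lo + eps
  hi <- hi - eps
  for (iter in 1:90) {
    mid <- (lo + hi) / 2
    up <- g(mid)
    up <- !is.finite(up) | up > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (all((hi - lo) < 1e-14 * hi)) break
  }
  roots <- (lo + hi) / 2
  res <- abs(g(roots))
  # at large q one ulp of the argument already moves tan(q) by ~eps*q, so
  # the residual check is floored at a few ulps of the root
  floor_tol <- pmax(residual_tol, 32 * .Machine$double.eps * roots)
  bad <- which(res > floor_tol)
  if (length(bad)) {
    abort(sprintf(
      "eigenvalue root %d did not converge for alpha = %g (residual %.3e > %.1e)",
      bad[1], alpha, res[bad[1]], residual_tol))
  }
  out <- tibble::tibble(n = seq_len(n_roots), root = roots, residual = res)
  attr(out, "alpha") <- alpha
  attr(out, "residual_tol") <- residual_tol
  class(out) <- c("root_spectrum", class(out))
  out
}

# Bare numeric vector of roots; cached per (alpha, n) within a session.
root_values <- local({
  cache <- new.env(parent = emptyenv())
  function(alpha, n_roots) {
    key <- sprintf("%.17g_%d", alpha, n_roots)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- compute_roots(alpha, n_roots)$root
    cache[[key]] <- v
    v
  }
})
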
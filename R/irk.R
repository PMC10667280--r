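#' Gauss-Legendre implicit Runge-Kutta tableau
#'
#' Builds the Butcher tableau of the `q`-stage Gauss-Legendre collocation
#' scheme on (0, 1): nodes `c` are the roots of the degree-`q` Legendre
#' polynomial (computed by the Golub-Welsch eigenvalue method), weights `b`
#' the corresponding quadrature weights, and the stage matrix
#' `a[n, m] = integral of the m-th Lagrange basis polynomial from 0 to c[n]`,
#' evaluated by exact Gauss quadrature with barycentric interpolation. The
#' construction is numerically stable up to at least `q = 100`.
#'
#' @param q number of stages (>= 1).
#' @return an object of class `irk_scheme` with fields `q`, `A` (q x q), `b`,
#'   `c`.
#' @export
irk_gauss <- function(q) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("q must be a positive integer")
  if (q == 1L) {
    x <- 0; w <- 2
  } else {
    k <- seq_len(q - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, q, q)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    x <- e$values[ord]
    w <- 2 * (e$vectors[1, ord])^2
  }
  cn <- (x + 1) / 2           # nodes on (0,1)
  bn <- w / 2                  # weights, sum to 1

  # barycentric weights of Gauss nodes (closed form, no products)
  wb <- (-1)^(seq_len(q)) * sqrt((1 - x^2) * w)

  # Lagrange basis values at arbitrary points, all m at once
  lag_eval <- function(t) {
    L <- matrix(0, length(t), q)
    for (i in seq_along(t)) {
      d <- t[i] - cn
      hit <- which(abs(d) < 1e-14)
      if (length(hit)) {
        L[i, hit[1]] <- 1
      } else {
        r <- wb / d
        L[i, ] <- r / sum(r)
      }
    }
    L
  }

  # a[n, m] = int_0^{c_n} ell_m ; degree q-1 integrand, q-point Gauss is exact
  A <- matrix(0, q, q)
  for (n in seq_len(q)) {
    tq <- cn[n] / 2 * (x + 1)   # quadrature points on [0, c_n]
    wq <- cn[n] / 2 * w
    A[n, ] <- colSums(lag_eval(tq) * wq)
  }
  structure(list(q = q, A = A, b = bn, c = cn), class = "irk_scheme")
}

#' @export
print.irk_scheme <- function(x, ...) {
  cat(sprintf("<irk_scheme> Gauss-Legendre, q = %d stages on (0, 1)\n", x$q))
  invisible(x)
}
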
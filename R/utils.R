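# Internal helpers: seeded evaluation, polynomial arithmetic, interpolation.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Polynomials are numeric vectors of coefficients in INCREASING power order:
# c(p0, p1, p2) represents p0 + p1*x + p2*x^2.
poly_eval <- function(coefs, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

poly_deriv <- function(coefs) {
  n <- length(coefs)
  if (n <= 1) return(0)
  coefs[-1] * seq_len(n - 1)
}

# Real roots of a polynomial inside [lo, hi], polished and deduplicated.
poly_real_roots <- function(coefs, lo = -Inf, hi = Inf, tol = 1e-7) {
  while (length(coefs) > 1 && abs(coefs[length(coefs)]) <
         1e-12 * max(abs(coefs))) {
    coefs <- coefs[-length(coefs)]
  }
  if (length(coefs) <= 1) return(numeric(0))
  z <- polyroot(coefs)
  scale <- max(1, abs(z))
  re <- Re(z)[abs(Im(z)) < 1e-6 * scale]
  re <- re[re >= lo - tol & re <= hi + tol]
  if (!length(re)) return(numeric(0))
  sort(unique(round(pmin(pmax(re, lo), hi), 10)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
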
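# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; computed once at package build.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (2 * e$vectors[1L, ]^2)[ord])
}

gauss_legendre_64 <- gauss_legendre(64L)

# Half-up rounding to `digits` decimals, used only in report writers so
# printed tables match the usual by-hand convention (R's round() is
# round-half-even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
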
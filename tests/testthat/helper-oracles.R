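# Independent brute-force oracles used across the suite.  They evaluate
# expectations by direct summation over a truncated Poisson pmf (tail mass
# below ~1e-15 for the lambda range exercised) and never call the code
# paths they check.

# E[(Y - lambda)^i] by direct pmf summation
bruteCentralMoment <- function(i, lambda) {
  hi <- ceiling(lambda + 40 * sqrt(lambda) + 40)
  y <- 0:hi
  sum((y - lambda)^i * dpois(y, lambda))
}

# per-pixel KL fidelity F(lambda; y), written independently of klTerm
bruteF <- function(lambda, y) {
  ifelse(y == 0, lambda, lambda - y * log(lambda) + y * log(y) - y)
}

# E[F(Y_lambda)] and Var[F(Y_lambda)] by direct pmf summation
bruteDeltaE <- function(lambda) {
  hi <- ceiling(lambda + 40 * sqrt(lambda) + 40)
  y <- 0:hi
  p <- dpois(y, lambda)
  f <- bruteF(lambda, y)
  m <- sum(f * p)
  list(mean = m, variance = sum((f - m)^2 * p))
}

# dense matrix of the periodic forward-difference gradient (2n x n),
# built column by column from first principles
denseGradient <- function(n1, n2) {
  n <- n1 * n2
  D <- matrix(0, 2 * n, n)
  for (j in seq_len(n)) {
    e <- matrix(0, n1, n2); e[j] <- 1
    gh <- e[, c(2:n2, 1), drop = FALSE] - e
    gv <- e[c(2:n1, 1), , drop = FALSE] - e
    D[, j] <- c(as.vector(gh), as.vector(gv))
  }
  D
}

# dense blur matrix from a model, built by applying it to basis vectors
denseBlur <- function(model) {
  n <- prod(model@dim)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- matrix(0, model@dim[1], model@dim[2]); e[j] <- 1
    H[, j] <- as.vector(applyBlur(model, e))
  }
  H
}
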
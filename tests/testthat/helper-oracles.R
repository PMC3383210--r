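## Independent oracles used to cross-check the package's PLS machinery.

## PLS1 through the Krylov-subspace characterization: the A-component
## PLS1 coefficient vector solves least squares restricted to
## span{s, Ms, ..., M^(A-1) s} with M = X'X, s = X'y. Orthonormalizing
## the Krylov basis keeps it numerically sane; completely independent of
## the NIPALS deflation implemented in the package.
pls1_krylov <- function(X, y, ncomp) {
  Xc <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  yc <- y - mean(y)
  M <- crossprod(Xc)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(Xc), ncomp)
  v <- s
  for (a in seq_len(ncomp)) { K[, a] <- v; v <- M %*% v }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  g <- qr.solve(crossprod(Z), crossprod(Z, yc))
  b <- drop(Q %*% g)
  list(fitted = drop(Xc %*% b) + mean(y), b_scaled = b)
}

## Brute-force leave-one-out through the exported user interface
## (fit_pls + predict), as opposed to the package's internal CV engine.
loo_brute <- function(X, y, ncomp) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  pred
}

## OLS fitted values via QR, the full-rank reference for PLS.
ols_fitted <- function(X, y) {
  Xd <- cbind(1, X)
  drop(Xd %*% qr.solve(Xd, y))
}

## Seeded permutation of a vector without touching global RNG state.
with_seed_perm <- function(v, seed) {
  withr::with_seed(seed, v[sample.int(length(v))])
}

## Small random regression problem with reproducible contents.
random_problem <- function(n, m, seed, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  colnames(X) <- paste0("v", seq_len(m))
  beta <- rnorm(m)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}
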
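# Symmetric FastICA with the tanh contrast function.
#
# Rows of `x` are observed channels, columns samples. The data are
# centred and whitened through the SVD; the unmixing matrix is estimated
# by fixed-point iteration with symmetric decorrelation. Returns the
# component time courses (n_comp x samples) and mixing information.
fast_ica <- function(x, n_comp = min(nrow(x), 20L), max_iter = 200L,
                     tol = 1e-5, seed = 42L) {
  nch <- nrow(x); n <- ncol(x)
  n_comp <- min(n_comp, nch)
  mu <- rowMeans(x)
  xc <- x - mu
  sv <- svd(xc / sqrt(n - 1), nu = n_comp, nv = 0)
  keep <- sv$d[seq_len(n_comp)] > 1e-12 * sv$d[1]
  n_comp <- sum(keep)
  K <- t(sv$u[, keep, drop = FALSE]) / sv$d[keep]  # whitening: K %*% xc
  z <- K %*% xc                                     # n_comp x n, unit covariance

  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp, n_comp)
  sym_decorr <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- (g %*% t(z)) / n - diag(rowMeans(gp), n_comp) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  s <- W %*% z
  list(sources = s, unmixing = W %*% K, whitening = K, center = mu,
       n_comp = n_comp, iterations = it, converged = delta < tol)
}
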
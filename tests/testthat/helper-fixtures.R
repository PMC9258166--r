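# shared fixture builders; everything is generated in code at test time

quick_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_permutations = 150L, n_bootstrap_model = 100L,
               n_bootstrap_vip = 250L)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

null_matrix <- function(n, p, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
}

balanced_labels <- function(n) rep(c(1, -1), each = n / 2)

# X whose first column carries the labels plus noise: a strong planted signal
signal_matrix <- function(n = 40, p = 10, noise = 0.2, seed = 1L) {
  y <- balanced_labels(n)
  X <- null_matrix(n, p, seed)
  X[, 1] <- y + noise * X[, 1]
  list(X = X, y = y)
}

small_dataset <- function(n = 6, p = 4, seed = 1L) {
  set.seed(seed)
  conc <- matrix(exp(rnorm(n * p, 3, 1)), n, p,
                 dimnames = list(sprintf("S%02d", 1:n), paste0("M", 1:p)))
  metabolomics_dataset(conc, group = rep(c("PD", "HC"), length.out = n),
                       age = seq(60, 80, length.out = n))
}

# dominant label-independent factors plus a weak planted group shift: the
# regime where a 3-component PLS-DA fits permuted labels as well as real ones
orthogonal_structure_matrix <- function(seed, n = 78, p = 300, m = 3,
                                        fscale = 40, noise = 0.5,
                                        sig = 30, d = 0.5) {
  set.seed(seed)
  y <- balanced_labels(n)
  Fm <- matrix(rnorm(n * m), n, m)
  L <- matrix(rnorm(p * m), p, m)
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/") * sqrt(p / m)
  X <- fscale * Fm %*% t(L) + noise * matrix(rnorm(n * p), n, p)
  X[, seq_len(sig)] <- X[, seq_len(sig)] + (d / 2) * y
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = y)
}

# five latent blocks with distinct but comparable variance shares, used to
# check that the PCA reduction recovers block structure
five_block_matrix <- function(seed, n = 400, sizes = c(10, 9, 8, 7, 6),
                              ccs = c(0.93, 0.915, 0.9, 0.885, 0.87)) {
  set.seed(seed)
  X <- NULL
  blk <- NULL
  for (b in seq_along(sizes)) {
    lam <- sqrt(ccs[b] / (1 - ccs[b]))
    f <- rnorm(n)
    X <- cbind(X, lam * f + matrix(rnorm(n * sizes[b]), n, sizes[b]))
    blk <- c(blk, rep(b, sizes[b]))
  }
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, block = blk)
}

block_of <- function(ids) sub("_[0-9]+$", "", ids)
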
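# small fixture builders shared across the suite

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(dims = c(6L, 6L, 2L), n_subjects = 3L, n_runs = 2L,
                   n_timepoints = 120L, n_studies = 20L, seed = 42L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# deterministic little brain volume on a 2-mm grid
tiny_volume <- function(dims = c(4, 5, 3), seed = 1) {
  set.seed(seed)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -12, -6)
  brain_vol(array(rnorm(prod(dims)), dims), aff)
}

# random symmetric connected nonnegative affinity on n nodes
random_affinity <- function(n, seed, density = 0.3) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    vals <- ifelse(runif(sum(up)) < density, runif(sum(up)), 0)
    W[up] <- vals
    W <- W + t(W)
    # ensure connectivity via a random spanning chain
    ord <- sample(n)
    for (i in seq_len(n - 1)) W[ord[i], ord[i + 1]] <- W[ord[i + 1], ord[i]] <-
        max(W[ord[i], ord[i + 1]], runif(1, 0.2, 1))
    if (all(rowSums(W) > 0)) return(W)
  }
}

# independent dense diffusion-embedding oracle: eigendecompose the
# nonsymmetric random-walk operator directly
dense_embedding_oracle <- function(W, n_components = 5, alpha = 0.5) {
  d <- rowSums(W)
  Wp <- W / outer(d^alpha, d^alpha)
  dp <- rowSums(Wp)
  P <- Wp / dp
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values[ord])[seq_len(n_components + 1)]
  V <- Re(e$vectors[, ord, drop = FALSE])[, seq_len(n_components + 1), drop = FALSE]
  list(eigenvalues = lam[-1],
       vectors = V[, -1, drop = FALSE],
       trivial = V[, 1])
}

# write a coordinate db to temp TSVs, return paths
write_db_fixture <- function(db) {
  f <- tempfile(fileext = ".tsv"); t <- tempfile(fileext = ".tsv")
  write_coordinate_db(db, f, t)
  list(foci = f, terms = t)
}
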
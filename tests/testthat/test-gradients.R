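test_that("row-wise sparsification keeps exactly the top off-diagonal values", {
  set.seed(3)
  n <- 10
  M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 1
  S <- sparsify_rows(M, 10)
  # ceil(10% of 10) = 1 kept value per row
  expect_true(all(rowSums(S != 0) == 1))
  # kept-min >= dropped-max per row, diagonal excluded
  for (i in 1:n) {
    kept <- S[i, S[i, ] != 0]
    dropped <- M[i, -i][S[i, -i] == 0]
    expect_gte(min(kept), max(dropped))
  }
  expect_true(all(diag(S) == 0))

  # all-equal rows: stable tie-break keeps the first k in voxel order
  E <- matrix(1, 6, 6)
  SE <- sparsify_rows(E, 50)           # ceil(3) per row
  expect_equal(which(SE[1, ] != 0), 2:4)
  expect_equal(which(SE[4, ] != 0), 1:3)
  expect_error(sparsify_rows(M, 0), "top_pct")

  # property on random matrices at the default percentage
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(30^2), 30); A <- (A + t(A)) / 2
    SA <- sparsify_rows(A, 10)
    k <- ceiling(0.1 * 30)
    expect_true(all(rowSums(SA != 0) == k))
  }
})

test_that("cosine affinity matches hand-computed values and flags zero rows", {
  S <- rbind(c(1, 2, 0),
             c(2, 1, 0),
             c(0, 0, 3))
  A <- cosine_affinity(S)
  expect_equal(A[1, 2], 4 / 5, tolerance = 1e-12)   # (2+2)/(sqrt5*sqrt5)
  expect_equal(A[1, 3], 0)                           # orthogonal support
  expect_equal(diag(A), rep(1, 3))
  expect_equal(unclass(A), t(unclass(A)))
  expect_equal(cosine_affinity(rbind(c(1, 2, 0), c(2, 4, 0)))[1, 2], 1,
               tolerance = 1e-12)                    # identical direction
  expect_error(cosine_affinity(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("diffusion embedding orders a chain and is permutation-equivariant", {
  n <- 20
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  gs <- diffusion_embedding(W, 3)
  g1 <- gs$embedding[, 1]
  expect_true(all(diff(g1) > 0) || all(diff(g1) < 0))  # strictly monotone

  # permutation equivariance
  set.seed(7)
  p <- sample(n)
  gsp <- diffusion_embedding(W[p, p], 3)
  al <- function(a, b) if (cor(a, b) < 0) -b else b
  expect_equal(gs$embedding[p, 1], al(gs$embedding[p, 1], gsp$embedding[, 1]),
               tolerance = 1e-8)

  # invariance to uniform positive rescaling of the affinity
  gs2 <- diffusion_embedding(3.7 * W, 3)
  expect_equal(gs$embedding, gs2$embedding, tolerance = 1e-8)

  # disconnected graphs are rejected with advice
  W2 <- W; W2[10, 11] <- W2[11, 10] <- 0
  expect_error(diffusion_embedding(W2, 2), "disconnected")
})

test_that("embedding components are ordered, sign-fixed and variance-normalized", {
  W <- random_affinity(40, seed = 11)
  gs <- diffusion_embedding(W, 6)
  expect_true(all(diff(gs$eigenvalues) <= 1e-12))        # nonincreasing
  expect_true(all(diff(gs$variance_explained) <= 1e-12))
  expect_equal(sum(gs$variance_explained), 1, tolerance = 1e-12)
  for (j in seq_len(ncol(gs$embedding)))
    expect_gt(gs$embedding[which.max(abs(gs$embedding[, j])), j], 0)
})

test_that("variance-explained ratios normalize the eigenvalues", {
  expect_equal(variance_explained(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(variance_explained(rep(3, 5)), rep(0.2, 5))
  set.seed(1)
  ev <- sort(runif(7), decreasing = TRUE)
  expect_equal(sum(variance_explained(ev)), 1)
})

test_that("gradation index hits its boundary and closed-form values", {
  # two disconnected complete components -> exactly 0
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  expect_equal(as.numeric(gradation_index(W)), 0, tolerance = 1e-12)

  # complete uniform graph -> exactly 1, any n
  for (n in c(5, 12, 20)) {
    K <- matrix(1, n, n); diag(K) <- 0
    expect_equal(as.numeric(gradation_index(K)), 1, tolerance = 1e-10)
  }

  # 3-node path: normalized-Laplacian eigenvalues are 0, 1, 2 -> index 2/3
  P3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(as.numeric(gradation_index(P3)), 2 / 3, tolerance = 1e-12)

  expect_error(gradation_index(rbind(c(0, 0), c(0, 0))), "isolated")
})

test_that("extreme clusters take the documented tail sizes, disjointly", {
  g <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  ext <- extreme_clusters(g, 20)         # floor(2) per tail
  expect_equal(ext$low, which(g %in% c(1, 2)))
  expect_equal(ext$high, which(g %in% c(9, 10)))
  expect_length(intersect(ext$low, ext$high), 0)
  expect_equal(length(ext$low), length(ext$high))

  # monotone values: masks are the two ends
  ext2 <- extreme_clusters(1:20, 20)
  expect_equal(ext2$low, 1:4)
  expect_equal(ext2$high, 17:20)
  # ties broken by fixed voxel order
  ext3 <- extreme_clusters(rep(1, 10), 20)
  expect_equal(ext3$low, 1:2)
  expect_error(extreme_clusters(g, 60), "pct")
  expect_error(extreme_clusters(g[1:4], 20), "zero")
})

test_that("gradient rank correlation sign-aligns before reporting", {
  g <- rnorm(50)
  expect_equal(gradient_rank_correlation(g, g)$rho, 1)
  out <- gradient_rank_correlation(g, -g)
  expect_equal(out$rho, 1)
  expect_equal(out$sign, -1)
  expect_error(gradient_rank_correlation(g, rep(0, 50)), "constant")

  # independent gradients: small |rho| in most seeded draws
  cnt <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(200); b <- rnorm(200)
    if (gradient_rank_correlation(a, b)$rho < 0.2) cnt <- cnt + 1
  }
  expect_gte(cnt, 95)
})

test_that("matrix reordering by gradient is a pure permutation", {
  M <- matrix(rnorm(36), 6); M <- M + t(M)
  expect_identical(reorder_by_gradient(M, 1:6), M)
  rev_ord <- reorder_by_gradient(M, 6:1)
  expect_equal(rev_ord, M[6:1, 6:1])
  g <- rnorm(6)
  expect_equal(sort(as.numeric(reorder_by_gradient(M, g))),
               sort(as.numeric(M)))
  expect_error(reorder_by_gradient(M, 1:5), "length")
})

test_that("embed_similarity relaxes sparsity on disconnected graphs", {
  # block-diagonal similarity disconnects at 10% but embeds once relaxed
  set.seed(9)
  n <- 40
  R <- diag(n)
  R[1:20, 1:20] <- 0.8; R[21:40, 21:40] <- 0.8
  R <- R + matrix(rnorm(n * n, 0, 0.02), n); R <- (R + t(R)) / 2; diag(R) <- 1
  gs <- embed_similarity(R, top_pct = 10, n_components = 2)
  expect_gt(gs$top_pct_used, 10)
  blk <- rep(1:2, each = 20)
  expect_gt(abs(cor(gs$embedding[, 1], blk, method = "spearman")), 0.8)
})
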
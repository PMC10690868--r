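#' Row-wise sparsification of a similarity matrix
#'
#' Keeps, per row, the `ceiling(pct * n / 100)` largest off-diagonal values
#' and zeroes the rest. Ties are broken by ascending voxel order (a stable
#' rule fixed by the ROI raster order), so every kept value is at least as
#' large as every dropped value in its row. The result is row-sparse and in
#' general asymmetric; symmetry is restored by the cosine affinity step.
#'
#' @param mat n x n similarity matrix.
#' @param top_pct percentage of values to keep per row, in (0, 100\].
#' @return matrix of the same shape with dropped entries set to 0 and a
#'   zero diagonal; attribute `top_pct` records the threshold.
#' @export
sparsify_rows <- function(mat, top_pct = 10) {
  if (!(top_pct > 0 && top_pct <= 100)) stop("top_pct must be in (0, 100]")
  mat <- unclass(as.matrix(mat))
  n <- nrow(mat)
  k <- min(ceiling(top_pct * n / 100), n - 1L)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    v <- mat[i, ]
    v[i] <- -Inf                          # diagonal excluded
    keep <- order(v, seq_len(n), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(k)]
    out[i, keep] <- mat[i, keep]
  }
  structure(out, top_pct = top_pct)
}

#' Cosine affinity between sparse similarity rows
#'
#' `affinity(i, j)` is the cosine similarity between rows i and j of the
#' sparsified matrix; symmetric by construction. Negative cosines are
#' clipped to 0 so the affinity is a valid nonnegative graph weight for the
#' Markov construction.
#'
#' @param sparse_mat row-sparse matrix from [sparsify_rows()].
#' @return n x n symmetric nonnegative `affinity_matrix` (unit diagonal).
#' @export
cosine_affinity <- function(sparse_mat) {
  sparse_mat <- unclass(as.matrix(sparse_mat))
  nrm <- sqrt(rowSums(sparse_mat^2))
  zero <- nrm == 0
  if (any(zero))
    stop("all-zero sparsified row for voxel(s) ",
         paste(which(zero), collapse = ", "))
  A <- tcrossprod(sparse_mat / nrm)
  A[A < 0] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 1
  structure(A, class = c("affinity_matrix", "matrix", "array"))
}

# connected components of the positive-weight graph
.n_components <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' Diffusion embedding of an affinity matrix
#'
#' Anisotropic-diffusion spectral embedding: the affinity is normalized as
#' `W' = D^-alpha W D^-alpha`, the random-walk operator `P = D'^-1 W'` is
#' eigendecomposed via its symmetric conjugate, the trivial constant
#' component is dropped, and coordinates follow the automatic
#' diffusion-time convention: component k is the k-th nontrivial right
#' eigenvector of P (normalized against the stationary component) scaled by
#' `lambda_k / (1 - lambda_k)`. The embedding is deterministic up to
#' per-component sign, which is fixed so that the entry of largest absolute
#' loading is positive.
#'
#' @param affinity symmetric nonnegative matrix (connected positive graph).
#' @param n_components number of nontrivial components to return.
#' @param alpha anisotropic normalization exponent (0.5 = Fokker-Planck).
#' @return a `gradient_set`: list with `embedding` (n x k), `eigenvalues`
#'   (nontrivial, nonincreasing), `variance_explained`, `n_components`,
#'   `alpha`.
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5) {
  W <- unclass(as.matrix(affinity))
  n <- nrow(W)
  if (max(abs(W - t(W))) > 1e-10) stop("affinity must be symmetric")
  if (min(W) < 0) stop("affinity must be nonnegative")
  d <- rowSums(W)
  if (any(d == 0)) stop("isolated node(s): ", paste(which(d == 0), collapse = ", "))
  if (.n_components(W) > 1)
    stop("affinity graph is disconnected; the diffusion embedding is ",
         "ill-defined - relax the sparsification threshold until the graph ",
         "is connected")
  k <- min(n_components, n - 1L)
  Wp <- W / outer(d^alpha, d^alpha)
  dp <- rowSums(Wp)
  M <- Wp / outer(sqrt(dp), sqrt(dp))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(k + 1L)]
  psi <- e$vectors[, seq_len(k + 1L), drop = FALSE] / sqrt(dp)
  psi <- psi / psi[1, 1]                 # normalize against the stationary vector
  lam_nt <- lam[-1]
  emb <- sweep(psi[, -1, drop = FALSE], 2, lam_nt / (1 - lam_nt), "*")
  for (j in seq_len(ncol(emb))) {
    # highest-|loading| voxel made positive; ties (e.g. symmetric graphs)
    # broken by the lowest voxel index so the choice is scale-invariant
    mx <- max(abs(emb[, j]))
    lead <- min(which(abs(emb[, j]) >= mx * (1 - 1e-9)))
    if (emb[lead, j] < 0) emb[, j] <- -emb[, j]
  }
  structure(list(embedding = emb, eigenvalues = lam_nt,
                 variance_explained = variance_explained(lam_nt),
                 n_components = k, alpha = alpha),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d voxels x %d components; var explained: %s\n",
              nrow(x$embedding), x$n_components,
              paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(min(3, x$n_components))]),
                    collapse = ", ")))
  invisible(x)
}

#' Variance-explained ratios of embedding eigenvalues
#'
#' Ratio of each retained nontrivial eigenvalue to their sum; nonincreasing
#' and summing to 1 over the retained set.
#'
#' @param eigenvalues nontrivial eigenvalues from [diffusion_embedding()].
#' @return numeric ratios.
#' @export
variance_explained <- function(eigenvalues) {
  if (any(eigenvalues < -1e-12)) eigenvalues <- pmax(eigenvalues, 0)
  eigenvalues / sum(eigenvalues)
}

#' Normalized algebraic connectivity (gradation index)
#'
#' The second-smallest eigenvalue of the symmetric normalized Laplacian
#' `L = I - D^-1/2 W D^-1/2`, scaled by `(n - 1) / n` so the index lies in
#' \[0, 1\]: it is 0 iff the graph has at least two disconnected
#' components, and 1 iff the graph is complete with uniform weights (purely
#' graded organization). Negative similarity entries are clipped to 0 and
#' the diagonal is ignored (no self-loops).
#'
#' @param mat symmetric matrix of similarity or affinity weights.
#' @param level descriptive tag stored on the result (`"group"` or
#'   `"subject"`).
#' @return scalar of class `gradation_index` with attribute `level`.
#' @export
gradation_index <- function(mat, level = "group") {
  W <- unclass(as.matrix(mat))
  n <- nrow(W)
  if (max(abs(W - t(W))) > 1e-8) stop("matrix must be symmetric")
  W <- (W + t(W)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  d <- rowSums(W)
  if (any(d == 0))
    stop("isolated node(s) with zero degree: ",
         paste(which(d == 0), collapse = ", "))
  L <- diag(n) - W / outer(sqrt(d), sqrt(d))
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  val <- max(0, ev[2]) * (n - 1) / n
  structure(val, level = level, class = "gradation_index")
}

#' @export
print.gradation_index <- function(x, ...) {
  cat(sprintf("gradation index (%s level): %.4f\n", attr(x, "level"),
              as.numeric(x)))
  invisible(x)
}

#' Gradient-extreme clusters
#'
#' Voxel sets with the `pct` lowest and `pct` highest values of a gradient
#' (`floor(pct * n / 100)` voxels per tail; ties broken by ascending voxel
#' order). The two masks are disjoint and equal-sized.
#'
#' @param gradient_values numeric vector over ROI voxels.
#' @param pct tail percentage, in (0, 50).
#' @return list with integer index vectors `low` and `high`.
#' @export
extreme_clusters <- function(gradient_values, pct = 20) {
  if (!(pct > 0 && pct < 50)) stop("pct must be in (0, 50)")
  n <- length(gradient_values)
  k <- floor(pct * n / 100)
  if (k < 1) stop("tail size is zero at this pct and n")
  ord <- order(gradient_values, seq_len(n), method = "radix")
  list(low = sort(ord[seq_len(k)]),
       high = sort(ord[n + 1L - seq_len(k)]))
}

#' Rank correlation between two gradients
#'
#' Spearman correlation of the voxels' gradient ranks. Gradient polarity is
#' arbitrary, so the sign of the second gradient is chosen to maximize the
#' correlation magnitude; the reported value is for the aligned
#' orientation, and the chosen sign is returned.
#'
#' @param g_a,g_b numeric gradients over the same voxel set.
#' @return list with `rho` (aligned Spearman correlation) and `sign` (+1 or
#'   -1, the orientation applied to `g_b`).
#' @export
gradient_rank_correlation <- function(g_a, g_b) {
  if (length(g_a) != length(g_b)) stop("gradients must cover the same voxels")
  if (stats::sd(g_a) == 0 || stats::sd(g_b) == 0)
    stop("constant gradient")
  rho <- stats::cor(g_a, g_b, method = "spearman")
  s <- if (rho < 0) -1 else 1
  list(rho = abs(rho) * 1, sign = s)
}

#' Reorder a matrix by gradient position
#'
#' @param mat n x n matrix.
#' @param gradient_values length-n vector; rows/columns are permuted by
#'   ascending value.
#' @return reordered matrix.
#' @export
reorder_by_gradient <- function(mat, gradient_values) {
  mat <- as.matrix(mat)
  if (nrow(mat) != length(gradient_values))
    stop("gradient length does not match the matrix")
  ord <- order(gradient_values, seq_along(gradient_values), method = "radix")
  mat[ord, ord]
}

#' Largest-to-median gap ratio of sorted gradient values
#'
#' Discontinuity diagnostic: the ratio of the largest to the median gap
#' between consecutive sorted gradient values. Graded maps have no dominant
#' gap; a hard boundary shows up as one gap orders of magnitude above the
#' median.
#'
#' @param gradient_values numeric vector.
#' @return scalar ratio (may be `Inf` when the median gap is 0).
#' @export
gradient_gap_ratio <- function(gradient_values) {
  gaps <- diff(sort(gradient_values))
  max(gaps) / stats::median(gaps)
}

#' Embed with automatic sparsity relaxation
#'
#' Runs sparsification, cosine affinity and diffusion embedding; when the
#' affinity graph at the requested sparsity is disconnected (the embedding
#' is then ill-defined), the kept percentage is increased stepwise until
#' the graph connects, as the embedding error message instructs.
#'
#' @param sim similarity matrix.
#' @param top_pct starting row-wise percentage.
#' @param n_components,alpha passed to [diffusion_embedding()].
#' @param step percentage increment per relaxation.
#' @param max_pct give up beyond this percentage.
#' @return a `gradient_set` with an extra element `top_pct_used`.
#' @export
embed_similarity <- function(sim, top_pct = 10, n_components = 10,
                             alpha = 0.5, step = 10, max_pct = 100) {
  pct <- top_pct
  repeat {
    A <- cosine_affinity(sparsify_rows(sim, pct))
    if (.n_components(unclass(A)) == 1) break
    pct <- pct + step
    if (pct > max_pct)
      stop("affinity graph remains disconnected even at 100% density")
  }
  gs <- diffusion_embedding(A, n_components, alpha)
  gs$top_pct_used <- pct
  gs
}
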
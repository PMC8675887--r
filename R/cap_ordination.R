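#' Column-standardize a parameter matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation, the
#' normalization applied before Euclidean distances are computed so that
#' parameters on very different scales (e.g. fluxes in a.u. vs
#' dimensionless yields) contribute comparably. Rows containing missing
#' values are dropped with a message; zero-variance columns are dropped
#' with a warning.
#'
#' @param X Numeric matrix or data frame, samples in rows.
#' @param method `"zscore"` (default) or `"none"` (identity).
#' @return Numeric matrix; attribute `dropped_rows` lists removed rows.
#' @export
normalize_matrix <- function(X, method = c("zscore", "none")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  bad <- apply(X, 1L, function(r) any(!is.finite(r)))
  dropped <- rownames(X)[bad]
  if (any(bad)) {
    message(sprintf("dropping %d row(s) with missing values: %s",
                    sum(bad), paste(dropped, collapse = ", ")))
    X <- X[!bad, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("need at least 2 complete samples")
  if (method == "none") {
    attr(X, "dropped_rows") <- dropped
    return(X)
  }
  sds <- apply(X, 2L, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (all(zero)) stop("all columns have zero variance")
  if (any(zero))
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(X)[zero], collapse = ", ")))
  X <- scale(X[, !zero, drop = FALSE])
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  attr(X, "dropped_rows") <- dropped
  X
}

# Gower double-centering of squared distances: G = -1/2 J (D o D) J
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm <- rowMeans(A); gm <- mean(A)
  A - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + gm
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: Gower double-centering of the squared distances
#' followed by a symmetric eigendecomposition. Eigenvalues are returned in
#' descending order; axis scores (`eigenvector * sqrt(eigenvalue)`) are
#' formed for positive eigenvalues only, and negative eigenvalues (which
#' arise for non-Euclidean dissimilarities) are reported but excluded from
#' the score space.
#'
#' @param D A `dist` object or a symmetric non-negative matrix with zero
#'   diagonal.
#' @return List of class `pcoa` with `eigenvalues` (all, descending),
#'   `vectors` (orthonormal eigenvectors of the positive axes), `scores`
#'   (vectors scaled by sqrt eigenvalue), `negative_eigenvalues`, and
#'   `gower_diag` (diagonal of the centered matrix, used to project new
#'   points).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have a zero diagonal")
  G <- .gower_center(D)
  ev <- eigen(G, symmetric = TRUE)
  tol <- max(abs(ev$values), 1) * 1e-9
  pos <- ev$values > tol
  vectors <- ev$vectors[, pos, drop = FALSE]
  scores <- sweep(vectors, 2L, sqrt(ev$values[pos]), `*`)
  rownames(vectors) <- rownames(scores) <- rownames(D)
  structure(list(eigenvalues = ev$values,
                 vectors = vectors,
                 scores = scores,
                 positive = which(pos),
                 negative_eigenvalues = ev$values[ev$values < -tol],
                 gower_diag = diag(G)),
            class = "pcoa")
}

# Gower add-a-point: orthonormal-axis coordinates of a new sample from its
# squared distances to the training samples.
.pcoa_project <- function(pc, d2_new) {
  lambda <- pc$eigenvalues[pc$positive]
  b <- -0.5 * (d2_new - pc$gower_diag)
  as.numeric(crossprod(pc$vectors, b) / lambda)
}

# Per-holdout reduced-space bases, computed once per fit: the PCoA of the
# n-1 training samples and the Gower projection of the held-out sample do
# not depend on group labels, so they are shared by the observed fit and
# by every permutation.
.precompute_holdouts <- function(D) {
  n <- nrow(D)
  lapply(seq_len(n), function(i) {
    pc <- pcoa(D[-i, -i, drop = FALSE])
    list(Q = pc$vectors, q0 = .pcoa_project(pc, D[i, -i]^2))
  })
}

# Canonical axes of the retained orthonormal axes Qm against the
# group-indicator space. Qm' H Qm = C' C with C the g x m matrix whose
# rows are sqrt(n_g) * group means, so the canonical squared correlations
# are the squared singular values of C and the axis-defining vectors its
# right singular vectors; an SVD of the small C replaces an m x m eigen.
.canonical_from_means <- function(M, cnt, k) {
  C <- M * sqrt(cnt)
  sv <- svd(C, nu = 0L)
  list(sq_corr = pmin(pmax(sv$d[seq_len(k)]^2, 0), 1),
       axes = sv$v[, seq_len(k), drop = FALSE])
}

# Leave-one-out nearest-centroid allocation for each candidate m under a
# given labeling. Returns the success rate per m (and optionally the
# predicted label matrix).
.loo_success <- function(holdouts, labels_int, g, m_values,
                         return_pred = FALSE) {
  n <- length(holdouts)
  pred <- if (return_pred)
    matrix(NA_integer_, n, length(m_values)) else NULL
  hits <- integer(length(m_values))
  for (i in seq_len(n)) {
    h <- holdouts[[i]]
    labs <- labels_int[-i]
    cnt <- tabulate(labs, nbins = g)
    M <- rowsum(h$Q, labs) / cnt
    r_i <- ncol(h$Q)
    for (j in seq_along(m_values)) {
      m <- min(m_values[j], r_i)
      k <- min(m, g - 1L)
      can <- .canonical_from_means(M[, seq_len(m), drop = FALSE], cnt, k)
      cent <- M[, seq_len(m), drop = FALSE] %*% can$axes
      z0 <- as.numeric(h$q0[seq_len(m)] %*% can$axes)
      d2 <- rowSums((cent - matrix(z0, g, k, byrow = TRUE))^2)
      p <- which.min(d2)
      if (p == labels_int[i]) hits[j] <- hits[j] + 1L
      if (return_pred) pred[i, j] <- p
    }
  }
  list(success = hits / n, pred = pred)
}

# Trace statistic tr(Qm' H Qm) = sum_g ||group sum of Qm rows||^2 / n_g.
.trace_stat <- function(Q, labels_int, g, m) {
  S <- rowsum(Q[, seq_len(m), drop = FALSE], labels_int)
  cnt <- tabulate(labels_int, nbins = g)
  sum(S^2 / cnt)
}

#' CAP configuration
#'
#' @param m Number of principal-coordinate axes to retain, or `"auto"`
#'   (default) to pick the m in `1..min(rank, n - 2)` that maximizes
#'   leave-one-out allocation success, ties broken toward smaller m.
#' @param n_permutations Number of random relabelings for the permutation
#'   test (default 999).
#' @param seed Integer seed governing the permutations.
#' @param normalization `"zscore"` (default) or `"none"`, applied to the
#'   input matrix before distances are computed.
#' @return A list of class `cap_config`.
#' @export
cap_config <- function(m = "auto", n_permutations = 999L, seed = 1L,
                       normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  if (!(identical(m, "auto") || (is.numeric(m) && length(m) == 1L && m >= 1)))
    stop("m must be a positive integer or \"auto\"")
  stopifnot(n_permutations >= 1L)
  structure(list(m = m, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), normalization = normalization),
            class = "cap_config")
}

#' Canonical Analysis of Principal Coordinates
#'
#' CAP for classification: Euclidean distances of the (normalized) sample
#' x parameter matrix, principal coordinates analysis, retention of m
#' orthonormal PCoA axes, and a canonical eigenanalysis of those axes
#' against the group-indicator space. Group separation is summarized by
#' the trace statistic (sum of canonical squared correlations);
#' classification success is measured by leave-one-out allocation to the
#' nearest group centroid in canonical space, with the PCoA re-fitted for
#' every holdout and the held-out sample projected onto the reduced-space
#' axes (Gower's add-a-point), so the allocation is free of information
#' leakage.
#'
#' The permutation p-value compares the observed trace with traces under
#' random relabelings, `p = (count of permuted traces >= observed + 1) /
#' (n_permutations + 1)`. When `m = "auto"`, the axis selection is itself
#' label-dependent, so the whole procedure — LOO-based choice of m, then
#' the trace at the chosen m — is repeated for every relabeling; this
#' keeps the statistic exchangeable under the null and the test exact.
#' With a fixed `m` the permuted traces use that m directly.
#'
#' @param X Numeric matrix or data frame (samples x variables) with row
#'   names as sample ids.
#' @param groups Factor (or coercible) of group labels, one per row of
#'   `X`; every group must have at least 2 samples.
#' @param cfg A [cap_config()].
#' @return An object of class `cap_result`: `eigenvalues` (PCoA, all),
#'   `m_used`, `canonical_sq_corr`, `canonical_scores`, `allocation`
#'   (true x predicted confusion table), `n_correct`, `loo_success_by_m`,
#'   `trace_statistic`, `p_perm`, `groups`, `cfg`.
#' @export
cap_fit <- function(X, groups, cfg = cap_config()) {
  X <- as.matrix(X)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(X)) stop("groups must have one label per row of X")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  n <- nrow(X)
  g <- nlevels(groups)
  labels_int <- as.integer(groups)
  Xn <- normalize_matrix(X, method = cfg$normalization)
  if (nrow(Xn) != n) stop("rows with missing values are not allowed in cap_fit")
  D <- as.matrix(stats::dist(Xn))
  pc <- pcoa(D)
  r <- ncol(pc$vectors)
  m_max <- min(r, n - 2L)
  if (m_max < 1L) stop("not enough samples for any principal-coordinate axis")
  auto <- identical(cfg$m, "auto")
  if (auto) {
    m_values <- seq_len(m_max)
  } else {
    if (cfg$m > n - 2L) stop("m must not exceed n - 2")
    if (cfg$m > r) stop(sprintf("m = %d exceeds the positive rank (%d)", cfg$m, r))
    m_values <- as.integer(cfg$m)
  }
  holdouts <- .precompute_holdouts(D)
  obs <- .loo_success(holdouts, labels_int, g, m_values, return_pred = TRUE)
  best <- which.max(obs$success)        # ties: first = smallest m
  m_used <- m_values[best]
  pred_used <- factor(levels(groups)[obs$pred[, best]], levels = levels(groups))
  allocation <- table(true = groups, predicted = pred_used)
  n_correct <- sum(diag(allocation))

  cnt <- tabulate(labels_int, nbins = g)
  Mu <- rowsum(pc$vectors[, seq_len(m_used), drop = FALSE], labels_int) / cnt
  can <- .canonical_from_means(Mu, cnt, k = min(m_used, g - 1L))
  scores <- pc$vectors[, seq_len(m_used), drop = FALSE] %*% can$axes
  rownames(scores) <- rownames(Xn)
  colnames(scores) <- paste0("CAP", seq_len(ncol(scores)))
  trace_obs <- .trace_stat(pc$vectors, labels_int, g, m_used)

  perm_traces <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(b) {
      perm <- labels_int[sample.int(n)]
      m_b <- if (auto) {
        sb <- .loo_success(holdouts, perm, g, m_values)$success
        m_values[which.max(sb)]
      } else m_used
      .trace_stat(pc$vectors, perm, g, m_b)
    }, numeric(1))
  })
  p_perm <- (sum(perm_traces >= trace_obs - 1e-12) + 1) / (cfg$n_permutations + 1)

  structure(list(eigenvalues = pc$eigenvalues,
                 m_used = m_used,
                 canonical_sq_corr = can$sq_corr,
                 canonical_scores = scores,
                 allocation = allocation,
                 n_correct = n_correct,
                 loo_success_by_m = stats::setNames(obs$success, m_values),
                 trace_statistic = trace_obs,
                 p_perm = p_perm,
                 groups = groups,
                 cfg = cfg),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  n <- length(x$groups)
  cat(sprintf("CAP: %d samples, %d groups, m = %d axes retained\n",
              n, nlevels(x$groups), x$m_used))
  cat(sprintf("  leave-one-out allocation: %d/%d correct (%.1f%%)\n",
              x$n_correct, n, 100 * x$n_correct / n))
  cat(sprintf("  trace = %.4f, permutation p = %.4g (%d permutations)\n",
              x$trace_statistic, x$p_perm, x$cfg$n_permutations))
  invisible(x)
}

#' Plot a CAP ordination
#'
#' Scatter of samples on the first two canonical axes, colored by group;
#' falls back to a one-dimensional strip plot when only one canonical axis
#' exists. Written as a PNG file.
#'
#' @param result A `cap_result`.
#' @param path Output image path.
#' @param metadata Optional metadata data frame; when supplied, every
#'   plotted sample must appear in its `sample_id` column.
#' @return Invisibly, `path`.
#' @export
plot_cap <- function(result, path, metadata = NULL) {
  scores <- result$canonical_scores
  if (!is.null(metadata)) {
    missing_ids <- setdiff(rownames(scores), metadata$sample_id)
    if (length(missing_ids))
      stop(sprintf("metadata missing for sample(s): %s",
                   paste(missing_ids, collapse = ", ")))
  }
  groups <- result$groups
  pal <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  grDevices::png(path, width = 900, height = 700, res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (ncol(scores) >= 2L) {
    graphics::plot(scores[, 1L], scores[, 2L], col = pal[as.integer(groups)],
                   pch = 19, xlab = "CAP1", ylab = "CAP2",
                   main = "Canonical analysis of principal coordinates")
  } else {
    graphics::plot(jitter(as.integer(groups)), scores[, 1L],
                   col = pal[as.integer(groups)], pch = 19, xaxt = "n",
                   xlab = "group", ylab = "CAP1",
                   main = "Canonical analysis of principal coordinates")
    graphics::axis(1, at = seq_len(nlevels(groups)), labels = levels(groups),
                   las = 2, cex.axis = 0.7)
  }
  graphics::legend("topright", legend = levels(groups), col = pal,
                   pch = 19, cex = 0.7)
  invisible(path)
}
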
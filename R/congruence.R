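# Distance-based host-parasite congruence testing.
#
# Host and parasite distance matrices are embedded by principal coordinates
# analysis; the cross-product of the two coordinate sets through the
# association matrix gives a global congruence statistic whose null
# distribution is obtained by permuting host identities. This tests the
# independence of host and parasite (patristic or genetic) distances given
# the observed links, without assuming that congruence is produced by
# cospeciation.

#' Principal coordinates analysis of a distance matrix
#'
#' Double-centers `-D^2/2`, eigendecomposes, and keeps axes whose eigenvalue
#' exceeds `1e-10` times the largest one; coordinates are eigenvectors
#' scaled by the square root of their eigenvalue, so Euclidean distances
#' among coordinates reproduce the input distances when the matrix is
#' Euclidean. Negative eigenvalues are dropped (no Lingoes/Cailliez
#' correction) unless `correction = "cailliez"`.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param correction `"none"` (default) or `"cailliez"` (adds the smallest
#'   constant to off-diagonal distances making the matrix Euclidean).
#' @return list of class `"pcoa_axes"` with `coordinates` (taxa x axes) and
#'   `eigenvalues`.
#' @export
pcoa_axes <- function(D, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) ||
      !isTRUE(all.equal(D, t(D), check.attributes = FALSE, tolerance = 1e-8))) {
    stop2("pcoa_axes requires a symmetric distance matrix")
  }
  if (any(abs(diag(D)) > 1e-12)) stop2("distance matrix diagonal must be zero")
  n <- nrow(D)
  if (correction == "cailliez" && n > 2L) {
    # Cailliez (1983): smallest c so that d_ij + c (i != j) is Euclidean
    D2 <- D^2
    J <- diag(n) - 1 / n
    F1 <- -0.5 * J %*% D2 %*% J
    F2 <- -0.5 * J %*% D %*% J
    M <- rbind(cbind(matrix(0, n, n), 2 * F1),
               cbind(-diag(n), -4 * F2))
    cail <- max(Re(eigen(M, only.values = TRUE)$values))
    if (cail > 0) {
      D <- D + cail
      diag(D) <- 0
    }
  }
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- which(e$values > 1e-10 * max(e$values, 0))
  coords <- if (length(keep)) {
    e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(e$values[keep]), nrow = length(keep))
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = e$values[keep]),
            class = "pcoa_axes")
}

# align distance matrices with the link matrix and embed both
.parafit_setup <- function(host_D, parasite_D, links) {
  hosts <- colnames(links)
  parasites <- rownames(links)
  if (length(hosts) < 3L || length(parasites) < 3L) {
    stop2("need at least 3 hosts and 3 parasites for a congruence test")
  }
  if (!all(hosts %in% rownames(host_D))) {
    stop2("host distance matrix does not cover all linked hosts")
  }
  if (!all(parasites %in% rownames(parasite_D))) {
    stop2("parasite distance matrix does not cover all linked parasites")
  }
  validate_links(links)
  B <- pcoa_axes(host_D[hosts, hosts])$coordinates
  C <- pcoa_axes(parasite_D[parasites, parasites])$coordinates
  list(A = links, B = B, C = C)
}

#' Global test of host-parasite congruence
#'
#' The global statistic is the sum of squared entries of
#' `t(C) %*% A %*% B`, where `B` and `C` are the host and parasite
#' principal-coordinate matrices and `A` the binary association matrix. The
#' null distribution permutes host identities (rows of `B`); the p-value
#' uses the add-one convention.
#'
#' @param host_D,parasite_D symmetric distance matrices covering the hosts /
#'   parasites of `links` (patristic or genetic distances).
#' @param links binary parasite-by-host matrix.
#' @param n_perm number of permutations (9999 by convention).
#' @param seed integer seed.
#' @return list of class `"congruence_test"` with `statistic`, `p_value`,
#'   `n_perm`, `seed` and the permutation sample `null`.
#' @export
parafit_global <- function(host_D, parasite_D, links, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .parafit_setup(host_D, parasite_D, links)
  CtA <- crossprod(s$C, s$A)          # axes_p x hosts
  stat <- sum((CtA %*% s$B)^2)
  nh <- nrow(s$B)
  null <- vapply(seq_len(n_perm), function(i) {
    sum((CtA %*% s$B[sample.int(nh), , drop = FALSE])^2)
  }, 0)
  structure(list(statistic = stat,
                 p_value = (1 + sum(null >= stat)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, null = null),
            class = "congruence_test")
}

#' @export
print.congruence_test <- function(x, ...) {
  cat(sprintf("host-parasite congruence: statistic %.6g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  if (!is.null(x$links)) {
    cat(sprintf("  %d/%d links significant at 0.05\n",
                sum(x$links$p_value <= 0.05), nrow(x$links)))
  }
  invisible(x)
}

#' Per-link contributions to host-parasite congruence
#'
#' Each link's statistic is the drop in the global statistic when that link
#' is removed from the association matrix; the same host permutations give
#' per-link p-values. For coordinates `C` (parasites), `B` (hosts) and
#' cross-product `D4 = t(C) A B`, removing link (i, j) subtracts the rank-1
#' term `outer(C[i,], B[j,])`, so each link statistic has the closed form
#' `2 * C[i,] D4 B[j,] - |C_i|^2 |B_j|^2`.
#'
#' @inheritParams parafit_global
#' @return list of class `"congruence_test"`; `links` is a data frame with
#'   one row per association (parasite, host, statistic, p_value).
#' @export
parafit_links <- function(host_D, parasite_D, links, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .parafit_setup(host_D, parasite_D, links)
  A <- s$A; B <- s$B; C <- s$C
  CtA <- crossprod(C, A)
  idx <- which(A == 1L, arr.ind = TRUE)
  cc2 <- rowSums(C^2)
  link_stats <- function(Bp) {
    D4 <- CtA %*% Bp
    S <- C %*% D4 %*% t(Bp)           # parasites x hosts
    bb2 <- rowSums(Bp^2)
    list(global = sum(D4^2),
         per_link = 2 * S[idx] - cc2[idx[, 1]] * bb2[idx[, 2]])
  }
  obs <- link_stats(B)
  nh <- nrow(B)
  ge_global <- 0
  ge_link <- numeric(nrow(idx))
  for (i in seq_len(n_perm)) {
    p <- link_stats(B[sample.int(nh), , drop = FALSE])
    ge_global <- ge_global + (p$global >= obs$global)
    ge_link <- ge_link + (p$per_link >= obs$per_link)
  }
  structure(list(statistic = obs$global,
                 p_value = (1 + ge_global) / (1 + n_perm),
                 n_perm = n_perm, seed = seed,
                 links = data.frame(
                   parasite = rownames(A)[idx[, 1]],
                   host = colnames(A)[idx[, 2]],
                   statistic = obs$per_link,
                   p_value = (1 + ge_link) / (1 + n_perm))),
            class = "congruence_test")
}
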
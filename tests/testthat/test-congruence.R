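euclid_D <- function(X, labs = NULL) {
  D <- as.matrix(stats::dist(X))
  labs <- labs %||% paste0("x", seq_len(nrow(D)))
  dimnames(D) <- list(labs, labs)
  D
}
`%||%` <- function(a, b) if (is.null(a)) b else a

congruent_data <- function(n, seed) {
  host <- simulate_yule(n, 1, seed = seed, labels = paste0("H", seq_len(n)))
  parasite <- host
  parasite$tip.label <- paste0("q", seq_len(n))
  list(host_D = patristic_distances(host),
       parasite_D = patristic_distances(parasite),
       links = links_matrix(parasite$tip.label, host$tip.label))
}

test_that("principal coordinates reproduce Euclidean distances", {
  # collinear points 0, 1, 3: a single positive axis
  D <- euclid_D(c(0, 1, 3), c("a", "b", "c"))
  pc <- pcoa_axes(D)
  expect_equal(ncol(pc$coordinates), 1L)
  expect_equal(sort(as.vector(stats::dist(pc$coordinates))), c(1, 2, 3),
               tolerance = 1e-10)
  # random 5x3 coordinates
  set.seed(101)
  X <- matrix(stats::rnorm(15), 5, 3)
  D5 <- euclid_D(X)
  rec <- as.matrix(stats::dist(pcoa_axes(D5)$coordinates))
  expect_lt(max(abs(unname(D5) - unname(rec))), 1e-8)
  # degenerate all-zero distances: no positive axes
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(ncol(pcoa_axes(Z)$coordinates), 0L)
  # asymmetric input rejected
  bad <- D5
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa_axes(bad), "symmetric")
  # eigenvalues sorted decreasingly
  expect_true(all(diff(pcoa_axes(D5)$eigenvalues) <= 1e-12))
})

test_that("the global congruence statistic matches the reference implementation", {
  cd <- congruent_data(8, seed = 301)
  mine <- parafit_global(cd$host_D, cd$parasite_D, cd$links, n_perm = 99, seed = 1)
  ref <- ape::parafit(cd$host_D[colnames(cd$links), colnames(cd$links)],
                      cd$parasite_D[rownames(cd$links), rownames(cd$links)],
                      t(cd$links), nperm = 9, silent = TRUE)
  expect_equal(mine$statistic, ref$ParaFitGlobal, tolerance = 1e-8)
})

test_that("perfect congruence is detected and label order is irrelevant", {
  cd <- congruent_data(8, seed = 302)
  g <- parafit_global(cd$host_D, cd$parasite_D, cd$links, n_perm = 999, seed = 5)
  expect_lte(g$p_value, 0.01)
  # shuffle taxon order in the distance matrices: same statistic
  ph <- sample(rownames(cd$host_D))
  pp <- sample(rownames(cd$parasite_D))
  g2 <- parafit_global(cd$host_D[ph, ph], cd$parasite_D[pp, pp], cd$links,
                       n_perm = 9, seed = 5)
  expect_equal(g$statistic, g2$statistic, tolerance = 1e-10)
  expect_error(parafit_global(cd$host_D[1:2, 1:2], cd$parasite_D,
                              cd$links[1:2, 1:2]), "at least 3")
})

test_that("destroying the host signal destroys significance", {
  set.seed(55)
  high <- 0
  for (i in 1:50) {
    cd <- congruent_data(8, seed = 400 + i)
    # permute host identities in the distance matrix before testing
    perm <- sample(rownames(cd$host_D))
    hd <- cd$host_D
    dimnames(hd) <- list(perm, perm)
    p <- parafit_global(hd, cd$parasite_D, cd$links, n_perm = 199)$p_value
    if (p > 0.05) high <- high + 1
  }
  expect_gte(high, 45)
})

test_that("per-link statistics decompose the global statistic sensibly", {
  cd <- congruent_data(8, seed = 303)
  res <- parafit_links(cd$host_D, cd$parasite_D, cd$links, n_perm = 499, seed = 3)
  expect_equal(nrow(res$links), sum(cd$links))
  expect_true(all(res$links$p_value > 0) && all(res$links$p_value <= 1))
  expect_gte(sum(res$links$p_value <= 0.05), nrow(res$links) / 2)
  # removing a positive-contribution link strictly decreases the statistic;
  # recompute the reduced statistic from scratch with the same coordinates
  pos <- which(res$links$statistic > 0)[1]
  A2 <- cd$links
  A2[res$links$parasite[pos], res$links$host[pos]] <- 0L
  B <- pcoa_axes(cd$host_D[colnames(cd$links), colnames(cd$links)])$coordinates
  C <- pcoa_axes(cd$parasite_D[rownames(cd$links), rownames(cd$links)])$coordinates
  stat_full <- sum((t(C) %*% cd$links %*% B)^2)
  stat_red <- sum((t(C) %*% A2 %*% B)^2)
  expect_lt(stat_red, stat_full)
  expect_equal(res$statistic, stat_full, tolerance = 1e-10)
  # the closed-form per-link statistic equals the direct recomputation
  expect_equal(res$links$statistic[pos], stat_full - stat_red, tolerance = 1e-8)
})

test_that("permutation p-values are seed-reproducible and stable across seeds", {
  set.seed(61)
  host <- simulate_yule(8, 1, labels = paste0("H", 1:8))
  parasite <- simulate_yule(8, 1, labels = paste0("q", 1:8))
  links <- links_matrix(paste0("q", 1:8), sample(host$tip.label))
  hd <- patristic_distances(host)
  pd <- patristic_distances(parasite)
  a <- parafit_global(hd, pd, links, n_perm = 999, seed = 7)
  b <- parafit_global(hd, pd, links, n_perm = 999, seed = 7)
  expect_identical(a$p_value, b$p_value)
  ps <- vapply(1:20, function(s) {
    parafit_global(hd, pd, links, n_perm = 999, seed = s)$p_value
  }, 0)
  expect_lt(stats::sd(ps), 0.02)
})
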
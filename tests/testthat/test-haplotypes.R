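aln_from <- function(x) {
  names(x) <- names(x) %||% paste0("s", seq_along(x))
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("alignment_stats counts variable and parsimony-informative sites", {
  expect_equal(alignment_stats(c(a = "ACGT", b = "ACGA", c = "ACGA")),
               list(length = 4L, n_variable = 1L, n_parsimony_informative = 0L))
  expect_equal(alignment_stats(c(a = "AAAA", b = "AAAA")),
               list(length = 4L, n_variable = 0L, n_parsimony_informative = 0L))
  expect_equal(alignment_stats(c(a = "ACGT", b = "ACGT", c = "TGCA", d = "TGCA")),
               list(length = 4L, n_variable = 4L, n_parsimony_informative = 4L))
  # gaps and Ns are ignored as states
  expect_equal(alignment_stats(c(a = "A-GT", b = "ANGT", c = "ACGT"))$n_variable, 0L)
  expect_error(alignment_stats(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("collapse_haplotypes merges identical sequences case-insensitively", {
  h <- collapse_haplotypes(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT", s4 = "AGGT"))
  expect_equal(length(h$sequences), 2L)
  expect_setequal(unname(h$multiplicity), c(3L, 1L))
  expect_equal(sum(h$multiplicity), 4L)
  h2 <- collapse_haplotypes(c(a = "acgt", b = "ACGT"))
  expect_equal(length(h2$sequences), 1L)
  h3 <- collapse_haplotypes(c(a = "AAAA", b = "CCCC", c = "GGGG"))
  expect_equal(length(h3$sequences), 3L)
})

test_that("pairwise distances follow the p, JC and gamma-JC formulas", {
  expect_equal(pairwise_distance("ACGT", "ACGA", model = "p"), 0.25)
  expect_equal(pairwise_distance("ACGT", "ACGT", model = "JC"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", model = "JC+G", alpha = 0.4), 0)
  # p = 0.05 with alpha = 0.40: frozen from direct evaluation of
  # (3a/4)((1-4p/3)^(-1/a)-1)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 5), rep("A", 95)), collapse = "")
  expect_equal(pairwise_distance(s1, s2, model = "JC+G", alpha = 0.4),
               0.05647519, tolerance = 1e-6)
  # pairwise deletion of gaps/N
  expect_equal(pairwise_distance("AC-T", "ACNT", model = "p"), 0)
  expect_error(pairwise_distance("----", "ACGT"), "no comparable")
  # saturation under JC
  sat1 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  sat2 <- paste(rep(c("C", "G", "T", "A"), 25), collapse = "")
  expect_error(pairwise_distance(sat1, sat2, model = "JC"), "aturat")
})

test_that("gamma-JC converges to JC as the shape parameter grows", {
  s1 <- paste(rep("A", 200), collapse = "")
  s2 <- paste(c(rep("C", 20), rep("A", 180)), collapse = "")
  d_jc <- pairwise_distance(s1, s2, model = "JC")
  d_g <- pairwise_distance(s1, s2, model = "JC+G", alpha = 1e6)
  expect_lt(abs(d_jc - d_g), 1e-6)
})

test_that("distances agree with ape::dist.dna under JC with pairwise deletion", {
  set.seed(17)
  tr <- simulate_yule(6, 1)
  aln <- simulate_sequences(tr, 600, rate = 0.05)
  D <- alignment_distances(aln, model = "JC")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(D[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  # and the gamma-corrected variant
  Dg <- alignment_distances(aln, model = "JC+G", alpha = 0.4)
  refg <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                                  gamma = 0.4, pairwise.deletion = TRUE))
  expect_equal(Dg[rownames(refg), colnames(refg)], refg, tolerance = 1e-10,
               ignore_attr = TRUE)
})

dmat <- function(v, labs = NULL, units = "percent") {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- v
  D <- D + t(D)
  labs <- labs %||% paste0("h", seq_len(n))
  dimnames(D) <- list(labs, labs)
  attr(D, "units") <- units
  D
}

test_that("threshold delimitation reproduces the worked examples", {
  expect_equal(delimit_species(dmat(4.8), 1, units = "percent")$n_species, 2L)
  expect_equal(delimit_species(dmat(0.2), 2, units = "percent")$n_species, 1L)
  set.seed(5)
  D4 <- dmat(runif(6, 0.1, 0.7))
  expect_equal(delimit_species(D4, 1, units = "percent")$n_species, 1L)
  expect_equal(delimit_species(dmat(11.6), 2, units = "percent")$n_species, 2L)
  one <- matrix(0, 1, 1, dimnames = list("h1", "h1"))
  expect_equal(delimit_species(one, 0.01)$n_species, 1L)
  # boundary is strict: exactly at the threshold counts as distinct
  expect_equal(delimit_species(dmat(1.0), 1, units = "percent")$n_species, 2L)
})

test_that("delimitation is monotone in the threshold and checks units", {
  set.seed(23)
  for (i in 1:10) {
    D <- dmat(runif(15, 0, 5))
    counts <- vapply(c(0.5, 1, 2, 4), function(th) {
      delimit_species(D, th, units = "percent")$n_species
    }, 1L)
    expect_true(all(diff(counts) <= 0))
  }
  D <- dmat(2)
  expect_error(delimit_species(D, 0.01, units = "fraction"), "unit mismatch")
  expect_error(delimit_species(dmat(0.5, units = "fraction"), 1.5, units = "fraction"),
               "threshold")
  # complete linkage never yields fewer clusters than single linkage
  set.seed(3)
  for (i in 1:5) {
    D <- dmat(runif(10, 0, 3))
    expect_gte(delimit_species(D, 1, units = "percent", linkage = "complete")$n_species,
               delimit_species(D, 1, units = "percent")$n_species)
  }
})

test_that("greedy pruning keeps representatives at least theta apart", {
  haps <- collapse_haplotypes(c(h1 = "AAAA", h2 = "AAAA", h3 = "AAAT", h4 = "TTTT"))
  D <- dmat(c(0.005, 0.9, 0.9), labs = names(haps$sequences), units = "fraction")
  pruned <- prune_similar(haps, D, threshold = 0.01)
  expect_equal(length(pruned$sequences), 2L)
  expect_equal(sum(pruned$multiplicity), 4L)
  # two haplotypes at 2% both survive a 1% threshold
  h2 <- collapse_haplotypes(c(a = "AAAA", b = "CCAA"))
  D2 <- dmat(0.02, labs = names(h2$sequences), units = "fraction")
  expect_equal(length(prune_similar(h2, D2, 0.01)$sequences), 2L)
  # property: all surviving representative pairs are >= theta apart
  set.seed(41)
  for (i in 1:10) {
    n <- 8
    labs <- paste0("x", 1:n)
    D <- dmat(runif(n * (n - 1) / 2, 0, 0.05), labs = labs, units = "fraction")
    mult <- stats::setNames(sample(1:5, n, TRUE), labs)
    hs <- structure(list(sequences = stats::setNames(as.character(1:n), labs),
                         multiplicity = mult,
                         members = stats::setNames(
                           lapply(labs, function(l) paste0(l, "_", seq_len(mult[l]))),
                           labs)),
                    class = "haplotype_set")
    pr <- prune_similar(hs, D, threshold = 0.01)
    reps <- names(pr$sequences)
    if (length(reps) > 1) {
      expect_true(all(D[reps, reps][upper.tri(diag(length(reps)))] >= 0.01))
    }
    expect_equal(sum(pr$multiplicity), sum(hs$multiplicity))
  }
})

test_that("rate calibration halves pairwise divergence and rounds to 0.1", {
  expect_equal(unname(calibrate_rate(2, 7, 2.4)), c(0.4, 1.5))
  expect_equal(unname(calibrate_rate(0, 0, 5)), c(0, 0))
  expect_equal(unname(calibrate_rate(4.8, 4.8, 2.4)), c(1.0, 1.0))
  expect_error(calibrate_rate(2, 7, 0), "T_mya")
  expect_error(calibrate_rate(7, 2, 2.4), "d_lo")
})

test_that("distance matrices round-trip through TSV", {
  D <- dmat(c(1, 2, 3), units = "percent")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, tf)
  D2 <- read_distance_matrix(tf, units = "percent")
  expect_equal(unclass(D), unclass(D2), ignore_attr = TRUE)
  expect_equal(attr(D2, "units"), "percent")
})
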
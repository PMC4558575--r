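mirrored_tanglegram <- function(n, seed = NULL) {
  host <- simulate_yule(n, 1, seed = seed, labels = paste0("H", seq_len(n)))
  parasite <- host
  parasite$tip.label <- paste0("q", seq_len(n))
  links <- links_matrix(parasite$tip.label, host$tip.label)
  list(host = host, parasite = parasite, links = links)
}

test_that("perfectly congruent tanglegrams are pure cospeciation at zero cost", {
  h <- parse_newick("((A:1,B:1):1,C:2);")
  p <- parse_newick("((a:1,b:1):1,c:2);")
  L <- links_matrix(c("a", "b", "c"), c("A", "B", "C"))
  r <- reconcile(h, p, L, cost_scheme(0, 1, 1, 2) / 4)
  expect_equal(unname(r$counts), c(2L, 0L, 0L, 0L))
  expect_equal(r$total_cost, 0)
  for (n in c(4, 6, 9)) {
    tg <- mirrored_tanglegram(n, seed = n)
    rc <- reconcile(tg$host, tg$parasite, tg$links)
    expect_equal(unname(rc$counts), c(n - 1L, 0L, 0L, 0L))
  }
})

test_that("the DP minimum equals exhaustive enumeration on random tanglegrams", {
  set.seed(77)
  for (i in 1:40) {
    tg <- random_tanglegram(sample(3:5, 1), sample(3:5, 1))
    cv <- stats::rexp(4)
    cv <- cv / sum(cv)
    costs <- cost_scheme(cv[1], cv[2], cv[3], cv[4])
    rtr <- i %% 2 == 0
    dp <- reconcile(tg$host, tg$parasite, tg$links, costs,
                    reconcile_options(root_to_root = rtr))
    bf <- brute_force_recon_cost(tg$host, tg$parasite, tg$links, costs, rtr)
    expect_equal(dp$total_cost, bf, tolerance = 1e-9)
    # spec example: swapped-leaf tanglegram under unit non-cospeciation costs
  }
  h <- parse_newick("((A,B)x,C)r;")
  h$edge.length <- rep(1, nrow(h$edge))
  p <- parse_newick("((a,c),b);")
  p$edge.length <- rep(1, nrow(p$edge))
  L <- links_matrix(c("a", "b", "c"), c("A", "B", "C"))
  costs <- cost_scheme(0, 1, 1, 1)
  expect_equal(reconcile(h, p, L, costs)$total_cost,
               brute_force_recon_cost(h, p, L, costs, TRUE))
})

test_that("event counts conserve parasite internal nodes and reproduce the cost", {
  set.seed(78)
  for (i in 1:15) {
    tg <- random_tanglegram(sample(4:6, 1), sample(4:7, 1))
    cv <- stats::rexp(4)
    costs <- cost_scheme(cv[1], cv[2], cv[3], cv[4])
    r <- reconcile(tg$host, tg$parasite, tg$links, costs)
    expect_equal(r$counts[["cospeciation"]] + r$counts[["duplication"]] +
                   r$counts[["switching"]], tg$parasite$Nnode)
    expect_equal(sum(r$counts * costs), r$total_cost, tolerance = 1e-9)
  }
})

test_that("raising the switch cost never increases the switch count", {
  set.seed(79)
  for (i in 1:8) {
    tg <- random_tanglegram(5, 6)
    prev <- Inf
    for (cw in c(0.2, 0.5, 1, 2, 4)) {
      r <- reconcile(tg$host, tg$parasite, tg$links, cost_scheme(0.1, 0.3, 0.5, cw))
      expect_lte(r$counts[["switching"]], prev)
      prev <- r$counts[["switching"]]
    }
  }
})

test_that("adaptive cost estimation favors cospeciation on identical trees", {
  h <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  p <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  L <- links_matrix(letters[1:4], LETTERS[1:4])
  for (s in 1:20) {
    est <- estimate_costs(h, p, L, n_sets = 150, seed = s)
    expect_equal(unname(which.min(est$costs)), 1L, label = paste("seed", s))
    expect_equal(sum(est$costs == min(est$costs)), 1L)
  }
})

test_that("estimated schemes are self-consistent and deterministic", {
  h <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  p <- parse_newick("((a:1,c:1):1,(b:1,d:1):1);")
  L <- links_matrix(letters[1:4], LETTERS[1:4])
  est <- estimate_costs(h, p, L, n_sets = 150, seed = 9)
  rec <- reconcile(h, p, L, est$costs)
  expect_equal(est$reconciliation$total_cost, rec$total_cost, tolerance = 1e-12)
  expect_identical(est$reconciliation$counts, rec$counts)
  est2 <- estimate_costs(h, p, L, n_sets = 150, seed = 9)
  expect_identical(est$costs, est2$costs)
  expect_identical(est$ranked, est2$ranked)
  expect_true(all(diff(est$ranked$quality) >= -1e-12))
})

test_that("the plausibility filter rejects zero-event/extreme-cost schemes", {
  # the degenerate pattern: an event never invoked precisely because its
  # cost is extreme
  f1 <- flag_implausible(c(cospeciation = 12, sorting = 51, duplication = 15,
                           switching = 0),
                         c(0.017, 0.0040, 0.013, 0.97))
  expect_true(f1$flagged)
  expect_match(f1$reasons, "switching")
  f2 <- flag_implausible(c(cospeciation = 10, sorting = 65, duplication = 17,
                           switching = 0),
                         c(0.000998, 0.00017, 0.00067, 0.998))
  expect_true(f2$flagged)
  f3 <- flag_implausible(c(cospeciation = 11, sorting = 33, duplication = 12,
                           switching = 4),
                         c(0.25, 0.074, 0.20, 0.47))
  expect_false(f3$flagged)
  f4 <- flag_implausible(c(cospeciation = 13, sorting = 40, duplication = 11,
                           switching = 3),
                         c(0.16, 0.051, 0.19, 0.60))
  expect_false(f4$flagged)
  # all event types used: never flagged, whatever the costs
  set.seed(91)
  for (i in 1:10) {
    cv <- stats::rexp(4)
    expect_false(flag_implausible(c(cospeciation = 1, sorting = 2,
                                    duplication = 3, switching = 4), cv)$flagged)
  }
})

test_that("chronological consistency detects switch-timing cycles", {
  h <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # node ids: A=1 B=2 C=3 D=4 root=5 (A,B)=6 (C,D)=7
  none <- data.frame(source = integer(0), target = integer(0))
  expect_true(check_chronology(h, none))
  ok <- data.frame(source = 1, target = 3)
  expect_true(check_chronology(h, ok))
  # two switches whose contemporaneity constraints order the two cherry
  # nodes both ways: infeasible
  cyc <- data.frame(source = c(1, 3), target = c(7, 6))
  expect_false(check_chronology(h, cyc))
  expect_false(brute_force_chronology(h, cyc))
  # randomized agreement with the total-order oracle
  set.seed(13)
  for (i in 1:20) {
    tr <- simulate_yule(6, 1)
    N <- ape::Ntip(tr) + tr$Nnode
    k <- sample(1:3, 1)
    sw <- data.frame(source = sample(N, k, replace = TRUE),
                     target = sample(N, k, replace = TRUE))
    expect_equal(check_chronology(tr, sw), brute_force_chronology(tr, sw),
                 label = paste("instance", i))
  }
})

test_that("true simulated switch histories are always chronologically consistent", {
  # switches in the generator target contemporaneous host branches by
  # construction, so the recorded event log is a guaranteed-feasible fixture
  set.seed(14)
  done <- 0
  while (done < 8) {
    host <- simulate_yule(8, 1, labels = paste0("H", 1:8))
    host$edge.length <- host$edge.length / max(ape::node.depth.edgelength(host))
    sim <- tryCatch(simulate_cophylogeny(host, sim_params(r_switch = 0.6)),
                    error = function(e) NULL)
    if (is.null(sim)) next
    sw <- do.call(rbind, lapply(Filter(function(e) {
      e$where == "branch" && identical(e$type, "switching")
    }, sim$event_log), function(e) data.frame(source = e$edge, target = e$target)))
    if (is.null(sw)) next
    expect_true(check_chronology(sim$host, sw))
    expect_true(brute_force_chronology(sim$host, sw))
    done <- done + 1
  }
})

test_that("topological congruence randomization behaves at the extremes", {
  tg <- mirrored_tanglegram(8, seed = 201)
  cs <- cospeciation_significance(tg$host, tg$parasite, tg$links,
                                  n_rand = 200, seed = 1)
  expect_equal(cs$observed, 7L)
  expect_lte(cs$p_value, 0.05)
  expect_gte(cs$p_value, 1 / 201)
  # two leaves: every topology is identical, p must be 1
  h2 <- parse_newick("(A:1,B:1);")
  p2 <- parse_newick("(a:1,b:1);")
  L2 <- links_matrix(c("a", "b"), c("A", "B"))
  cs2 <- cospeciation_significance(h2, p2, L2, n_rand = 50, seed = 2)
  expect_equal(cs2$p_value, 1)
})

test_that("parasite polytomies and multi-host leaves are handled", {
  h <- parse_newick("((A:1,B:1):1,C:2);")
  poly <- parse_newick("(a:1,b:1,c:1);")
  L <- links_matrix(c("a", "b", "c"), c("A", "B", "C"))
  expect_error(reconcile(h, poly, L), "polytom")
  r <- reconcile(h, poly, L, options = reconcile_options(allow_polytomies = TRUE))
  expect_equal(r$counts[["cospeciation"]] + r$counts[["duplication"]] +
                 r$counts[["switching"]], 2L)
  # a leaf linked to two hosts is split into pseudo-leaves
  p <- parse_newick("(x:1,c:1);")
  Lm <- links_matrix(c("x", "x", "c"), c("A", "B", "C"))
  expect_message(rm_ <- reconcile(h, p, Lm), "pseudo-leaves")
  expect_equal(ape::Ntip(rm_$parasite), 3L)
  Lz <- links_matrix("a", "A")
  expect_error(reconcile(h, parse_newick("(a:1,z:1);"), Lz), "without a host link")
})
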
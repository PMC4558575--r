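# Synthetic data: trees, joint host-parasite histories with known event
# tallies, and sequence evolution. This module provides the ground truth
# against which the inferential modules are validated.

#' Simulate branching ages under a (possibly density-dependent) birth process
#'
#' Interval durations with k lineages are exponential with total rate
#' `k * rate_fn(k)`; the process is conditioned on reaching `n_tips` tips,
#' with a final interval at `n_tips` lineages before the present.
#'
#' @param n_tips number of tips (>= 2).
#' @param rate_fn function of the lineage count k returning the per-lineage
#'   speciation rate.
#' @param seed optional integer seed.
#' @return numeric vector of node ages, decreasing (root first).
#' @export
simulate_branching_ages <- function(n_tips, rate_fn, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- 2:n_tips
  rates <- vapply(k, rate_fn, 0)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop2("rate_fn must return positive finite rates for k = 2..n_tips")
  }
  g <- stats::rexp(length(k), rate = k * rates)
  total <- sum(g)
  c(total, total - cumsum(g)[seq_len(n_tips - 2)])
}

# assemble an ultrametric tree from given merge ages by joining uniformly
# chosen lineage pairs backwards in time (the Yule/Harding topology law,
# identical to forward random-splitting)
.ages_to_tree <- function(ages, labels) {
  n <- length(ages) + 1L
  stopifnot(length(labels) == n)
  pool <- lapply(labels, function(l) list(nwk = l, age = 0))
  for (a in sort(ages)) {
    ij <- sample.int(length(pool), 2L)
    x <- pool[[ij[1]]]; y <- pool[[ij[2]]]
    joined <- list(
      nwk = sprintf("(%s:%s,%s:%s)", x$nwk, .fmt_len(a - x$age),
                    y$nwk, .fmt_len(a - y$age)),
      age = a)
    pool <- c(pool[-ij], list(joined))
  }
  ape::read.tree(text = paste0(pool[[1]]$nwk, ";"))
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' @param n_tips number of tips.
#' @param lambda speciation rate (> 0).
#' @param seed optional integer seed.
#' @param labels tip labels (default `t1..tn`).
#' @return an ultrametric `"phylo"`.
#' @export
simulate_yule <- function(n_tips, lambda, seed = NULL, labels = NULL) {
  stopifnot(n_tips >= 2, is.numeric(lambda), lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  ages <- simulate_branching_ages(n_tips, function(k) lambda)
  labels <- labels %||% paste0("t", seq_len(n_tips))
  .ages_to_tree(ages, labels)
}

#' Simulate a uniform random labeled topology (PDA model)
#'
#' Draws uniformly from the (2n-3)!! labeled rooted binary topologies by
#' sequentially attaching each leaf to a uniformly chosen edge (including
#' the root stem). No branch lengths are assigned.
#'
#' @param labels character vector of >= 2 distinct leaf labels.
#' @param seed optional integer seed.
#' @return a `"phylo"` without branch lengths.
#' @export
simulate_pda <- function(labels, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop2("need at least 2 labels")
  if (anyDuplicated(labels)) stop2("duplicate labels")
  if (!is.null(seed)) set.seed(seed)
  # nested-list tree; every subtree stands for its stem edge, the whole
  # tree for the root stem, so a k-leaf tree offers 2k-1 attachment points
  count <- function(t) if (is.character(t)) 1L else 1L + count(t[[1]]) + count(t[[2]])
  attach_at <- function(t, idx, leaf) {
    if (idx == 1L) return(list(t, leaf))
    n1 <- count(t[[1]])
    if (idx - 1L <= n1) {
      t[[1]] <- attach_at(t[[1]], idx - 1L, leaf)
    } else {
      t[[2]] <- attach_at(t[[2]], idx - 1L - n1, leaf)
    }
    t
  }
  tr <- list(labels[1], labels[2])
  for (i in seq_along(labels)[-(1:2)]) {
    tr <- attach_at(tr, sample.int(2L * (i - 1L) - 1L, 1L), labels[i])
  }
  to_nwk <- function(t) {
    if (is.character(t)) t else paste0("(", to_nwk(t[[1]]), ",", to_nwk(t[[2]]), ")")
  }
  ape::read.tree(text = paste0(to_nwk(tr), ";"))
}

#' Parameters of the joint host-parasite simulation
#'
#' Defaults emulate a cospeciation-dominated, host-specific system with
#' appreciable within-host speciation, parasite extinction and rare
#' host-switching: on a 16-tip host tree scaled to height 1 they yield a
#' parasite fauna about twice the host richness whose true histories carry
#' only a handful of host-switches -- the regime of a host-specific gill
#' parasite radiation on a lacustrine host radiation. Rates are per
#' host-tree time unit, so scale the host tree to height 1 for the defaults
#' to be meaningful.
#'
#' @param p_cosp probability that a parasite lineage cospeciates at a host
#'   node (otherwise it follows one daughter, a sorting event).
#' @param r_dup,r_switch,r_loss per-lineage rates of within-host
#'   duplication, host-switch and extinction along host branches.
#' @param seq_length,subst_rate,gamma_shape sequence-evolution settings used
#'   when alignments are generated from the simulated parasite tree.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(p_cosp = 0.9, r_dup = 1.5, r_switch = 0.3, r_loss = 0.5,
                       seq_length = 1000L, subst_rate = 0.05, gamma_shape = NULL) {
  stopifnot(p_cosp >= 0, p_cosp <= 1, r_dup >= 0, r_switch >= 0, r_loss >= 0,
            seq_length >= 1, subst_rate >= 0)
  structure(list(p_cosp = p_cosp, r_dup = r_dup, r_switch = r_switch,
                 r_loss = r_loss, seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, gamma_shape = gamma_shape),
            class = "sim_params")
}

# host-tree geometry used by the cophylogeny simulation: for every node its
# time from the root, and for every edge its child node and time span
.host_geometry <- function(host) {
  depth <- ape::node.depth.edgelength(host)
  ntip <- ape::Ntip(host)
  tipd <- depth[seq_len(ntip)]
  if (diff(range(tipd)) > 1e-6 * max(tipd)) {
    stop2("host tree must be ultrametric")
  }
  kids <- vector("list", ntip + host$Nnode)
  for (i in seq_len(nrow(host$edge))) {
    p <- host$edge[i, 1]
    kids[[p]] <- c(kids[[p]], host$edge[i, 2])
  }
  list(depth = depth, ntip = ntip, root = ntip + 1L, kids = kids,
       parent = {p <- rep(NA_integer_, ntip + host$Nnode)
                 p[host$edge[, 2]] <- host$edge[, 1]; p},
       present = max(tipd))
}

# edges (identified by their child node) alive at time t
.alive_edges <- function(geom, t) {
  v <- seq_along(geom$depth)[-geom$root]
  v[geom$depth[geom$parent[v]] < t & t < geom$depth[v]]
}

#' Simulate a parasite tree on a host tree with a known event history
#'
#' One parasite lineage starts at the host root. At every host node it
#' cospeciates with probability `p_cosp` (following both daughters) or
#' follows a uniformly chosen single daughter (one sorting event). Along
#' host branches, within-host duplications, host-switches and losses occur
#' as Poisson events at the given rates; a switch moves one daughter to a
#' uniformly chosen contemporaneous host branch, which makes every
#' simulated history chronologically consistent by construction. Lineages
#' surviving to the present become parasite leaves linked to their current
#' host. The complete event log and the true event tally (including events
#' on subsequently extinct lineages) are returned; sorting counts both
#' missed host daughters and branch losses.
#'
#' @param host ultrametric host `"phylo"` with branch lengths.
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @return object of class `"cophylo_sim"`: list with `host`, `parasite`
#'   (extant lineages only, unifurcations suppressed), `links`, `tally`,
#'   `event_log`, `params`, `seed`.
#' @export
simulate_cophylogeny <- function(host, params = sim_params(), seed = NULL) {
  stopifnot(inherits(host, "phylo"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  eng <- .cophylo_engine(host, params, driver = NULL)
  if (is.null(eng$result)) {
    stop2("all parasite lineages went extinct; retry with another seed or ",
          "lower r_loss / higher p_cosp")
  }
  n_extant <- length(eng$leaves)
  if (n_extant < 2L) {
    stop2("fewer than 2 extant parasite lineages; retry with another seed or ",
          "lower r_loss / higher p_cosp")
  }
  par_tree <- ape::read.tree(text = paste0(.sim_newick(eng$result, 0), ";"))
  links <- links_matrix(vapply(eng$leaves, `[[`, "", "parasite"),
                        vapply(eng$leaves, `[[`, "", "host"))
  structure(list(host = host, parasite = par_tree, links = links,
                 tally = eng$tally, event_log = eng$log, params = params,
                 seed = seed),
            class = "cophylo_sim")
}

#' @export
print.cophylo_sim <- function(x, ...) {
  cat(sprintf("simulated cophylogeny: %d host tips, %d parasite tips\n",
              ape::Ntip(x$host), ape::Ntip(x$parasite)))
  cat(sprintf("  true events: %d cospeciation, %d sorting, %d duplication, %d host-switch\n",
              x$tally[["cospeciation"]], x$tally[["sorting"]],
              x$tally[["duplication"]], x$tally[["switching"]]))
  invisible(x)
}

# run the event process; driver == NULL draws from the RNG, otherwise it is
# an environment replaying a recorded event log
.cophylo_engine <- function(host, params, driver = NULL) {
  geom <- .host_geometry(host)
  env <- new.env()
  env$log <- list()
  env$tally <- c(cospeciation = 0L, sorting = 0L, duplication = 0L, switching = 0L)
  env$leaves <- list()
  env$leaf_i <- 0L
  rho <- params$r_dup + params$r_switch + params$r_loss

  record <- function(entry) env$log[[length(env$log) + 1L]] <- entry

  next_branch_event <- function(edge, t0, t1) {
    if (!is.null(driver)) {
      e <- driver$pop()
      if (!is.null(e) && e$where == "branch" && e$edge == edge && e$time <= t1) {
        return(e)
      }
      driver$push(e)
      return(NULL)
    }
    if (rho <= 0) return(NULL)
    dt <- stats::rexp(1, rho)
    if (t0 + dt >= t1) return(NULL)
    type <- sample(c("duplication", "switching", "loss"), 1L,
                   prob = c(params$r_dup, params$r_switch, params$r_loss))
    target <- NA_integer_
    if (type == "switching") {
      cand <- setdiff(.alive_edges(geom, t0 + dt), edge)
      if (!length(cand)) return(list(where = "branch", edge = edge,
                                     time = t0 + dt, type = "none"))
      target <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    list(where = "branch", edge = edge, time = t0 + dt, type = type,
         target = target)
  }

  node_decision <- function(node) {
    if (!is.null(driver)) {
      e <- driver$pop()
      stopifnot(e$where == "node", e$node == node)
      return(e)
    }
    if (stats::runif(1) < params$p_cosp) {
      list(where = "node", node = node, type = "cospeciation")
    } else {
      ch <- geom$kids[[node]]
      list(where = "node", node = node, type = "sorting",
           follow = ch[sample.int(length(ch), 1L)])
    }
  }

  # returns a nested subtree (list(time, children) / leaf) or NULL (extinct)
  on_edge <- function(edge, t0) {
    repeat {
      ev <- next_branch_event(edge, t0, geom$depth[edge])
      if (is.null(ev)) break
      record(ev)
      if (ev$type == "none") { t0 <- ev$time; next }
      if (ev$type == "loss") {
        env$tally["sorting"] <- env$tally["sorting"] + 1L
        return(NULL)
      }
      if (ev$type == "duplication") {
        env$tally["duplication"] <- env$tally["duplication"] + 1L
        a <- on_edge(edge, ev$time)
        b <- on_edge(edge, ev$time)
        return(.join_or_survivor(a, b, ev$time))
      }
      # host switch: one daughter stays, the other jumps
      env$tally["switching"] <- env$tally["switching"] + 1L
      a <- on_edge(edge, ev$time)
      b <- on_edge(ev$target, ev$time)
      return(.join_or_survivor(a, b, ev$time))
    }
    at_node(edge)
  }

  at_node <- function(node) {
    if (length(geom$kids[[node]]) == 0L) {
      if (!is.null(driver)) {
        e <- driver$pop()
        stopifnot(e$where == "tip", e$node == node)
      }
      env$leaf_i <- env$leaf_i + 1L
      lab <- sprintf("p%03d", env$leaf_i)
      env$leaves[[length(env$leaves) + 1L]] <-
        list(parasite = lab, host = host$tip.label[node])
      record(list(where = "tip", node = node, label = lab))
      return(list(leaf = lab, time = geom$depth[node]))
    }
    ev <- node_decision(node)
    record(ev)
    if (ev$type == "cospeciation") {
      env$tally["cospeciation"] <- env$tally["cospeciation"] + 1L
      ch <- geom$kids[[node]]
      subs <- lapply(ch, function(c) on_edge(c, geom$depth[node]))
      alive <- Filter(Negate(is.null), subs)
      if (length(alive) == 0L) return(NULL)
      if (length(alive) == 1L) return(alive[[1]])
      res <- alive[[1]]
      for (s in alive[-1]) res <- list(time = geom$depth[node], children = list(res, s))
      return(res)
    }
    env$tally["sorting"] <- env$tally["sorting"] +
      (length(geom$kids[[node]]) - 1L)
    on_edge(ev$follow, geom$depth[node])
  }

  env$result <- at_node(geom$root)
  env
}

.join_or_survivor <- function(a, b, time) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(time = time, children = list(a, b))
}

# serialize the nested simulation result; branch length = child time - t0
.sim_newick <- function(node, t0) {
  if (!is.null(node$leaf)) {
    return(sprintf("%s:%s", node$leaf, .fmt_len(node$time - t0)))
  }
  inner <- paste(vapply(node$children, function(c) .sim_newick(c, node$time), ""),
                 collapse = ",")
  sprintf("(%s):%s", inner, .fmt_len(node$time - t0))
}

#' Replay a recorded cophylogeny event log
#'
#' Re-runs the simulation engine with all random decisions taken from the
#' recorded log instead of the RNG, reproducing the parasite tree, links
#' and tally exactly. Used to verify the bookkeeping of
#' [simulate_cophylogeny()].
#'
#' @param sim a `"cophylo_sim"`.
#' @return list with `parasite` (Newick string), `links` and `tally`.
#' @export
replay_cophylogeny <- function(sim) {
  stopifnot(inherits(sim, "cophylo_sim"))
  queue <- sim$event_log
  pos <- 1L
  # pop() consumes the next logged decision; push() rewinds when the engine
  # peeked at an entry that belongs to a later point of the recursion (which
  # means "no branch event before the node" at the current edge)
  driver <- new.env()
  driver$pop <- function() {
    if (pos > length(queue)) return(NULL)
    e <- queue[[pos]]
    pos <<- pos + 1L
    e
  }
  driver$push <- function(e) {
    if (!is.null(e)) pos <<- pos - 1L
  }
  eng <- .cophylo_engine(sim$host, sim$params, driver = driver)
  links <- links_matrix(vapply(eng$leaves, `[[`, "", "parasite"),
                        vapply(eng$leaves, `[[`, "", "host"))
  list(parasite = paste0(.sim_newick(eng$result, 0), ";"),
       links = links, tally = eng$tally)
}

#' Simulate sequence evolution along a tree (Jukes-Cantor)
#'
#' The root sequence is uniform over A/C/G/T; each site evolves
#' independently along every branch, changing with probability
#' `3/4 (1 - exp(-4 r t / 3))` to a uniformly chosen different base.
#' Optional gamma rate heterogeneity draws per-site rate multipliers from a
#' Gamma(shape, shape) distribution.
#'
#' @param tree `"phylo"` with branch lengths (substitution-time units).
#' @param length number of sites.
#' @param rate substitution rate multiplier applied to all branch lengths.
#' @param seed optional integer seed.
#' @param gamma_shape optional gamma shape for among-site rate variation.
#' @return character matrix alignment (rows = tips).
#' @export
simulate_sequences <- function(tree, length, rate = 1, seed = NULL,
                               gamma_shape = NULL) {
  stopifnot(inherits(tree, "phylo"), length >= 1, rate >= 0)
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  site_rate <- if (is.null(gamma_shape)) rep(1, L) else
    stats::rgamma(L, shape = gamma_shape, rate = gamma_shape)
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  kids <- vector("list", N)
  elen <- rep(NA_real_, N)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  seqs <- matrix("", ntip, L, dimnames = list(tree$tip.label, NULL))
  evolve <- function(node, s) {
    if (node != ntip + 1L) {
      p_change <- 0.75 * (1 - exp(-4 * rate * site_rate * elen[node] / 3))
      hit <- stats::runif(L) < p_change
      if (any(hit)) {
        cur <- s[hit]
        pick <- function(b) sample(setdiff(.DNA_STATES, b), 1L)
        s[hit] <- vapply(cur, pick, "")
      }
    }
    if (length(kids[[node]]) == 0L) {
      seqs[node, ] <<- s
    } else {
      for (c in kids[[node]]) evolve(c, s)
    }
    invisible()
  }
  root_seq <- sample(.DNA_STATES, L, replace = TRUE)
  evolve(ntip + 1L, root_seq)
  seqs
}

#' Simulate an alignment with a known number of divergent clusters
#'
#' Builds a star-of-stars tree: `n_clusters` ancestral lineages radiating
#' from the root, each carrying `tips_per_cluster` shallowly diverged tips,
#' with branch lengths chosen so that expected between-cluster model
#' distances are about `3.5 * theta` and within-cluster distances at most
#' about `0.4 * theta` — well-separated clusters around the delimitation
#' threshold `theta`.
#'
#' @param n_clusters,tips_per_cluster cluster layout.
#' @param theta delimitation threshold the clusters are calibrated to.
#' @param seq_length alignment length.
#' @param seed optional integer seed.
#' @return list with `alignment`, `tree` and `truth` (cluster id per tip).
#' @export
simulate_clustered_alignment <- function(n_clusters, tips_per_cluster = 3,
                                         theta = 0.01, seq_length = 2000,
                                         seed = NULL) {
  stopifnot(n_clusters >= 1, tips_per_cluster >= 1)
  if (!is.null(seed)) set.seed(seed)
  deep <- 3.5 * theta / 2     # per-lineage depth: pairwise between ~ 3.5 theta
  shallow <- 0.4 * theta / 2  # pairwise within ~ 0.4 theta
  tipblock <- function(ci) {
    tips <- paste0("c", ci, "_t", seq_len(tips_per_cluster), ":", .fmt_len(shallow))
    if (tips_per_cluster == 1L) {
      paste0("c", ci, "_t1:", .fmt_len(deep + shallow))
    } else {
      paste0("(", paste(tips, collapse = ","), "):", .fmt_len(deep))
    }
  }
  nwk <- if (n_clusters == 1L) {
    paste0(tipblock(1), ";")
  } else {
    paste0("(", paste(vapply(seq_len(n_clusters), tipblock, ""), collapse = ","),
           ");")
  }
  tree <- ape::read.tree(text = nwk)
  aln <- simulate_sequences(tree, seq_length, rate = 1)
  truth <- as.integer(sub("^c(\\d+)_.*$", "\\1", tree$tip.label))
  names(truth) <- tree$tip.label
  list(alignment = aln, tree = tree, truth = truth)
}
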
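# Independent oracles and small fixture builders used across the test files.
# The reconciliation oracle enumerates every assignment of parasite internal
# nodes to host nodes and scores it from first principles; it shares no code
# with the DP in the package.

# index a phylo into parent/children/ancestor tables (test-local, minimal)
oracle_index <- function(tr) {
  ntip <- ape::Ntip(tr)
  N <- ntip + tr$Nnode
  kids <- vector("list", N)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[i, 2])
  }
  parent <- rep(NA_integer_, N)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  depth <- integer(N)
  anc <- matrix(FALSE, N, N)   # anc[a, d]: a ancestor of or equal to d
  fill <- function(v) {
    anc[v, v] <<- TRUE
    for (c in kids[[v]]) {
      anc[, c] <<- anc[, v] | anc[, c]
      anc[c, c] <<- TRUE
      depth[c] <<- depth[v] + 1L
      fill(c)
    }
  }
  fill(ntip + 1L)
  list(ntip = ntip, N = N, root = ntip + 1L, kids = kids, parent = parent,
       anc = anc, depth = depth)
}

# exhaustive minimum reconciliation cost; costs = named scheme as in the
# package, root_to_root as in reconcile_options()
brute_force_recon_cost <- function(host, parasite, links, costs,
                                   root_to_root = TRUE) {
  H <- oracle_index(host)
  P <- oracle_index(parasite)
  cc <- costs[["cospeciation"]]; cs <- costs[["sorting"]]
  cd <- costs[["duplication"]]; cw <- costs[["switching"]]
  leaf_pos <- integer(P$ntip)
  for (t in seq_len(P$ntip)) {
    h <- colnames(links)[links[parasite$tip.label[t], ] == 1L]
    leaf_pos[t] <- match(h, host$tip.label)
  }
  internals <- which(lengths(P$kids) > 0L)
  # postorder so children positions are known when a node is scored
  po <- integer(0)
  walk <- function(v) {
    for (c in P$kids[[v]]) walk(c)
    if (length(P$kids[[v]])) po <- c(po, v)
    po
  }
  po <- local({
    out <- integer(0)
    rec <- function(v) {
      for (c in P$kids[[v]]) rec(c)
      if (length(P$kids[[v]])) out <<- c(out, v)
    }
    rec(P$root)
    out
  })
  dist_down <- function(a, d) H$depth[d] - H$depth[a]
  node_cost <- function(h, m1, m2) {
    best <- Inf
    ch <- H$kids[[h]]
    if (length(ch)) {
      for (a in ch) {
        for (b in ch) {
          if (a == b) next
          if (H$anc[a, m1] && H$anc[b, m2]) {
            best <- min(best, cc + cs * (dist_down(a, m1) + dist_down(b, m2)))
          }
        }
      }
    }
    if (H$anc[h, m1] && H$anc[h, m2]) {
      best <- min(best, cd + cs * (dist_down(h, m1) + dist_down(h, m2)))
    }
    # one child stays under h, the other jumps to any non-ancestral node
    if (H$anc[h, m1] && !H$anc[m2, h]) {
      best <- min(best, cw + cs * dist_down(h, m1))
    }
    if (H$anc[h, m2] && !H$anc[m1, h]) {
      best <- min(best, cw + cs * dist_down(h, m2))
    }
    best
  }
  grid <- rep(list(seq_len(H$N)), length(internals))
  names(grid) <- internals
  best_total <- Inf
  assign_pos <- integer(P$N)
  assign_pos[seq_len(P$ntip)] <- leaf_pos
  enumerate <- function(i) {
    if (i > length(internals)) {
      if (root_to_root && assign_pos[P$root] != H$root) return(invisible())
      total <- 0
      for (p in po) {
        q <- P$kids[[p]]
        total <- total + node_cost(assign_pos[p], assign_pos[q[1]], assign_pos[q[2]])
        if (!is.finite(total)) return(invisible())
      }
      if (total < best_total) best_total <<- total
      return(invisible())
    }
    for (h in seq_len(H$N)) {
      assign_pos[internals[i]] <<- h
      enumerate(i + 1L)
    }
  }
  enumerate(1L)
  best_total
}

# a random tanglegram with nh host and np parasite leaves, 1:1-or-random links
random_tanglegram <- function(nh, np, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  host <- simulate_pda(paste0("H", seq_len(nh)))
  parasite <- simulate_pda(paste0("q", seq_len(np)))
  links <- links_matrix(parasite$tip.label,
                        sample(host$tip.label, np, replace = TRUE))
  list(host = host, parasite = parasite, links = links)
}

# brute-force chronological feasibility: try every total order of the host
# internal nodes against the tree constraints plus the switch constraints
brute_force_chronology <- function(host, switches) {
  H <- oracle_index(host)
  internal <- which(lengths(H$kids) > 0L)
  cons <- list()
  add <- function(u, v) {
    if (u %in% internal && v %in% internal) cons[[length(cons) + 1L]] <<- c(u, v)
  }
  for (v in internal) if (!is.na(H$parent[v])) add(H$parent[v], v)
  if (NROW(switches)) {
    for (i in seq_len(nrow(switches))) {
      s <- switches$source[i]; t <- switches$target[i]
      if (!is.na(H$parent[s])) add(H$parent[s], t)
      if (!is.na(H$parent[t])) add(H$parent[t], s)
    }
  }
  if (!length(cons)) return(TRUE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (ord in perms(internal)) {
    rank <- match(seq_len(H$N), ord)
    ok <- all(vapply(cons, function(uv) rank[uv[1]] < rank[uv[2]], TRUE))
    if (ok) return(TRUE)
  }
  FALSE
}

# patristic distances by explicit root-path intersection (oracle for the
# package implementation)
oracle_patristic <- function(tree) {
  H <- oracle_index(tree)
  elen <- rep(NA_real_, H$N)
  elen[tree$edge[, 2]] <- tree$edge.length
  path_up <- function(v) {
    out <- integer(0)
    while (!is.na(H$parent[v])) {
      out <- c(out, v)
      v <- H$parent[v]
    }
    out
  }
  n <- H$ntip
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pi_ <- path_up(i); pj <- path_up(j)
      shared <- intersect(pi_, pj)
      D[i, j] <- D[j, i] <- sum(elen[setdiff(c(pi_, pj), shared)])
    }
  }
  ord <- order(rownames(D))
  D[ord, ord]
}

# canonical form of a rooted topology (for PDA uniformity checks)
canonical_topology <- function(tree) {
  idx <- oracle_index(tree)
  canon <- function(v) {
    if (length(idx$kids[[v]]) == 0L) return(tree$tip.label[v])
    paste0("(", paste(sort(vapply(idx$kids[[v]], canon, "")), collapse = ","), ")")
  }
  canon(idx$root)
}
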
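# Event-based host-parasite tree reconciliation.
#
# The parasite tree is embedded into the host tree under four event types:
# cospeciation (parasite node tracks a host speciation), duplication
# (within-host speciation), host-switch (one daughter jumps to a
# non-ancestral host lineage) and sorting/loss (a host edge is traversed
# without a matching parasite event, or a lineage is missed). The minimum
# total cost embedding is found by dynamic programming over (parasite node,
# host node) pairs, in the style of undated duplication-transfer-loss
# reconciliation. Chronological feasibility of host-switches is checked
# afterwards on the recovered event set; checking it inside the DP is
# NP-hard.

EVENT_TYPES <- c("cospeciation", "sorting", "duplication", "switching")

#' Event cost scheme
#'
#' @param cospeciation,sorting,duplication,switching nonnegative event costs.
#' @param normalize divide by the sum so the costs lie on the simplex (the
#'   scale used for adaptive cost estimation and plausibility filtering).
#' @return named numeric vector of length 4.
#' @export
cost_scheme <- function(cospeciation = 0, sorting = 1, duplication = 1,
                        switching = 2, normalize = FALSE) {
  v <- c(cospeciation = cospeciation, sorting = sorting,
         duplication = duplication, switching = switching)
  if (any(!is.finite(v)) || any(v < 0)) stop2("event costs must be finite and >= 0")
  if (normalize) {
    if (sum(v) <= 0) stop2("cannot normalize an all-zero cost scheme")
    v <- v / sum(v)
  }
  v
}

#' Reconciliation options
#'
#' @param root_to_root force the parasite root onto the host root (the
#'   conventional setting when the parasite ingroup is known to span the
#'   whole host clade).
#' @param charge_dup_with_switch also bill a duplication for every
#'   host-switch (off by default: the switch itself accounts for the
#'   parasite speciation).
#' @param allow_polytomies resolve parasite polytomies greedily instead of
#'   erroring.
#' @return list of options.
#' @export
reconcile_options <- function(root_to_root = TRUE, charge_dup_with_switch = FALSE,
                              allow_polytomies = FALSE) {
  list(root_to_root = isTRUE(root_to_root),
       charge_dup_with_switch = isTRUE(charge_dup_with_switch),
       allow_polytomies = isTRUE(allow_polytomies))
}

# ---- tree indexing ---------------------------------------------------------

# static index of a rooted tree for the DP: children (deterministically
# ordered by smallest descendant leaf label), postorder, ancestor matrix
.tree_index <- function(tr) {
  ntip <- ape::Ntip(tr)
  N <- ntip + tr$Nnode
  root <- ntip + 1L
  kids <- vector("list", N)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[i, 2])
  }
  parent <- rep(NA_integer_, N)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  po <- integer(0)
  walk <- function(v) {
    for (c in kids[[v]]) walk(c)
    po[[length(po) + 1L]] <<- v
  }
  walk(root)
  po <- unlist(po)
  pre <- rev(po)
  # anc[a, d]: a is an ancestor of d, or a == d
  anc <- matrix(FALSE, N, N)
  for (v in pre) {
    if (v == root) anc[v, v] <- TRUE else {
      anc[, v] <- anc[, parent[v]]
      anc[v, v] <- TRUE
    }
  }
  key <- character(N)
  for (v in po) {
    key[v] <- if (v <= ntip) tr$tip.label[v] else min(key[kids[[v]]])
  }
  kids <- lapply(kids, function(cs) if (length(cs)) cs[order(key[cs])] else cs)
  list(tree = tr, ntip = ntip, N = N, root = root, kids = kids,
       parent = parent, po = po, anc = anc, key = key,
       internal = which(lengths(kids) > 0L))
}

# ---- parasite preprocessing ------------------------------------------------

# split parasite leaves linked to several hosts into one pseudo-leaf per
# host, and (optionally) resolve polytomies greedily by repeatedly joining
# the two children whose linked hosts are closest on the host tree
.prepare_parasite <- function(parasite, links, host_idx, options) {
  validate_links(links, parasite_tree = parasite)
  multi <- rownames(links)[rowSums(links) > 1L]
  if (length(multi)) {
    message("splitting multi-host parasite leaf(s) into pseudo-leaves: ",
            paste(multi, collapse = ", "))
    tab <- .phylo_tab(parasite)
    pairs <- list()
    for (lab in multi) {
      v <- match(lab, tab$lab[seq_len(tab$ntip)])
      hs <- colnames(links)[links[lab, ] == 1L]
      new_ids <- tab$N + seq_along(hs)
      for (k in seq_along(hs)) {
        id <- new_ids[k]
        tab$parent[id] <- v
        tab$len[id] <- 0
        tab$lab[id] <- paste0(lab, "@", hs[k])
        tab$kids[[id]] <- integer(0)
        pairs[[length(pairs) + 1L]] <- c(tab$lab[id], hs[k])
      }
      tab$kids[[v]] <- new_ids
      tab$lab[v] <- ""
      tab$N <- tab$N + length(hs)
    }
    parasite <- .tab_to_phylo(tab)
    keep <- rownames(links)[rowSums(links) == 1L]
    entries <- rbind(
      if (length(keep)) {
        cbind(keep, colnames(links)[apply(links[keep, , drop = FALSE], 1, which.max)])
      },
      do.call(rbind, pairs))
    links <- links_matrix(entries[, 1], entries[, 2])
  }
  tab <- .phylo_tab(parasite)
  if (any(lengths(tab$kids) > 2L)) {
    if (!options$allow_polytomies) {
      stop2("parasite tree is not binary; set allow_polytomies = TRUE to ",
            "resolve polytomies greedily")
    }
    parasite <- .resolve_polytomies(parasite, links, host_idx)
  }
  list(parasite = parasite, links = links)
}

# greedy local resolution: join the pair of polytomy children whose linked
# host MRCAs are closest (fewest edges apart) on the host tree
.resolve_polytomies <- function(parasite, links, host_idx) {
  tab <- .phylo_tab(parasite)
  host_mrca <- function(node) {
    tips <- .tab_tips(tab, node)
    hs <- unique(unlist(lapply(tips, function(t) {
      colnames(links)[links[t, ] == 1L]
    })))
    hids <- match(hs, host_idx$tree$tip.label)
    m <- hids[1]
    for (h in hids[-1]) m <- .mrca_pair(host_idx, m, h)
    m
  }
  node_dist <- function(a, b) {
    m <- .mrca_pair(host_idx, a, b)
    .depth_of(host_idx, a) + .depth_of(host_idx, b) - 2 * .depth_of(host_idx, m)
  }
  repeat {
    poly <- which(lengths(tab$kids) > 2L)
    if (!length(poly)) break
    v <- poly[1]
    ch <- tab$kids[[v]]
    pos <- vapply(ch, host_mrca, 1L)
    best <- NULL
    best_d <- Inf
    for (i in seq_along(ch)[-length(ch)]) {
      for (j in seq(i + 1L, length(ch))) {
        d <- node_dist(pos[i], pos[j])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    id <- tab$N + 1L
    tab$N <- id
    tab$parent[id] <- v
    tab$len[id] <- 0
    tab$lab[id] <- ""
    tab$kids[[id]] <- ch[best]
    tab$parent[ch[best]] <- id
    tab$kids[[v]] <- c(setdiff(ch, ch[best]), id)
  }
  .tab_to_phylo(tab)
}

.tab_tips <- function(tab, node) {
  if (length(tab$kids[[node]]) == 0L) return(tab$lab[node])
  unlist(lapply(tab$kids[[node]], function(c) .tab_tips(tab, c)))
}

.mrca_pair <- function(idx, a, b) {
  v <- a
  while (!idx$anc[v, b]) v <- idx$parent[v]
  v
}

.depth_of <- function(idx, v) {
  d <- 0L
  while (!is.na(idx$parent[v])) { v <- idx$parent[v]; d <- d + 1L }
  d
}

# ---- the DP ----------------------------------------------------------------

#' Reconcile a parasite tree with its host tree
#'
#' Computes a minimum-total-cost embedding of the parasite tree into the
#' host tree under the four-event model by dynamic programming. Every
#' parasite internal node is assigned a host node and an event; sorting
#' events are the host edges traversed in between. Host-switch targets are
#' restricted to host nodes that are not ancestors of (and not equal to) the
#' switch source. Tie-breaking is fully deterministic: events are preferred
#' in the order cospeciation > duplication > host-switch, and equal-cost
#' host positions are taken in lexicographic order of their smallest
#' descendant leaf label, so repeated runs give identical reports.
#'
#' @param host rooted host `"phylo"` (binary or with polytomies).
#' @param parasite rooted parasite `"phylo"`; must be binary unless
#'   `options$allow_polytomies`.
#' @param links binary parasite-by-host matrix. Leaves linked to several
#'   hosts are split into pseudo-leaves first.
#' @param costs a [cost_scheme()].
#' @param options a [reconcile_options()].
#' @return object of class `"reconciliation"`: list with `mapping`
#'   (data frame of parasite node, host node and event), `counts` (named
#'   event tally), `switches` (source/target host nodes), `total_cost`,
#'   `costs`, `quality` (`NA` unless set by [estimate_costs()]) and
#'   `options`.
#' @export
reconcile <- function(host, parasite, links,
                      costs = cost_scheme(0, 1, 1, 2),
                      options = reconcile_options()) {
  ctx <- .recon_ctx(host, parasite, links, options)
  .recon_result(ctx, .recon_dp(ctx, costs), costs)
}

# everything that does not depend on the cost scheme, prepared once so that
# adaptive cost search can run the DP thousands of times cheaply
.recon_ctx <- function(host, parasite, links, options) {
  stopifnot(inherits(host, "phylo"), inherits(parasite, "phylo"))
  validate_links(links, parasite_tree = parasite, host_tree = host)
  unlinked <- setdiff(parasite$tip.label, rownames(links))
  if (length(unlinked)) {
    stop2("parasite leaf(s) without a host link: ", paste(unlinked, collapse = ", "))
  }
  H <- .tree_index(host)
  prep <- .prepare_parasite(parasite, links, H, options)
  parasite <- prep$parasite
  links <- prep$links
  P <- .tree_index(parasite)
  phi <- integer(P$ntip)
  for (t in seq_len(P$ntip)) {
    lab <- parasite$tip.label[t]
    h <- colnames(links)[links[lab, ] == 1L]
    phi[t] <- match(h, host$tip.label)
  }
  list(host = host, parasite = parasite, links = links, options = options,
       H = H, P = P, phi = phi, allowed = !H$anc)
}

# minimum-cost DP plus deterministic backtracking under one cost scheme
.recon_dp <- function(ctx, costs) {
  H <- ctx$H; P <- ctx$P; phi <- ctx$phi
  options <- ctx$options
  cc <- costs[["cospeciation"]]; cs <- costs[["sorting"]]
  cd <- costs[["duplication"]]; cw <- costs[["switching"]]
  dup_extra <- if (options$charge_dup_with_switch) cd else 0

  Nh <- H$N
  host_po <- H$po
  # allowed switch targets for a lineage sitting on the edge above h:
  # everything except h and its ancestors
  allowed <- ctx$allowed       # allowed[target, source]
  Cm <- matrix(Inf, P$N, Nh)   # parasite node mapped exactly at host node
  INm <- matrix(Inf, P$N, Nh)  # entering the edge above host node, may sort

  in_pass <- function(Cv) {
    INv <- Cv
    for (h in host_po) {
      ch <- H$kids[[h]]
      if (length(ch)) {
        INv[h] <- min(Cv[h], cs + min(INv[ch]))
      }
    }
    INv
  }

  for (p in P$po) {
    if (length(P$kids[[p]]) == 0L) {
      Cv <- rep(Inf, Nh)
      Cv[phi[p]] <- 0
      Cm[p, ] <- Cv
      INm[p, ] <- in_pass(Cv)
    } else {
      q <- P$kids[[p]]
      in1 <- INm[q[1], ]; in2 <- INm[q[2], ]
      bn1 <- vapply(seq_len(Nh), function(h) suppressWarnings(min(in1[allowed[, h]])), 0)
      bn2 <- vapply(seq_len(Nh), function(h) suppressWarnings(min(in2[allowed[, h]])), 0)
      cosp <- rep(Inf, Nh)
      for (h in H$internal) {
        ch <- H$kids[[h]]
        best <- Inf
        for (i in seq_along(ch)) {
          for (j in seq_along(ch)) {
            if (i != j) best <- min(best, in1[ch[i]] + in2[ch[j]])
          }
        }
        cosp[h] <- cc + best
      }
      dup <- cd + in1 + in2
      sw <- cw + dup_extra + pmin(in1 + bn2, in2 + bn1)
      Cv <- pmin(cosp, dup, sw)
      Cm[p, ] <- Cv
      INm[p, ] <- in_pass(Cv)
    }
  }

  if (options$root_to_root) {
    total <- Cm[P$root, H$root]
    start_h <- H$root
  } else {
    total <- min(Cm[P$root, ])
    cand <- which(Cm[P$root, ] <= total + 1e-12)
    start_h <- cand[order(H$key[cand])][1]
  }
  if (!is.finite(total)) stop2("no feasible reconciliation found")

  # ---- backtracking --------------------------------------------------------
  eps <- 1e-9 * max(1, sum(costs))
  counts <- c(cospeciation = 0L, sorting = 0L, duplication = 0L, switching = 0L)
  map_p <- integer(0); map_h <- integer(0); map_ev <- character(0)
  sw_src <- integer(0); sw_tgt <- integer(0)

  pick_min <- function(vals, mask) {
    v <- vals
    v[!mask] <- Inf
    m <- min(v)
    cand <- which(v <= m + eps)
    cand[order(H$key[cand])][1]
  }

  bt_at <- function(p, h) {
    map_p <<- c(map_p, p); map_h <<- c(map_h, h)
    if (length(P$kids[[p]]) == 0L) {
      map_ev <<- c(map_ev, "leaf")
      return(invisible())
    }
    q <- P$kids[[p]]
    in1 <- INm[q[1], ]; in2 <- INm[q[2], ]
    val <- Cm[p, h]
    ch <- H$kids[[h]]
    if (length(ch)) {
      for (i in seq_along(ch)) {
        for (j in seq_along(ch)) {
          if (i == j) next
          if (cc + in1[ch[i]] + in2[ch[j]] <= val + eps) {
            map_ev <<- c(map_ev, "cospeciation")
            counts["cospeciation"] <<- counts["cospeciation"] + 1L
            bt_in(q[1], ch[i]); bt_in(q[2], ch[j])
            return(invisible())
          }
        }
      }
    }
    if (cd + in1[h] + in2[h] <= val + eps) {
      map_ev <<- c(map_ev, "duplication")
      counts["duplication"] <<- counts["duplication"] + 1L
      bt_in(q[1], h); bt_in(q[2], h)
      return(invisible())
    }
    cwv <- cw + dup_extra
    ok1 <- allowed[, h]
    if (cwv + in1[h] + suppressWarnings(min(in2[ok1])) <= val + eps) {
      tgt <- pick_min(in2, ok1)
      map_ev <<- c(map_ev, "switching")
      counts["switching"] <<- counts["switching"] + 1L
      if (options$charge_dup_with_switch) counts["duplication"] <<- counts["duplication"] + 1L
      sw_src <<- c(sw_src, h); sw_tgt <<- c(sw_tgt, tgt)
      bt_in(q[1], h); bt_in(q[2], tgt)
      return(invisible())
    }
    if (cwv + in2[h] + suppressWarnings(min(in1[ok1])) <= val + eps) {
      tgt <- pick_min(in1, ok1)
      map_ev <<- c(map_ev, "switching")
      counts["switching"] <<- counts["switching"] + 1L
      if (options$charge_dup_with_switch) counts["duplication"] <<- counts["duplication"] + 1L
      sw_src <<- c(sw_src, h); sw_tgt <<- c(sw_tgt, tgt)
      bt_in(q[2], h); bt_in(q[1], tgt)
      return(invisible())
    }
    stop2("internal error: backtracking found no consistent event")
  }

  bt_in <- function(p, h) {
    if (Cm[p, h] <= INm[p, h] + eps) {
      bt_at(p, h)
      return(invisible())
    }
    for (c in H$kids[[h]]) {
      if (cs + INm[p, c] <= INm[p, h] + eps) {
        counts["sorting"] <<- counts["sorting"] + 1L
        bt_in(p, c)
        return(invisible())
      }
    }
    stop2("internal error: backtracking lost the sorting path")
  }

  bt_at(P$root, start_h)

  # each internal parasite node carries exactly one node event (a switch that
  # also bills a duplication still occupies a single node)
  node_dups <- counts[["duplication"]] -
    (if (options$charge_dup_with_switch) counts[["switching"]] else 0L)
  stopifnot(counts[["cospeciation"]] + node_dups + counts[["switching"]] ==
              ctx$parasite$Nnode)
  implied <- sum(counts * costs[EVENT_TYPES])
  if (abs(implied - total) > 1e-6 * max(1, abs(total))) {
    stop2("internal error: event tally does not reproduce the DP cost")
  }
  list(counts = counts, total = total, map_p = map_p, map_h = map_h,
       map_ev = map_ev, sw_src = sw_src, sw_tgt = sw_tgt)
}

# wrap a DP result into the user-facing S3 object
.recon_result <- function(ctx, r, costs) {
  H <- ctx$H; P <- ctx$P
  node_lab <- function(idx, v) {
    if (v <= idx$ntip) idx$tree$tip.label[v] else paste0("mrca(", idx$key[v], ")")
  }
  mapping <- data.frame(
    parasite_node = r$map_p,
    parasite_label = vapply(r$map_p, function(v) node_lab(P, v), ""),
    host_node = r$map_h,
    host_label = vapply(r$map_h, function(v) node_lab(H, v), ""),
    event = r$map_ev,
    stringsAsFactors = FALSE)
  out <- list(mapping = mapping,
              counts = r$counts,
              switches = data.frame(source = r$sw_src, target = r$sw_tgt),
              total_cost = r$total,
              costs = costs,
              quality = NA_real_,
              options = ctx$options,
              parasite = ctx$parasite,
              host = ctx$host,
              links = ctx$links)
  class(out) <- "reconciliation"
  out
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("host-parasite reconciliation\n")
  cat(sprintf("  events: %d cospeciation, %d sorting, %d duplication, %d host-switch\n",
              x$counts[["cospeciation"]], x$counts[["sorting"]],
              x$counts[["duplication"]], x$counts[["switching"]]))
  cat(sprintf("  total cost %.4g under costs (%s)\n", x$total_cost,
              paste(signif(x$costs, 3), collapse = ", ")))
  if (!is.na(x$quality)) cat(sprintf("  quality %.4g\n", x$quality))
  invisible(x)
}

# ---- adaptive cost estimation ---------------------------------------------

#' Quality of a cost scheme given its optimal event tally
#'
#' Parameter-adaptive reconciliation scores a cost vector by how close it is
#' to being anti-proportional to the event frequencies it induces: the
#' quality is the Euclidean distance between the normalized cost vector and
#' the normalized inverse-frequency vector (frequencies floored at half an
#' event to keep absent event types finite). Lower is better; 0 means the
#' costs are exactly inversely proportional to how often each event is used.
#'
#' @param counts named event tally (length 4).
#' @param costs cost vector (any positive scale).
#' @return the quality value.
#' @export
recon_quality <- function(counts, costs) {
  if (!is.null(names(counts))) counts <- counts[EVENT_TYPES]
  if (!is.null(names(costs))) costs <- costs[EVENT_TYPES]
  stopifnot(length(counts) == 4L, length(costs) == 4L)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  eps <- 0.5 / tot
  f <- counts / tot
  chat <- 1 / pmax(f, eps)
  chat <- chat / sum(chat)
  cn <- costs / sum(costs)
  sqrt(sum((cn - chat)^2))
}

#' Estimate event costs adaptively
#'
#' Samples cost vectors uniformly from the simplex, reconciles under each,
#' scores each by [recon_quality()], then refines the best candidates by
#' Nelder-Mead on the simplex (via a softmax parameterization). Avoids any a
#' priori cost assignment: the data decide which event costs make the
#' inferred event usage and the costs mutually consistent.
#'
#' @param host,parasite,links,options as in [reconcile()].
#' @param n_sets number of sampled cost vectors (the conventional setting is
#'   1e4; reduce for quick exploration).
#' @param seed integer seed for reproducibility.
#' @param refine how many top candidates to polish with Nelder-Mead.
#' @return list with `costs` (best normalized scheme), `reconciliation`
#'   (with its `quality` filled in), `quality`, and `ranked`, a data frame
#'   of the top candidate schemes with their event tallies (the shape of a
#'   published reconciliation summary table).
#' @export
estimate_costs <- function(host, parasite, links, n_sets = 10000, seed = NULL,
                           options = reconcile_options(), refine = 5) {
  stopifnot(n_sets >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctx <- .recon_ctx(host, parasite, links, options)
  E <- matrix(stats::rexp(n_sets * 4), ncol = 4)
  schemes <- E / rowSums(E)
  eval_full <- function(cv) {
    r <- .recon_dp(ctx, cost_scheme(cv[1], cv[2], cv[3], cv[4]))
    list(q = recon_quality(r$counts, cv), total = r$total)
  }
  q_of <- function(cv) eval_full(cv)$q
  qs <- apply(schemes, 1, q_of)
  ord <- order(qs)
  top <- ord[seq_len(min(refine, n_sets))]
  # deterministic archetype starts (one event type cheap at a time, plus a
  # uniform scheme) make sure every event-dominant basin is explored even
  # when the random sample happens to miss one
  archetypes <- rbind(diag(4) * -0.2 + 0.3, rep(0.25, 4))
  starts <- rbind(schemes[top, , drop = FALSE], archetypes)
  cands <- lapply(seq_len(nrow(starts)), function(i) {
    z0 <- log(starts[i, -1] / starts[i, 1])
    opt <- stats::optim(z0, function(z) {
      cv <- exp(c(0, pmin(pmax(z, -30), 30)))
      cv <- cv / sum(cv)
      q_of(cv)
    }, method = "Nelder-Mead", control = list(maxit = 150, reltol = 1e-8))
    cv <- exp(c(0, pmin(pmax(opt$par, -30), 30)))
    cv <- cv / sum(cv)
    c(list(cv = cv), eval_full(cv))
  })
  # several exact fixpoints of the anti-proportionality criterion can
  # coexist (that is the degeneracy the plausibility filter targets); among
  # quality ties prefer the cheaper, i.e. more parsimonious, reconciliation
  q_all <- vapply(cands, `[[`, 0, "q")
  tied <- which(q_all <= min(q_all) + 1e-6)
  best <- tied[which.min(vapply(cands[tied], `[[`, 0, "total"))]
  best_cv <- cands[[best]]$cv
  best_costs <- cost_scheme(best_cv[1], best_cv[2], best_cv[3], best_cv[4])
  rec <- .recon_result(ctx, .recon_dp(ctx, best_costs), best_costs)
  rec$quality <- recon_quality(rec$counts, best_cv)
  ranked <- do.call(rbind, lapply(cands, function(cd) {
    cv <- cd$cv
    r <- .recon_dp(ctx, cost_scheme(cv[1], cv[2], cv[3], cv[4]))
    data.frame(quality = cd$q, total_cost = r$total,
               cospeciation = r$counts[["cospeciation"]],
               sorting = r$counts[["sorting"]],
               duplication = r$counts[["duplication"]],
               switching = r$counts[["switching"]],
               c_cospeciation = cv[1], c_sorting = cv[2],
               c_duplication = cv[3], c_switching = cv[4])
  }))
  list(costs = best_costs, reconciliation = rec, quality = rec$quality,
       ranked = ranked[order(ranked$quality, ranked$total_cost), ])
}

#' Flag biologically implausible reconciliations
#'
#' An adaptive cost search can return degenerate solutions in which an event
#' type is never used precisely because it was assigned an extreme cost
#' (e.g. zero host-switches with a near-1 normalized switch cost). Such
#' solutions are statistically optimal but biologically vacuous and should
#' be discarded in favor of the next-best scheme. The operational rule: flag
#' when any event type has zero inferred occurrences while its normalized
#' cost exceeds 0.9.
#'
#' @param x a `"reconciliation"` or a named event-count vector (length 4).
#' @param costs cost vector; defaults to `x$costs` for reconciliations.
#' @return list with `flagged` (logical) and `reasons` (character).
#' @export
flag_implausible <- function(x, costs = NULL) {
  if (inherits(x, "reconciliation")) {
    counts <- x$counts
    if (is.null(costs)) costs <- x$costs
  } else {
    counts <- if (!is.null(names(x))) x[EVENT_TYPES] else x
    if (is.null(costs)) stop2("'costs' is required when passing raw counts")
  }
  if (!is.null(names(costs))) costs <- costs[EVENT_TYPES]
  stopifnot(length(counts) == 4L, length(costs) == 4L)
  cn <- costs / sum(costs)
  bad <- which(counts == 0 & cn > 0.9)
  list(flagged = length(bad) > 0L,
       reasons = if (length(bad)) {
         sprintf("%s: 0 events inferred but normalized cost %.3g > 0.9",
                 EVENT_TYPES[bad], cn[bad])
       } else character(0))
}

#' Chronological consistency of a reconciliation
#'
#' A host-switch requires its source and target host edges to be
#' contemporaneous, which induces ordering constraints among host internal
#' nodes beyond the tree's own ancestor order: for a switch from the edge
#' above `s` to the edge above `t`, the parent of `s` must predate `t` and
#' the parent of `t` must predate `s`. The reconciliation is chronologically
#' consistent iff the combined constraint graph is acyclic.
#'
#' @param host host `"phylo"` used for the reconciliation.
#' @param rec a `"reconciliation"` (only its `switches` field is used).
#' @return `TRUE` if a consistent dating of host nodes exists.
#' @export
check_chronology <- function(host, rec) {
  stopifnot(inherits(host, "phylo"))
  sw <- if (inherits(rec, "reconciliation")) rec$switches else rec
  if (NROW(sw) == 0L) return(TRUE)
  H <- .tree_index(host)
  internal <- H$internal
  edges <- list()
  add <- function(u, v) {
    # constraint: u strictly before v; tips are at the present and internal
    # nodes strictly before them (positive branch lengths), so constraints
    # with a tip on the later side always hold
    if (u %in% internal && v %in% internal) edges[[length(edges) + 1L]] <<- c(u, v)
  }
  for (v in internal) {
    if (!is.na(H$parent[v])) add(H$parent[v], v)
  }
  for (i in seq_len(nrow(sw))) {
    s <- sw$source[i]; t <- sw$target[i]
    if (!is.na(H$parent[s])) add(H$parent[s], t)
    if (!is.na(H$parent[t])) add(H$parent[t], s)
  }
  if (!length(edges)) return(TRUE)
  em <- do.call(rbind, edges)
  nodes <- sort(unique(c(em)))
  adj <- lapply(nodes, function(u) em[em[, 1] == u, 2])
  names(adj) <- nodes
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  acyclic <- TRUE
  visit <- function(u) {
    k <- as.character(u)
    if (state[k] == 1L) { acyclic <<- FALSE; return(invisible()) }
    if (state[k] == 2L) return(invisible())
    state[k] <<- 1L
    for (v in adj[[k]]) visit(v)
    state[k] <<- 2L
  }
  for (u in nodes) {
    if (!acyclic) break
    visit(u)
  }
  acyclic
}

#' Randomization test of topological congruence
#'
#' Counts cospeciations in a maximum-cospeciation reconciliation (costs 0
#' for cospeciation, 1 for every other event) and compares the count with
#' the same statistic on pairs of random topologies drawn uniformly from all
#' labeled rooted binary trees (the proportional-to-distinguishable model)
#' over the same leaf sets, keeping the links fixed.
#'
#' @param host,parasite,links,options as in [reconcile()].
#' @param n_rand number of random tree pairs.
#' @param seed integer seed.
#' @return list with `observed` (cospeciation count), `p_value`
#'   (add-one permutation p), `n_rand` and the `null` sample.
#' @export
cospeciation_significance <- function(host, parasite, links, n_rand = 10000,
                                      seed = NULL, options = reconcile_options()) {
  if (!is.null(seed)) set.seed(seed)
  max_cosp_costs <- cost_scheme(0, 1, 1, 1)
  obs <- reconcile(host, parasite, links, max_cosp_costs, options)$counts[["cospeciation"]]
  null <- vapply(seq_len(n_rand), function(i) {
    hr <- simulate_pda(host$tip.label)
    pr <- simulate_pda(parasite$tip.label)
    reconcile(hr, pr, links, max_cosp_costs, options)$counts[["cospeciation"]]
  }, 0L)
  p <- (1 + sum(null >= obs)) / (1 + n_rand)
  list(observed = obs, p_value = p, n_rand = n_rand, null = null)
}

#' Event-count summary table for one or more reconciliations
#'
#' @param ... `"reconciliation"` objects (or one list of them).
#' @return data frame with quality, total cost, the four event counts and
#'   their (normalized) costs — the conventional reconciliation summary
#'   layout.
#' @export
event_table <- function(...) {
  recs <- list(...)
  if (length(recs) == 1L && !inherits(recs[[1]], "reconciliation")) recs <- recs[[1]]
  do.call(rbind, lapply(recs, function(r) {
    cn <- r$costs / sum(r$costs)
    data.frame(quality = r$quality, total_cost = r$total_cost,
               cospeciation = r$counts[["cospeciation"]],
               cost_cospeciation = cn[["cospeciation"]],
               sorting = r$counts[["sorting"]],
               cost_sorting = cn[["sorting"]],
               duplication = r$counts[["duplication"]],
               cost_duplication = cn[["duplication"]],
               switching = r$counts[["switching"]],
               cost_switching = cn[["switching"]])
  }))
}
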
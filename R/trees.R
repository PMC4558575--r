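# Tree and association-table input/output and preprocessing.
#
# Trees are ordinary ape "phylo" objects throughout; node supports live in
# node.label (the usual Newick dialect of writing bootstrap values as
# internal-node labels). Host-parasite links are binary matrices with
# parasites as rows and hosts as columns.

#' Parse a single rooted Newick statement
#'
#' Thin validating wrapper around [ape::read.tree()]. Beyond parsing, it
#' rejects unbalanced parentheses, missing terminal semicolons, duplicate
#' leaf labels and negative branch lengths, and rescales node supports given
#' as fractions in \[0, 1\] to percentages (with a warning), so downstream
#' support thresholds can always be stated on the 0-100 scale.
#'
#' @param text a single Newick string.
#' @return an object of class `"phylo"`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop2("'text' must be a single Newick string")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop2("empty Newick string")
  n_open <- nchar(gsub("[^(]", "", txt))
  n_close <- nchar(gsub("[^)]", "", txt))
  if (n_open != n_close) {
    stop2(sprintf("unbalanced parentheses in Newick string: %d '(' vs %d ')'",
                  n_open, n_close))
  }
  if (!grepl(";[[:space:]]*$", txt)) {
    stop2("Newick statement must end with ';'")
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop2("could not parse Newick string: ", substr(txt, 1, 60))
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop2("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    bad <- signif(tr$edge.length[tr$edge.length < 0], 6)
    stop2("negative branch lengths: ", paste(bad, collapse = ", "))
  }
  # supports printed as fractions (e.g. posterior probabilities) -> percent
  if (!is.null(tr$node.label)) {
    s <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(s)
    if (any(num) && all(s[num] >= 0 & s[num] <= 1) && any(s[num] > 0)) {
      warning("node supports look like fractions in [0, 1]; rescaling to percent")
      tr$node.label[num] <- sprintf("%.6g", s[num] * 100)
    }
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `"phylo"` object.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nwk <- ape::write.tree(tree)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Numeric node supports of a tree
#'
#' @param tree a `"phylo"` object.
#' @return numeric vector of length `tree$Nnode` (`NA` where a node carries
#'   no numeric label), or `NULL` when the tree has no node labels at all.
#' @export
node_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(NULL)
  suppressWarnings(as.numeric(tree$node.label))
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of leaves.
#' Rows/columns are sorted by leaf label so writers are diffable.
#'
#' @param tree a `"phylo"` object with branch lengths on every edge.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop2("tree has no branch lengths; patristic distances undefined")
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))
    stop2("missing branch length on edge(s): ",
          paste(apply(tree$edge[bad, , drop = FALSE], 1, paste, collapse = "->"),
                collapse = ", "))
  }
  D <- stats::cophenetic(tree)
  ord <- order(rownames(D))
  D[ord, ord, drop = FALSE]
}

# ---- internal mutable tree table ------------------------------------------

# flatten a phylo into parent/children arrays that are easy to edit in place
.phylo_tab <- function(tr) {
  ntip <- ape::Ntip(tr)
  N <- ntip + tr$Nnode
  parent <- rep(NA_integer_, N)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  len <- rep(NA_real_, N)
  if (!is.null(tr$edge.length)) len[tr$edge[, 2]] <- tr$edge.length
  lab <- c(tr$tip.label,
           if (!is.null(tr$node.label)) tr$node.label else rep("", tr$Nnode))
  kids <- vector("list", N)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[i, 2])
  }
  list(ntip = ntip, N = N, root = ntip + 1L, parent = parent, len = len,
       lab = lab, kids = kids, has_len = !is.null(tr$edge.length))
}

# serialize (possibly edited) table back to Newick, starting at `node`
.tab_newick <- function(tab, node) {
  ch <- tab$kids[[node]]
  lab <- tab$lab[node]
  body <- if (length(ch) == 0L) {
    lab
  } else {
    paste0("(", paste(vapply(ch, function(c) .tab_newick(tab, c), ""),
                      collapse = ","), ")", lab)
  }
  if (tab$has_len && !is.na(tab$len[node]) && node != tab$root) {
    body <- paste0(body, ":", .fmt_len(tab$len[node]))
  }
  body
}

.tab_to_phylo <- function(tab) {
  ape::read.tree(text = paste0(.tab_newick(tab, tab$root), ";"))
}

#' Collapse poorly supported internal nodes into polytomies
#'
#' Every internal non-root node whose support is strictly below `threshold`
#' is contracted into its parent. Unlabeled nodes are never collapsed, and a
#' node with support exactly equal to the threshold is retained. The
#' contracted edge's length is added to its children so leaf depths (and an
#' ultrametric tree's leaf ages) are preserved.
#'
#' @param tree a `"phylo"` object with supports in `node.label`.
#' @param threshold support value on the same scale as the labels
#'   (conventionally 0-100).
#' @return a `"phylo"` object with the same leaf set.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), is.numeric(threshold), length(threshold) == 1L)
  sup <- node_supports(tree)
  if (is.null(sup)) return(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  node_ids <- ntip + seq_len(tree$Nnode)
  victims <- node_ids[!is.na(sup) & sup < threshold & node_ids != root]
  if (!length(victims)) return(tree)
  tab <- .phylo_tab(tree)
  for (v in victims) {
    p <- tab$parent[v]
    ch <- tab$kids[[v]]
    pos <- match(v, tab$kids[[p]])
    if (tab$has_len && !is.na(tab$len[v])) {
      tab$len[ch] <- tab$len[ch] + tab$len[v]
    }
    tab$kids[[p]] <- append(tab$kids[[p]][-pos], ch, after = pos - 1L)
    for (c in ch) tab$parent[c] <- p
    tab$kids[[v]] <- integer(0)
    tab$parent[v] <- NA_integer_
    tab$lab[v] <- ""
  }
  # drop contracted nodes by rebuilding from the root
  .tab_to_phylo(tab)
}

#' Collapse terminal clades restricted to a single host
#'
#' Maximal terminal monophyletic parasite clades whose leaves all link to
#' exactly one, common host species are replaced by a single representative
#' leaf carrying that link (the alphabetically smallest member label). This
#' removes within-host speciation in terminal taxa, which would otherwise
#' inflate cospeciation counts at the price of spurious duplications in an
#' event-based reconciliation. Applied to fixpoint; the root itself is never
#' collapsed so at least two leaves remain.
#'
#' @param tree parasite `"phylo"` object.
#' @param links binary parasite-by-host matrix (see [links_matrix()]).
#' @return list with elements `tree` and `links`.
#' @export
collapse_terminal_host_clades <- function(tree, links) {
  stopifnot(inherits(tree, "phylo"), is.matrix(links))
  missing <- setdiff(tree$tip.label, rownames(links))
  if (length(missing)) {
    stop2("parasite leaves missing from links: ", paste(missing, collapse = ", "))
  }
  repeat {
    tab <- .phylo_tab(tree)
    # per node: single common host of all descendant leaves, or NA
    host_of <- rep(NA_character_, tab$N)
    ok <- rep(FALSE, tab$N)
    members <- vector("list", tab$N)
    po <- .postorder_nodes(tab)
    for (v in po) {
      if (length(tab$kids[[v]]) == 0L) {
        hs <- colnames(links)[links[tab$lab[v], ] == 1L]
        members[[v]] <- tab$lab[v]
        if (length(hs) == 1L) {
          host_of[v] <- hs
          ok[v] <- TRUE
        }
      } else {
        ch <- tab$kids[[v]]
        members[[v]] <- unlist(members[ch])
        hs <- unique(host_of[ch])
        ok[v] <- all(ok[ch]) && length(hs) == 1L && !is.na(hs[1])
        if (ok[v]) host_of[v] <- hs[1]
      }
    }
    ok[tab$root] <- FALSE
    # maximal qualifying internal nodes
    maximal <- which(ok & vapply(seq_len(tab$N), function(v) {
      length(tab$kids[[v]]) > 0L && (is.na(tab$parent[v]) || !ok[tab$parent[v]])
    }, TRUE))
    if (!length(maximal)) break
    for (v in maximal) {
      rep_lab <- min(members[[v]])
      tab$lab[v] <- rep_lab
      tab$kids[[v]] <- integer(0)
    }
    tree <- .tab_to_phylo(tab)
  }
  keep <- tree$tip.label
  new_links <- matrix(0L, length(keep), ncol(links),
                      dimnames = list(sort(keep), colnames(links)))
  for (p in sort(keep)) new_links[p, ] <- links[p, ]
  list(tree = tree, links = new_links)
}

.postorder_nodes <- function(tab) {
  out <- integer(0)
  walk <- function(v) {
    for (c in tab$kids[[v]]) walk(c)
    out[[length(out) + 1L]] <<- v
  }
  walk(tab$root)
  unlist(out)
}

# ---- host-parasite association tables -------------------------------------

#' Build a binary host-parasite association matrix
#'
#' @param parasite,host character vectors of equal length; each pair is one
#'   association.
#' @return an integer 0/1 matrix, parasites as (sorted) rows, hosts as
#'   (sorted) columns.
#' @export
links_matrix <- function(parasite, host) {
  stopifnot(length(parasite) == length(host), length(parasite) >= 1L)
  p <- sort(unique(as.character(parasite)))
  h <- sort(unique(as.character(host)))
  A <- matrix(0L, length(p), length(h), dimnames = list(p, h))
  A[cbind(match(parasite, p), match(host, h))] <- 1L
  A
}

#' Read a host-parasite link table
#'
#' Two tab-separated columns, `parasite<TAB>host`; lines starting with `#`
#' are comments, an optional `parasite	host` header row is skipped, and
#' duplicate rows are dropped with a warning.
#'
#' @param path path to a TSV file.
#' @return an integer 0/1 matrix (see [links_matrix()]).
#' @export
read_links <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop2("empty link table: ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop2("malformed link table row(s) (expected 2 tab-separated fields) at line ",
          paste(keep[bad], collapse = ", "), " of ", path)
  }
  m <- do.call(rbind, parts)
  m <- matrix(trimws(m), ncol = 2L)
  if (tolower(m[1, 1]) == "parasite" && tolower(m[1, 2]) == "host") {
    m <- m[-1, , drop = FALSE]
    if (!nrow(m)) stop2("link table has a header but no rows: ", path)
  }
  dup <- duplicated(paste(m[, 1], m[, 2], sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated link(s) dropped")
    m <- m[!dup, , drop = FALSE]
  }
  links_matrix(m[, 1], m[, 2])
}

#' Write a link table as TSV
#' @param links binary parasite-by-host matrix.
#' @param path output path.
#' @export
write_links <- function(links, path) {
  idx <- which(links == 1L, arr.ind = TRUE)
  df <- data.frame(parasite = rownames(links)[idx[, 1]],
                   host = colnames(links)[idx[, 2]])
  df <- df[order(df$parasite, df$host), ]
  utils::write.table(rbind(c("parasite", "host"), as.matrix(df)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(df)
}

#' Validate a link matrix against trees
#'
#' @param links binary parasite-by-host matrix.
#' @param parasite_tree,host_tree optional `"phylo"` objects whose leaf sets
#'   must cover the row/column names.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_links <- function(links, parasite_tree = NULL, host_tree = NULL) {
  stopifnot(is.matrix(links))
  if (!all(links %in% c(0L, 1L))) stop2("link matrix entries must be 0/1")
  if (any(rowSums(links) < 1L)) {
    stop2("parasite(s) without any host link: ",
          paste(rownames(links)[rowSums(links) < 1L], collapse = ", "))
  }
  if (!is.null(parasite_tree)) {
    miss <- setdiff(rownames(links), parasite_tree$tip.label)
    if (length(miss)) stop2("parasites absent from parasite tree: ",
                            paste(miss, collapse = ", "))
  }
  if (!is.null(host_tree)) {
    miss <- setdiff(colnames(links), host_tree$tip.label)
    if (length(miss)) stop2("hosts absent from host tree: ",
                            paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
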
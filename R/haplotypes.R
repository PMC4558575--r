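# Alignment summaries, haplotype collapsing, pairwise distances and
# threshold-based species delimitation.
#
# Alignments are character matrices (rows = sequences, rownames = labels,
# one column per site, upper-case). Distance matrices carry a "units"
# attribute ("fraction" or "percent") so thresholds cannot silently be
# applied on the wrong scale.

.DNA_STATES <- c("A", "C", "G", "T")

# coerce list-of-strings / ape DNAbin / matrix into the canonical matrix form
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- as.character(x)
    if (is.list(x)) {
      if (length(unique(lengths(x))) != 1L) {
        stop2("ragged alignment: sequence lengths ",
              paste(unique(lengths(x)), collapse = ", "))
      }
      x <- do.call(rbind, x)
    }
  }
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop2("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x) %||% paste0("seq", seq_along(x))
  } else {
    stop2("cannot interpret alignment input of class ", class(x)[1])
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop2("duplicate sequence labels in alignment")
  m
}

#' Read a FASTA alignment
#'
#' @param path path to an (uncompressed) FASTA file with aligned sequences.
#' @return character matrix, rows = sequences.
#' @export
read_alignment <- function(path) {
  x <- ape::read.FASTA(path)
  lens <- lengths(x)
  if (length(unique(lens)) != 1L) {
    stop2("sequences in ", path, " are not aligned (lengths ",
          paste(sort(unique(lens)), collapse = ", "), ")")
  }
  as_alignment(x)
}

#' Write an alignment as FASTA
#' @param aln alignment (any form accepted by internal coercion).
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  m <- as_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(c(paste0(">", rownames(m)[i]), paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Alignment summary statistics
#'
#' A site is *variable* when it shows at least two distinct unambiguous
#' nucleotide states (gaps and Ns ignored), and *parsimony-informative* when
#' at least two states each occur in at least two sequences.
#'
#' @param aln alignment.
#' @return list with `length`, `n_variable`, `n_parsimony_informative`.
#' @export
alignment_stats <- function(aln) {
  m <- as_alignment(aln)
  if (nrow(m) == 0L || ncol(m) == 0L) stop2("empty alignment")
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(m))) {
    states <- m[, j][m[, j] %in% .DNA_STATES]
    if (!length(states)) next
    tab <- table(states)
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(length = ncol(m), n_variable = variable,
       n_parsimony_informative = informative)
}

#' Collapse identical sequences into haplotypes
#'
#' Case-insensitive; the representative keeps the label of its first member
#' in input order.
#'
#' @param aln alignment.
#' @return object of class `"haplotype_set"`: list with `sequences` (named
#'   character vector of haplotype strings), `multiplicity` and `members`.
#' @export
collapse_haplotypes <- function(aln) {
  m <- as_alignment(aln)
  seqs <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(seqs)
  reps <- seqs[first]
  grp <- match(seqs, reps)
  members <- split(rownames(m), grp)
  names(members) <- names(reps)
  out <- list(sequences = reps,
              multiplicity = vapply(members, length, 1L),
              members = members)
  class(out) <- "haplotype_set"
  out
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype set:", length(x$sequences), "haplotypes,",
      sum(x$multiplicity), "sequences\n")
  invisible(x)
}

#' Pairwise genetic distance between two aligned sequences
#'
#' Sites with a gap, `N` or other ambiguity in either sequence are excluded
#' pairwise. Models: `"p"` (raw proportion), `"JC"` (Jukes-Cantor,
#' d = -3/4 ln(1 - 4p/3)) and `"JC+G"` (gamma-rate-corrected Jukes-Cantor,
#' d = (3 alpha / 4) ((1 - 4p/3)^(-1/alpha) - 1)).
#'
#' @param s1,s2 sequences (strings or character vectors of equal length).
#' @param model one of `"p"`, `"JC"`, `"JC+G"`.
#' @param alpha gamma shape (required for `"JC+G"`; the package-wide
#'   defaults used in the analysis scripts are 0.40 for ITS rDNA and 0.11
#'   for COI).
#' @return distance as a fraction.
#' @export
pairwise_distance <- function(s1, s2, model = c("p", "JC", "JC+G"), alpha = NULL) {
  model <- match.arg(model)
  v1 <- if (length(s1) == 1L) strsplit(toupper(s1), "")[[1]] else toupper(s1)
  v2 <- if (length(s2) == 1L) strsplit(toupper(s2), "")[[1]] else toupper(s2)
  if (length(v1) != length(v2)) stop2("sequences differ in length")
  use <- v1 %in% .DNA_STATES & v2 %in% .DNA_STATES
  n <- sum(use)
  if (n == 0L) stop2("no comparable sites after pairwise deletion")
  p <- sum(v1[use] != v2[use]) / n
  switch(model,
    "p" = p,
    "JC" = {
      if (p >= 0.75) stop2("saturated distance (p >= 3/4) under the JC model")
      -0.75 * log(1 - 4 * p / 3)
    },
    "JC+G" = {
      if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0) {
        stop2("'alpha' (gamma shape > 0) is required for model JC+G")
      }
      if (p >= 0.75) stop2("saturated distance (p >= 3/4) under the JC+G model")
      (3 * alpha / 4) * ((1 - 4 * p / 3)^(-1 / alpha) - 1)
    })
}

#' All pairwise distances of an alignment or haplotype set
#'
#' @param x alignment or `"haplotype_set"`.
#' @param model,alpha passed to [pairwise_distance()].
#' @param exclude_codon_position optional codon position (1, 2 or 3, with the
#'   reading frame starting at the first column) whose sites are masked
#'   before distances are computed; used to drop saturated third positions
#'   of protein-coding markers.
#' @return symmetric distance matrix (fractions; `units` attribute set).
#' @export
alignment_distances <- function(x, model = "JC+G", alpha = NULL,
                                exclude_codon_position = NULL) {
  m <- if (inherits(x, "haplotype_set")) {
    as_alignment(x$sequences)
  } else {
    as_alignment(x)
  }
  if (!is.null(exclude_codon_position)) {
    stopifnot(exclude_codon_position %in% 1:3)
    drop <- seq(exclude_codon_position, ncol(m), by = 3L)
    m <- m[, -drop, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        D[i, j] <- D[j, i] <- pairwise_distance(m[i, ], m[j, ], model, alpha)
      }
    }
  }
  attr(D, "units") <- "fraction"
  D
}

#' Threshold-based species delimitation
#'
#' Haplotypes are grouped by single linkage: any pair closer than the
#' threshold (strict `d < theta`) falls in the same cluster, so the species
#' count is the number of connected components of the sub-threshold graph.
#' Haplotypes at or above the threshold from every member of a cluster start
#' their own. Complete linkage (every within-cluster pair below the
#' threshold) is available as an alternative rule.
#'
#' @param D symmetric distance matrix over haplotypes.
#' @param threshold divergence threshold, in the units of `D` (1% ITS and 2%
#'   COI are the conventional species-level cut-offs for these markers).
#' @param units units of both `D` and `threshold` (`"fraction"` or
#'   `"percent"`); must agree with `attr(D, "units")` when that is set.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return list with `n_species` and `clusters` (named integer vector).
#' @export
delimit_species <- function(D, threshold, units = c("fraction", "percent"),
                            linkage = c("single", "complete")) {
  units <- match.arg(units)
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop2("distance matrix must be symmetric")
  }
  du <- attr(D, "units")
  if (!is.null(du) && du != units) {
    stop2("unit mismatch: distance matrix is in ", du,
          " but threshold was declared in ", units)
  }
  if (!is.numeric(threshold) || threshold <= 0) stop2("threshold must be > 0")
  if (units == "fraction" && threshold >= 1) {
    stop2("threshold >= 1 with units = 'fraction'; did you mean percent?")
  }
  n <- nrow(D)
  labs <- rownames(D) %||% paste0("h", seq_len(n))
  if (n == 1L) {
    return(list(n_species = 1L, clusters = stats::setNames(1L, labs)))
  }
  if (linkage == "single") {
    # connected components of the strict sub-threshold graph
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (D[i, j] < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    cl <- as.integer(factor(roots, levels = unique(roots)))
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    h <- hc$height[hc$height < threshold]
    cl <- if (length(h)) {
      stats::cutree(hc, h = max(h))
    } else {
      seq_len(n)
    }
    cl <- as.integer(cl)
  }
  list(n_species = length(unique(cl)), clusters = stats::setNames(cl, labs))
}

#' Greedy similarity pruning of haplotypes
#'
#' Used to thin an alignment to (approximately) one sequence per species
#' before diversification analyses: haplotypes are processed by decreasing
#' multiplicity (ties broken by label order); one within `threshold`
#' (strict `d < threshold`) of an already retained representative joins that
#' representative's cluster, otherwise it seeds a new cluster.
#'
#' @param haps a `"haplotype_set"`.
#' @param D distance matrix over the haplotypes (fractions).
#' @param threshold divergence below which haplotypes are considered
#'   conspecific (default 0.01).
#' @return a `"haplotype_set"` of representatives; multiplicities are summed
#'   over each cluster and `members` lists all absorbed labels.
#' @export
prune_similar <- function(haps, D, threshold = 0.01) {
  stopifnot(inherits(haps, "haplotype_set"))
  D <- as.matrix(D)
  labs <- names(haps$sequences)
  if (!all(labs %in% rownames(D))) stop2("distance matrix does not cover all haplotypes")
  ord <- labs[order(-haps$multiplicity[labs], labs)]
  reps <- character(0)
  assign_to <- character(0)
  for (l in ord) {
    hit <- reps[which(D[l, reps] < threshold)[1]]
    if (length(reps) && !is.na(hit)) {
      assign_to[l] <- hit
    } else {
      reps <- c(reps, l)
      assign_to[l] <- l
    }
  }
  members <- lapply(reps, function(r) {
    unlist(haps$members[names(assign_to)[assign_to == r]], use.names = FALSE)
  })
  names(members) <- reps
  out <- list(sequences = haps$sequences[reps],
              multiplicity = vapply(members, length, 1L),
              members = members)
  class(out) <- "haplotype_set"
  out
}

#' Calibrate a per-lineage molecular rate from a divergence range
#'
#' Pairwise divergence accumulates along both lineages since their split, so
#' a pairwise distance `d` over `T` million years gives a per-lineage rate
#' of `(d/2)/T`. Endpoints are rounded to one decimal, matching how such
#' rates are conventionally reported.
#'
#' @param d_lo,d_hi pairwise divergence range endpoints, in percent.
#' @param T_mya divergence time in million years.
#' @return named numeric vector `c(rate_lo, rate_hi)` in percent per million
#'   years.
#' @export
calibrate_rate <- function(d_lo, d_hi, T_mya) {
  if (!is.numeric(T_mya) || T_mya <= 0) stop2("T_mya must be > 0")
  if (d_lo < 0 || d_hi < d_lo) stop2("need 0 <= d_lo <= d_hi")
  c(rate_lo = round((d_lo / 2) / T_mya, 1),
    rate_hi = round((d_hi / 2) / T_mya, 1))
}

#' Read / write a labeled square distance matrix as TSV
#'
#' @param path file path.
#' @param units units recorded on the returned matrix.
#' @return numeric matrix with `units` attribute.
#' @export
read_distance_matrix <- function(path, units = c("fraction", "percent")) {
  units <- match.arg(units)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  D <- as.matrix(df)
  if (nrow(D) != ncol(D) || !identical(rownames(D), colnames(D))) {
    stop2("distance matrix in ", path, " is not square with matching labels")
  }
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop2("distance matrix in ", path, " is not symmetric")
  }
  attr(D, "units") <- units
  D
}

#' @rdname read_distance_matrix
#' @param D matrix to write.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(label = rownames(D), as.data.frame(D, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
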
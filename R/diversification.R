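# Branching-time extraction, lineages-through-time series and
# maximum-likelihood diversification model fitting.
#
# Likelihoods follow the classical internode-interval decomposition for
# reconstructed ultrametric trees: between consecutive branching events
# with k lineages alive, each lineage speciates at per-lineage rate
# lambda(k), so the interval of duration g_k contributes
# ln(k lambda(k)) - k lambda(k) g_k when it ends in a branching event and
# -n lambda(n) g_n for the terminal interval. Rate-constant models
# (pure birth, constant birth-death) are contrasted with rate-variable ones
# (density-dependent linear/exponential, two-rate pure birth) via AIC.

#' Branching times of an ultrametric tree
#'
#' @param tree ultrametric `"phylo"` (leaf depths equal to relative
#'   tolerance 1e-6).
#' @return numeric vector of node ages sorted decreasingly, with attribute
#'   `n_tips`.
#' @export
branching_times <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  disc <- diff(range(depths))
  if (disc > 1e-6 * max(depths)) {
    stop2(sprintf("tree is not ultrametric: leaf depth discrepancy %.6g (max depth %.6g)",
                  disc, max(depths)))
  }
  ages <- sort(as.numeric(ape::branching.times(tree)), decreasing = TRUE)
  attr(ages, "n_tips") <- ape::Ntip(tree)
  ages
}

#' Lineages-through-time series
#'
#' @param times branching times (decreasing ages, from [branching_times()]
#'   or raw).
#' @return data frame with `age` (time before present, decreasing to 0) and
#'   `lineages` (2 at the root age up to the tip count at the present).
#' @export
ltt_series <- function(times) {
  ages <- sort(as.numeric(times), decreasing = TRUE)
  n <- length(ages) + 1L
  data.frame(age = c(ages, 0),
             lineages = c(seq.int(2L, n), n))
}

# interval decomposition shared by all likelihoods
.bt_stats <- function(times) {
  ages <- sort(as.numeric(times), decreasing = TRUE)
  if (length(ages) < 3L) stop2("need at least 4 tips (3 branching times)")
  n <- length(ages) + 1L
  b <- c(ages, 0)
  g <- b[-n] - b[-1]           # durations of intervals with k = 2..n lineages
  list(n = n, k = 2:n, g = g, ages = ages, lg = lgamma(n))
}

.fit_pure_birth <- function(st) {
  S <- sum(st$k * st$g)
  lam <- (st$n - 2) / S
  logL <- st$lg + (st$n - 2) * log(lam) - lam * S
  list(model = "pureBirth", parameters = c(lambda = lam), logL = logL, k = 1L)
}

# constant-rate birth-death likelihood (reconstructed process, conditioned
# on the root age), parameterized by net rate r = lambda - mu and
# a = mu / lambda
.bd_loglik <- function(r, a, st) {
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  ages <- st$ages
  st$lg + (st$n - 2) * log(r) + r * sum(ages[-1]) + st$n * log(1 - a) -
    2 * sum(r * ages + log(1 - a * exp(-r * ages)))
}

.fit_birth_death <- function(st) {
  lam0 <- (st$n - 2) / sum(st$k * st$g)
  best <- NULL
  for (a0 in c(0.05, 0.5)) {
    opt <- stats::optim(c(log(lam0), stats::qlogis(a0)), function(p) {
      -.bd_loglik(exp(p[1]), stats::plogis(p[2]), st)
    }, method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  r <- exp(best$par[1]); a <- stats::plogis(best$par[2])
  lam <- r / (1 - a); mu <- lam * a
  list(model = "birthDeath", parameters = c(lambda = lam, mu = mu),
       logL = -best$value, k = 2L)
}

# density-dependent (linear): lambda(k) = lambda0 (1 - k / K); for fixed K
# the rate scale has a closed-form ML, leaving a 1-D search over K
.fit_ddl <- function(st) {
  n <- st$n
  # logL(K) = lg + sum_{k=2}^{n-1} ln(k lam0 beta_k) - lam0 W, lam0 = (n-2)/W
  prof <- function(K) {
    beta <- 1 - st$k / K
    if (any(beta <= 1e-12)) return(-Inf)
    W <- sum(st$k * beta * st$g)
    lam0 <- (n - 2) / W
    ev <- seq_len(n - 2)
    # sum(log(k)) over events equals the lgamma(n) constant of the other
    # models, so no extra constant here
    sum(log(st$k[ev] * lam0 * beta[ev])) - lam0 * W
  }
  opt <- stats::optimize(function(u) -prof(n + exp(u)), c(-12, 12), tol = 1e-6)
  K <- n + exp(opt$minimum)
  beta <- 1 - st$k / K
  lam0 <- (n - 2) / sum(st$k * beta * st$g)
  list(model = "DDL", parameters = c(lambda0 = lam0, K = K),
       logL = -opt$objective, k = 2L)
}

# density-dependent (exponential): lambda(k) = lambda0 k^(-x)
.fit_ddx <- function(st) {
  n <- st$n
  prof <- function(x) {
    W <- sum(st$k^(1 - x) * st$g)
    lam0 <- (n - 2) / W
    ev <- seq_len(n - 2)
    sum(log(st$k[ev] * lam0 * st$k[ev]^(-x))) - lam0 * W
  }
  opt <- stats::optimize(function(x) -prof(x), c(-3, 5), tol = 1e-6)
  x <- opt$minimum
  lam0 <- (n - 2) / sum(st$k^(1 - x) * st$g)
  list(model = "DDX", parameters = c(lambda0 = lam0, x = x),
       logL = -opt$objective, k = 2L)
}

# two-rate pure birth with the shift time searched on the grid of observed
# branching times (ties resolved toward the earlier time)
.fit_yule2rate <- function(st) {
  n <- st$n
  kg <- st$k * st$g
  best <- NULL
  for (i in 2:(n - 2)) {
    W1 <- sum(kg[seq_len(i - 1)])
    W2 <- sum(kg[seq.int(i, n - 1)])
    e1 <- i - 1; e2 <- n - 1 - i
    if (W1 <= 0 || W2 <= 0) next
    l1 <- e1 / W1; l2 <- e2 / W2
    ll <- st$lg + e1 * log(l1) + e2 * log(l2) - l1 * W1 - l2 * W2
    if (is.null(best) || ll > best$logL + 1e-12) {
      best <- list(logL = ll, l1 = l1, l2 = l2, ts = st$ages[i])
    }
  }
  list(model = "yule2rate",
       parameters = c(lambda1 = best$l1, lambda2 = best$l2, t_shift = best$ts),
       logL = best$logL, k = 3L)
}

.RATE_CONSTANT <- c("pureBirth", "birthDeath")
.RATE_VARIABLE <- c("DDL", "DDX", "yule2rate")

#' Fit diversification models to branching times
#'
#' @param times branching times (ages, decreasing; any order accepted).
#' @param models subset of `c("pureBirth", "birthDeath", "DDL", "DDX",
#'   "yule2rate")`.
#' @return data frame with one row per model: `model`, `logL`, `k`, `AIC`
#'   and a `parameters` list-column.
#' @export
fit_models <- function(times, models = c(.RATE_CONSTANT, .RATE_VARIABLE)) {
  models <- match.arg(models, c(.RATE_CONSTANT, .RATE_VARIABLE), several.ok = TRUE)
  st <- .bt_stats(times)
  fits <- lapply(models, function(m) {
    f <- switch(m,
                pureBirth = .fit_pure_birth(st),
                birthDeath = .fit_birth_death(st),
                DDL = .fit_ddl(st),
                DDX = .fit_ddx(st),
                yule2rate = .fit_yule2rate(st))
    if (!is.finite(f$logL)) stop2("non-finite likelihood for model ", m)
    f
  })
  out <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    logL = vapply(fits, `[[`, 0, "logL"),
                    k = vapply(fits, `[[`, 0L, "k"))
  out$AIC <- 2 * out$k - 2 * out$logL
  out$parameters <- lapply(fits, `[[`, "parameters")
  out
}

# difference between best rate-constant and best rate-variable AIC;
# positive values favor temporal rate variation
.delta_aic_rc <- function(times, models) {
  fits <- fit_models(times, models)
  rc <- fits$AIC[fits$model %in% .RATE_CONSTANT]
  rv <- fits$AIC[fits$model %in% .RATE_VARIABLE]
  if (!length(rc) || !length(rv)) {
    stop2("model set must contain at least one rate-constant and one rate-variable model")
  }
  min(rc) - min(rv)
}

#' Randomization test for a diversification rate shift
#'
#' Computes the AIC difference between the best rate-constant and the best
#' rate-variable model on the observed branching times, then compares it
#' with the same statistic on trees simulated under constant-rate pure
#' birth (with the rate estimated from the data) of the same tip count. A
#' positive difference indicates that the speciation rate changed over
#' time; the add-one p-value measures how often random constant-rate trees
#' produce an equal or larger difference.
#'
#' @param times branching times of the observed tree.
#' @param n_null number of null trees (5000 by convention).
#' @param seed integer seed.
#' @param models model set (see [fit_models()]).
#' @return list of class `"rate_shift_test"` with `delta_aic`, `p_value`,
#'   `lambda` (null simulation rate), `n_null`, `n_tips` and the `null`
#'   sample.
#' @export
rate_shift_test <- function(times, n_null = 5000, seed = NULL,
                            models = c(.RATE_CONSTANT, .RATE_VARIABLE)) {
  if (!is.null(seed)) set.seed(seed)
  st <- .bt_stats(times)
  obs <- .delta_aic_rc(times, models)
  lam <- .fit_pure_birth(st)$parameters[["lambda"]]
  n <- st$n
  null <- vapply(seq_len(n_null), function(i) {
    .delta_aic_rc(simulate_branching_ages(n, function(k) lam), models)
  }, 0)
  structure(list(delta_aic = obs,
                 p_value = (1 + sum(null >= obs)) / (1 + n_null),
                 lambda = lam, n_null = n_null, n_tips = n, null = null),
            class = "rate_shift_test")
}

#' @export
print.rate_shift_test <- function(x, ...) {
  cat(sprintf("rate-shift test: delta AIC (constant - variable) = %.3f, p = %.4g (%d null trees, %d tips)\n",
              x$delta_aic, x$p_value, x$n_null, x$n_tips))
  invisible(x)
}
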
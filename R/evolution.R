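#' @importFrom ape reorder.phylo Ntip Nnode
NULL

# 2-state transition probability matrix over time t for rates q01, q10
mk_pmat <- function(q01, q10, t) {
  r <- q01 + q10
  if (r == 0) return(diag(2))
  p0 <- q10 / r; p1 <- q01 / r
  e <- exp(-r * t)
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e), 2, 2)
  # rows = from (0,1), cols = to (0,1)
}

mk_root_prior <- function(q01, q10, root_prior) {
  if (root_prior == "flat" || q01 + q10 == 0) c(0.5, 0.5)
  else c(q10, q01) / (q01 + q10)
}

check_states <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips without a trait state: ", paste(miss, collapse = ", "))
  s <- as.integer(states[tree$tip.label])
  if (!all(s %in% c(0L, 1L))) stop("states must be binary 0/1")
  s
}

# pruning pass; returns list(partials (scaled), logscale, postorder edges)
mk_partials <- function(tree, states, q01, q10) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr); nn <- n + tr$Nnode
  s <- check_states(tr, states)
  L <- matrix(1, nn, 2)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), s + 1L)] <- 1
  logscale <- numeric(nn)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- mk_pmat(q01, q10, tr$edge.length[e])
    msg <- as.vector(P %*% L[ch, ])
    m <- max(msg)
    if (m == 0) { logscale[p] <- -Inf; next }
    L[p, ] <- L[p, ] * (msg / m)
    logscale[p] <- logscale[p] + logscale[ch] + log(m)
  }
  list(tree = tr, partials = L, logscale = logscale, root = n + 1L)
}

#' Log-likelihood of binary tip states under a two-state Markov model
#'
#' Exact Felsenstein pruning over the tree: per-branch transition
#' probabilities from the closed-form 2x2 matrix exponential, partials
#' combined post-order with numerical rescaling.
#'
#' @param tree a rooted binary `phylo` with branch lengths (million years).
#' @param states named 0/1 vector over all tip labels (1 = coral-endolithic).
#' @param q01,q10 gain (0->1) and loss (1->0) rates per unit branch length.
#' @param root_prior `"stationary"` (default) or `"flat"`.
#' @return the log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q01, q10,
                      root_prior = c("stationary", "flat")) {
  root_prior <- match.arg(root_prior)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  pr <- mk_partials(tree, states, q01, q10)
  prior <- mk_root_prior(q01, q10, root_prior)
  lik <- sum(prior * pr$partials[pr$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

#' Fit the two-state Markov model of the endolithic trait
#'
#' Maximises [mk_loglik()] over the transition rates: a bounded 1-D search
#' on the log rate for the equal-rates variant, a 2-D quasi-Newton search
#' for all-rates-different.  Monomorphic tip data yield the zero-rate
#' boundary with a warning rather than failing silently.
#'
#' @param tree a rooted binary `phylo` with branch lengths.
#' @param states named 0/1 vector over tips.
#' @param variant `"equal_rates"` (default) or `"all_rates_different"`.
#' @param root_prior `"stationary"` or `"flat"`.
#' @return an object of class `mk_fit` with components `q01`, `q10`,
#'   `logLik`, `variant`, `root_prior`, `boundary`, `convergence`, plus the
#'   data.  Methods: `print`, `summary`, `coef`, `logLik`, `simulate`.
#' @export
fit_mk <- function(tree, states, variant = c("equal_rates", "all_rates_different"),
                   root_prior = c("stationary", "flat")) {
  variant <- match.arg(variant); root_prior <- match.arg(root_prior)
  s <- check_states(tree, states)
  boundary <- FALSE
  if (length(unique(s)) == 1L) {
    warning("all tips share one state; returning zero-rate boundary fit")
    fit <- list(q01 = 0, q10 = 0,
                logLik = mk_loglik(tree, states, 0, 0, root_prior),
                convergence = 0L, boundary = TRUE)
  } else if (variant == "equal_rates") {
    f <- function(lr) -mk_loglik(tree, states, exp(lr), exp(lr), root_prior)
    opt <- optimise(f, interval = c(-18, 8))
    r <- exp(opt$minimum)
    boundary <- opt$minimum < -17 || opt$minimum > 7
    fit <- list(q01 = r, q10 = r, logLik = -opt$objective,
                convergence = 0L, boundary = boundary)
  } else {
    f <- function(lr) -mk_loglik(tree, states, exp(lr[1]), exp(lr[2]),
                                 root_prior)
    start <- log(rep(max(1, sum(diff(s[order(s)]) != 0)) /
                       sum(tree$edge.length), 2))
    opt <- optim(start, f, method = "L-BFGS-B", lower = -18, upper = 8)
    boundary <- any(opt$par < -17 | opt$par > 7)
    fit <- list(q01 = exp(opt$par[1]), q10 = exp(opt$par[2]),
                logLik = -opt$value, convergence = opt$convergence,
                boundary = boundary)
  }
  if (fit$boundary && !isTRUE(fit$q01 == 0 && fit$q10 == 0))
    warning("rate estimate at search boundary")
  structure(c(fit, list(tree = tree, states = states, variant = variant,
                        root_prior = root_prior)), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<Mk fit, %s, %s root prior>\n  q01 (gain) = %.5g  q10 (loss) = %.5g  logLik = %.3f%s\n",
              x$variant, x$root_prior, x$q01, x$q10, x$logLik,
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) c(q01 = object$q01, q10 = object$q10)

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik,
            df = if (object$variant == "equal_rates") 1 else 2,
            class = "logLik")
}

#' @export
summary.mk_fit <- function(object, ...) {
  print(object)
  s <- as.integer(object$states[object$tree$tip.label])
  cat(sprintf("  %d tips: %d endolithic, %d non-endolithic; tree length %.1f\n",
              length(s), sum(s == 1), sum(s == 0),
              sum(object$tree$edge.length)))
  invisible(object)
}

#' Simulate tip states from a fitted model
#'
#' Draws a fresh character history down the fitted tree under the fitted
#' rates (unconditional on the observed tips).
#'
#' @param object an `mk_fit`.
#' @param nsim number of simulated tip-state vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of named 0/1 vectors.
#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    sim_character_history(object$tree, object$q01, object$q10,
                          root_state = rbinom(1, 1,
                            mk_root_prior(object$q01, object$q10,
                                          object$root_prior)[2]))$tip_states)
}

# marginal ancestral state probabilities by the standard two-pass
# (inside/outside) computation; returns matrix (node x 2), rows 1..Ntip are
# tip rows (degenerate at the observed state).
mk_marginals <- function(tree, states, q01, q10,
                         root_prior = c("stationary", "flat")) {
  root_prior <- match.arg(root_prior)
  pr <- mk_partials(tree, states, q01, q10)
  tr <- pr$tree; L <- pr$partials
  n <- ape::Ntip(tr); nn <- n + tr$Nnode
  prior <- mk_root_prior(q01, q10, root_prior)
  G <- matrix(0, nn, 2)
  G[pr$root, ] <- prior
  # preorder = reverse postorder edge sweep
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- mk_pmat(q01, q10, tr$edge.length[e])
    # sibling contribution at p excluding child ch
    sib <- rep(1, 2)
    sibs <- tr$edge[tr$edge[, 1] == p, 2]
    for (b in setdiff(sibs, ch)) {
      Pb <- mk_pmat(q01, q10, tr$edge.length[tr$edge[, 2] == b])
      sib <- sib * as.vector(Pb %*% L[b, ])
    }
    G[ch, ] <- as.vector((G[p, ] * sib) %*% P)
    if (max(G[ch, ]) > 0) G[ch, ] <- G[ch, ] / max(G[ch, ])
  }
  M <- L * G
  M / rowSums(M)
}

#' Draw stochastic character maps
#'
#' Samples full character histories conditional on the tip states and the
#' model: node states are drawn jointly from the pruning partials (root
#' first, then each child given its parent), and each branch history is
#' drawn from the endpoint-conditioned process by uniformization (exact; no
#' time discretisation).
#'
#' @param object an `mk_fit`, or a `phylo` (then `states`, `q01`, `q10`
#'   must be given).
#' @param n_maps number of maps (default 1000).
#' @param seed integer seed.
#' @param states,q01,q10,root_prior used when `object` is a bare tree.
#' @return an object of class `stochastic_maps`: the (postorder) tree,
#'   `node_states` (n_maps x nodes matrix of 0/1), and `events` (data.frame
#'   `map`, `edge`, `time`, `from`, `to`; `time` measured from the parent
#'   end of the branch).
#' @export
sample_maps <- function(object, n_maps = 1000L, seed = 1L, states = NULL,
                        q01 = NULL, q10 = NULL,
                        root_prior = c("stationary", "flat")) {
  if (inherits(object, "mk_fit")) {
    tree <- object$tree; states <- object$states
    q01 <- object$q01; q10 <- object$q10; root_prior <- object$root_prior
  } else {
    tree <- object; root_prior <- match.arg(root_prior)
    if (is.null(states) || is.null(q01) || is.null(q10))
      stop("states, q01 and q10 are required with a bare tree")
  }
  set.seed(seed)
  pr <- mk_partials(tree, states, q01, q10)
  tr <- pr$tree; L <- pr$partials
  n <- ape::Ntip(tr); nn <- n + tr$Nnode
  prior <- mk_root_prior(q01, q10, root_prior)

  ns <- matrix(NA_integer_, n_maps, nn)
  w <- prior * L[pr$root, ]
  ns[, pr$root] <- as.integer(runif(n_maps) < w[2] / sum(w))
  # joint node-state sampling, vectorised across maps, preorder
  edges <- rev(seq_len(nrow(tr$edge)))
  Plist <- lapply(seq_len(nrow(tr$edge)), function(e)
    mk_pmat(q01, q10, tr$edge.length[e]))
  for (e in edges) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- Plist[[e]]
    pa <- ns[, p]
    # P(child = 1 | parent state, subtree)
    w0 <- P[1, ] * L[ch, ]; w1 <- P[2, ] * L[ch, ]
    p1 <- ifelse(pa == 0L, w0[2] / (w0[1] + w0[2]), w1[2] / (w1[1] + w1[2]))
    ns[, ch] <- as.integer(runif(n_maps) < p1)
  }

  # endpoint-conditioned branch histories by uniformization
  mu <- max(q01, q10)
  ev <- list()
  if (mu > 0) {
    R <- diag(2) + matrix(c(-q01, q10, q01, -q10), 2, 2) / mu
    for (e in seq_len(nrow(tr$edge))) {
      t_e <- tr$edge.length[e]
      P <- Plist[[e]]
      a <- ns[, tr$edge[e, 1]]; b <- ns[, tr$edge[e, 2]]
      nmax <- max(10, ceiling(mu * t_e + 10 * sqrt(mu * t_e) + 10))
      Rpow <- vector("list", nmax + 1)
      Rpow[[1]] <- diag(2)
      for (k in seq_len(nmax)) Rpow[[k + 1]] <- Rpow[[k]] %*% R
      pois <- stats::dpois(0:nmax, mu * t_e)
      for (ab in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        idx <- which(a == ab[1] & b == ab[2])
        if (!length(idx)) next
        pn <- pois * vapply(Rpow, function(Rk) Rk[ab[1] + 1, ab[2] + 1],
                            numeric(1))
        if (sum(pn) == 0)
          stop("cannot condition branch ", e, " on endpoints ", ab[1], "->",
               ab[2], " at these rates")
        pn <- pn / sum(pn)
        nj <- sample.int(nmax + 1, length(idx), replace = TRUE,
                         prob = pn) - 1L
        for (ii in seq_along(idx)) {
          if (nj[ii] == 0L) next
          if (nj[ii] == 1L && ab[1] == ab[2]) next  # single virtual jump
          path <- sample_uniformized_path(ab[1], ab[2], nj[ii], R, Rpow)
          real <- which(path[-1] != path[-length(path)])
          if (!length(real)) next
          times <- sort(runif(nj[ii], 0, t_e))
          ev[[length(ev) + 1L]] <- data.frame(
            map = idx[ii], edge = e, time = times[real],
            from = path[real], to = path[real + 1])
        }
      }
    }
  } else if (any(ns[, tr$edge[, 1]] != ns[, tr$edge[, 2]])) {
    stop("endpoint states incompatible with zero rates")
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(map = integer(0), edge = integer(0), time = numeric(0),
               from = integer(0), to = integer(0))
  structure(list(tree = tr, node_states = ns, events = events,
                 n_maps = n_maps, seed = seed,
                 model = list(q01 = q01, q10 = q10, root_prior = root_prior)),
            class = "stochastic_maps")
}

# chain of uniformized-jump states from a to b in n jumps (virtual allowed)
sample_uniformized_path <- function(a, b, n, R, Rpow) {
  path <- integer(n + 1)
  path[1] <- a; path[n + 1] <- b
  cur <- a
  if (n >= 2) for (i in 2:n) {
    rem <- n + 1 - i   # jumps remaining after this one
    w <- R[cur + 1, ] * c(Rpow[[rem + 1]][1, b + 1], Rpow[[rem + 1]][2, b + 1])
    cur <- as.integer(runif(1) < w[2] / sum(w))
    path[i] <- cur
  }
  path
}

#' @export
print.stochastic_maps <- function(x, ...) {
  cat(sprintf("<stochastic maps> %d maps on %d tips; %.2f events/map (q01=%.4g, q10=%.4g)\n",
              x$n_maps, ape::Ntip(x$tree), nrow(x$events) / x$n_maps,
              x$model$q01, x$model$q10))
  invisible(x)
}

#' Count independent origins of the endolithic state
#'
#' Per map, an origin is a 0->1 transition on any branch, plus one when the
#' root itself starts in state 1.  Averaging node states over maps gives the
#' per-node probability of being endolithic.
#'
#' @param maps a [sample_maps()] result.
#' @return an `origins_summary`: `per_map` integer vector, `mean`, `median`,
#'   `q2.5`, `q97.5`, and `node_prob` (per-node probability of state 1,
#'   ordered as the map tree's nodes).
#' @export
count_origins <- function(maps) {
  n <- ape::Ntip(maps$tree)
  root <- n + 1L
  gains <- maps$events[maps$events$from == 0L & maps$events$to == 1L, ]
  per_map <- tabulate(gains$map, nbins = maps$n_maps) +
    (maps$node_states[, root] == 1L)
  structure(list(
    per_map = as.integer(per_map),
    mean = mean(per_map), median = median(per_map),
    q2.5 = unname(quantile(per_map, 0.025)),
    q97.5 = unname(quantile(per_map, 0.975)),
    node_prob = colMeans(maps$node_states)
  ), class = "origins_summary")
}

#' @export
print.origins_summary <- function(x, ...) {
  cat(sprintf("<origins of the endolithic state> mean %.2f, median %d, 95%% interval [%d, %d]\n",
              x$mean, x$median, x$q2.5, x$q97.5))
  invisible(x)
}
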
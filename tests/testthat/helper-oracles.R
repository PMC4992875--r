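# Independent oracles used across the suite.  These re-derive expected
# values by brute force and must stay independent of the package internals
# they check.

# -- full-matrix affine-gap global alignment with explicit traceback -------
# Same scoring scheme and tie conventions as the package definition
# (match +1, mismatch -1, gap open -2, extension -1; substitution preferred
# over gap-in-b over gap-in-a), implemented as a plain three-matrix DP with
# stored pointers.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18; GO <- 2; GE <- 1
  M <- A <- B <- matrix(NEG, n + 1, m + 1)
  pM <- pA <- pB <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    A[i + 1, 1] <- -(GO + GE * i)
    pA[i + 1, 1] <- if (i == 1) 1L else 2L
  }
  for (j in seq_len(m)) {
    B[1, j + 1] <- -(GO + GE * j)
    pB[1, j + 1] <- if (j == 1) 1L else 3L
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) 1 else -1
    v <- c(M[i, j], A[i, j], B[i, j])
    k <- which.max(v); M[i + 1, j + 1] <- v[k] + s; pM[i + 1, j + 1] <- k
    v <- c(M[i, j + 1] - GO - GE, A[i, j + 1] - GE, B[i, j + 1] - GO - GE)
    k <- which.max(v); A[i + 1, j + 1] <- v[k]; pA[i + 1, j + 1] <- k
    v <- c(M[i + 1, j] - GO - GE, A[i + 1, j] - GO - GE, B[i + 1, j] - GE)
    k <- which.max(v); B[i + 1, j + 1] <- v[k]; pB[i + 1, j + 1] <- k
  }
  st <- which.max(c(M[n + 1, m + 1], A[n + 1, m + 1], B[n + 1, m + 1]))
  i <- n; j <- m; ops <- integer(0); match <- integer(0)
  while (i > 0 || j > 0) {
    if (st == 1) {
      ops <- c(1L, ops); match <- c(as.integer(av[i] == bv[j]), match)
      st <- pM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (st == 2) {
      ops <- c(2L, ops); match <- c(0L, match)
      st <- pA[i + 1, j + 1]; i <- i - 1
    } else {
      ops <- c(3L, ops); match <- c(0L, match)
      st <- pB[i + 1, j + 1]; j <- j - 1
    }
  }
  L <- length(ops)
  lead <- 0; while (lead < L && ops[lead + 1] != 1L) lead <- lead + 1
  trail <- 0; while (trail < L - lead && ops[L - trail] != 1L) trail <- trail + 1
  cols <- L - lead - trail
  if (cols <= 0) return(0)
  sum(match) / cols
}

# -- exhaustive-enumeration likelihood for the two-state model -------------
oracle_loglik <- function(tree, states, q01, q10, root_prior = "stationary") {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr); nn <- n + tr$Nnode
  s <- as.integer(states[tr$tip.label])
  internals <- (n + 1):nn
  prior <- if (root_prior == "flat" || q01 + q10 == 0) c(0.5, 0.5) else
    c(q10, q01) / (q01 + q10)
  P <- lapply(tr$edge.length, function(t) {
    r <- q01 + q10
    if (r == 0) return(diag(2))
    p0 <- q10 / r; p1 <- q01 / r; e <- exp(-r * t)
    matrix(c(p0 + p1 * e, p0 * (1 - e), p1 * (1 - e), p1 + p0 * e), 2, 2)
  })
  k <- length(internals); tot <- 0
  for (assign in 0:(2^k - 1)) {
    st <- integer(nn); st[seq_len(n)] <- s
    st[internals] <- bitwAnd(bitwShiftR(assign, 0:(k - 1)), 1L)
    p <- prior[st[n + 1] + 1]
    for (e in seq_len(nrow(tr$edge)))
      p <- p * P[[e]][st[tr$edge[e, 1]] + 1, st[tr$edge[e, 2]] + 1]
    tot <- tot + p
  }
  log(tot)
}

# -- brute-force mate merging over all overlap offsets ---------------------
oracle_merge <- function(b1, b2rc, min_overlap, max_ratio) {
  n1 <- nchar(b1); n2 <- nchar(b2rc)
  v1 <- strsplit(b1, "")[[1]]; v2 <- strsplit(b2rc, "")[[1]]
  best <- NULL
  for (o in min_overlap:min(n1, n2)) {
    mism <- sum(v1[(n1 - o + 1):n1] != v2[1:o])
    r <- mism / o
    if (is.null(best) || r < best$ratio || (r == best$ratio && o > best$o))
      best <- list(o = o, ratio = r)
  }
  if (is.null(best) || best$ratio > max_ratio) return(NULL)
  paste0(substr(b1, 1, n1 - best$o), substr(b2rc, 1, n2))
}

# -- IUPAC primer-offset enumeration ---------------------------------------
oracle_match_primer <- function(bases, primer, spacer_max, max_mismatches) {
  exp_set <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pv <- strsplit(primer, "")[[1]]; L <- length(pv)
  cand <- list()
  for (s in 0:spacer_max) {
    if (nchar(bases) < s + L) next
    w <- strsplit(substr(bases, s + 1, s + L), "")[[1]]
    mm <- sum(vapply(seq_len(L), function(p) !(w[p] %in% exp_set[[pv[p]]]),
                     logical(1)))
    cand[[length(cand) + 1]] <- c(s, mm)
  }
  if (!length(cand)) return(list(matched = FALSE))
  tab <- do.call(rbind, cand)
  tab <- tab[order(tab[, 2], tab[, 1]), , drop = FALSE]
  if (tab[1, 2] > max_mismatches) return(list(matched = FALSE))
  list(matched = TRUE, spacer_len = tab[1, 1], mismatches = tab[1, 2])
}

# concrete instantiation of an IUPAC string (first expansion letter)
concretize_test <- function(x) {
  exp_set <- list(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C",
                  S = "C", W = "A", K = "G", M = "A", B = "C", D = "A",
                  H = "A", V = "A", N = "A")
  paste(vapply(strsplit(x, "")[[1]], function(c) exp_set[[c]], character(1)),
        collapse = "")
}
concretize_test_iupac <- concretize_test

int_to_phred_test <- function(q) intToUtf8(q + 33L)

# random DNA helper local to tests
rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# planted topology: four tight endolithic clades (terminal branches 0.2)
# separated by long internal branches (2.0) on a 32-tip balanced tree
planted_four_clade <- function() {
  tree <- ape::stree(32, "balanced")
  tree$edge.length <- ifelse(tree$edge[, 2] <= 32, 0.2, 2.0)
  states <- setNames(rep(0L, 32), tree$tip.label)
  for (st in c(1, 9, 17, 25)) states[paste0("t", st:(st + 3))] <- 1L
  list(tree = tree, states = states)
}
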
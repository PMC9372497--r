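# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and p.adjust / igraph): direct evaluation of the defining
# formulas, used to pin down expected values.

# Pearson r via the raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

oracle_pearson_p <- function(r, n) {
  tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-tstat, n - 2)
}

# Benjamini-Hochberg step-up by its definition: largest k with
# p_(k) <= k q / m; reject the k smallest
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

# paired and pooled two-sample t p-values from the textbook statistics
oracle_t_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  2 * stats::pt(-abs(tstat), n - 1)
}

oracle_t_unpaired <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), nx + ny - 2)
}

# graph metric oracles on a logical adjacency matrix, explicit loops
oracle_degree_centrality <- function(A, v) {
  n <- nrow(A)
  deg <- 0L
  for (j in seq_len(n)) if (j != v && A[v, j]) deg <- deg + 1L
  deg / (n - 1)
}

oracle_mean_induced_dc <- function(A, subset) {
  k <- length(subset)
  vals <- numeric(k)
  for (ii in seq_len(k)) {
    deg <- 0L
    for (jj in seq_len(k)) if (ii != jj && A[subset[ii], subset[jj]]) deg <- deg + 1L
    vals[ii] <- deg / (k - 1)
  }
  mean(vals)
}

oracle_local_clustering <- function(A, v) {
  nb <- which(A[v, ])
  k <- length(nb)
  if (k < 2L) return(0)
  links <- 0L
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
    if (A[nb[a], nb[b]]) links <- links + 1L
  2 * links / (k * (k - 1))
}

oracle_mean_clustering <- function(A) {
  mean(vapply(seq_len(nrow(A)), function(v) oracle_local_clustering(A, v),
              numeric(1)))
}

# all-pairs shortest paths by BFS
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0L
    seen <- logical(n); seen[s] <- TRUE
    while (length(frontier) > 0L) {
      depth <- depth + 1L
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ]))
        if (!seen[w]) { seen[w] <- TRUE; D[s, w] <- depth; nxt <- c(nxt, w) }
      frontier <- nxt
    }
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D[row(D) != col(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# independent re-evaluation of one candidate's discriminability p-value
# from the raw stack arrays: own BH, own induced degrees, own paired t
oracle_score <- function(stack, subsetKeys, q = 0.05) {
  keys <- roiKeys(stack)
  idx <- match(subsetKeys, keys)
  nC <- length(conditions(stack)); nS <- length(subjects(stack))
  vals <- matrix(NA_real_, nC, nS)
  for (ci in seq_len(nC)) for (si in seq_len(nS)) {
    r <- connMatrix(stack, ci, si)
    p <- pvalMatrix(stack, ci, si)
    ut <- which(upper.tri(p))
    rej <- oracle_bh(p[ut], q)
    A <- matrix(FALSE, nrow(p), ncol(p))
    A[ut[rej]] <- TRUE
    A <- A | t(A)
    A <- A & (r > 0) & t(r > 0)
    diag(A) <- FALSE
    vals[ci, si] <- if (length(idx) == 1L) {
      oracle_degree_centrality(A, idx)
    } else oracle_mean_induced_dc(A, idx)
  }
  stopifnot(nC == 2L)
  d <- vals[1L, ] - vals[2L, ]
  if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
  oracle_t_paired(vals[1L, ], vals[2L, ])
}

# exhaustive prefix evaluation of the fusion search
oracle_prefix_trace <- function(stack, mainKeys, suppKeys, q = 0.05) {
  vapply(0L:length(suppKeys), function(i)
    oracle_score(stack, c(mainKeys, head(suppKeys, i)), q = q), numeric(1))
}
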
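# Independent brute-force oracles used across the suites. These deliberately
# share no code with the implementation paths they check.

# Node-wise evaluation of the degree-normalized reference convolution,
# written directly from the update rule with its own neighbor bookkeeping.
oracle_gcn_ref <- function(X, edges, Theta) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(Theta))
  for (i in seq_len(n)) {
    kids <- edges[1, edges[2, ] == i]
    di <- 1 + length(kids)
    acc <- numeric(ncol(X))
    for (j in c(kids, i)) {
      dj <- 1 + sum(edges[2, ] == j)
      acc <- acc + X[j, ] / sqrt(dj * di)
    }
    out[i, ] <- t(Theta) %*% acc
  }
  out
}

# Loop-based evaluation of the attention convolution: per-node scores,
# softmax over children + self, weighted combination; independent of both
# the compiled kernel and gat_attention().
oracle_gat <- function(X, edges, Ws, Wt, a, bias, slope = 0.2) {
  n <- nrow(X)
  out <- matrix(0, n, nrow(Ws))
  lrelu <- function(u) ifelse(u > 0, u, slope * u)
  for (i in seq_len(n)) {
    kids <- edges[1, edges[2, ] == i]
    si <- Ws %*% X[i, ]
    scores <- vapply(c(i, kids), function(j) {
      sum(a * lrelu(si + Wt %*% X[j, ]))
    }, 0)
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    val <- w[1] * si
    if (length(kids)) {
      for (m in seq_along(kids)) val <- val + w[m + 1] * (Wt %*% X[kids[m], ])
    }
    out[i, ] <- val + bias
  }
  out
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Average precision by explicit iteration over every distinct threshold.
oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  P <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# A random tree in canonical layout plus its edge index, for network tests.
random_tree_graph <- function(n, time_scale = 100) {
  tr <- random_coalescent_tree(n, interval = c(0, 1), time_scale = time_scale)
  list(tree = tr, edges = build_edge_index(tr), N = 2L * n - 1L)
}

# Minimal hand-built featurized record (random features over a random
# topology) for forward/backward contract tests that do not need real data.
fake_feature <- function(n_trees, n, k = 1L, label = 0) {
  N <- 2L * n - 1L
  Fd <- 2L + k + 1L
  es <- lapply(seq_len(n_trees), function(t) {
    build_edge_index(random_coalescent_tree(n)) + (t - 1L) * N
  })
  list(x = matrix(rnorm(n_trees * N * Fd), ncol = Fd),
       edges = do.call(cbind, es),
       tree_summ = matrix(rnorm(n_trees * 12), ncol = 12),
       global = rnorm(37), n_trees = n_trees, n_nodes = N, F = Fd, k = k,
       label = label)
}

# Fitted normalization statistics with chosen constants, for feature tests.
manual_stats <- function(logage_mean = 0, logage_sd = 1, mut_mean = 0,
                         mut_sd = 1) {
  structure(list(
    logage = c(mean = logage_mean, sd = logage_sd),
    mut = c(mean = mut_mean, sd = mut_sd),
    tree = list(mean = rep(0, 12), sd = rep(1, 12)),
    global = list(mean = rep(0, 37), sd = rep(1, 37)),
    target = NULL, schema_version = 1L, degenerate = character(0)
  ), class = "normalization_stats")
}

require_sim_backend <- function() {
  # The msprime backend is part of the supported environment; if it is
  # genuinely absent the simulation tests should fail loudly, so this is an
  # assertion rather than a skip.
  expect_true(sim_backend_available())
}
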
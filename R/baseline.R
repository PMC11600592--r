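# The alignment-CNN comparison path: genotype-matrix padding, seriation row
# sorting under cosine distance, cross-population row matching by optimal
# assignment, and the exact learnable-parameter inventory of the
# ResNet34-shape baseline network.

#' Pad or crop a genotype matrix to a fixed polymorphism count
#'
#' Columns beyond `W` are dropped (left-aligned crop: the first `W` columns
#' are kept); narrower matrices are right-padded with zeros. Idempotent at
#' fixed `W`.
#'
#' @param m binary matrix (rows = haploid individuals).
#' @param W target column count.
#' @return matrix with exactly `W` columns.
#' @export
pad_or_crop <- function(m, W) {
  stopifnot(W >= 1)
  if (ncol(m) >= W) return(m[, seq_len(W), drop = FALSE])
  cbind(m, matrix(0, nrow(m), W - ncol(m)))
}

#' Pairwise cosine distance between matrix rows
#'
#' `1 - x.y / (|x| |y|)`; any pair involving an all-zero row (whose cosine
#' is mathematically undefined) is assigned distance 1, deterministically.
#'
#' @param a matrix of row vectors.
#' @param b optional second matrix (defaults to `a`).
#' @return `nrow(a) x nrow(b)` distance matrix.
#' @export
cosine_distance <- function(a, b = a) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  d <- 1 - (a %*% t(b)) / outer(na, nb)
  d[outer(na == 0, nb == 0, "|")] <- 1
  d
}

path_cost <- function(D, ord) {
  n <- length(ord)
  if (n < 2L) return(0)
  sum(D[cbind(ord[-n], ord[-1])])
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

seriate_exact <- function(D) {
  n <- nrow(D)
  P <- all_perms(n)
  cost <- numeric(nrow(P))
  for (kk in seq_len(n - 1L)) cost <- cost + D[cbind(P[, kk], P[, kk + 1L])]
  unname(P[which.min(cost), ])  # which.min takes the first (lexicographically
                                # smallest) optimum: 2 rows tie-break to identity
}

nearest_neighbor_path <- function(D, start) {
  n <- nrow(D)
  ord <- integer(n)
  ord[1] <- start
  left <- setdiff(seq_len(n), start)
  for (i in 2L:n) {
    nxt <- left[which.min(D[ord[i - 1L], left])]
    ord[i] <- nxt
    left <- setdiff(left, nxt)
  }
  ord
}

two_opt <- function(D, ord) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        old <- (if (i > 1L) D[ord[i - 1L], ord[i]] else 0) +
          (if (j < n) D[ord[j], ord[j + 1L]] else 0)
        new <- (if (i > 1L) D[ord[i - 1L], ord[j]] else 0) +
          (if (j < n) D[ord[i], ord[j + 1L]] else 0)
        if (new < old - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Seriation row ordering of a genotype matrix
#'
#' Finds a row permutation approximately minimizing the total cosine
#' distance between consecutive rows (an open path, not a cycle), the
#' canonical input arrangement for the alignment CNN. Up to 8 rows the exact
#' optimum is found by exhaustive search; larger inputs use nearest-neighbor
#' construction from every start followed by 2-opt refinement (which never
#' increases the path cost).
#'
#' @param m binary matrix with at least 2 rows (or a [genotype_matrix]).
#' @param method `"auto"` (exact for `<= 8` rows), `"exact"`, or
#'   `"heuristic"`.
#' @return integer row permutation.
#' @export
seriate_rows <- function(m, method = c("auto", "exact", "heuristic")) {
  method <- match.arg(method)
  if (inherits(m, "genotype_matrix")) m <- m$alleles
  n <- nrow(m)
  if (n == 0L) stop_tsgcn("seriate_rows: empty matrix")
  if (n == 1L) return(1L)
  D <- cosine_distance(m)
  if (method == "exact" || (method == "auto" && n <= 8L)) {
    return(seriate_exact(D))
  }
  best <- NULL
  best_cost <- Inf
  for (s in seq_len(n)) {
    ord <- two_opt(D, nearest_neighbor_path(D, s))
    cst <- path_cost(D, ord)
    if (cst < best_cost - 1e-12) {
      best <- ord
      best_cost <- cst
    }
  }
  best
}

# Exact linear-sum assignment (Hungarian / shortest augmenting path) on a
# square cost matrix; returns for each row the assigned column.
hungarian_assign <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  u <- numeric(n + 1L)          # row potentials, slot n+1 = virtual row 0
  v <- numeric(n + 1L)          # column potentials, slot 1 = virtual column
  p <- integer(n + 1L)          # p[j] = row matched to column j-1 (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- C[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Align two population blocks by seriation plus optimal assignment
#'
#' The first block's rows are seriated; the second block's rows are then
#' matched one-to-one to the (seriated) first-block rows by an exact
#' linear-sum assignment minimizing total cosine distance, and reordered so
#' matched rows sit at the same index. With unequal row counts, `min(n1,
#' n2)` rows are matched and any remaining second-block rows are appended in
#' seriated order.
#'
#' @param blocks list of exactly two matrices with equal column counts.
#' @return list with `blocks` (the two aligned matrices), `order1`
#'   (seriation permutation of block 1), `assignment` (for each row of the
#'   aligned block 1, the original block-2 row index matched to it, `NA` if
#'   unmatched), and `cost` (total matched cosine distance).
#' @export
match_populations <- function(blocks) {
  if (!is.list(blocks) || length(blocks) != 2L) {
    stop_tsgcn("match_populations: exactly 2 population blocks required (use seriate_rows for one)")
  }
  b1 <- blocks[[1]]; b2 <- blocks[[2]]
  if (ncol(b1) != ncol(b2)) {
    stop_tsgcn("match_populations: blocks have %d vs %d columns", ncol(b1), ncol(b2))
  }
  ord1 <- seriate_rows(b1)
  b1s <- b1[ord1, , drop = FALSE]
  m1 <- nrow(b1s); m2 <- nrow(b2)
  n <- max(m1, m2)
  C <- matrix(0, n, n)
  C[seq_len(m1), seq_len(m2)] <- cosine_distance(b1s, b2)
  asg <- hungarian_assign(C)           # asg[i] = column (block-2 row) for row i
  assignment <- rep(NA_integer_, m1)
  for (i in seq_len(m1)) if (asg[i] <= m2) assignment[i] <- asg[i]
  matched2 <- assignment[!is.na(assignment)]
  cost <- sum(C[cbind(which(!is.na(assignment)), matched2)])
  rows2 <- lapply(assignment, function(j) if (is.na(j)) NULL else b2[j, ])
  aligned2 <- do.call(rbind, rows2[!vapply(rows2, is.null, TRUE)])
  leftover <- setdiff(seq_len(m2), matched2)
  if (length(leftover)) {
    lb <- b2[leftover, , drop = FALSE]
    lord <- if (nrow(lb) > 1L) seriate_rows(lb) else 1L
    aligned2 <- rbind(aligned2, lb[lord, , drop = FALSE])
  }
  list(blocks = list(b1s, aligned2), order1 = ord1, assignment = assignment,
       cost = cost)
}

#' Baseline network configuration
#'
#' @param architecture only `"resnet34-shape"` is defined.
#' @param channels input channels (= populations of the padded alignment).
#' @param M output size.
#' @return a `baseline_net_config` list.
#' @export
baseline_net_config <- function(architecture = "resnet34-shape",
                                channels = 1L, M = 5L) {
  stopifnot(architecture == "resnet34-shape", channels >= 1L, M >= 1L)
  structure(list(architecture = architecture, channels = as.integer(channels),
                 M = as.integer(M)),
            class = "baseline_net_config")
}

#' Learnable-parameter inventory of the ResNet34-shape baseline
#'
#' Enumerates every layer of the standard ResNet34 shape -- 7x7 stem
#' convolution, four stages of basic residual blocks (3/4/6/3 blocks at
#' widths 64/128/256/512, each block two 3x3 convolutions with batch
#' normalization, 1x1 projection shortcuts where the width changes), global
#' pooling and the final affine classifier -- and sums their learnable
#' scalars (convolutions carry no bias; each batch normalization contributes
#' a scale and a shift per channel).
#'
#' @param config a [baseline_net_config()].
#' @return total parameter count (numeric scalar) with the per-layer
#'   itemization attached as attribute `"layers"` (a data frame).
#' @export
baseline_param_count <- function(config = baseline_net_config()) {
  layers <- list()
  add <- function(name, count) {
    layers[[length(layers) + 1L]] <<- data.frame(layer = name, count = count,
                                                 stringsAsFactors = FALSE)
  }
  conv <- function(kk, cin, cout) kk * kk * cin * cout
  bn <- function(c) 2L * c
  add("conv1 7x7", conv(7L, config$channels, 64L))
  add("bn1", bn(64L))
  widths <- c(64L, 128L, 256L, 512L)
  blocks <- c(3L, 4L, 6L, 3L)
  cin <- 64L
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in seq_len(blocks[s])) {
      pre <- sprintf("layer%d.block%d", s, b)
      c_in_block <- if (b == 1L) cin else w
      add(paste0(pre, ".conv1 3x3"), conv(3L, c_in_block, w))
      add(paste0(pre, ".bn1"), bn(w))
      add(paste0(pre, ".conv2 3x3"), conv(3L, w, w))
      add(paste0(pre, ".bn2"), bn(w))
      if (b == 1L && c_in_block != w) {
        add(paste0(pre, ".downsample conv 1x1"), conv(1L, c_in_block, w))
        add(paste0(pre, ".downsample bn"), bn(w))
      }
    }
    cin <- w
  }
  add("fc", 512L * config$M + config$M)
  df <- do.call(rbind, layers)
  total <- sum(df$count)
  attr(total, "layers") <- df
  total
}
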
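# The learnable architecture: node embedding with skip concatenations, a
# block of attention graph convolutions with additive skips + layer
# normalization + ReLU, a per-tree recurrent unit over the canonical node
# ordering, concatenation of the 12-dim tree summary, a per-sequence
# recurrent unit over the (padded) sequence of trees, concatenation of the
# affine-embedded 37-dim sequence summary, and a fully connected head with
# batch normalization. Forward and backward passes are written explicitly
# (there is no autograd here); gradients are verified against finite
# differences in the test suite.

#' Architecture configuration
#'
#' @param k number of populations (node feature width is `F = 2 + k + 1`).
#' @param M output size: class count for classification, target dimension for
#'   regression.
#' @param embed_dim node embedding width (default 26).
#' @param n_conv number of attention convolution layers (default 6); each has
#'   width `embed_dim + F` preserved by the additive skip.
#' @param h_tree per-tree recurrent hidden size (default 256).
#' @param h_seq per-sequence recurrent hidden size (default 256).
#' @param head_dim width of the two fully connected head layers (default 256).
#' @param cap tree-count cap used at featurization time (default 128).
#' @param use_graph_conv,use_tree_summary,use_global_summary ablation
#'   switches. With `use_graph_conv = FALSE` the embedding + convolution
#'   block is bypassed and raw node features flow into the per-tree
#'   recurrence (topology is then ignored entirely).
#' @param leaky_slope LeakyReLU negative slope inside the attention (0.2).
#' @return an object of class `gcn_config`.
#' @export
gcn_config <- function(k = 1L, M = 1L, embed_dim = 26L, n_conv = 6L,
                       h_tree = 256L, h_seq = 256L, head_dim = 256L,
                       cap = 128L, use_graph_conv = TRUE,
                       use_tree_summary = TRUE, use_global_summary = TRUE,
                       leaky_slope = 0.2) {
  Fdim <- 2L + k + 1L
  d <- embed_dim + Fdim
  stopifnot(embed_dim >= 1L, n_conv >= 0L, h_tree >= 1L, h_seq >= 1L,
            head_dim >= 1L, M >= 1L, cap >= 1L)
  structure(list(
    k = as.integer(k), F = Fdim, M = as.integer(M),
    embed_dim = as.integer(embed_dim), n_conv = as.integer(n_conv),
    conv_dim = as.integer(d),
    h_tree = as.integer(h_tree), h_seq = as.integer(h_seq),
    head_dim = as.integer(head_dim), cap = as.integer(cap),
    use_graph_conv = isTRUE(use_graph_conv),
    use_tree_summary = isTRUE(use_tree_summary),
    use_global_summary = isTRUE(use_global_summary),
    leaky_slope = leaky_slope,
    tree_in = if (isTRUE(use_graph_conv)) as.integer(d + Fdim) else Fdim,
    seq_in = as.integer(h_tree + if (isTRUE(use_tree_summary)) 12L else 0L),
    head_in = as.integer(h_seq + if (isTRUE(use_global_summary)) 37L else 0L)
  ), class = "gcn_config")
}

unif_init <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

orthogonal_init <- function(n) {
  qrres <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qrres)
  q * sign(diag(qr.R(qrres)))[col(q)]
}

gru_params <- function(input, hidden) {
  list(W_ih = unif_init(3L * hidden, input, input),
       W_hh = do.call(rbind, replicate(3, orthogonal_init(hidden), simplify = FALSE)),
       b_ih = numeric(3L * hidden),
       b_hh = numeric(3L * hidden))
}

#' Instantiate a model from a configuration
#'
#' Affine and convolution weights use uniform fan-in initialization,
#' recurrent (hidden-to-hidden) weights are orthogonal, biases start at zero,
#' and normalization layers start at identity. Batch-normalization running
#' statistics live in `$state`.
#'
#' @param config a [gcn_config()].
#' @param seed integer seed for the initialization draw.
#' @return an object of class `gcn_model` with elements `config`, `params`
#'   (flat named list of arrays) and `state`.
#' @export
gcn_model <- function(config, seed = 1L) {
  with_seed(seed, {
    p <- list()
    d <- config$conv_dim
    if (config$use_graph_conv) {
      p[["embed.W"]] <- unif_init(config$embed_dim, config$F, config$F)
      p[["embed.b"]] <- numeric(config$embed_dim)
      for (l in seq_len(config$n_conv)) {
        pre <- sprintf("conv%d.", l)
        p[[paste0(pre, "Ws")]] <- unif_init(d, d, d)
        p[[paste0(pre, "Wt")]] <- unif_init(d, d, d)
        p[[paste0(pre, "a")]] <- runif(d, -1, 1) / sqrt(d)
        p[[paste0(pre, "bias")]] <- numeric(d)
        p[[paste0(pre, "ln_gamma")]] <- rep(1, d)
        p[[paste0(pre, "ln_beta")]] <- numeric(d)
      }
    }
    gt <- gru_params(config$tree_in, config$h_tree)
    for (nm in names(gt)) p[[paste0("gru_tree.", nm)]] <- gt[[nm]]
    gs <- gru_params(config$seq_in, config$h_seq)
    for (nm in names(gs)) p[[paste0("gru_seq.", nm)]] <- gs[[nm]]
    if (config$use_global_summary) {
      p[["gemb.W"]] <- unif_init(37L, 37L, 37L)
      p[["gemb.b"]] <- numeric(37L)
    }
    p[["fc1.W"]] <- unif_init(config$head_dim, config$head_in, config$head_in)
    p[["fc1.b"]] <- numeric(config$head_dim)
    p[["bn1.gamma"]] <- rep(1, config$head_dim)
    p[["bn1.beta"]] <- numeric(config$head_dim)
    p[["fc2.W"]] <- unif_init(config$head_dim, config$head_dim, config$head_dim)
    p[["fc2.b"]] <- numeric(config$head_dim)
    p[["bn2.gamma"]] <- rep(1, config$head_dim)
    p[["bn2.beta"]] <- numeric(config$head_dim)
    p[["out.W"]] <- unif_init(config$M, config$head_dim, config$head_dim)
    p[["out.b"]] <- numeric(config$M)
    state <- list(bn1.mean = numeric(config$head_dim),
                  bn1.var = rep(1, config$head_dim),
                  bn2.mean = numeric(config$head_dim),
                  bn2.var = rep(1, config$head_dim))
    structure(list(config = config, params = p, state = state, seed = seed),
              class = "gcn_model")
  })
}

#' @export
print.gcn_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf("<gcn_model> F = %d, M = %d, %d conv layer(s), hidden %d/%d, %s parameters\n",
              x$config$F, x$config$M, x$config$n_conv, x$config$h_tree,
              x$config$h_seq, format(attr(cp, "total"), big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters
#'
#' Itemized per layer; the total is attached as attribute `"total"`.
#' Batch-normalization running statistics are state, not parameters, and are
#' not counted.
#'
#' @param model a [gcn_model()].
#' @return data frame with columns `layer` and `count`; attribute `total`.
#' @export
count_parameters <- function(model) {
  cnt <- vapply(model$params, length, 0L)
  out <- data.frame(layer = names(cnt), count = as.integer(cnt),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$count)
  out
}

## ---- small layers (explicit forward/backward) ------------------------------

linear_fw <- function(x, W, b) sweep(x %*% t(W), 2, b, "+")
linear_bw <- function(x, W, dy) {
  list(dx = dy %*% W, dW = crossprod(dy, x), db = colSums(dy))
}

# Layer normalization (per-row over features) runs in compiled code; the
# forward result carries an external-pointer cache for the backward call.
layernorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  .ln_forward_ptr(x, gamma, beta, eps)
}
layernorm_bw <- function(cache, gamma, dy) {
  .ln_backward_ptr(cache$cache, gamma, dy)
}

batchnorm_fw <- function(x, gamma, beta, run_mean, run_var, train,
                         momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(x, 2, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv = inv, train = train,
       run_mean = run_mean, run_var = run_var)
}
batchnorm_bw <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  B <- nrow(xhat)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- if (cache$train) {
    sweep(dxhat - rep(colMeans(dxhat), each = B) -
            xhat * rep(colMeans(dxhat * xhat), each = B), 2, cache$inv, "*")
  } else {
    sweep(dxhat, 2, cache$inv, "*")
  }
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

## ---- batch assembly --------------------------------------------------------

#' Assemble featurized sequences into a network batch
#'
#' Concatenates node features and (offset) edge indices across sequences,
#' stacks tree and global summaries, and records per-sequence tree counts so
#' the per-sequence recurrence can be padded to the batch maximum while the
#' true final hidden state of every sequence is the one that is read out.
#'
#' @param features list of [featurize_record()] outputs (all with the same
#'   `F` and nodes-per-tree).
#' @return a `gcn_batch` list.
#' @export
assemble_batch <- function(features) {
  B <- length(features)
  n_trees <- as.integer(vapply(features, function(f) as.numeric(f$n_trees), 0))
  N <- features[[1]]$n_nodes
  node_offsets <- c(0L, cumsum(n_trees * N))
  edges <- do.call(cbind, lapply(seq_len(B), function(b) {
    features[[b]]$edges + node_offsets[b]
  }))
  structure(list(
    x = do.call(rbind, lapply(features, `[[`, "x")),
    edges = edges,
    tree_summ = do.call(rbind, lapply(features, `[[`, "tree_summ")),
    global = do.call(rbind, lapply(features, `[[`, "global")),
    n_trees = n_trees,
    n_nodes = N,
    B = B,
    labels = lapply(features, `[[`, "label")
  ), class = "gcn_batch")
}

# Index matrix mapping (sequence, position) -> global tree row, 0 when padded.
tree_index_matrix <- function(n_trees) {
  B <- length(n_trees)
  Tp <- max(n_trees)
  idx <- matrix(0L, B, Tp)
  off <- c(0L, cumsum(n_trees))
  for (b in seq_len(B)) idx[b, seq_len(n_trees[b])] <- off[b] + seq_len(n_trees[b])
  idx
}

## ---- forward / backward ----------------------------------------------------

#' Forward pass
#'
#' Runs a batch through the full pipeline and returns the `B x M` prediction
#' matrix (classification outputs are logits; apply softmax for posterior
#' probabilities). In training mode the head's batch normalization uses batch
#' statistics and the returned `$state` carries updated running statistics;
#' in evaluation mode running statistics are used, making the output of a
#' sequence independent of what it is batched with and of sequence padding.
#'
#' @param model a [gcn_model()].
#' @param batch an [assemble_batch()] result.
#' @param train logical; training or evaluation mode.
#' @param keep_cache keep intermediate activations for [gcn_backward()].
#' @return list with `out` (`B x M`), `state`, and (if requested) `cache`.
#' @export
gcn_forward <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  cf <- model$config
  p <- model$params
  cache <- list()
  x <- batch$x
  N <- batch$n_nodes
  if (cf$use_graph_conv) {
    e0 <- linear_fw(x, p[["embed.W"]], p[["embed.b"]])
    h <- cbind(e0, x)
    child0 <- as.integer(batch$edges[1, ]) - 1L
    parent0 <- as.integer(batch$edges[2, ]) - 1L
    conv_caches <- vector("list", cf$n_conv)
    for (l in seq_len(cf$n_conv)) {
      pre <- sprintf("conv%d.", l)
      g <- .gat_forward_cpp(h, child0, parent0, p[[paste0(pre, "Ws")]],
                            p[[paste0(pre, "Wt")]], p[[paste0(pre, "a")]],
                            p[[paste0(pre, "bias")]], cf$leaky_slope)
      s <- g$out + h
      ln <- layernorm_fw(s, p[[paste0(pre, "ln_gamma")]], p[[paste0(pre, "ln_beta")]])
      hn <- ln$y * (ln$y > 0)
      if (keep_cache) {
        conv_caches[[l]] <- list(gat = g, ln = ln, relu_in = ln$y)
      }
      h <- hn
    }
    hcat <- cbind(h, x)
    if (keep_cache) cache$conv <- conv_caches
  } else {
    hcat <- x
  }
  ## per-tree recurrence over the canonical node ordering: tree b's node t
  ## sits at row (b-1)*N + t of hcat
  n_tr <- nrow(hcat) %/% N
  node_idx <- matrix(seq_len(n_tr * N), nrow = n_tr, ncol = N, byrow = TRUE)
  g1 <- .gru_forward_ptr(hcat, node_idx, matrix(0, n_tr, cf$h_tree),
                         p[["gru_tree.W_ih"]], p[["gru_tree.W_hh"]],
                         p[["gru_tree.b_ih"]], p[["gru_tree.b_hh"]],
                         rep(N, n_tr))
  tree_vec <- g1$out
  tv <- if (cf$use_tree_summary) cbind(tree_vec, batch$tree_summ) else tree_vec
  ## per-sequence recurrence over the padded tree axis; each sequence's
  ## output is the hidden state at its true length
  idx <- tree_index_matrix(batch$n_trees)
  B <- batch$B
  g2 <- .gru_forward_ptr(tv, idx, matrix(0, B, cf$h_seq),
                         p[["gru_seq.W_ih"]], p[["gru_seq.W_hh"]],
                         p[["gru_seq.b_ih"]], p[["gru_seq.b_hh"]],
                         batch$n_trees)
  h_seq <- g2$out
  if (cf$use_global_summary) {
    ge <- linear_fw(batch$global, p[["gemb.W"]], p[["gemb.b"]])
    z <- cbind(h_seq, ge)
  } else {
    z <- h_seq
  }
  st <- model$state
  z1 <- linear_fw(z, p[["fc1.W"]], p[["fc1.b"]])
  bn1 <- batchnorm_fw(z1, p[["bn1.gamma"]], p[["bn1.beta"]],
                      st$bn1.mean, st$bn1.var, train)
  r1 <- bn1$y * (bn1$y > 0)
  z2 <- linear_fw(r1, p[["fc2.W"]], p[["fc2.b"]])
  bn2 <- batchnorm_fw(z2, p[["bn2.gamma"]], p[["bn2.beta"]],
                      st$bn2.mean, st$bn2.var, train)
  r2 <- bn2$y * (bn2$y > 0)
  out <- linear_fw(r2, p[["out.W"]], p[["out.b"]])
  state <- list(bn1.mean = bn1$run_mean, bn1.var = bn1$run_var,
                bn2.mean = bn2$run_mean, bn2.var = bn2$run_var)
  if (keep_cache) {
    cache <- c(cache, list(
      x = x, g1 = g1, g2 = g2, h_seq = h_seq, z = z,
      z1 = z1, bn1 = bn1, r1 = r1, z2 = z2, bn2 = bn2, r2 = r2,
      n_trees = batch$n_trees, N = N, global_raw = batch$global))
  }
  list(out = out, state = state, cache = if (keep_cache) cache else NULL)
}

#' Backward pass
#'
#' Propagates the gradient of a scalar loss with respect to the predictions
#' back through the whole pipeline.
#'
#' @param model a [gcn_model()].
#' @param cache the cache from `gcn_forward(..., keep_cache = TRUE)`.
#' @param dout `B x M` gradient of the loss w.r.t. the predictions.
#' @return flat named list of gradients matching `model$params`.
#' @export
gcn_backward <- function(model, cache, dout) {
  cf <- model$config
  p <- model$params
  g <- list()
  lb <- linear_bw(cache$r2, p[["out.W"]], dout)
  g[["out.W"]] <- lb$dW; g[["out.b"]] <- lb$db
  dr2 <- lb$dx * (cache$bn2$y > 0)
  bb <- batchnorm_bw(cache$bn2, p[["bn2.gamma"]], dr2)
  g[["bn2.gamma"]] <- bb$dgamma; g[["bn2.beta"]] <- bb$dbeta
  lb <- linear_bw(cache$r1, p[["fc2.W"]], bb$dx)
  g[["fc2.W"]] <- lb$dW; g[["fc2.b"]] <- lb$db
  dr1 <- lb$dx * (cache$bn1$y > 0)
  bb <- batchnorm_bw(cache$bn1, p[["bn1.gamma"]], dr1)
  g[["bn1.gamma"]] <- bb$dgamma; g[["bn1.beta"]] <- bb$dbeta
  lb <- linear_bw(cache$z, p[["fc1.W"]], bb$dx)
  g[["fc1.W"]] <- lb$dW; g[["fc1.b"]] <- lb$db
  dz <- lb$dx
  if (cf$use_global_summary) {
    dh_seq <- dz[, seq_len(cf$h_seq), drop = FALSE]
    dge <- dz[, cf$h_seq + seq_len(37L), drop = FALSE]
  } else {
    dh_seq <- dz
  }
  ## sequence recurrence (the kernel scatters the gradient back to the
  ## per-tree input vectors, padded positions contributing nothing)
  gb2 <- .gru_backward_ptr(cache$g2$cache, p[["gru_seq.W_ih"]],
                           p[["gru_seq.W_hh"]], dh_seq)
  g[["gru_seq.W_ih"]] <- gb2$dW_ih; g[["gru_seq.W_hh"]] <- gb2$dW_hh
  g[["gru_seq.b_ih"]] <- as.numeric(gb2$db_ih); g[["gru_seq.b_hh"]] <- as.numeric(gb2$db_hh)
  dtree_vec <- gb2$dXsrc[, seq_len(cf$h_tree), drop = FALSE]
  ## per-tree recurrence
  gb1 <- .gru_backward_ptr(cache$g1$cache, p[["gru_tree.W_ih"]],
                           p[["gru_tree.W_hh"]], dtree_vec)
  g[["gru_tree.W_ih"]] <- gb1$dW_ih; g[["gru_tree.W_hh"]] <- gb1$dW_hh
  g[["gru_tree.b_ih"]] <- as.numeric(gb1$db_ih); g[["gru_tree.b_hh"]] <- as.numeric(gb1$db_hh)
  dhcat <- gb1$dXsrc
  if (cf$use_graph_conv) {
    d <- cf$conv_dim
    dh <- dhcat[, seq_len(d), drop = FALSE]
    for (l in rev(seq_len(cf$n_conv))) {
      pre <- sprintf("conv%d.", l)
      cc <- cache$conv[[l]]
      dln_y <- dh * (cc$relu_in > 0)
      lnb <- layernorm_bw(cc$ln, p[[paste0(pre, "ln_gamma")]], dln_y)
      g[[paste0(pre, "ln_gamma")]] <- as.numeric(lnb$dgamma)
      g[[paste0(pre, "ln_beta")]] <- as.numeric(lnb$dbeta)
      ds <- lnb$dx
      gatb <- .gat_backward_ptr(cc$gat$cache, p[[paste0(pre, "Ws")]],
                                p[[paste0(pre, "Wt")]], p[[paste0(pre, "a")]],
                                ds, cf$leaky_slope)
      g[[paste0(pre, "Ws")]] <- gatb$dWs
      g[[paste0(pre, "Wt")]] <- gatb$dWt
      g[[paste0(pre, "a")]] <- as.numeric(gatb$da)
      g[[paste0(pre, "bias")]] <- as.numeric(gatb$dbias)
      dh <- gatb$dX + ds  # additive skip
    }
    ## dh is now the gradient w.r.t. cbind(embed(x), x)
    de0 <- dh[, seq_len(cf$embed_dim), drop = FALSE]
    lb <- linear_bw(cache$x, p[["embed.W"]], de0)
    g[["embed.W"]] <- lb$dW; g[["embed.b"]] <- lb$db
  }
  if (cf$use_global_summary) {
    lb <- linear_bw(cache$global_raw, p[["gemb.W"]], dge)
    g[["gemb.W"]] <- lb$dW; g[["gemb.b"]] <- lb$db
  }
  g
}

## ---- losses ----------------------------------------------------------------

#' Loss specification
#'
#' @param kind `"categorical_cross_entropy"` or `"smooth_l1"`.
#' @param beta smooth-L1 transition point (default 1).
#' @param M class count (classification) or target dimension (regression).
#' @return a `loss_spec` list.
#' @export
loss_spec <- function(kind = c("categorical_cross_entropy", "smooth_l1"),
                      beta = 1, M = 1L) {
  kind <- match.arg(kind)
  stopifnot(beta > 0)
  structure(list(kind = kind, beta = beta, M = as.integer(M)),
            class = "loss_spec")
}

#' Evaluate a task loss
#'
#' Classification: categorical cross-entropy with the conventional negative
#' sign (a positive quantity to minimize), `-1/N sum_i log p_{i, y_i}`, with
#' `predictions` the posterior class probabilities (rows summing to 1) and
#' `targets` 0-based class indices. Regression: smooth L1, elementwise
#' `0.5 d^2 / beta` for `|d| < beta` else `|d| - beta/2`, averaged over all
#' elements; targets are expected on the standardized scale.
#'
#' @param predictions `N x M` matrix (class probabilities or predicted
#'   z-scores).
#' @param targets integer class indices (0-based) or numeric target matrix.
#' @param spec a [loss_spec()].
#' @return scalar loss.
#' @export
network_loss <- function(predictions, targets, spec) {
  if (spec$kind == "categorical_cross_entropy") {
    targets <- as.integer(targets)
    if (any(targets < 0L | targets >= spec$M)) {
      stop_tsgcn("network_loss: class index outside 0..%d", spec$M - 1L)
    }
    predictions <- as.matrix(predictions)
    -mean(log(predictions[cbind(seq_len(nrow(predictions)), targets + 1L)]))
  } else {
    d <- as.matrix(predictions) - as.matrix(targets)
    b <- spec$beta
    mean(ifelse(abs(d) < b, 0.5 * d^2 / b, abs(d) - 0.5 * b))
  }
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Loss on logits plus its gradient, used by the training loop.
loss_and_grad <- function(logits, targets, spec) {
  n <- nrow(logits)
  if (spec$kind == "categorical_cross_entropy") {
    targets <- as.integer(targets)
    pmat <- softmax_rows(logits)
    loss <- -mean(log(pmax(pmat[cbind(seq_len(n), targets + 1L)], 1e-300)))
    grad <- pmat
    grad[cbind(seq_len(n), targets + 1L)] <- grad[cbind(seq_len(n), targets + 1L)] - 1
    list(loss = loss, grad = grad / n)
  } else {
    tmat <- as.matrix(targets)
    d <- logits - tmat
    b <- spec$beta
    loss <- mean(ifelse(abs(d) < b, 0.5 * d^2 / b, abs(d) - 0.5 * b))
    grad <- ifelse(abs(d) < b, d / b, sign(d)) / length(d)
    list(loss = loss, grad = grad)
  }
}

## ---- optimizer -------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-5, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gmat
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
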
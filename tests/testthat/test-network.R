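# The network: reference convolution, attention convolution, forward
# contracts, losses, parameter counting, and analytic gradients.

test_that("reference convolution matches hand arithmetic and its matrix form", {
  ## isolated node with identity weights is unchanged (degree 1 self-loop)
  x <- matrix(c(1.5, -2), 1, 2)
  e0 <- matrix(integer(0), 2, 0)
  expect_equal(gcn_conv_reference(x, e0, diag(2)), x)
  ## single parent/child pair: x'_p = x_p/2 + x_c/sqrt(2)
  X <- rbind(c(1, 0), c(0, 1))
  e <- matrix(c(1L, 2L), 2, 1)  # child 1 -> parent 2
  out <- gcn_conv_reference(X, e, diag(2))
  expect_equal(out[2, ], X[2, ] / 2 + X[1, ] / sqrt(2), tolerance = 1e-12)
  expect_equal(out[1, ], X[1, ], tolerance = 1e-12)  # leaf: self term only
  ## matrix form == node-wise form == independent oracle on random trees
  set.seed(21)
  for (i in 1:10) {
    g <- random_tree_graph(sample(3:6, 1))
    Xr <- matrix(rnorm(g$N * 3), g$N)
    Th <- matrix(rnorm(9), 3)
    a1 <- gcn_conv_reference(Xr, g$edges, Th, form = "nodewise")
    a2 <- gcn_conv_reference(Xr, g$edges, Th, form = "matrix")
    a3 <- oracle_gcn_ref(Xr, g$edges, Th)
    expect_equal(a1, a2, tolerance = 1e-6)
    expect_equal(a1, a3, tolerance = 1e-6)
  }
})

test_that("attention weights are a softmax over self plus children", {
  set.seed(22)
  d <- 3
  Ws <- matrix(rnorm(d * d) / 4, d)
  Wt <- matrix(rnorm(d * d) / 4, d)
  a <- rnorm(d) / 4
  ## a leaf attends only to itself
  w <- gat_attention(rnorm(d), matrix(0, 0, d), Ws, Wt, a)
  expect_equal(unname(w), 1)
  ## weights sum to one for a 2-child node, and match scalar arithmetic
  xi <- c(0.3, -0.2, 0.5)
  kids <- rbind(c(1, 0, -1), c(0.2, 0.4, 0))
  w2 <- gat_attention(xi, kids, Ws, Wt, a, slope = 0.2)
  expect_equal(sum(w2), 1, tolerance = 1e-6)
  lrelu <- function(u) ifelse(u > 0, u, 0.2 * u)
  sc <- c(sum(a * lrelu(Ws %*% xi + Wt %*% xi)),
          sum(a * lrelu(Ws %*% xi + Wt %*% kids[1, ])),
          sum(a * lrelu(Ws %*% xi + Wt %*% kids[2, ])))
  expect_equal(unname(w2), exp(sc) / sum(exp(sc)), tolerance = 1e-9)
})

test_that("attention convolution matches the loop oracle and shape contract", {
  set.seed(23)
  for (i in 1:10) {
    g <- random_tree_graph(sample(3:10, 1))
    d_in <- 4; d_out <- if (i %% 2) 4L else 6L
    Xr <- matrix(rnorm(g$N * d_in), g$N)
    pars <- list(Ws = matrix(rnorm(d_out * d_in) / 3, d_out),
                 Wt = matrix(rnorm(d_out * d_in) / 3, d_out),
                 a = rnorm(d_out) / 3, bias = rnorm(d_out) / 5)
    got <- gat_conv(Xr, g$edges, pars)
    expect_equal(ncol(got), d_out)
    want <- oracle_gat(Xr, g$edges, pars$Ws, pars$Wt, pars$a, pars$bias)
    expect_equal(got, want, tolerance = 1e-6)
  }
  ## a leaf with identity self-transform and zero bias passes through
  g <- random_tree_graph(4)
  Xr <- matrix(rnorm(g$N * 3), g$N)
  pars <- list(Ws = diag(3), Wt = matrix(rnorm(9), 3), a = rnorm(3),
               bias = numeric(3))
  got <- gat_conv(Xr, g$edges, pars)
  expect_equal(got[1:4, ], Xr[1:4, ], tolerance = 1e-9)
})

test_that("losses follow their closed forms", {
  sp <- loss_spec("categorical_cross_entropy", M = 4L)
  perfect <- diag(4)[c(1, 3), ]
  expect_equal(network_loss(perfect, c(0L, 2L), sp), 0)
  unif <- matrix(1 / 4, 3, 4)
  expect_equal(network_loss(unif, c(0L, 1L, 3L), sp), log(4), tolerance = 1e-12)
  expect_error(network_loss(unif, c(0L, 4L, 1L), sp), "class index")
  sl <- loss_spec("smooth_l1", beta = 1)
  expect_equal(network_loss(matrix(0.5), matrix(0), sl), 0.125)
  expect_equal(network_loss(matrix(2), matrix(0), sl), 1.5)
  expect_equal(network_loss(matrix(0), matrix(0), sl), 0)
  expect_error(loss_spec("smooth_l1", beta = 0))
})

test_that("parameter counts match closed forms layer by layer", {
  cfg <- gcn_config(k = 1L, M = 5L)  # F = 4
  model <- gcn_model(cfg, seed = 1)
  cp <- count_parameters(model)
  total <- attr(cp, "total")
  expect_equal(sum(cp$count), total)
  ## node embedding: a lone linear F=4 -> 26 with bias
  expect_equal(sum(cp$count[cp$layer %in% c("embed.W", "embed.b")]), 130L)
  ## single-layer unidirectional GRU: 3(IH + H^2 + 2H)
  gru_closed <- function(I, H) 3L * (I * H + H * H + 2L * H)
  expect_equal(sum(cp$count[grepl("^gru_tree", cp$layer)]),
               gru_closed(cfg$tree_in, cfg$h_tree))
  expect_equal(sum(cp$count[grepl("^gru_seq", cp$layer)]),
               gru_closed(cfg$seq_in, cfg$h_seq))
  ## independent whole-architecture closed form
  d <- cfg$conv_dim
  expected <- 130L +                                  # embedding
    cfg$n_conv * (2L * d * d + d + d + 2L * d) +      # Ws, Wt, a, bias, LN
    gru_closed(cfg$tree_in, cfg$h_tree) +
    gru_closed(cfg$seq_in, cfg$h_seq) +
    (37L * 37L + 37L) +                               # global embedding
    (cfg$head_in * cfg$head_dim + cfg$head_dim) + 2L * cfg$head_dim +
    (cfg$head_dim * cfg$head_dim + cfg$head_dim) + 2L * cfg$head_dim +
    (cfg$head_dim * cfg$M + cfg$M)
  expect_equal(total, expected)
})

small_cfg <- function(...) {
  gcn_config(k = 1L, M = 2L, embed_dim = 6L, n_conv = 2L, h_tree = 8L,
             h_seq = 8L, head_dim = 8L, ...)
}

test_that("forward handles unequal lengths; padding cannot leak into outputs", {
  set.seed(24)
  f1 <- fake_feature(3L, 5L, label = 0L)
  f2 <- fake_feature(7L, 5L, label = 1L)
  model <- gcn_model(small_cfg(), seed = 3)
  outB <- gcn_forward(model, assemble_batch(list(f1, f2)), train = FALSE)$out
  expect_equal(dim(outB), c(2L, 2L))
  ## the same sequence alone vs inside a padded batch (evaluation mode)
  out1 <- gcn_forward(model, assemble_batch(list(f1)), train = FALSE)$out
  expect_equal(unname(outB[1, ]), unname(out1[1, ]), tolerance = 1e-5)
  ## all ablation switches off still yields well-formed outputs
  m0 <- gcn_model(small_cfg(use_graph_conv = FALSE, use_tree_summary = FALSE,
                            use_global_summary = FALSE), seed = 3)
  out0 <- gcn_forward(m0, assemble_batch(list(f1, f2)), train = FALSE)$out
  expect_equal(dim(out0), c(2L, 2L))
  expect_true(all(is.finite(out0)))
})

test_that("conv layers are permutation-equivariant over node relabeling", {
  set.seed(25)
  g <- random_tree_graph(6)
  X <- matrix(rnorm(g$N * 4), g$N)
  pars <- list(Ws = matrix(rnorm(16) / 3, 4), Wt = matrix(rnorm(16) / 3, 4),
               a = rnorm(4) / 3, bias = rnorm(4) / 5)
  out <- gat_conv(X, g$edges, pars)
  perm <- sample(g$N)
  e2 <- matrix(match(g$edges, perm), 2)  # edges in permuted row coordinates
  out2 <- gat_conv(X[perm, , drop = FALSE], e2, pars)
  expect_equal(out2, out[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("without graph convolution the edge list is ignored entirely", {
  set.seed(26)
  f <- fake_feature(4L, 5L)
  model <- gcn_model(small_cfg(use_graph_conv = FALSE), seed = 4)
  o1 <- gcn_forward(model, assemble_batch(list(f)), train = FALSE)$out
  f_shuffled <- f
  f_shuffled$edges <- f$edges[, sample(ncol(f$edges))]
  ## even a nonsensical edge list changes nothing when the conv block is off
  f_shuffled$edges[1, ] <- rev(f_shuffled$edges[1, ])
  o2 <- gcn_forward(model, assemble_batch(list(f_shuffled)), train = FALSE)$out
  expect_identical(o1, o2)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(27)
  feats <- list(fake_feature(2L, 4L, label = 0L),
                fake_feature(4L, 4L, label = 1L))
  batch <- assemble_batch(feats)
  model <- gcn_model(small_cfg(), seed = 5)
  spec <- loss_spec("categorical_cross_entropy", M = 2L)
  targ <- c(0L, 1L)
  lossfun <- function(m) {
    fw <- gcn_forward(m, batch, train = TRUE)
    tsgcn:::loss_and_grad(fw$out, targ, spec)$loss
  }
  fw <- gcn_forward(model, batch, train = TRUE, keep_cache = TRUE)
  lg <- tsgcn:::loss_and_grad(fw$out, targ, spec)
  gr <- gcn_backward(model, fw$cache, lg$grad)
  h <- 1e-5
  for (nm in c("embed.W", "conv1.Ws", "conv2.a", "conv1.ln_gamma",
               "gru_tree.W_hh", "gru_seq.W_ih", "gemb.W", "fc1.W",
               "bn2.gamma", "out.b")) {
    for (i in sample(length(model$params[[nm]]), min(3L, length(model$params[[nm]])))) {
      m2 <- model
      m2$params[[nm]][i] <- model$params[[nm]][i] + h
      lp <- lossfun(m2)
      m2$params[[nm]][i] <- model$params[[nm]][i] - h
      lm <- lossfun(m2)
      num <- (lp - lm) / (2 * h)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("model initialization and forward are deterministic given the seed", {
  m1 <- gcn_model(small_cfg(), seed = 11)
  m2 <- gcn_model(small_cfg(), seed = 11)
  expect_identical(m1$params, m2$params)
  set.seed(28)
  f <- fake_feature(3L, 4L)
  b <- assemble_batch(list(f))
  expect_identical(gcn_forward(m1, b)$out, gcn_forward(m2, b)$out)
})
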
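# Reference spectral graph convolution and the attention convolution surface.
#
# The reference (degree-normalized) convolution is kept as an executable
# specification: the attention convolution used by the trained model replaces
# the fixed 1/sqrt(d_i d_j) weights with learned attention coefficients, but
# shares the neighborhood structure (children plus a self-loop, edges directed
# child to parent).

children_of <- function(edges, n_nodes) {
  out <- vector("list", n_nodes)
  if (ncol(edges) == 0L) return(out)
  sp <- split(edges[1, ], edges[2, ])
  out[as.integer(names(sp))] <- sp
  out
}

#' Reference degree-normalized graph convolution
#'
#' The classic spectral graph convolution with self-loops:
#' `x'_i = Theta^T sum_{j in N(i) + {i}} x_j / sqrt(dhat_j dhat_i)` where
#' `N(i)` is the set of children of node `i` and `dhat_i = 1 + |N(i)|`.
#' Both the matrix form (`D^-1/2 (A + I) D^-1/2 X Theta`) and the node-wise
#' form are available; they are algebraically identical and the pair serves
#' as a cross-check.
#'
#' @param X numeric `n_nodes x d` feature matrix.
#' @param edges `2 x E` integer matrix of (child, parent) node indices.
#' @param Theta `d x d_out` weight matrix.
#' @param form `"nodewise"` or `"matrix"`.
#' @return `n_nodes x d_out` matrix of convolved features.
#' @export
gcn_conv_reference <- function(X, edges, Theta,
                               form = c("nodewise", "matrix")) {
  form <- match.arg(form)
  n <- nrow(X)
  if (nrow(Theta) != ncol(X)) stop_tsgcn("gcn_conv_reference: Theta has %d rows but X has %d columns",
                                         nrow(Theta), ncol(X))
  kids <- children_of(edges, n)
  deg <- 1 + lengths(kids)
  if (form == "matrix") {
    A <- diag(n)
    if (ncol(edges)) A[cbind(edges[2, ], edges[1, ])] <- 1
    Dm <- diag(1 / sqrt(deg), n)
    return(Dm %*% A %*% Dm %*% X %*% Theta)
  }
  out <- matrix(0, n, ncol(Theta))
  for (i in seq_len(n)) {
    nb <- c(kids[[i]], i)
    agg <- colSums(X[nb, , drop = FALSE] / sqrt(deg[nb] * deg[i]))
    out[i, ] <- crossprod(Theta, agg)
  }
  out
}

#' Attention coefficients for one node
#'
#' Computes the attention weights of a focal node over its children plus
#' itself: `alpha_{i,j} = softmax_j a^T LeakyReLU(Theta_s x_i + Theta_t x_j)`
#' with the softmax taken over `N(i) + {i}`. A leaf (no children) receives
#' `alpha_{i,i} = 1`.
#'
#' @param x_i focal node feature vector (length d).
#' @param children_x matrix of child feature rows (0 rows for a leaf).
#' @param Theta_s,Theta_t `d_out x d` transform matrices for the focal node
#'   and its neighbors.
#' @param a attention projection vector (length d_out).
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return numeric vector `c(self = alpha_ii, alpha_ij ...)` summing to 1,
#'   children in input row order.
#' @export
gat_attention <- function(x_i, children_x, Theta_s, Theta_t, a, slope = 0.2) {
  if (is.null(dim(children_x))) children_x <- matrix(children_x, ncol = length(x_i))
  s_i <- as.numeric(Theta_s %*% x_i)
  score <- function(t_j) {
    u <- s_i + t_j
    sum(a * ifelse(u > 0, u, slope * u))
  }
  self_score <- score(as.numeric(Theta_t %*% x_i))
  child_scores <- if (nrow(children_x)) {
    apply(children_x, 1, function(xj) score(as.numeric(Theta_t %*% xj)))
  } else numeric(0)
  sc <- c(self_score, child_scores)
  e <- exp(sc - max(sc))
  w <- e / sum(e)
  names(w) <- c("self", if (length(child_scores)) paste0("child", seq_along(child_scores)))
  w
}

#' Attention graph convolution over a tree
#'
#' Per-node update `x'_i = alpha_ii Theta_s x_i +
#' sum_{j in N(i)} alpha_ij Theta_t x_j + bias`, with attention weights as in
#' [gat_attention()]. Leaves reduce to `Theta_s x_i + bias`. The heavy
#' lifting is done in compiled code; [gat_attention()] provides the scalar
#' reference for the attention weights.
#'
#' @param X `n_nodes x d` feature matrix.
#' @param edges `2 x E` integer (child, parent) matrix, 1-based.
#' @param params list with elements `Ws`, `Wt` (`d_out x d`), `a` (`d_out`)
#'   and `bias` (`d_out`; defaults to zero).
#' @param slope LeakyReLU negative slope.
#' @return `n_nodes x d_out` matrix.
#' @export
gat_conv <- function(X, edges, params, slope = 0.2) {
  bias <- params$bias %||% numeric(nrow(params$Ws))
  if (nrow(params$Ws) != nrow(params$Wt) || ncol(params$Ws) != ncol(X)) {
    stop_tsgcn("gat_conv: parameter shapes inconsistent with input width %d", ncol(X))
  }
  res <- .gat_forward_cpp(X, as.integer(edges[1, ]) - 1L,
                          as.integer(edges[2, ]) - 1L,
                          params$Ws, params$Wt, as.numeric(params$a),
                          as.numeric(bias), slope)
  res$out
}
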
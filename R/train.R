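# Training loop with target standardization and early stopping.

#' Fit target standardization statistics on the training split
#'
#' @param values numeric vector or matrix of raw training targets (columns =
#'   target dimensions).
#' @param log_scale natural-log the values before standardizing (used for
#'   recombination rates and demographic parameters).
#' @return a `target_stats` list with per-dimension `mean`, `sd` and the
#'   `log_scale` flag.
#' @export
fit_target_stats <- function(values, log_scale = FALSE) {
  v <- as.matrix(values)
  if (log_scale) {
    if (any(v <= 0)) stop_tsgcn("fit_target_stats: non-positive value with log_scale = TRUE")
    v <- log(v)
  }
  sds <- apply(v, 2, sd_pop)
  sds[sds < 1e-12] <- 1
  structure(list(mean = colMeans(v), sd = sds, log_scale = log_scale),
            class = "target_stats")
}

#' Standardize / invert task targets
#'
#' `z = (ln v - mu) / sigma` when the statistics were fitted with
#' `log_scale = TRUE`, else `z = (v - mu) / sigma`. The two functions are
#' exact inverses.
#'
#' @param values numeric vector or matrix.
#' @param stats a [fit_target_stats()] object (fitted on training targets
#'   only).
#' @return matrix of z-values (or raw-scale values for the inverse).
#' @export
standardize_targets <- function(values, stats) {
  v <- as.matrix(values)
  if (stats$log_scale) {
    if (any(v <= 0)) stop_tsgcn("standardize_targets: non-positive value with log_scale = TRUE")
    v <- log(v)
  }
  sweep(sweep(v, 2, stats$mean), 2, stats$sd, "/")
}

#' @rdname standardize_targets
#' @export
unstandardize_targets <- function(values, stats) {
  v <- sweep(sweep(as.matrix(values), 2, stats$sd, "*"), 2, stats$mean, "+")
  if (stats$log_scale) exp(v) else v
}

#' Training configuration
#'
#' Defaults follow the tree-sequence network's training recipe: ADAM with
#' learning rate 1e-5 (betas 0.9/0.999), up to 100 epochs, early stopping
#' after ten consecutive epochs without strict improvement of the validation
#' criterion (accuracy for classification, negative validation loss for
#' regression), and per-task batch sizes (recombination 16, introgression 36,
#' sweeps 20, demography 30). The alignment-CNN baseline recipe uses learning
#' rate 1e-3.
#'
#' @param task one of `"recombination"`, `"introgression"`, `"sweeps"`,
#'   `"demography"`, or `NULL` for generic defaults.
#' @param lr,batch_size,max_epochs,patience,beta1,beta2,seed overrides.
#' @return a `train_config` list.
#' @export
train_config <- function(task = NULL, lr = 1e-5, batch_size = NULL,
                         max_epochs = 100L, patience = 10L,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  default_bs <- c(recombination = 16L, introgression = 36L, sweeps = 20L,
                  demography = 30L)
  bs <- batch_size %||% if (!is.null(task)) default_bs[[task]] else 16L
  stopifnot(patience < max_epochs, bs >= 1L)
  structure(list(task = task, lr = lr, batch_size = as.integer(bs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed)),
            class = "train_config")
}

batch_targets <- function(features, spec) {
  labs <- lapply(features, `[[`, "label")
  if (spec$kind == "categorical_cross_entropy") {
    as.integer(unlist(labs))
  } else {
    do.call(rbind, lapply(labs, function(l) matrix(as.numeric(l), nrow = 1L)))
  }
}

eval_pass <- function(model, features, spec, batch_size = 64L) {
  n <- length(features)
  outs <- vector("list", ceiling(n / batch_size))
  bi <- 1L
  for (s in seq(1L, n, by = batch_size)) {
    sel <- s:min(n, s + batch_size - 1L)
    fw <- gcn_forward(model, assemble_batch(features[sel]), train = FALSE)
    outs[[bi]] <- fw$out
    bi <- bi + 1L
  }
  do.call(rbind, outs)
}

#' Train a model
#'
#' Mini-batch ADAM training with early stopping on the validation criterion
#' (classification accuracy, or negative validation loss for regression);
#' strict improvement is required, the best-validation parameters are
#' restored at the end. Labels inside the featurized records are used as
#' targets: 0-based class indices for classification, standardized target
#' vectors for regression. Runs are reproducible given the configuration
#' seed (all shuffling derives from it).
#'
#' @param model a [gcn_model()].
#' @param train_features,val_features featurized splits
#'   ([featurize_dataset()] output with labels set).
#' @param spec a [loss_spec()].
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` (per-epoch data
#'   frame), `best_epoch`, and `stopped_early`.
#' @export
gcn_train <- function(model, train_features, val_features, spec, config,
                      verbose = FALSE) {
  if (!length(train_features) || !length(val_features)) {
    stop_tsgcn("gcn_train: empty training or validation split")
  }
  n <- length(train_features)
  opt <- adam_state(model$params)
  val_targets <- batch_targets(val_features, spec)
  best <- list(metric = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  bad_epochs <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    tr_loss <- 0
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      sel <- ord[s:min(n, s + config$batch_size - 1L)]
      feats <- train_features[sel]
      batch <- assemble_batch(feats)
      fw <- gcn_forward(model, batch, train = TRUE, keep_cache = TRUE)
      lg <- loss_and_grad(fw$out, batch_targets(feats, spec), spec)
      if (!is.finite(lg$loss)) {
        stop_tsgcn("gcn_train: non-finite loss at epoch %d, batch %d", epoch, nb + 1L)
      }
      grads <- gcn_backward(model, fw$cache, lg$grad)
      st <- adam_step(model$params, grads, opt, lr = config$lr,
                      beta1 = config$beta1, beta2 = config$beta2)
      model$params <- st$params
      model$state <- fw$state
      opt <- st$opt
      tr_loss <- tr_loss + lg$loss
      nb <- nb + 1L
    }
    val_out <- eval_pass(model, val_features, spec)
    vl <- loss_and_grad(val_out, val_targets, spec)$loss
    metric <- if (spec$kind == "categorical_cross_entropy") {
      mean(max.col(val_out) - 1L == val_targets)
    } else {
      -vl
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                val_loss = vl, val_metric = metric)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  metric %.4f",
                      epoch, tr_loss / nb, vl, metric))
    }
    if (metric > best$metric) {
      best <- list(metric = metric, params = model$params,
                   state = model$state, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch,
       stopped_early = bad_epochs >= config$patience)
}

#' Predict with a trained model
#'
#' @param model a trained [gcn_model()].
#' @param features featurized records.
#' @param type `"response"` returns raw outputs (logits / z-scores);
#'   `"prob"` applies the row softmax.
#' @return numeric matrix, one row per record.
#' @export
gcn_predict <- function(model, features, type = c("response", "prob")) {
  type <- match.arg(type)
  spec <- loss_spec("smooth_l1", M = model$config$M)
  out <- eval_pass(model, features, spec)
  if (type == "prob") softmax_rows(out) else out
}
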
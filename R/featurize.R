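# Conversion of tree-sequence records into network inputs: per-tree node
# feature matrices and edge indices, 12-dim tree summary vectors, the 37-dim
# per-sequence summary vector, training-set normalization, and the two tree
# downsampling schemes.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic featurization goes through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Canonical node ordering of a marginal tree
#'
#' Leaves first, in sample order, followed by the internal nodes in ascending
#' time order. This is the sequence in which node features are fed to the
#' per-tree recurrent layer.
#'
#' @param tree a [marginal_tree].
#' @return an integer permutation of node indices.
#' @export
node_ordering <- function(tree) {
  leaves <- which(tree$is_leaf)
  internals <- which(!tree$is_leaf)
  c(leaves, internals[order(tree$time[internals], internals, method = "radix")])
}

#' Fit featurization normalization statistics on the training split
#'
#' Computes per-dimension means and standard deviations (population, ddof 0)
#' for: internal-node log-ages (leaves excluded from the pool; their feature
#' value is a fixed 0 after normalization), per-branch mutation counts (all
#' nodes pooled, root included with count 0), the 12 tree-summary dimensions,
#' and the 37 per-sequence summary dimensions. Dimensions with sd below 1e-12
#' have sd replaced by 1 and are flagged in `$degenerate`, with a warning.
#'
#' Only ever call this on the training split: validation and test data are
#' standardized with the training statistics to prevent leakage.
#'
#' @param records list of [tree_sequence_record]s (the training split, after
#'   any downsampling that the training pipeline applies).
#' @return an object of class `normalization_stats`.
#' @export
fit_normalization <- function(records) {
  stopifnot(length(records) >= 1L)
  logages <- unlist(lapply(records, function(r)
    unlist(lapply(r$trees, function(tr) log(tr$time[!tr$is_leaf])))))
  muts <- unlist(lapply(records, function(r)
    unlist(lapply(r$trees, function(tr) as.numeric(tr$mutations)))))
  tree_mat <- do.call(rbind, lapply(records, function(r) {
    t(vapply(r$trees, tree_summary, numeric(12), L = r$sequence_length))
  }))
  glob_mat <- t(vapply(records, function(r) {
    vs <- lapply(r$trees, tree_summary, L = r$sequence_length)
    sequence_summary(vs, r$original_T)
  }, numeric(37)))
  ms <- function(x) c(mean = mean(x), sd = sd_pop(x))
  col_ms <- function(m) list(mean = colMeans(m), sd = apply(m, 2, sd_pop))
  st <- list(
    logage = ms(logages),
    mut = ms(muts),
    tree = col_ms(tree_mat),
    global = col_ms(glob_mat),
    target = NULL,
    schema_version = 1L
  )
  degen <- character(0)
  fix <- function(sd_vec, tag) {
    bad <- sd_vec < 1e-12
    if (any(bad)) {
      degen <<- c(degen, paste0(tag, which(bad)))
      sd_vec[bad] <- 1
    }
    sd_vec
  }
  st$logage["sd"] <- fix(st$logage["sd"], "logage")
  st$mut["sd"] <- fix(st$mut["sd"], "mut")
  st$tree$sd <- fix(st$tree$sd, "tree")
  st$global$sd <- fix(st$global$sd, "global")
  st$degenerate <- degen
  if (length(degen)) {
    warning(sprintf("constant dimension(s) in normalization fit (sd -> 1): %s",
                    paste(degen, collapse = ", ")), call. = FALSE)
  }
  structure(st, class = "normalization_stats")
}

is_fitted_stats <- function(stats) {
  inherits(stats, "normalization_stats") && !is.null(stats$logage)
}

#' Serialize / read normalization statistics as JSON
#'
#' @param stats a `normalization_stats` object.
#' @param path file path.
#' @return `read_normalization_stats` returns the restored object.
#' @export
write_normalization_stats <- function(stats, path) {
  out <- unclass(stats)
  ## canonical JSON layout: every mean/sd group is an object
  out$logage <- as.list(stats$logage)
  out$mut <- as.list(stats$mut)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_normalization_stats
#' @export
read_normalization_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$logage <- c(mean = x$logage$mean, sd = x$logage$sd)
  x$mut <- c(mean = x$mut$mean, sd = x$mut$sd)
  x$target <- if (is.null(x$target) || !length(x$target)) NULL else x$target
  structure(x, class = "normalization_stats")
}

#' Build the node feature matrix of a marginal tree
#'
#' One row per node in [node_ordering()] order, with `F = 2 + (k + 1)`
#' columns: column 1 is the standardized natural-log node age for internal
#' nodes and exactly 0 for leaves; column 2 is the standardized per-branch
#' mutation count; the remaining `k + 1` columns one-hot encode the node role
#' over `{internal, population 1, ..., population k}`.
#'
#' @param tree a [marginal_tree].
#' @param stats fitted [fit_normalization()] statistics.
#' @param k number of populations.
#' @return a `(2n - 1) x F` numeric matrix.
#' @export
build_node_features <- function(tree, stats, k = 1L) {
  if (!is_fitted_stats(stats)) stop_tsgcn("build_node_features: normalization stats are not fitted")
  ord <- node_ordering(tree)
  N <- length(ord)
  Fdim <- 2L + k + 1L
  X <- matrix(0, nrow = N, ncol = Fdim)
  time <- tree$time[ord]
  is_leaf <- tree$is_leaf[ord]
  X[!is_leaf, 1] <- (log(time[!is_leaf]) - stats$logage[["mean"]]) / stats$logage[["sd"]]
  X[, 2] <- (as.numeric(tree$mutations[ord]) - stats$mut[["mean"]]) / stats$mut[["sd"]]
  pop <- tree$population[ord]
  ## role one-hot: column 3 = internal; leaf with 0-based population p -> column 4 + p
  X[cbind(seq_len(N), ifelse(is_leaf, 4L + pop, 3L))] <- 1
  X
}

#' Build the directed edge index of a marginal tree
#'
#' One column per non-root node: `(child_row, parent_row)` in the coordinates
#' of [node_ordering()]. Edges are directed child to parent, so during the
#' graph convolution each node aggregates messages from its children (and
#' itself); leaves receive only their own self-loop contribution.
#'
#' @param tree a [marginal_tree].
#' @return a `2 x (2n - 2)` integer matrix, first row child, second row parent.
#' @export
build_edge_index <- function(tree) {
  ord <- node_ordering(tree)
  rank_of <- integer(length(ord))
  rank_of[ord] <- seq_along(ord)
  child <- which(!is.na(tree$parent))
  e <- rbind(child = rank_of[child], parent = rank_of[tree$parent[child]])
  e[, order(e[1, ]), drop = FALSE]
}

#' Tree summary vector (12 statistics)
#'
#' Hand-crafted per-tree statistics concatenated to the per-tree recurrent
#' embedding: the TMRCA; mean, median and standard deviation of the `n - 1`
#' coalescence times; mean, median, standard deviation, skew and maximum of
#' the `2n - 2` branch lengths; the interval midpoint scaled to `(0, 1)`;
#' the fraction of the locus spanned; and the total branch length. All
#' moment statistics use population (ddof 0) moments; the skew is the
#' Fisher-Pearson moment coefficient, defined as 0 for equal branch lengths.
#'
#' @param tree a [marginal_tree].
#' @param L locus length in bp.
#' @return a numeric vector of length 12.
#' @export
tree_summary <- function(tree, L) {
  ct <- tree$time[!tree$is_leaf]
  child <- which(!is.na(tree$parent))
  bl <- tree$time[tree$parent[child]] - tree$time[child]
  c(max(ct),
    mean(ct), stats::median(ct), sd_pop(ct),
    mean(bl), stats::median(bl), sd_pop(bl), skew_g1(bl), max(bl),
    (tree$interval[1] + tree$interval[2]) / (2 * L),
    (tree$interval[2] - tree$interval[1]) / L,
    sum(bl))
}

#' Per-sequence summary vector (37 values)
#'
#' Elementwise mean, standard deviation (population) and median of a
#' sequence's tree summary vectors, followed by the number of trees in the
#' original, pre-downsampling sequence: `3 * 12 + 1 = 37` values.
#'
#' @param vectors list (or matrix rows) of 12-dim tree summary vectors.
#' @param original_T tree count of the original sequence.
#' @return a numeric vector of length 37.
#' @export
sequence_summary <- function(vectors, original_T) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(vectors)) stop_tsgcn("sequence_summary: no tree summary vectors supplied")
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  if (nrow(vectors) < 1L) stop_tsgcn("sequence_summary: no tree summary vectors supplied")
  if (original_T < nrow(vectors)) {
    stop_tsgcn("sequence_summary: original_T (%d) < number of vectors (%d)",
               original_T, nrow(vectors))
  }
  c(colMeans(vectors),
    apply(vectors, 2, sd_pop),
    apply(vectors, 2, stats::median),
    as.numeric(original_T))
}

#' Downsample a long tree sequence
#'
#' Sequences longer than `cap` trees are reduced before featurization.
#' `"window"` keeps a contiguous run of exactly `cap` trees with the window
#' start uniform over valid starts (the default used for most tasks);
#' `"span_weighted"` draws `cap` trees with replacement with probability
#' proportional to the fraction of the chromosome each tree spans, then
#' restores the original left-to-right ordering (duplicates retained) --
#' appropriate when the signal of interest can sit anywhere along the locus,
#' as in sweep classification. Sequences with at most `cap` trees are
#' returned unchanged. The returned record keeps `original_T` so the
#' per-sequence summary still reflects the full sequence.
#'
#' @param record a [tree_sequence_record].
#' @param cap maximum number of trees retained (default 128).
#' @param mode `"window"` or `"span_weighted"`.
#' @param seed integer seed for the draw.
#' @return a [tree_sequence_record] with at most `cap` trees.
#' @export
downsample <- function(record, cap = 128L, mode = c("window", "span_weighted"),
                       seed = 1L) {
  mode <- match.arg(mode)
  Tn <- length(record$trees)
  if (Tn <= cap) return(record)
  idx <- with_seed(seed, {
    if (mode == "window") {
      s <- sample.int(Tn - cap + 1L, 1L)
      s:(s + cap - 1L)
    } else {
      spans <- vapply(record$trees, function(t) t$interval[2] - t$interval[1], 0)
      sort(sample.int(Tn, cap, replace = TRUE, prob = spans))
    }
  })
  out <- record
  out$trees <- record$trees[idx]
  out$original_T <- record$original_T
  out
}

#' Featurize a tree-sequence record for the network
#'
#' Applies the complete input pipeline of the architecture: per-tree node
#' feature matrices (stacked tree-major in a single matrix), within-sequence
#' edge indices, normalized tree summary vectors, and the normalized
#' per-sequence summary vector.
#'
#' @param record a [tree_sequence_record], already downsampled if desired.
#' @param stats fitted [fit_normalization()] statistics.
#' @return a list with elements `x` (`(T*N) x F` node features), `edges`
#'   (`2 x (T*(2n-2))` child/parent rows, offset per tree within the
#'   sequence), `tree_summ` (`T x 12`, normalized), `global` (length 37,
#'   normalized), `n_trees`, `n_nodes`, `F`, `k`, and `label`.
#' @export
featurize_record <- function(record, stats) {
  if (!is_fitted_stats(stats)) stop_tsgcn("featurize_record: normalization stats are not fitted")
  k <- record$k_populations
  trees <- record$trees
  Tn <- length(trees)
  N <- 2L * record$n_samples - 1L
  xs <- vector("list", Tn)
  es <- vector("list", Tn)
  ts_raw <- matrix(0, Tn, 12L)
  for (t in seq_len(Tn)) {
    xs[[t]] <- build_node_features(trees[[t]], stats, k)
    es[[t]] <- build_edge_index(trees[[t]]) + (t - 1L) * N
    ts_raw[t, ] <- tree_summary(trees[[t]], record$sequence_length)
  }
  g_raw <- sequence_summary(ts_raw, record$original_T)
  list(
    x = do.call(rbind, xs),
    edges = do.call(cbind, es),
    tree_summ = sweep(sweep(ts_raw, 2, stats$tree$mean), 2, stats$tree$sd, "/"),
    global = (g_raw - stats$global$mean) / stats$global$sd,
    n_trees = Tn,
    n_nodes = N,
    F = 2L + k + 1L,
    k = k,
    label = record$label
  )
}

#' Featurize a dataset split
#'
#' Downsamples every record (per-record seeds derived from `seed`), then
#' featurizes with the supplied training statistics. Use
#' [save_feature_archive()] to persist the result as a single container file.
#'
#' @param records list of [tree_sequence_record]s.
#' @param stats fitted [fit_normalization()] statistics.
#' @param cap downsampling cap (default 128).
#' @param mode downsampling mode, see [downsample()].
#' @param seed integer seed.
#' @return list of featurized records (see [featurize_record()]).
#' @export
featurize_dataset <- function(records, stats, cap = 128L,
                              mode = c("window", "span_weighted"), seed = 1L) {
  mode <- match.arg(mode)
  lapply(seq_along(records), function(i) {
    featurize_record(downsample(records[[i]], cap, mode, derive_seed(seed, i)),
                     stats)
  })
}

#' Persist / load a featurized split as a single container file
#'
#' The container groups node features, edge indices, tree summaries, global
#' summaries, labels and provenance for every record of one dataset split.
#'
#' @param features output of [featurize_dataset()].
#' @param path container path (RDS).
#' @return `load_feature_archive` returns the feature list.
#' @export
save_feature_archive <- function(features, path) {
  saveRDS(features, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_feature_archive
#' @export
load_feature_archive <- function(path) readRDS(path)
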
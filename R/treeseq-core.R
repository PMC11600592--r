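# Data model and I/O for sequences of marginal genealogical trees and for
# ms-format genotype alignments.
#
# Internal conventions (documented in the methods vignette):
#   * genomic coordinates are 0-based, half-open [left, right) base pairs;
#   * all leaves are sampled at the present day (time 0);
#   * within a tree, nodes are indexed 1..(2n-1) with the n leaves first, in
#     sample order, followed by the n-1 internal nodes in ascending time order
#     (this is also the node ordering consumed by the recurrent layers);
#   * populations are integer labels 0..k-1 for leaves and NA ("unknown") for
#     internal nodes;
#   * equal parent/child times are forbidden: loaders perturb exact ties
#     upward by `time_epsilon` (default 1e-6 generations) and report it.

#' Construct a marginal tree
#'
#' A rooted binary genealogy of `n` present-day samples over one genomic
#' interval. With `n` leaves the tree has `2n - 1` nodes and `2n - 2`
#' child-to-parent edges.
#'
#' @param parent integer vector of length `2n - 1`; `parent[i]` is the node
#'   index of `i`'s parent, `NA` for the root.
#' @param time numeric node times in generations; 0 for leaves.
#' @param interval numeric length-2 half-open genomic span `[left, right)` in bp.
#' @param population integer population label per node (0-based for leaves,
#'   `NA` for internal nodes). Defaults to population 0 for all leaves.
#' @param mutations non-negative integer count of mutations on the branch
#'   above each node (0 for the root). Defaults to all zero.
#' @param is_leaf logical per node; defaults to `time == 0`.
#' @return an object of class `marginal_tree`.
#' @export
marginal_tree <- function(parent, time, interval, population = NULL,
                          mutations = NULL, is_leaf = NULL) {
  parent <- as.integer(parent)
  time <- as.numeric(time)
  if (is.null(is_leaf)) is_leaf <- time == 0
  n <- sum(is_leaf)
  if (is.null(population)) {
    population <- ifelse(is_leaf, 0L, NA_integer_)
  }
  if (is.null(mutations)) mutations <- integer(length(time))
  structure(list(
    parent = parent,
    time = time,
    is_leaf = is_leaf,
    population = as.integer(population),
    mutations = as.integer(mutations),
    interval = as.numeric(interval),
    n_leaves = as.integer(n)
  ), class = "marginal_tree")
}

#' @export
print.marginal_tree <- function(x, ...) {
  cat(sprintf("<marginal_tree> %d leaves, %d nodes, interval [%g, %g), TMRCA %.4g\n",
              x$n_leaves, length(x$time), x$interval[1], x$interval[2],
              max(x$time)))
  invisible(x)
}

#' Construct a tree-sequence record
#'
#' An ordered list of marginal trees whose intervals tile the locus `[0, L)`.
#'
#' @param trees list of [marginal_tree] objects, ordered along the chromosome.
#' @param sequence_length locus length `L` in bp.
#' @param n_samples haploid sample count `n`.
#' @param k_populations number of populations `k >= 1`.
#' @param provenance `"true_simulation"` or `"inferred"`.
#' @param label optional task target (class index or numeric parameter vector).
#' @param original_T tree count of the sequence before any downsampling;
#'   defaults to `length(trees)`.
#' @return an object of class `tree_sequence_record`.
#' @export
tree_sequence_record <- function(trees, sequence_length, n_samples,
                                 k_populations = 1L,
                                 provenance = c("true_simulation", "inferred"),
                                 label = NULL, original_T = NULL) {
  provenance <- match.arg(provenance)
  structure(list(
    trees = trees,
    sequence_length = as.numeric(sequence_length),
    n_samples = as.integer(n_samples),
    k_populations = as.integer(k_populations),
    provenance = provenance,
    label = label,
    original_T = as.integer(original_T %||% length(trees))
  ), class = "tree_sequence_record")
}

#' @export
print.tree_sequence_record <- function(x, ...) {
  cat(sprintf(
    "<tree_sequence_record> %d trees (original %d), n = %d, k = %d, L = %g bp, %s\n",
    length(x$trees), x$original_T, x$n_samples, x$k_populations,
    x$sequence_length, x$provenance))
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Binary haplotype alignment: rows are haploid individuals, columns are
#' segregating sites (0 = ancestral, 1 = derived).
#'
#' @param alleles binary matrix with entries in `{0, 1}`.
#' @param positions strictly increasing bp coordinates in `[0, L)`.
#' @param population_of_row integer population label per row (default all 0).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, positions,
                            population_of_row = integer(nrow(alleles))) {
  structure(list(
    alleles = alleles,
    positions = as.numeric(positions),
    population_of_row = as.integer(population_of_row)
  ), class = "genotype_matrix")
}

root_of <- function(tree) which(is.na(tree$parent))

violation <- function(tree, invariant, message) {
  data.frame(tree = tree, invariant = invariant, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a tree-sequence record
#'
#' Checks every structural invariant of the data model: rooted binary trees
#' with `2n - 1` nodes, strictly increasing times along edges, leaves at time
#' zero, populations known exactly for leaves, zero mutations above the root,
#' non-empty intervals that tile `[0, L)` contiguously, and a shared leaf set
#' across trees. Violations are returned, never raised.
#'
#' @param record a [tree_sequence_record].
#' @return a data frame with columns `tree` (index, `NA` for record-level
#'   violations), `invariant` (short name) and `message`; zero rows iff the
#'   record is valid.
#' @export
validate_record <- function(record) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  trees <- record$trees
  if (length(trees) < 1L) {
    add(violation(NA_integer_, "empty sequence", "record contains no trees"))
    return(do.call(rbind, out))
  }
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    n <- tr$n_leaves
    N <- length(tr$time)
    if (N != 2L * n - 1L) {
      add(violation(ti, "node count",
                    sprintf("tree %d: %d nodes for %d leaves, expected %d",
                            ti, N, n, 2L * n - 1L)))
      next
    }
    roots <- root_of(tr)
    if (length(roots) != 1L) {
      add(violation(ti, "root count",
                    sprintf("tree %d: %d roots, expected 1", ti, length(roots))))
      next
    }
    kids <- tabulate(tr$parent[!is.na(tr$parent)], nbins = N)
    if (any(kids[!tr$is_leaf] != 2L)) {
      add(violation(ti, "non-binary",
                    sprintf("tree %d: internal node(s) without exactly 2 children: %s",
                            ti, paste(which(!tr$is_leaf & kids != 2L), collapse = ","))))
    }
    if (any(kids[tr$is_leaf] != 0L)) {
      add(violation(ti, "leaf with children",
                    sprintf("tree %d: leaf node(s) with children", ti)))
    }
    edge_child <- which(!is.na(tr$parent))
    bad <- edge_child[tr$time[tr$parent[edge_child]] <= tr$time[edge_child]]
    if (length(bad)) {
      add(violation(ti, "non-increasing time",
                    sprintf("tree %d: parent time <= child time for child node(s) %s",
                            ti, paste(bad, collapse = ","))))
    }
    if (any(tr$is_leaf & tr$time != 0)) {
      add(violation(ti, "nonzero leaf time",
                    sprintf("tree %d: leaf node(s) with time != 0", ti)))
    }
    if (any(!tr$is_leaf & tr$time <= 0)) {
      add(violation(ti, "nonpositive internal time",
                    sprintf("tree %d: internal node(s) with time <= 0", ti)))
    }
    if (tr$mutations[roots] != 0L) {
      add(violation(ti, "root mutations",
                    sprintf("tree %d: root has %d mutations above it", ti,
                            tr$mutations[roots])))
    }
    if (any(tr$mutations < 0L)) {
      add(violation(ti, "negative mutations",
                    sprintf("tree %d: negative mutation count", ti)))
    }
    pops <- tr$population
    k <- record$k_populations
    if (any(tr$is_leaf & (is.na(pops) | pops < 0L | pops >= k))) {
      add(violation(ti, "population label",
                    sprintf("tree %d: leaf population outside 0..%d", ti, k - 1L)))
    }
    if (any(!tr$is_leaf & !is.na(pops))) {
      add(violation(ti, "population label",
                    sprintf("tree %d: internal node with known population", ti)))
    }
    if (tr$interval[2] <= tr$interval[1]) {
      add(violation(ti, "empty interval",
                    sprintf("tree %d: right (%g) <= left (%g)", ti,
                            tr$interval[2], tr$interval[1])))
    }
  }
  ## record-level: contiguous tiling of [0, L)
  lefts <- vapply(trees, function(t) t$interval[1], 0)
  rights <- vapply(trees, function(t) t$interval[2], 0)
  if (lefts[1] != 0) {
    add(violation(NA_integer_, "interval gap",
                  sprintf("first tree starts at %g, expected 0", lefts[1])))
  }
  L <- record$sequence_length
  if (abs(rights[length(rights)] - L) > 1e-9 * max(1, L)) {
    add(violation(NA_integer_, "interval gap",
                  sprintf("last tree ends at %g, expected L = %g",
                          rights[length(rights)], L)))
  }
  if (length(trees) > 1L) {
    dl <- lefts[-1] - rights[-length(rights)]
    gap <- which(dl > 1e-9)
    ovl <- which(dl < -1e-9)
    for (i in gap) {
      add(violation(i + 1L, "interval gap",
                    sprintf("gap between tree %d (ends %g) and tree %d (starts %g)",
                            i, rights[i], i + 1L, lefts[i + 1L])))
    }
    for (i in ovl) {
      add(violation(i + 1L, "interval overlap",
                    sprintf("tree %d starts at %g before tree %d ends at %g",
                            i + 1L, lefts[i + 1L], i, rights[i])))
    }
  }
  ## shared leaf set and population assignment
  n0 <- trees[[1]]$n_leaves
  pop0 <- trees[[1]]$population[seq_len(n0)]
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    if (tr$n_leaves != n0 ||
        !identical(tr$population[seq_len(min(tr$n_leaves, n0))], pop0[seq_len(min(tr$n_leaves, n0))])) {
      add(violation(ti, "leaf set",
                    sprintf("tree %d: leaf set/populations differ from tree 1", ti)))
    }
  }
  if (record$n_samples != n0) {
    add(violation(NA_integer_, "sample count",
                  sprintf("record says n = %d but trees have %d leaves",
                          record$n_samples, n0)))
  }
  if (length(out) == 0L) {
    return(data.frame(tree = integer(0), invariant = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Number of topology breakpoints of a tree sequence
#'
#' The number of trees in the (pre-downsampling) sequence minus one: the count
#' of historical recombination events that are in principle observable as
#' topology changes along the locus.
#'
#' @param record a valid [tree_sequence_record].
#' @return integer `T - 1`, with `T` the original tree count.
#' @export
num_topology_breakpoints <- function(record) {
  record$original_T - 1L
}

#' Read ms-style simulator output
#'
#' Parses the standard ms text dialect: replicates delimited by `//`, then a
#' `segsites:` line, a `positions:` line with site coordinates as fractions of
#' the locus, and one 0/1 row per haplotype. Fractional positions are mapped
#' to base pairs by `floor(p * L)`; collisions are retained as distinct
#' columns.
#'
#' @param x path to an ms output file, or a character vector of its lines.
#' @param L locus length in bp used to map fractional positions.
#' @param populations optional integer vector of per-row population labels
#'   applied to every replicate.
#' @return a list of [genotype_matrix] objects, one per replicate.
#' @export
read_ms <- function(x, L, populations = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0L) stop_tsgcn("ms parse error: no '//' replicate delimiter found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (r in seq_along(starts)) {
    i <- starts[r] + 1L
    stop_at <- bounds[r + 1L]
    while (i < stop_at && !grepl("^segsites:", trimws(lines[i]))) i <- i + 1L
    if (i >= stop_at) stop_tsgcn("ms parse error at line %d: missing 'segsites:' header", starts[r])
    s <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", trimws(lines[i]))))
    if (is.na(s) || s < 0L) stop_tsgcn("ms parse error at line %d: bad segsites value", i)
    if (s == 0L) {
      out[[r]] <- genotype_matrix(matrix(0L, nrow = 0L, ncol = 0L), numeric(0))
      next
    }
    i <- i + 1L
    while (i < stop_at && !grepl("^positions:", trimws(lines[i]))) i <- i + 1L
    if (i >= stop_at) stop_tsgcn("ms parse error at line %d: missing 'positions:' header", i - 1L)
    pos_frac <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", trimws(lines[i]))), "\\s+")[[1]])
    if (length(pos_frac) != s) {
      stop_tsgcn("ms parse error at line %d: %d positions for segsites %d", i, length(pos_frac), s)
    }
    i <- i + 1L
    rows <- list()
    while (i < stop_at && nzchar(trimws(lines[i]))) {
      row <- trimws(lines[i])
      if (nchar(row) != s) {
        stop_tsgcn("ms parse error at line %d: row length %d != segsites %d", i, nchar(row), s)
      }
      v <- as.integer(strsplit(row, "")[[1]])
      if (anyNA(v) || any(v < 0L | v > 1L)) {
        stop_tsgcn("ms parse error at line %d: non-{0,1} character in haplotype row", i)
      }
      rows[[length(rows) + 1L]] <- v
      i <- i + 1L
    }
    if (length(rows) == 0L) stop_tsgcn("ms parse error: replicate %d has no haplotype rows", r)
    alle <- do.call(rbind, rows)
    pops <- populations %||% integer(nrow(alle))
    out[[r]] <- genotype_matrix(alle, floor(pos_frac * L), pops)
  }
  out
}

# Enforce strictly increasing times along edges by nudging tying parents
# upward by eps, processing nodes in ascending time order. Returns the
# adjusted time vector and the number of ties broken.
break_time_ties <- function(parent, time, is_leaf, eps = 1e-6) {
  n_tie <- 0L
  ord <- order(time, method = "radix")
  for (i in ord) {
    p <- parent[i]
    if (!is.na(p) && time[p] <= time[i]) {
      time[p] <- time[i] + eps
      n_tie <- n_tie + 1L
    }
  }
  list(time = time, n_ties = n_tie)
}

# Build one canonical marginal tree from (global parent map restricted to the
# active edge set). `active_child`/`active_parent` are global node ids of the
# current tree's edges; `leaf_ids` are the global sample ids in sample order.
build_local_tree <- function(active_child, active_parent, leaf_ids, node_time,
                             node_pop, interval, time_epsilon = 1e-6) {
  internals <- sort(unique(active_parent))
  internals <- internals[order(node_time[internals], internals, method = "radix")]
  gl <- c(leaf_ids, internals)
  local_of <- integer(max(gl))
  local_of[gl] <- seq_along(gl)
  n <- length(leaf_ids)
  N <- length(gl)
  parent <- rep(NA_integer_, N)
  parent[local_of[active_child]] <- local_of[active_parent]
  time <- node_time[gl]
  is_leaf <- c(rep(TRUE, n), rep(FALSE, N - n))
  tied <- break_time_ties(parent, time, is_leaf, time_epsilon)
  marginal_tree(parent = parent, time = tied$time, interval = interval,
                population = c(node_pop[leaf_ids], rep(NA_integer_, N - n)),
                is_leaf = is_leaf)
}

# Core table -> record conversion shared by the text "tables" dialect and the
# simulator backend. Tables use tskit conventions: 0-based node ids, edges
# (left, right, parent, child), mutations (position, node).
record_from_tables <- function(nodes, edges, muts, L, provenance = "true_simulation",
                               label = NULL, time_epsilon = 1e-6) {
  nid <- as.integer(nodes$id) + 1L
  node_time <- numeric(max(nid)); node_time[nid] <- nodes$time
  node_pop <- rep(NA_integer_, max(nid))
  node_pop[nid] <- ifelse(nodes$is_sample == 1L, as.integer(nodes$population), NA_integer_)
  leaf_ids <- nid[nodes$is_sample == 1L]
  leaf_ids <- leaf_ids[order(leaf_ids)]
  leaf_pops <- node_pop[leaf_ids]
  leaf_pops[is.na(leaf_pops) | leaf_pops < 0L] <- 0L
  node_pop[leaf_ids] <- leaf_pops
  k <- max(leaf_pops) + 1L
  ec <- as.integer(edges$child) + 1L
  ep <- as.integer(edges$parent) + 1L
  el <- as.numeric(edges$left)
  er <- as.numeric(edges$right)
  bp <- sort(unique(c(0, el, er, L)))
  bp <- bp[bp <= L]
  Tn <- length(bp) - 1L
  ins_order <- order(el, method = "radix")
  rem_order <- order(er, method = "radix")
  active <- logical(length(ec))
  trees <- vector("list", Tn)
  ii <- 1L; ri <- 1L
  mut_pos <- if (!is.null(muts) && nrow(muts)) as.numeric(muts$position) else numeric(0)
  mut_node <- if (!is.null(muts) && nrow(muts)) as.integer(muts$node) + 1L else integer(0)
  mut_tree <- if (length(mut_pos)) findInterval(mut_pos, bp, rightmost.closed = FALSE,
                                                left.open = FALSE) else integer(0)
  for (t in seq_len(Tn)) {
    x <- bp[t]
    while (ri <= length(rem_order) && er[rem_order[ri]] <= x) {
      active[rem_order[ri]] <- FALSE
      ri <- ri + 1L
    }
    while (ii <= length(ins_order) && el[ins_order[ii]] <= x) {
      active[ins_order[ii]] <- TRUE
      ii <- ii + 1L
    }
    idx <- which(active)
    tr <- build_local_tree(ec[idx], ep[idx], leaf_ids, node_time, node_pop,
                           interval = c(bp[t], bp[t + 1L]),
                           time_epsilon = time_epsilon)
    if (length(mut_pos)) {
      sel <- which(mut_tree == t)
      if (length(sel)) {
        internals <- sort(unique(ep[idx]))
        internals <- internals[order(node_time[internals], internals, method = "radix")]
        gl <- c(leaf_ids, internals)
        local_of <- integer(max(gl)); local_of[gl] <- seq_along(gl)
        counts <- tabulate(local_of[mut_node[sel]], nbins = length(gl))
        tr$mutations <- as.integer(counts)
      }
    }
    trees[[t]] <- tr
  }
  tree_sequence_record(trees, sequence_length = L,
                       n_samples = length(leaf_ids), k_populations = k,
                       provenance = provenance, label = label)
}

parse_table_section <- function(lines, cols) {
  if (length(lines) == 0L) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  df <- utils::read.table(text = lines, sep = "\t", col.names = cols,
                          colClasses = "numeric")
  df
}

#' Load a tree sequence from disk
#'
#' Two dialects are supported. `"tables"` is a text dump of succinct
#' tree-sequence tables (sections `#nodes` with `id/time/population/is_sample`,
#' `#edges` with `left/right/parent/child`, optional `#mutations` with
#' `position/node`; tab-separated, `#L` header line carries the locus length;
#' the helper `inst/python/dump_trees.py` produces this dump losslessly from a
#' binary `.trees` file). `"newick"` is the package's per-tree text dialect:
#' one line per tree with `left`, `right` and a Newick string with branch
#' lengths in generations; internal nodes may carry their canonical node index
#' as a label, and an optional companion table `(tree_index, child_id, count)`
#' populates per-branch mutation counts.
#'
#' Exact parent/child time ties are perturbed upward by `time_epsilon` (and
#' reported via a message) because downstream log-age features require
#' strictly positive internal times.
#'
#' @param path file path.
#' @param dialect `"tables"` or `"newick"`.
#' @param mutations_path optional companion mutation-count table (newick
#'   dialect only).
#' @param provenance provenance tag for the record.
#' @param label optional task label.
#' @param time_epsilon tie-breaking perturbation in generations.
#' @return a [tree_sequence_record] that passes [validate_record()].
#' @export
load_tree_sequence <- function(path, dialect = c("tables", "newick"),
                               mutations_path = NULL,
                               provenance = "true_simulation", label = NULL,
                               time_epsilon = 1e-6) {
  dialect <- match.arg(dialect)
  rec <- if (dialect == "tables") {
    load_tables_dialect(path, provenance, label, time_epsilon)
  } else {
    load_newick_dialect(path, mutations_path, provenance, label, time_epsilon)
  }
  viol <- validate_record(rec)
  if (nrow(viol)) {
    stop_tsgcn("load error: record fails validation: %s",
               paste(utils::head(viol$message, 3L), collapse = "; "))
  }
  rec
}

load_tables_dialect <- function(path, provenance, label, time_epsilon) {
  lines <- readLines(path)
  Lline <- grep("^#L\\b", lines, value = TRUE)
  if (length(Lline) != 1L) stop_tsgcn("tables dialect: missing '#L<TAB>length' header in %s", path)
  L <- as.numeric(strsplit(Lline, "\t")[[1]][2])
  sec <- function(name) {
    i <- which(trimws(lines) == paste0("#", name))
    if (length(i) == 0L) return(character(0))
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], "#")) j <- j + 1L
    if (j <= i + 1L) character(0) else lines[(i + 1L):(j - 1L)]
  }
  nodes <- parse_table_section(sec("nodes"), c("id", "time", "population", "is_sample"))
  edges <- parse_table_section(sec("edges"), c("left", "right", "parent", "child"))
  muts <- parse_table_section(sec("mutations"), c("position", "node"))
  if (nrow(nodes) == 0L || nrow(edges) == 0L) {
    stop_tsgcn("tables dialect: %s has an empty #nodes or #edges section", path)
  }
  record_from_tables(nodes, edges, muts, L, provenance, label, time_epsilon)
}

# Convert one ape "phylo" tree (branch lengths in generations) into the
# canonical marginal_tree layout. Tip order: numeric labels are ordered
# numerically, otherwise lexicographically (radix / C locale).
tree_from_phylo <- function(phy, interval, populations = NULL,
                            time_epsilon = 1e-6) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  if (phy$Nnode != n - 1L) stop_tsgcn("load error: non-binary tree (Nnode = %d for %d tips)",
                                      phy$Nnode, n)
  depth <- node_depths(phy)
  age <- max(depth[seq_len(n)]) - depth
  age[seq_len(n)][abs(age[seq_len(n)]) < 1e-8 * max(1, max(age))] <- 0
  labs <- phy$tip.label
  num <- suppressWarnings(as.numeric(labs))
  tip_rank <- if (!anyNA(num)) order(num) else order(labs, method = "radix")
  ## ape index -> canonical index
  internal_ape <- (n + 1L):N
  internal_ord <- internal_ape[order(age[internal_ape], internal_ape, method = "radix")]
  canon <- integer(N)
  canon[tip_rank] <- seq_len(n)
  canon[internal_ord] <- n + seq_len(n - 1L)
  parent <- rep(NA_integer_, N)
  parent[canon[phy$edge[, 2]]] <- canon[phy$edge[, 1]]
  time <- numeric(N)
  time[canon] <- age
  is_leaf <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  tied <- break_time_ties(parent, time, is_leaf, time_epsilon)
  pops <- populations %||% c(rep(0L, n), rep(NA_integer_, n - 1L))
  marginal_tree(parent = parent, time = tied$time, interval = interval,
                population = pops, is_leaf = is_leaf)
}

# Root-to-node path lengths of an ape phylo object.
node_depths <- function(phy) {
  N <- length(phy$tip.label) + phy$Nnode
  depth <- numeric(N)
  root <- length(phy$tip.label) + 1L
  ## edges of a phylo are not guaranteed ordered root-down; iterate until fixed
  e <- phy$edge
  el <- phy$edge.length
  done <- logical(N); done[root] <- TRUE
  remaining <- seq_len(nrow(e))
  while (length(remaining)) {
    ready <- remaining[done[e[remaining, 1]]]
    if (!length(ready)) stop_tsgcn("load error: disconnected Newick tree")
    depth[e[ready, 2]] <- depth[e[ready, 1]] + el[ready]
    done[e[ready, 2]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  depth
}

load_newick_dialect <- function(path, mutations_path, provenance, label,
                                time_epsilon) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  kline <- grep("^#k\\b", hdr, value = TRUE)
  pline <- grep("^#pop\\b", hdr, value = TRUE)
  k <- if (length(kline)) as.integer(strsplit(kline, "\t")[[1]][2]) else 1L
  pops <- if (length(pline)) {
    as.integer(strsplit(strsplit(pline, "\t")[[1]][2], " ")[[1]])
  } else NULL
  trees <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) < 3L) stop_tsgcn("newick dialect: line %d needs left<TAB>right<TAB>newick", i)
    phy <- tryCatch(ape::read.tree(text = f[3]),
                    error = function(e) NULL)
    if (is.null(phy)) stop_tsgcn("newick dialect: unparseable Newick on line %d", i)
    n <- length(phy$tip.label)
    popv <- if (!is.null(pops)) c(pops, rep(NA_integer_, n - 1L)) else NULL
    trees[[i]] <- tree_from_phylo(phy, as.numeric(f[1:2]), popv, time_epsilon)
  }
  n <- trees[[1]]$n_leaves
  L <- trees[[length(trees)]]$interval[2]
  if (!is.null(mutations_path)) {
    mt <- utils::read.table(mutations_path, sep = "\t", comment.char = "#",
                            col.names = c("tree_index", "child_id", "count"))
    for (r in seq_len(nrow(mt))) {
      ti <- mt$tree_index[r]
      trees[[ti]]$mutations[mt$child_id[r]] <- as.integer(mt$count[r])
    }
  }
  tree_sequence_record(trees, sequence_length = L, n_samples = n,
                       k_populations = k, provenance = provenance, label = label)
}

canonical_newick <- function(tree, digits = 10) {
  kids <- split(which(!is.na(tree$parent)), tree$parent[!is.na(tree$parent)])
  fmt <- function(i) {
    bl <- if (is.na(tree$parent[i])) NULL else tree$time[tree$parent[i]] - tree$time[i]
    lab <- as.character(i)
    if (tree$is_leaf[i]) {
      paste0(lab, if (!is.null(bl)) paste0(":", format(bl, digits = digits)) else "")
    } else {
      ch <- kids[[as.character(i)]]
      paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")", lab,
             if (!is.null(bl)) paste0(":", format(bl, digits = digits)) else "")
    }
  }
  paste0(fmt(root_of(tree)), ";")
}

#' Write a tree-sequence record in the Newick text dialect
#'
#' One line per tree (`left`, `right`, Newick with node indices as labels and
#' branch lengths in generations), plus an optional companion table of
#' per-branch mutation counts. The written file round-trips through
#' [load_tree_sequence()] with node times reproduced to near machine
#' precision.
#'
#' @param record a [tree_sequence_record].
#' @param path output path.
#' @param mutations_path optional output path for the mutation-count table.
#' @return `path`, invisibly.
#' @export
write_tree_sequence <- function(record, path, mutations_path = NULL) {
  n <- record$n_samples
  hdr <- c("# tsgcn newick dialect",
           sprintf("#L\t%s", format(record$sequence_length, digits = 15)),
           sprintf("#k\t%d", record$k_populations),
           sprintf("#pop\t%s",
                   paste(record$trees[[1]]$population[seq_len(n)], collapse = " ")))
  body <- vapply(record$trees, function(tr) {
    sprintf("%s\t%s\t%s",
            format(tr$interval[1], digits = 15),
            format(tr$interval[2], digits = 15),
            canonical_newick(tr, digits = 15))
  }, "")
  writeLines(c(hdr, body), path)
  if (!is.null(mutations_path)) {
    rows <- c("# tree_index\tchild_id\tcount")
    for (ti in seq_along(record$trees)) {
      m <- record$trees[[ti]]$mutations
      nz <- which(m > 0L)
      if (length(nz)) {
        rows <- c(rows, sprintf("%d\t%d\t%d", ti, nz, m[nz]))
      }
    }
    writeLines(rows, mutations_path)
  }
  invisible(path)
}
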
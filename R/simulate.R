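# Synthetic benchmark data: coalescent simulations with recombination for
# the four benchmark tasks, deterministic fixtures, and the external
# genealogy-inference adapter. Simulation itself is delegated to msprime
# (invoked through the system `python`); this module owns the parameter
# distributions, class balancing, seeding, and conversion of the simulator's
# tables into tree_sequence_record objects.

python_binary <- function() Sys.which("python")

#' Is the coalescent simulation backend available?
#'
#' Checks that a `python` with `msprime` importable is on the PATH.
#' @return logical.
#' @export
sim_backend_available <- function() {
  py <- python_binary()
  if (!nzchar(py)) return(FALSE)
  code <- suppressWarnings(system2(py, c("-c", shQuote("import msprime, tskit")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

sim_script <- function(name) {
  p <- system.file("python", name, package = "tsgcn")
  if (!nzchar(p)) stop_tsgcn("cannot locate bundled python script %s", name)
  p
}

#' Recombination-rate task configuration
#'
#' The historical-recombination regression benchmark: population size `N`
#' drawn uniformly from `{1000, 2000, 5000, 10000, 20000, 50000}` (diploid),
#' locus `L = 20` kb, mutation rate `1.5e-8` per bp per generation, per-bp
#' crossover rate `r` from an exponential distribution truncated to
#' `[1e-8, 1e-6]` (pre-truncation mean `1e-7`, the geometric midpoint of the
#' bounds; the mean is a configurable assumption), 50 haploid samples. The
#' regression target is `ln r`.
#'
#' @param N_set,L,mu,r_mean,r_low,r_high,n overrides of the above.
#' @return a `recomb_task_config` list.
#' @export
recomb_task_config <- function(N_set = c(1000, 2000, 5000, 10000, 20000, 50000),
                               L = 20000, mu = 1.5e-8, r_mean = 1e-7,
                               r_low = 1e-8, r_high = 1e-6, n = 50L) {
  structure(list(N_set = N_set, L = L, mu = mu, r_mean = r_mean,
                 r_low = r_low, r_high = r_high, n = as.integer(n)),
            class = "recomb_task_config")
}

#' Demographic-inference task configuration
#'
#' Three-epoch single-population model with five targets in fixed order
#' `(N0, T1, N1, T2, N2)`: present size `N0 ~ U[100, 4e4]`, recent change
#' time `T1 ~ U[100, 3500]`, middle size `N1 ~ U[100, 5000]`, ancient change
#' time `T2 = T1 + U[1, 3500]`, ancestral size `N2 ~ U[100, 2e4]`; 50
#' haploid samples. Locus length, mutation and recombination rates default
#' to 100 kb, `1.5e-8` and `1e-8` (documented assumptions).
#'
#' @param n,L,mu,r overrides.
#' @return a `demog_task_config` list.
#' @export
demog_task_config <- function(n = 50L, L = 1e5, mu = 1.5e-8, r = 1e-8) {
  structure(list(n = as.integer(n), L = L, mu = mu, r = r),
            class = "demog_task_config")
}

#' Introgression task configuration
#'
#' Two populations (k = 2) that split `T_split` generations ago, with a
#' single pulse admixture event at a time drawn from `U(0.3, 0.5) * T_split`
#' in one of two directions, or absent: three balanced classes
#' (0 = A to B, 1 = B to A, 2 = none). The default parameterization is a
#' generic isolation-with-migration model (sizes `N` diploid for both
#' daughters and the ancestor, pulse proportion 0.25) with a 20 + 14
#' haploid sample split.
#'
#' @param n1,n2 haploid sample counts for populations A and B.
#' @param N diploid size of each population and the ancestor.
#' @param T_split split time in generations.
#' @param pulse_prop admixture pulse proportion.
#' @param t_frac range of the pulse time as a fraction of `T_split`.
#' @param mu,r,L locus parameters.
#' @return an `introg_task_config` list.
#' @export
introg_task_config <- function(n1 = 20L, n2 = 14L, N = 1e5, T_split = 4e5,
                               pulse_prop = 0.25, t_frac = c(0.3, 0.5),
                               mu = 5e-9, r = 1e-8, L = 1e4) {
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), N = N,
                 T_split = T_split, pulse_prop = pulse_prop, t_frac = t_frac,
                 mu = mu, r = r, L = L),
            class = "introg_task_config")
}

run_sim_job <- function(task, n_reps, params, seed, write_ms = TRUE,
                        keep_dir = NULL) {
  if (!sim_backend_available()) {
    stop_tsgcn("simulation backend unavailable: needs `python` with msprime on the PATH")
  }
  out_dir <- keep_dir %||% tempfile("simjob")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  job <- list(task = task, n_reps = n_reps, seed = seed, out_dir = out_dir,
              params = params, write_ms = write_ms)
  job_path <- file.path(out_dir, "job.json")
  jsonlite::write_json(job, job_path, auto_unbox = TRUE, digits = NA)
  status <- system2(python_binary(), c(sim_script("simtrees.py"), job_path),
                    stdout = file.path(out_dir, "log.txt"),
                    stderr = file.path(out_dir, "log.txt"))
  if (!identical(status, 0L)) {
    stop_tsgcn("simulator backend failure (exit %s): %s", status,
               paste(tail(readLines(file.path(out_dir, "log.txt")), 5), collapse = " | "))
  }
  fr <- function(f, cols) {
    d <- data.table::fread(file.path(out_dir, f), header = FALSE, sep = "\t",
                           showProgress = FALSE)
    data.table::setnames(d, cols)
    d
  }
  nodes <- fr("nodes.tsv", c("rep", "id", "time", "population", "is_sample"))
  edges <- fr("edges.tsv", c("rep", "left", "right", "parent", "child"))
  muts <- if (file.size(file.path(out_dir, "mutations.tsv")) > 0) {
    fr("mutations.tsv", c("rep", "position", "node"))
  } else NULL
  tre <- fr("trees.tsv", c("rep", "num_trees"))
  pars <- data.table::fread(file.path(out_dir, "params.tsv"), sep = "\t",
                            showProgress = FALSE)
  L <- params$L
  nodes_by <- split(nodes, by = "rep", keep.by = FALSE)
  edges_by <- split(edges, by = "rep", keep.by = FALSE)
  muts_by <- if (!is.null(muts)) split(muts, by = "rep", keep.by = FALSE) else list()
  target_cols <- grep("^target", names(pars), value = TRUE)
  records <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    key <- as.character(i)
    lab <- as.numeric(pars[i, target_cols, with = FALSE])
    records[[i]] <- record_from_tables(nodes_by[[key]], edges_by[[key]],
                                       muts_by[[key]], L,
                                       provenance = "true_simulation",
                                       label = if (length(lab) == 1L) lab else lab)
  }
  genotypes <- if (write_ms) read_ms(file.path(out_dir, "ms.txt"), L) else NULL
  if (is.null(keep_dir)) unlink(out_dir, recursive = TRUE)
  list(records = records, genotypes = genotypes, params = as.data.frame(pars),
       sim_num_trees = tre$num_trees)
}

#' Simulate the recombination-rate benchmark
#'
#' Each replicate carries the true marginal-tree sequence (provenance
#' `"true_simulation"`, label `ln r`), the ms-style genotype matrix (unless
#' `write_ms = FALSE`), and its parameter draws.
#'
#' @param n_reps number of replicates.
#' @param config a [recomb_task_config()].
#' @param seed integer seed (all per-replicate seeds derive from it).
#' @param write_ms also return genotype matrices.
#' @return list with `records`, `genotypes`, `params` (per-replicate draws
#'   including `log_r`), and `sim_num_trees` (the simulator's own tree
#'   count per replicate).
#' @export
sim_recombination <- function(n_reps, config = recomb_task_config(), seed = 1L,
                              write_ms = TRUE) {
  run_sim_job("recombination", n_reps, unclass(config), seed, write_ms)
}

#' Simulate the demographic-inference benchmark
#'
#' @inheritParams sim_recombination
#' @param config a [demog_task_config()].
#' @return as [sim_recombination()]; labels are the raw 5-vectors
#'   `(N0, T1, N1, T2, N2)` (log scaling happens at target standardization).
#' @export
sim_demography <- function(n_reps, config = demog_task_config(), seed = 1L,
                           write_ms = TRUE) {
  run_sim_job("demography", n_reps, unclass(config), seed, write_ms)
}

#' Simulate the introgression benchmark
#'
#' Classes are assigned round-robin (hence balanced to within one):
#' 0 = pulse from A into B, 1 = pulse from B into A, 2 = no admixture.
#'
#' @inheritParams sim_recombination
#' @param config an [introg_task_config()].
#' @return as [sim_recombination()]; labels are 0-based class indices.
#' @export
sim_introgression <- function(n_reps, config = introg_task_config(), seed = 1L,
                              write_ms = TRUE) {
  out <- run_sim_job("introgression", n_reps, unclass(config), seed, write_ms)
  for (i in seq_along(out$records)) {
    out$records[[i]]$label <- as.integer(out$records[[i]]$label)
  }
  out
}

#' Sweep-classification task specification
#'
#' Five classes in fixed order: hard sweep, hard-linked, soft sweep,
#' soft-linked, neutral (0-based indices 0..4). A simulated window counts as
#' a "sweep" when the selected site lies in the central subwindow covering
#' 1/11 of the locus; elsewhere it is "linked". Fixation times are drawn
#' from `U(0, 2000)` generations by the external selection simulator; the
#' sample size is 104 haploids. Sweep simulations are ingested from ms-format
#' files (selection simulators are external tools), and the span-weighted
#' downsampling mode is the appropriate one for this task.
#'
#' @param n haploid sample count.
#' @param central_frac width of the central subwindow as a locus fraction.
#' @param tau_max upper bound of the fixation-time distribution.
#' @return a `sweep_task_spec` list.
#' @export
sweep_task_spec <- function(n = 104L, central_frac = 1 / 11, tau_max = 2000) {
  structure(list(
    classes = c("hard", "hard-linked", "soft", "soft-linked", "neutral"),
    n = as.integer(n), central_frac = central_frac, tau_max = tau_max,
    downsample_mode = "span_weighted"
  ), class = "sweep_task_spec")
}

#' Ingest an externally simulated sweep dataset
#'
#' Reads ms-format files plus a tab-separated label manifest with columns
#' `replicate`, `label` (one of the five class names) and `sel_pos` (selected
#' site position as a locus fraction; `NA` for neutral). When positions are
#' given, labels are validated against the central-subwindow rule: a selected
#' site within the central 1/11 of the locus must be labeled `hard`/`soft`,
#' outside it `hard-linked`/`soft-linked`.
#'
#' @param ms_path ms output file containing all replicates in manifest order.
#' @param manifest_path manifest path.
#' @param spec a [sweep_task_spec()].
#' @param L locus length in bp.
#' @return list with `genotypes`, integer `labels` (0-based), and the
#'   manifest data frame; attribute `downsample_mode` set to
#'   `"span_weighted"`.
#' @export
ingest_sweep_dataset <- function(ms_path, manifest_path, spec = sweep_task_spec(),
                                 L = 1.1e6) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("replicate", "label") %in% names(man))) {
    stop_tsgcn("sweep manifest must have columns replicate, label")
  }
  bad <- setdiff(unique(man$label), spec$classes)
  if (length(bad)) stop_tsgcn("sweep manifest: unknown class label(s): %s",
                              paste(bad, collapse = ", "))
  gm <- read_ms(ms_path, L)
  if (length(gm) != nrow(man)) {
    stop_tsgcn("sweep manifest has %d rows but ms file has %d replicates",
               nrow(man), length(gm))
  }
  if ("sel_pos" %in% names(man)) {
    half <- spec$central_frac / 2
    for (i in seq_len(nrow(man))) {
      p <- man$sel_pos[i]
      lab <- man$label[i]
      if (lab == "neutral") next
      if (is.na(p)) stop_tsgcn("sweep manifest row %d: selected class without sel_pos", i)
      central <- abs(p - 0.5) <= half
      if (central && !(lab %in% c("hard", "soft"))) {
        stop_tsgcn("sweep manifest row %d: selected site at %.3f is central but label is '%s'",
                   i, p, lab)
      }
      if (!central && !(lab %in% c("hard-linked", "soft-linked"))) {
        stop_tsgcn("sweep manifest row %d: selected site at %.3f is not central but label is '%s'",
                   i, p, lab)
      }
    }
  }
  missing <- setdiff(spec$classes, unique(man$label))
  if (length(missing)) stop_tsgcn("sweep manifest: class(es) missing: %s",
                                  paste(missing, collapse = ", "))
  labels <- match(man$label, spec$classes) - 1L
  structure(list(genotypes = gm, labels = labels, manifest = man),
            downsample_mode = spec$downsample_mode)
}

#' Infer a tree sequence from genotypes with an external tool
#'
#' Adapter around a genealogy-inference tool (default Relate). The tool is
#' given the mean values of the simulated parameter distributions (its
#' required point estimates of mutation rate, recombination rate and
#' effective size). The tool's binary output is converted to the text table
#' dialect and loaded as a record with provenance `"inferred"`. If the tool
#' (or its converter) is not on the PATH this raises an explicit error --
#' there is deliberately no silent fallback to true trees.
#'
#' @param genotypes a [genotype_matrix].
#' @param L locus length in bp.
#' @param mean_mu,mean_r mean mutation/recombination rate per bp per
#'   generation supplied to the tool.
#' @param mean_N mean diploid effective size supplied to the tool.
#' @param tool name of the inference binary.
#' @param workdir scratch directory (kept for inspection).
#' @return a [tree_sequence_record] with provenance `"inferred"`.
#' @export
infer_trees_adapter <- function(genotypes, L, mean_mu, mean_r, mean_N,
                                tool = "Relate", workdir = tempfile("relate")) {
  bin <- Sys.which(tool)
  conv <- Sys.which("RelateFileFormats")
  if (!nzchar(bin)) {
    stop_tsgcn("external tool unavailable: %s is not on the PATH", tool)
  }
  if (!nzchar(conv)) {
    stop_tsgcn("external tool unavailable: RelateFileFormats is not on the PATH")
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(genotypes$alleles)
  s <- length(genotypes$positions)
  haps <- vapply(seq_len(s), function(j) {
    paste(c("1", sprintf("snp%d", j), format(genotypes$positions[j] + 1),
            "A", "T", genotypes$alleles[, j]), collapse = " ")
  }, "")
  writeLines(haps, file.path(workdir, "input.haps"))
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               sprintf("UNR%d NA 0", seq_len(n))),
             file.path(workdir, "input.sample"))
  ## recombination map: rate in cM/Mb (r per bp per generation x 1e8),
  ## cumulative map in cM (r x pos x 100)
  writeLines(c("pos COMBINED_rate Genetic_Map",
               sprintf("%d %f %f", c(1L, as.integer(L)), mean_r * 1e8,
                       c(0, mean_r * L * 100))),
             file.path(workdir, "input.map"))
  cmd_log <- file.path(workdir, "commands.log")
  run <- function(bin, args) {
    cat(paste(c(bin, args), collapse = " "), "\n", file = cmd_log, append = TRUE)
    status <- system2(bin, args, stdout = file.path(workdir, "tool.log"),
                      stderr = file.path(workdir, "tool.log"))
    if (!identical(status, 0L)) {
      stop_tsgcn("inference tool failed (exit %s); see %s", status,
                 file.path(workdir, "tool.log"))
    }
  }
  owd <- setwd(workdir); on.exit(setwd(owd), add = TRUE)
  run(bin, c("--mode", "All", "-m", format(mean_mu), "-N", format(2 * mean_N),
             "--haps", "input.haps", "--sample", "input.sample",
             "--map", "input.map", "-o", "inferred"))
  run(conv, c("--mode", "ConvertToTreeSequence", "--anc", "inferred.anc",
              "--mut", "inferred.mut", "-o", "inferred"))
  run(python_binary(), c(sim_script("dump_trees.py"), "inferred.trees",
                         "inferred.tables.txt"))
  load_tree_sequence(file.path(workdir, "inferred.tables.txt"),
                     dialect = "tables", provenance = "inferred")
}

## ---- fixtures and random trees --------------------------------------------

#' Random coalescent-shaped tree (test utility)
#'
#' Builds a random rooted binary tree in canonical layout by sequential
#' pairwise merging with exponential waiting times at rate
#' `choose(k, 2) / time_scale`. This is a lightweight fixture generator, not
#' a population-genetic simulator (no recombination, no mutation model --
#' mutation counts can be attached separately).
#'
#' @param n number of leaves.
#' @param interval genomic interval of the tree.
#' @param time_scale coalescent time scale (2N in generations).
#' @param populations optional leaf population labels.
#' @return a [marginal_tree].
#' @export
random_coalescent_tree <- function(n, interval = c(0, 1), time_scale = 1000,
                                   populations = NULL) {
  N <- 2L * n - 1L
  parent <- rep(NA_integer_, N)
  time <- numeric(N)
  active <- 1:n
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1, rate = k * (k - 1) / 2 / time_scale)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  pops <- if (!is.null(populations)) c(populations, rep(NA_integer_, n - 1L)) else NULL
  marginal_tree(parent = parent, time = time, interval = interval,
                population = pops)
}

# A record of independent random trees tiling [0, L) (test utility).
random_record <- function(n, n_trees, L = 1000, time_scale = 1000,
                          mut_rate = 0.5, k = 1L, populations = NULL) {
  bp <- sort(c(0, runif(n_trees - 1L, 0, L), L))
  trees <- lapply(seq_len(n_trees), function(t) {
    tr <- random_coalescent_tree(n, interval = bp[t + 0:1], time_scale,
                                 populations)
    child <- which(!is.na(tr$parent))
    bl <- tr$time[tr$parent[child]] - tr$time[child]
    tr$mutations[child] <- rpois(length(child), mut_rate * bl / mean(bl))
    tr
  })
  tree_sequence_record(trees, sequence_length = L, n_samples = n,
                       k_populations = k, provenance = "true_simulation")
}

#' Deterministic tiny fixture records
#'
#' Hand-specified and seeded records of 2-8 leaves used across the test
#' suites: `twoLeaf10` (single 2-leaf tree with coalescence at 10 spanning
#' the whole locus -- its tree summary vector is the worked example of
#' [tree_summary()]), `threeLeaf` (times 0,0,0,5,9 with a few mutations),
#' `eightLeafRandom` (3 random trees), and `twoPop` (k = 2).
#'
#' @param seed integer seed for the randomized fixtures.
#' @return named list of [tree_sequence_record]s.
#' @export
make_fixtures <- function(seed = 1L) {
  with_seed(seed, {
    two <- marginal_tree(parent = c(3L, 3L, NA), time = c(0, 0, 10),
                         interval = c(0, 100))
    three <- marginal_tree(parent = c(4L, 4L, 5L, 5L, NA),
                           time = c(0, 0, 0, 5, 9), interval = c(0, 50),
                           mutations = c(1L, 0L, 2L, 1L, 0L))
    list(
      twoLeaf10 = tree_sequence_record(list(two), sequence_length = 100,
                                       n_samples = 2L),
      threeLeaf = tree_sequence_record(list(three), sequence_length = 50,
                                       n_samples = 3L),
      eightLeafRandom = random_record(8L, 3L, L = 1000),
      twoPop = random_record(4L, 2L, L = 500, k = 2L,
                             populations = c(0L, 0L, 1L, 1L))
    )
  })
}
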
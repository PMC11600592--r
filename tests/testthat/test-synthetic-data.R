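# Coalescent benchmark generators (msprime backend), sweep ingestion,
# fixtures, and the genealogy-inference adapter contract.

test_that("recombination draws stay in their supports and trees match the simulator", {
  require_sim_backend()
  cfg <- recomb_task_config(n = 10L)
  res <- sim_recombination(150, cfg, seed = 101)
  expect_length(res$records, 150L)
  expect_true(all(res$params$N %in% cfg$N_set))
  expect_true(all(res$params$r >= cfg$r_low & res$params$r <= cfg$r_high))
  expect_equal(res$params$log_r, log(res$params$r), tolerance = 1e-8)
  ## labels carry the regression target
  expect_equal(vapply(res$records, `[[`, 0, "label"), res$params$log_r,
               tolerance = 1e-8)
  ## every record validates; tree count agrees exactly with the simulator
  for (i in seq_len(20)) {
    expect_equal(nrow(validate_record(res$records[[i]])), 0L)
  }
  expect_equal(vapply(res$records, function(r) length(r$trees), 0L),
               as.integer(res$sim_num_trees))
  expect_equal(vapply(res$records, num_topology_breakpoints, 0L),
               as.integer(res$sim_num_trees) - 1L)
  ## genotype matrices parse alongside
  expect_length(res$genotypes, 150L)
  ## every replicate with segregating sites has one row per haplotype
  rows <- vapply(res$genotypes, function(g) nrow(g$alleles), 0L)
  cols <- vapply(res$genotypes, function(g) ncol(g$alleles), 0L)
  expect_true(all(rows == 10L | cols == 0L))
  expect_gt(sum(cols > 0L), 100L)
})

test_that("higher recombination rates produce more marginal trees", {
  require_sim_backend()
  lo <- sim_recombination(100, recomb_task_config(N_set = 10000, n = 8L,
                                                  r_low = 1e-8, r_high = 10^-7.5),
                          seed = 102, write_ms = FALSE)
  hi <- sim_recombination(100, recomb_task_config(N_set = 10000, n = 8L,
                                                  r_low = 10^-6.5, r_high = 1e-6),
                          seed = 103, write_ms = FALSE)
  expect_gt(mean(hi$sim_num_trees), mean(lo$sim_num_trees))
})

test_that("at the lower rate bound and small N, single-tree replicates occur", {
  require_sim_backend()
  res <- sim_recombination(150, recomb_task_config(N_set = 1000, n = 10L,
                                                   r_low = 1e-8, r_high = 1e-8 + 1e-12),
                           seed = 104, write_ms = FALSE)
  expect_gt(mean(res$sim_num_trees == 1), 0)
})

test_that("pairwise coalescence times match the closed-form expectation 2N", {
  require_sim_backend()
  ## constant-size coalescent, n = 2, negligible recombination: E[TMRCA] = 2N
  ## generations under the diploid-size convention used throughout
  N <- 5000
  res <- sim_recombination(400, recomb_task_config(N_set = N, n = 2L,
                                                   r_low = 1e-12, r_high = 1.0001e-12,
                                                   mu = 1e-9),
                           seed = 105, write_ms = FALSE)
  tmrca <- vapply(res$records, function(r) max(r$trees[[1]]$time), 0)
  mc_sd <- 2 * N / sqrt(length(tmrca))  # TMRCA for n=2 is Exp(mean 2N)
  expect_lt(abs(mean(tmrca) - 2 * N), 3 * mc_sd)
})

test_that("demography draws respect their supports and target layout", {
  require_sim_backend()
  res <- sim_demography(40, demog_task_config(n = 10L, L = 2e4), seed = 106,
                        write_ms = FALSE)
  p <- res$params
  expect_true(all(p$T2 - p$T1 >= 1 & p$T2 - p$T1 <= 3500))
  expect_true(all(p$N0 >= 100 & p$N0 <= 4e4))
  expect_true(all(p$N1 >= 100 & p$N1 <= 5000))
  expect_true(all(p$N2 >= 100 & p$N2 <= 2e4))
  expect_true(all(p$T1 >= 100 & p$T1 <= 3500))
  ## label is the 5-vector in fixed order (N0, T1, N1, T2, N2)
  lab <- res$records[[1]]$label
  expect_length(lab, 5L)
  expect_equal(lab, as.numeric(p[1, c("N0", "T1", "N1", "T2", "N2")]),
               tolerance = 1e-6)
  expect_equal(nrow(validate_record(res$records[[1]])), 0L)
})

test_that("introgression classes are balanced; admixture lowers cross-population divergence", {
  require_sim_backend()
  cfg <- introg_task_config(n1 = 6L, n2 = 6L, N = 1e4, T_split = 4e4,
                            pulse_prop = 0.3, mu = 1e-8, L = 5000)
  res <- sim_introgression(90, cfg, seed = 107)
  labs <- vapply(res$records, `[[`, 0L, "label")
  expect_true(max(table(labs)) - min(table(labs)) <= 1)
  ## records are two-population with k = 2 and F = 5 downstream
  expect_equal(res$records[[1]]$k_populations, 2L)
  ## "none" replicates carry no admixture event in the provenance log
  expect_true(all(res$params$t_mig[res$params$cls == 2] < 0))
  expect_true(all(res$params$t_mig[res$params$cls != 2] > 0))
  ## mean between-population difference: admixed < none
  cross_div <- vapply(seq_along(res$genotypes), function(i) {
    g <- res$genotypes[[i]]$alleles
    if (ncol(g) == 0) return(NA_real_)
    a <- g[1:cfg$n1, , drop = FALSE]
    b <- g[cfg$n1 + 1:cfg$n2, , drop = FALSE]
    mean(outer(seq_len(nrow(a)), seq_len(nrow(b)),
               Vectorize(function(x, y) sum(a[x, ] != b[y, ]))))
  }, 0)
  expect_lt(mean(cross_div[labs != 2], na.rm = TRUE),
            mean(cross_div[labs == 2], na.rm = TRUE))
})

test_that("sweep ingestion validates the five-class manifest and the central-subwindow rule", {
  ms <- c("//", "segsites: 2", "positions: 0.4 0.6", "01", "10", "11", "")
  ms5 <- rep(ms, 5)
  msf <- tempfile(); writeLines(ms5, msf)
  man <- data.frame(replicate = 1:5,
                    label = c("hard", "hard-linked", "soft", "soft-linked", "neutral"),
                    sel_pos = c(0.5, 0.05, 0.52, 0.95, NA))
  mf <- tempfile()
  write.table(man, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- ingest_sweep_dataset(msf, mf, sweep_task_spec(), L = 1.1e6)
  expect_length(ds$genotypes, 5L)
  expect_equal(ds$labels, 0:4)
  expect_equal(attr(ds, "downsample_mode"), "span_weighted")
  ## selected site in the central 1/11 must be a sweep class
  man_bad <- man
  man_bad$label[1] <- "hard-linked"  # central site labeled linked
  write.table(man_bad, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(ingest_sweep_dataset(msf, mf, sweep_task_spec(), L = 1.1e6),
               "central")
  ## a selected site outside the central subwindow must be a linked class
  man_bad2 <- man
  man_bad2$label[2] <- "hard"
  write.table(man_bad2, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(ingest_sweep_dataset(msf, mf, sweep_task_spec(), L = 1.1e6),
               "not central")
  ## a manifest missing one of the five classes is rejected
  man_miss <- man
  man_miss$label[5] <- "hard"
  man_miss$sel_pos[5] <- 0.5
  write.table(man_miss, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(ingest_sweep_dataset(msf, mf, sweep_task_spec(), L = 1.1e6),
               "missing")
  ## replicate/manifest count mismatch
  write.table(man[1:4, ], mf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(ingest_sweep_dataset(msf, mf, sweep_task_spec(), L = 1.1e6),
               "replicates|missing")
})

test_that("the inference adapter refuses to run silently without the external tool", {
  gm <- genotype_matrix(rbind(c(0L, 1L), c(1L, 0L)), c(10, 20))
  if (!nzchar(Sys.which("Relate"))) {
    expect_error(infer_trees_adapter(gm, L = 100, mean_mu = 1e-8,
                                     mean_r = 1e-8, mean_N = 1e4),
                 "external tool unavailable: Relate")
  } else {
    rec <- infer_trees_adapter(gm, L = 100, mean_mu = 1e-8, mean_r = 1e-8,
                               mean_N = 1e4)
    expect_equal(rec$provenance, "inferred")
    expect_equal(nrow(validate_record(rec)), 0L)
  }
  ## a nonexistent tool name is also reported explicitly
  expect_error(infer_trees_adapter(gm, L = 100, mean_mu = 1e-8, mean_r = 1e-8,
                                   mean_N = 1e4, tool = "no-such-binary-xyz"),
               "external tool unavailable")
})

test_that("fixtures are deterministic, valid, and include the worked example", {
  f1 <- make_fixtures(seed = 3)
  f2 <- make_fixtures(seed = 3)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  for (nm in names(f1)) expect_equal(nrow(validate_record(f1[[nm]])), 0L)
  expect_equal(tree_summary(f1$twoLeaf10$trees[[1]], f1$twoLeaf10$sequence_length),
               c(10, 10, 10, 0, 10, 10, 0, 0, 10, 0.5, 1.0, 20))
})

test_that("replicate order is exchangeable for downstream statistics", {
  recs <- tsgcn:::with_seed(55, replicate(10, tsgcn:::random_record(4L, 3L, L = 100),
                                          simplify = FALSE))
  st1 <- suppressWarnings(fit_normalization(recs))
  st2 <- suppressWarnings(fit_normalization(rev(recs)))
  expect_equal(st1$tree$mean, st2$tree$mean, tolerance = 1e-12)
  expect_equal(st1$logage, st2$logage, tolerance = 1e-12)
})
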
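test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(missing_rate = 1.5), "probabilities")
  expect_error(sim_config(fst_neutral = 1), "fst")
  expect_error(sim_config(n_outlier_loci = 10, fst_neutral = 0.3,
                          fst_outlier = 0.2), "exceed")
  expect_error(sim_config(n_pops = 3, n_outlier_loci = 5, origin_effect = TRUE,
                          pop_labels = c("VA-B", "VA-W", "RI-B")),
               "2-origin x 2-state")
})

test_that("F -> 0 limit: population frequencies equal the ancestral frequency", {
  cfg <- sim_config(n_neutral_loci = 50, n_outlier_loci = 0, fst_neutral = 0,
                    clone_pairs = 0, missing_rate = 0, seed = 3)
  sim <- simulate_genotypes(cfg)
  tr <- sim$truth$loci
  for (p in cfg$pop_labels)
    expect_equal(tr[[paste0("freq_", p)]], tr$ancestral_freq)
})

test_that("planted clone pair is an exact copy at clone_error_rate 0", {
  cfg <- sim_config(n_neutral_loci = 100, n_outlier_loci = 0,
                    clone_pairs = 1, clone_error_rate = 0, missing_rate = 0,
                    seed = 4)
  sim <- simulate_genotypes(cfg)
  cl <- sim$truth$clones
  expect_equal(nrow(cl), 1L)
  expect_true(all(c(cl$donor, cl$ramet) %in% gm_samples(sim$gm)))
  expect_identical(sim$gm$calls[cl$donor, ], sim$gm$calls[cl$ramet, ])
})

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_neutral_loci = 80, n_outlier_loci = 10,
                    fst_neutral = 0.05, fst_outlier = 0.4, seed = 9)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$gm$calls, s2$gm$calls)
  expect_identical(s1$gm$depth, s2$gm$depth)
  expect_identical(s1$truth$loci, s2$truth$loci)
})

test_that("truth table covers every locus once; clone refs exist", {
  cfg <- sim_config(n_neutral_loci = 60, n_outlier_loci = 15,
                    fst_neutral = 0.02, fst_outlier = 0.4, seed = 5)
  sim <- simulate_genotypes(cfg)
  expect_identical(sim$truth$loci$locus_id, gm_loci(sim$gm))
  expect_equal(sum(sim$truth$loci$is_outlier), 15L)
  expect_true(all(sim$truth$clones$donor %in% gm_samples(sim$gm)))
})

test_that("sample frequencies converge to truth frequencies at large n", {
  cfg <- sim_config(n_ind_per_pop = 500, n_neutral_loci = 300,
                    n_outlier_loci = 0, fst_neutral = 0.1, clone_pairs = 0,
                    missing_rate = 0.02, seed = 6)
  sim <- simulate_genotypes(cfg)
  pops <- pop_labels(sim$gm, sim$pm)
  devs <- sapply(cfg$pop_labels, function(p) {
    sub <- sim$gm$calls[pops == p, , drop = FALSE]
    obs <- colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
    abs(obs - sim$truth$loci[[paste0("freq_", p)]])
  })
  expect_gt(mean(devs < 0.05), 0.99)
})

test_that("depth follows the negative-binomial model and missingness the rate", {
  cfg <- sim_config(n_neutral_loci = 800, n_outlier_loci = 0, clone_pairs = 0,
                    missing_rate = 0.08, mean_depth = 25, depth_dispersion = 4,
                    seed = 7)
  sim <- simulate_genotypes(cfg)
  expect_equal(mean(is.na(sim$gm$calls)), 0.08, tolerance = 0.05)
  d <- sim$gm$depth[!is.na(sim$gm$calls)]  # untouched by the missingness zeroing
  expect_equal(mean(d), 25, tolerance = 0.02)
  expect_gt(stats::var(d) / mean(d), 2)  # overdispersed vs Poisson
})

test_that("POD with identity covariance and fixed pi gives centered draws", {
  pod <- simulate_pod(diag(4), 0.5, c(a = 30, b = 30, c = 30, d = 30),
                      n_loci = 400, seed = 11)
  pops <- pop_labels(pod$gm, pod$pm)
  freqs <- sapply(unique(pops), function(p) {
    sub <- pod$gm$calls[pops == p, , drop = FALSE]
    colMeans(sub) / 2
  })
  expect_equal(unname(colMeans(freqs)), rep(0.5, 4), tolerance = 0.06)
  ## determinism
  pod2 <- simulate_pod(diag(4), 0.5, c(a = 30, b = 30, c = 30, d = 30),
                       n_loci = 400, seed = 11)
  expect_identical(pod$gm$calls, pod2$gm$calls)
})

test_that("POD rejects invalid models", {
  om <- matrix(c(1, 2, 2, 1), 2, 2)   # symmetric but not PSD
  expect_error(simulate_pod(om, 0.5, c(10, 10), 10), "semi-definite")
  expect_error(simulate_pod(diag(2), 0.5, c(10, 0), 10), "positive")
})

test_that("POD fitted to neutral data reproduces its XtX scale", {
  cfg <- sim_config(n_ind_per_pop = 10, n_neutral_loci = 5000,
                    n_outlier_loci = 0, fst_neutral = 0.05, clone_pairs = 0,
                    missing_rate = 0.03, seed = 12)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  sc <- xtx(sim$gm, sim$pm, m)
  pod <- pod_calibrate(sim$gm, sim$pm, m, n_pod_loci = 5000, seed = 13)
  expect_equal(mean(pod$pod_xtx), mean(sc$xtx), tolerance = 0.1)
})

test_that("outlier separation: outlier mean XtX exceeds neutral mean XtX", {
  cfg <- sim_config(n_neutral_loci = 1500, n_outlier_loci = 50,
                    fst_neutral = 0.05, fst_outlier = 0.4, clone_pairs = 0,
                    seed = 14)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  sc <- xtx(sim$gm, sim$pm, m)
  expect_gt(mean(sc$xtx[sim$truth$loci$is_outlier]),
            mean(sc$xtx[!sim$truth$loci$is_outlier]))
})

test_that("fixture bundle is complete, consistent and deterministic", {
  cfg <- sim_config(n_neutral_loci = 120, n_outlier_loci = 10,
                    fst_neutral = 0.02, fst_outlier = 0.4, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- write_fixture_bundle(cfg, d1)
  b2 <- write_fixture_bundle(cfg, d2)
  expect_identical(b1$manifest$md5, b2$manifest$md5)

  gm <- read_vcf(b1$paths$vcf)
  n_expected <- cfg$n_pops * cfg$n_ind_per_pop + cfg$clone_pairs
  expect_equal(nrow(gm$calls), n_expected)

  ## every host-labelled contig satisfies the host rule and not clean-sym
  hits <- do.call(rbind, lapply(
    c("dirty_coral", "dirty_sym", "clean_coral", "clean_sym",
      "rRNA_LSU", "rRNA_SSU"),
    function(db) read_blast_hits(b1$paths[[paste0("blast_", db)]], db)))
  tc <- b1$truth$contigs
  assign <- assign_compartments(
    stats::setNames(tc$length, tc$contig), hits)
  merged <- merge(assign, tc, by = "contig")
  expect_identical(merged$label, merged$truth_label)
})

test_that("fixture VCF round-trips the simulated matrix", {
  cfg <- sim_config(n_neutral_loci = 90, n_outlier_loci = 0, seed = 22)
  d <- withr::local_tempdir()
  b <- write_fixture_bundle(cfg, d)
  gm <- read_vcf(b$paths$vcf)
  sim <- simulate_genotypes(cfg)
  host_cols <- seq_len(ncol(sim$gm$calls))
  expect_identical(gm$calls[, host_cols], sim$gm$calls)
  expect_identical(gm$depth[, host_cols], sim$gm$depth)
})
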
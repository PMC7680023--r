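test_that("omega: centered-residual structure, shared drift, order invariance", {
  # independent populations: centering by the cross-population mean makes
  # E[omega] proportional to I - 11'/J, i.e. equal diagonal and off-diagonal
  # terms of -diag/(J-1)
  cfg <- sim_config(n_ind_per_pop = 30, n_neutral_loci = 4000,
                    n_outlier_loci = 0, fst_neutral = 0.3, clone_pairs = 0,
                    missing_rate = 0, seed = 51)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  dg <- diag(m$omega)
  off <- m$omega[upper.tri(m$omega)]
  expect_lt(max(dg) / min(dg), 1.3)              # exchangeable populations
  expect_true(all(off < 0))
  expect_equal(mean(off) / mean(dg), -1 / 3, tolerance = 0.15)
  # locus-order invariance
  perm <- withr::with_seed(1, sample(ncol(sim$gm$calls)))
  m2 <- estimate_omega(gm_subset(sim$gm, loci = perm), sim$pm)
  expect_equal(m$omega, m2$omega, tolerance = 1e-12)

  # shared drift: two of four populations given identical frequency draws
  # show a distinctly elevated off-diagonal entry
  cfg2 <- sim_config(n_ind_per_pop = 30, n_neutral_loci = 3000,
                     n_outlier_loci = 0, fst_neutral = 0.2, clone_pairs = 0,
                     missing_rate = 0, seed = 52)
  sim2 <- simulate_genotypes(cfg2)
  tr <- sim2$truth$loci
  calls <- sim2$gm$calls
  pops <- pop_labels(sim2$gm, sim2$pm)
  withr::with_seed(53, {
    # re-draw VA-W's genotypes from VA-B's latent frequencies: shared drift
    for (i in which(pops == "VA-W"))
      calls[i, ] <- rbinom(ncol(calls), 2L, tr$`freq_VA-B`)
  })
  gm2 <- geno_matrix(calls, sim2$gm$loci)
  mshared <- estimate_omega(gm2, sim2$pm)
  o <- mshared$omega
  shared_cov <- o["VA-B", "VA-W"]
  other_off <- o[upper.tri(o)]
  other_off <- other_off[other_off != shared_cov]
  expect_gt(shared_cov, max(other_off) + 0.5 * abs(max(other_off)))

  # brute-force oracle for the raw (uncorrected) covariance
  pmat <- sapply(unique(pops), function(p)
    colMeans(gm2$calls[pops == p, , drop = FALSE]) / 2)
  pi_l <- rowMeans(pmat)
  keep <- pi_l > 0 & pi_l < 1
  zb <- (pmat[keep, ] - pi_l[keep]) / sqrt(pi_l[keep] * (1 - pi_l[keep]))
  bf_omega <- crossprod(zb) / sum(keep)
  expect_equal(unname(mshared$omega_raw),
               unname(bf_omega[unique(pops), unique(pops)]), tolerance = 1e-8)
})

test_that("estimate_omega errors on degenerate input", {
  calls <- matrix(c(0L, 0L, 2L, 2L), 4, 1,
                  dimnames = list(sprintf("s%d", 1:4), NULL))
  gm <- geno_matrix(calls, data.frame(contig = "c", pos = 1L, ref = "A",
                                      alt = "T", stringsAsFactors = FALSE))
  pm <- pop_map(sprintf("s%d", 1:4), rep(c("VA", "RI"), each = 2), "B")
  expect_error(estimate_omega(gm, pm), "fewer than 2")
})

test_that("xtx: zero residual, identity-omega closed form, monomorphic flag", {
  gm <- random_gm(n = 20, L = 100, miss = 0, seed = 55)
  pm <- random_pm(gm, n_pops = 4, seed = 55)
  model <- estimate_omega(gm, pm)
  # identity omega: XtX reduces to the per-locus sum of squared residuals
  model_id <- list(omega = diag(length(model$pop_labels)),
                   pop_labels = model$pop_labels)
  dimnames(model_id$omega) <- dimnames(model$omega)
  sc <- xtx(gm, pm, model_id)
  pops <- pop_labels(gm, pm)
  bf <- sapply(seq_len(ncol(gm$calls)), function(l) {
    p <- sapply(unique(pops), function(pp)
      mean(gm$calls[pops == pp, l]) / 2)
    pi <- mean(p)
    if (pi == 0 || pi == 1) return(0)
    sum(((p - pi) / sqrt(pi * (1 - pi)))^2)
  })
  expect_equal(sc$xtx, bf, tolerance = 1e-10)
  # equal frequencies across populations -> zero
  calls <- matrix(rep(c(0L, 1L, 1L, 2L), 4), 16, 2,
                  dimnames = list(sprintf("s%02d", 1:16), NULL))
  gm0 <- geno_matrix(calls, data.frame(contig = "c", pos = 1:2, ref = "A",
                                       alt = "T", stringsAsFactors = FALSE))
  pm0 <- pop_map(rownames(calls), rep(c("VA", "RI"), each = 8), "B")
  m0 <- list(omega = diag(2), pop_labels = c("VA-B", "RI-B"))
  sc0 <- xtx(gm0, pm0, m0)
  expect_equal(sc0$xtx, c(0, 0))
  # monomorphic loci flagged with XtX 0
  callsm <- cbind(calls[, 1], rep(0L, 16))
  rownames(callsm) <- rownames(calls)
  gmm <- geno_matrix(callsm, data.frame(contig = "c", pos = 1:2, ref = "A",
                                        alt = "T", stringsAsFactors = FALSE))
  scm <- xtx(gmm, pm0, m0)
  expect_true(scm$monomorphic[2])
  expect_equal(scm$xtx[2], 0)
})

test_that("population relabeling permutes omega and leaves XtX unchanged", {
  cfg <- sim_config(n_neutral_loci = 500, n_outlier_loci = 20,
                    fst_neutral = 0.05, fst_outlier = 0.4, clone_pairs = 0,
                    seed = 56)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  sc <- xtx(sim$gm, sim$pm, m)
  # reorder samples so populations appear in a different order
  perm <- withr::with_seed(2, sample(nrow(sim$gm$calls)))
  gmp <- gm_subset(sim$gm, samples = perm)
  mp <- estimate_omega(gmp, sim$pm)
  scp <- xtx(gmp, sim$pm, mp)
  expect_equal(scp$xtx, sc$xtx, tolerance = 1e-8)
  expect_equal(mp$omega[m$pop_labels, m$pop_labels], m$omega,
               tolerance = 1e-8)
})

test_that("pod threshold quantile conventions", {
  fake <- list(threshold = NA)
  x <- 1:1000
  expect_equal(as.numeric(quantile(x, 1 - 0.005, type = 7)), 995.005)
  # the calibrator uses exactly this convention
  cfg <- sim_config(n_neutral_loci = 300, n_outlier_loci = 0,
                    fst_neutral = 0.05, clone_pairs = 0, seed = 57)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  pod <- pod_calibrate(sim$gm, sim$pm, m, n_pod_loci = 1000, fdr = 0.005,
                       seed = 3)
  expect_equal(pod$threshold,
               as.numeric(quantile(pod$pod_xtx, 0.995, type = 7)))
  pod_all <- pod_calibrate(sim$gm, sim$pm, m, n_pod_loci = 500, fdr = 1,
                           seed = 3)
  expect_equal(pod_all$threshold, min(pod_all$pod_xtx))
})

test_that("classification is strict exceedance and partitions loci", {
  sc <- data.frame(locus_id = c("a", "b", "c"), xtx = c(1, 2, 3),
                   monomorphic = FALSE, stringsAsFactors = FALSE)
  cl <- classify_outliers(sc, 2)
  expect_equal(cl$class, c("neutral", "neutral", "high_outlier"))
  expect_error(classify_outliers(sc, Inf), "finite")
  cl0 <- classify_outliers(sc, 10)
  expect_true(all(cl0$class == "neutral"))
})

test_that("neutral-only null calibration: exceedance fraction near fdr", {
  cfg <- sim_config(n_neutral_loci = 5000, n_outlier_loci = 0,
                    fst_neutral = 0.02, clone_pairs = 0, seed = 58)
  sim <- simulate_genotypes(cfg)
  m <- estimate_omega(sim$gm, sim$pm)
  sc <- xtx(sim$gm, sim$pm, m)
  pod <- pod_calibrate(sim$gm, sim$pm, m, n_pod_loci = 10000, seed = 59)
  frac <- mean(sc$xtx > pod$threshold)
  expect_gte(frac, 0)
  expect_lte(frac, 0.02)
})
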
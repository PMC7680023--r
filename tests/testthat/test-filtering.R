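test_that("low-depth recoding masks exactly the sub-threshold genotypes", {
  gm <- random_gm(n = 10, L = 50, miss = 0.1, seed = 11)
  gm$depth[2, 3] <- 4L; gm$depth[5, 7] <- 5L
  out <- recode_low_depth(gm, 5)
  mask <- !is.na(gm$depth) & gm$depth < 5
  expect_true(all(is.na(out$calls[mask])))
  expect_identical(out$calls[!mask], gm$calls[!mask])
  expect_identical(recode_low_depth(gm, 0)$calls, gm$calls)
  gm$depth <- NULL
  expect_error(recode_low_depth(gm, 5), "depth")
})

test_that("basic site filter boundaries: QUAL, mac, indels, multiallelics", {
  calls <- matrix(rep(c(0L, 1L, 1L, 2L, 0L, 0L), 5), 6, 5)
  rownames(calls) <- sprintf("s%d", 1:6)
  loci <- data.frame(contig = "c", pos = 1:5, ref = c("A", "A", "AT", "A", "A"),
                     alt = c("T", "T", "T", "T", "T"),
                     multiallelic = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  gm <- geno_matrix(calls, loci, qual = c(30, 30.1, 99, 99, 99))
  out <- filter_sites_basic(gm, filter_params())
  # locus 1: QUAL exactly 30 fails "above 30"; locus 3 indel; locus 4 multiallelic
  expect_equal(gm_loci(out), c("c_2", "c_5"))
  # mac boundary: 4 alt alleles among 6 individuals (mac 4 >= 3) kept;
  # a site with 2 alt alleles (mac 2) removed
  calls2 <- cbind(c(0L, 0L, 0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L, 0L, 2L))
  rownames(calls2) <- sprintf("s%d", 1:6)
  gm2 <- geno_matrix(calls2, data.frame(contig = "c", pos = 1:2, ref = "A",
                                        alt = "T", stringsAsFactors = FALSE),
                     qual = c(99, 99))
  out2 <- filter_sites_basic(gm2, filter_params())
  expect_equal(gm_loci(out2), character(0))
  gm3 <- gm2; gm3$calls[1, ] <- 1L  # now mac 3 at both sites
  expect_equal(gm_loci(filter_sites_basic(gm3, filter_params())),
               c("c_1", "c_2"))
})

test_that("individual missingness threshold is strict", {
  calls <- matrix(0L, 4, 100, dimnames = list(sprintf("s%d", 1:4), NULL))
  calls[1, 1:51] <- NA   # 51% missing: dropped at 0.50
  calls[2, 1:50] <- NA   # exactly 50%: kept
  gm <- geno_matrix(calls, data.frame(contig = "c", pos = 1:100, ref = "A",
                                      alt = "T", stringsAsFactors = FALSE))
  out <- filter_individuals(gm, 0.50)
  expect_equal(gm_samples(out), c("s2", "s3", "s4"))
  calls[] <- NA
  gm_all <- geno_matrix(calls, gm$loci)
  expect_error(filter_individuals(gm_all, 0.5), "all individuals")
})

test_that("secondary site filter: missingness, maf and mean depth boundaries", {
  n <- 20
  calls <- matrix(1L, n, 4, dimnames = list(sprintf("s%d", 1:n), NULL))
  calls[1:16, 1] <- NA                      # 80% missing: removed
  calls[, 2] <- c(rep(0L, 18), 1L, 1L)      # maf = 2/40 = 0.05: kept
  calls[, 3] <- c(rep(0L, 19), 1L)          # maf = 1/40 < 0.05: removed
  depth <- matrix(20L, n, 4)
  depth[, 4] <- c(rep(10L, n - 1), 9L)      # mean 9.95 < 10: removed
  gm <- geno_matrix(calls, data.frame(contig = "c", pos = 1:4, ref = "A",
                                      alt = "T", stringsAsFactors = FALSE),
                    depth = depth)
  out <- filter_sites_secondary(gm, filter_params())
  expect_equal(gm_loci(out), "c_2")
})

test_that("HWE exact test matches the enumeration oracle and its boundaries", {
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  expect_equal(hwe_exact_test(2, 8, 0), enum_hwe_p(2, 8, 0))
  # frozen oracle values
  expect_equal(hwe_exact_test(5, 0, 5), enum_hwe_p(5, 0, 5))
  expect_equal(hwe_exact_test(0, 10, 0), enum_hwe_p(0, 10, 0))
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
})

test_that("per-population HWE filter removes multi-population violations only", {
  # pop1 wildly out of HWE (all het), pop2 in HWE at locus 1;
  # both pops out of HWE at locus 2
  calls <- cbind(c(rep(1L, 10), c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L)),
                 rep(1L, 20))
  rownames(calls) <- sprintf("s%02d", 1:20)
  gm <- geno_matrix(calls, data.frame(contig = "c", pos = 1:2, ref = "A",
                                      alt = "T", stringsAsFactors = FALSE))
  pm <- pop_map(rownames(calls), origin = rep(c("VA", "RI"), each = 10),
                state = "B")
  p1 <- hwe_exact_test(0, 10, 0)
  expect_lt(p1, 0.01)   # sanity: the all-het pop violates
  out <- hwe_filter_by_pop(gm, pm, p_cutoff = 0.01, pop_fraction = 0.5)
  expect_equal(gm_loci(out), "c_1")
})

test_that("thinning keeps exactly one random SNP per contig, deterministically", {
  gm <- random_gm(n = 6, L = 40, seed = 13)
  t1 <- thin_one_snp_per_contig(gm, seed = 5)
  t2 <- thin_one_snp_per_contig(gm, seed = 5)
  expect_identical(gm_loci(t1), gm_loci(t2))
  expect_equal(ncol(t1$calls), length(unique(gm$loci$contig)))
  expect_equal(anyDuplicated(t1$loci$contig), 0L)
  # identity when already thinned
  t3 <- thin_one_snp_per_contig(t1, seed = 99)
  expect_identical(gm_loci(t3), gm_loci(t1))
  # mechanism on truth: thinned counts equal distinct contig counts per class
  cfg <- sim_config(n_neutral_loci = 200, n_outlier_loci = 40,
                    fst_neutral = 0.02, fst_outlier = 0.4, seed = 17)
  sim <- simulate_genotypes(cfg)
  tr <- sim$truth$loci
  for (cls in c(TRUE, FALSE)) {
    sub <- gm_subset(sim$gm, loci = which(tr$is_outlier == cls))
    th <- thin_one_snp_per_contig(sub, seed = 1)
    expect_equal(ncol(th$calls), length(unique(tr$contig_id[tr$is_outlier == cls])))
  }
})

test_that("cascade equals brute-force predicates, is idempotent and order-invariant", {
  params <- filter_params()
  for (seed in 1:6) {
    gm <- random_gm(n = sample(8:20, 1), L = sample(50:200, 1),
                    miss = runif(1, 0, 0.3), seed = seed)
    pm <- random_pm(gm, n_pops = 2, seed = seed)
    res <- run_cascade(gm, pm, params)
    # oracle: replay the steps with independent predicates
    g <- recode_low_depth(gm, params$depth_min_genotype)
    g <- gm_subset(g, loci = which(bf_site_keep_basic(g, params)))
    g <- gm_subset(g, samples = which(bf_ind_keep(g, params$ind_missing_1)))
    g <- gm_subset(g, samples = which(bf_ind_keep(g, params$ind_missing_2)))
    g <- gm_subset(g, loci = which(bf_site_keep_secondary(g, params)))
    # step 4 (HWE) uses the package's exact test, itself oracle-checked above
    g <- hwe_filter_by_pop(g, pm, params$hwe_p_cutoff, params$hwe_pop_fraction)
    expect_identical(gm_loci(res$gm), gm_loci(g))
    expect_identical(gm_samples(res$gm), gm_samples(g))
    # idempotence
    res2 <- run_cascade(res$gm, pm, params)
    expect_identical(gm_loci(res2$gm), gm_loci(res$gm))
    expect_identical(gm_samples(res2$gm), gm_samples(res$gm))
    # monotone report
    expect_true(all(res$report$sites_out <= res$report$sites_in))
    expect_true(all(diff(res$report$sites_in) <= 0))
    # permuting sample order leaves the surviving site set unchanged
    perm <- withr::with_seed(seed, sample(nrow(gm$calls)))
    gmp <- gm_subset(gm, samples = perm)
    resp <- run_cascade(gmp, pm, params)
    expect_identical(gm_loci(resp$gm), gm_loci(res$gm))
  }
})
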
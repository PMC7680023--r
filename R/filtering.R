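#' Parameters of the four-step variant filter cascade
#'
#' Defaults reproduce a conservative transcriptome-SNP filtering recipe:
#' step 1 recodes genotypes with fewer than 5 reads as missing, keeps sites
#' with QUAL strictly above 30, biallelic SNPs only, no indels, minor
#' allele count >= 3, and drops individuals with more than 50% missing
#' data; step 2 drops individuals with more than 85% missing data; step 3
#' keeps sites with at most 75% missing data, minor allele frequency
#' >= 0.05 and mean depth across retained individuals >= 10; step 4
#' removes sites out of Hardy-Weinberg equilibrium (exact-test p < 0.01)
#' in more than half of the populations.
#'
#' @param ind_missing_1 individual missingness cap, step 1 (strict >).
#' @param mac_min minimum minor allele count (>=), step 1. Set
#'   `mac_literal_exclude = TRUE` to instead *exclude* sites with mac >= 3
#'   (a literal reading of some pipeline descriptions; not the default).
#' @param qual_min site QUAL floor, exclusive.
#' @param depth_min_genotype genotypes with fewer reads are set missing.
#' @param biallelic_only,drop_indels flags for step 1 site rules.
#' @param ind_missing_2 individual missingness cap, step 2 (strict >).
#' @param site_missing_max site missingness cap, step 3 (inclusive <=).
#'   Set `site_missing_as_callrate = TRUE` to require call rate >= 1 -
#'   site_missing_max instead (the inverted flag convention some tools use).
#' @param maf_min minimum minor allele frequency (>=), step 3.
#' @param mean_depth_min minimum mean depth across individuals (>=), step 3.
#' @param hwe_p_cutoff exact-test p-value floor, step 4 (strict <).
#' @param hwe_pop_fraction remove a site when it violates HWE in more than
#'   this fraction of evaluable populations.
#' @param mac_literal_exclude,site_missing_as_callrate alternate readings,
#'   see above.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(ind_missing_1 = 0.50, mac_min = 3, qual_min = 30,
                          depth_min_genotype = 5, biallelic_only = TRUE,
                          drop_indels = TRUE, ind_missing_2 = 0.85,
                          site_missing_max = 0.75, maf_min = 0.05,
                          mean_depth_min = 10, hwe_p_cutoff = 0.01,
                          hwe_pop_fraction = 0.5,
                          mac_literal_exclude = FALSE,
                          site_missing_as_callrate = FALSE) {
  p <- as.list(environment())
  fr <- c(p$ind_missing_1, p$ind_missing_2, p$site_missing_max, p$maf_min,
          p$hwe_p_cutoff, p$hwe_pop_fraction)
  if (any(fr < 0 | fr > 1)) stop_holopop("fractions must lie in [0,1]")
  if (p$mac_min < 0 || p$depth_min_genotype < 0)
    stop_holopop("counts must be non-negative")
  class(p) <- "filter_params"
  p
}

#' Recode low-depth genotypes as missing
#'
#' @param gm a [geno_matrix()] with depth data.
#' @param min_depth genotypes with depth < min_depth (strict) become NA.
#' @return a [geno_matrix()].
#' @export
recode_low_depth <- function(gm, min_depth = 5) {
  if (min_depth <= 0) return(gm)
  if (is.null(gm$depth))
    stop_holopop("no depth data: read DP from the VCF or set depth_min_genotype = 0")
  low <- !is.na(gm$depth) & gm$depth < min_depth
  gm$calls[low] <- NA_integer_
  gm
}

site_allele_stats <- function(calls) {
  n_called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  total <- 2 * n_called
  mac <- pmin(alt, total - alt)
  maf <- ifelse(total > 0, mac / total, 0)
  list(n_called = n_called, mac = mac, maf = maf, total = total)
}

#' Step-1 site filters: quality, biallelic SNPs, indels, minor allele count
#'
#' @param gm a [geno_matrix()] (after low-depth recoding).
#' @param params a [filter_params()].
#' @return a [geno_matrix()] with surviving sites.
#' @export
filter_sites_basic <- function(gm, params = filter_params()) {
  keep <- rep(TRUE, ncol(gm$calls))
  if (!is.null(gm$qual) && params$qual_min > -Inf)
    keep <- keep & !is.na(gm$qual) & gm$qual > params$qual_min
  if (params$biallelic_only)
    keep <- keep & !gm$loci$multiallelic
  if (params$drop_indels)
    keep <- keep & nchar(gm$loci$ref) == 1L & nchar(gm$loci$alt) == 1L &
      gm$loci$ref != "-" & gm$loci$alt != "-"
  st <- site_allele_stats(gm$calls)
  if (params$mac_min > 0) {
    keep <- keep & if (params$mac_literal_exclude)
      st$mac < params$mac_min else st$mac >= params$mac_min
  }
  gm_subset(gm, loci = which(keep))
}

#' Drop individuals exceeding a missingness threshold
#'
#' @param gm a [geno_matrix()].
#' @param max_missing_fraction drop samples with missing fraction strictly
#'   above this value.
#' @return a [geno_matrix()].
#' @export
filter_individuals <- function(gm, max_missing_fraction) {
  frac <- rowMeans(is.na(gm$calls))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop_holopop("all individuals exceed the missingness threshold")
  gm_subset(gm, samples = which(keep))
}

#' Step-3 site filters: missingness, minor allele frequency, mean depth
#'
#' @param gm a [geno_matrix()] (individuals already filtered).
#' @param params a [filter_params()].
#' @return a [geno_matrix()].
#' @export
filter_sites_secondary <- function(gm, params = filter_params()) {
  n <- nrow(gm$calls)
  miss <- colMeans(is.na(gm$calls))
  keep <- if (params$site_missing_as_callrate)
    (1 - miss) >= (1 - params$site_missing_max) else miss <= params$site_missing_max
  st <- site_allele_stats(gm$calls)
  keep <- keep & st$maf >= params$maf_min
  if (!is.null(gm$depth) && params$mean_depth_min > 0) {
    mean_dp <- colMeans(gm$depth, na.rm = TRUE)
    keep <- keep & mean_dp >= params$mean_depth_min
  }
  gm_subset(gm, loci = which(keep))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on diploid genotype counts: conditional on the
#' allele counts, enumerate every heterozygote count of matching parity,
#' compute its probability under random mating, and sum the probabilities
#' not exceeding that of the observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop_holopop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop_holopop("no genotypes")
  n_a <- 2 * n_hom_ref + n_het   # ref allele copies
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)       # monomorphic: single configuration
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  if (is.na(p_obs)) stop_holopop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Step-4: remove sites out of HWE within populations
#'
#' A site is removed when the exact-test p-value falls below `p_cutoff` in
#' strictly more than `pop_fraction` of the populations where the test is
#' evaluable (at least 2 genotyped individuals).
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param p_cutoff exact-test p floor (strict <), default 0.01.
#' @param pop_fraction violating-population fraction, default 0.5.
#' @return a [geno_matrix()].
#' @export
hwe_filter_by_pop <- function(gm, pm, p_cutoff = 0.01, pop_fraction = 0.5) {
  pops <- pop_labels(gm, pm)
  L <- ncol(gm$calls)
  viol <- integer(L); evaluable <- integer(L)
  for (p in unique(pops)) {
    sub <- gm$calls[pops == p, , drop = FALSE]
    n0 <- colSums(sub == 0L, na.rm = TRUE)
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    n2 <- colSums(sub == 2L, na.rm = TRUE)
    ok <- (n0 + n1 + n2) >= 2L
    pv <- rep(NA_real_, L)
    for (l in which(ok)) pv[l] <- hwe_exact_test(n0[l], n1[l], n2[l])
    evaluable <- evaluable + ok
    viol <- viol + (ok & !is.na(pv) & pv < p_cutoff)
  }
  keep <- evaluable == 0L | viol <= pop_fraction * evaluable
  gm_subset(gm, loci = which(keep))
}

#' Thin to one random SNP per contig
#'
#' Linked SNPs on one assembly contig are not independent; downstream
#' structure/diversity analyses therefore retain a single uniformly random
#' SNP per contig.
#'
#' @param gm a [geno_matrix()].
#' @param seed integer seed for reproducible choice.
#' @return a [geno_matrix()] with one locus per contig.
#' @export
thin_one_snp_per_contig <- function(gm, seed = 1L) {
  with_seed(seed, {
    idx <- vapply(split(seq_len(ncol(gm$calls)), gm$loci$contig),
                  function(i) if (length(i) == 1L) i else sample(i, 1L),
                  integer(1))
    gm_subset(gm, loci = sort(unname(idx)))
  })
}

#' Run the full four-step filter cascade
#'
#' Order: low-depth recoding and step-1 site rules, individuals > 50%
#' missing; individuals > 85% missing; step-3 site rules; per-population
#' HWE. Every step's before/after counts and removed ids are recorded.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param params a [filter_params()].
#' @return list with `gm` (filtered matrix) and `report` (data.frame, one
#'   row per step: sites/individuals in and out, removed ids collapsed).
#' @export
run_cascade <- function(gm, pm, params = filter_params()) {
  steps <- list()
  note <- function(name, before, after) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name,
      sites_in = ncol(before$calls), sites_out = ncol(after$calls),
      individuals_in = nrow(before$calls), individuals_out = nrow(after$calls),
      removed_sites = paste(setdiff(gm_loci(before), gm_loci(after)), collapse = ","),
      removed_individuals = paste(setdiff(gm_samples(before), gm_samples(after)),
                                  collapse = ","),
      stringsAsFactors = FALSE)
  }
  g0 <- gm
  g1 <- if (params$depth_min_genotype > 0 && !is.null(gm$depth))
    recode_low_depth(g0, params$depth_min_genotype) else g0
  g1 <- filter_sites_basic(g1, params)
  g1 <- filter_individuals(g1, params$ind_missing_1)
  note("step1_basic", g0, g1)
  g2 <- filter_individuals(g1, params$ind_missing_2)
  note("step2_ind_missing", g1, g2)
  g3 <- filter_sites_secondary(g2, params)
  note("step3_site_secondary", g2, g3)
  g4 <- hwe_filter_by_pop(g3, pm, params$hwe_p_cutoff, params$hwe_pop_fraction)
  note("step4_hwe", g3, g4)
  list(gm = g4, report = do.call(rbind, steps))
}

#' Write a filter report as TSV
#' @param report the `report` element of [run_cascade()]'s result.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
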
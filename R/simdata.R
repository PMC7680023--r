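#' Configuration for the synthetic holobiont generator
#'
#' Defines a dual-origin, dual-state sampling design (default four
#' populations VA-B, VA-W, RI-B, RI-W of 10 diploid individuals each) and a
#' two-class locus architecture: neutral loci drifting mildly around a shared
#' ancestral frequency, and outlier loci strongly diverged between origins.
#'
#' Neutral differentiation follows the Balding-Nichols model: for ancestral
#' frequency p and differentiation F, each population's frequency is a draw
#' from Beta(p(1-F)/F, (1-p)(1-F)/F), whose expected Fst equals F. Outlier
#' loci instead take one Balding-Nichols draw per *origin* with F =
#' `fst_outlier`, so both populations of an origin share it: divergence is
#' between origins, not between symbiotic states, mirroring an
#' adaptation-by-origin scenario.
#'
#' @param n_pops number of populations (must be 4 when `origin_effect`).
#' @param n_ind_per_pop diploid individuals per population.
#' @param n_neutral_loci,n_outlier_loci locus counts per class.
#' @param fst_neutral,fst_outlier Balding-Nichols F per class, in [0,1);
#'   `fst_outlier > fst_neutral` required when both are positive.
#' @param origin_effect if TRUE (default), outlier divergence is applied
#'   between origins (VA vs RI) rather than per population.
#' @param missing_rate per-genotype missingness probability (MCAR).
#' @param mean_depth,depth_dispersion negative-binomial read-depth model
#'   (mean and size); depths below a filter threshold are what the
#'   low-depth genotype recoding step exercises.
#' @param clone_pairs number of planted clone pairs (ramets are appended as
#'   extra samples in the clone population).
#' @param clone_error_rate per-allele-copy flip probability for a ramet.
#' @param clone_pop population label receiving the planted clones.
#' @param loci_per_contig mean number of SNPs per contig (>= 1); contig
#'   sizes are 1 + Poisson(loci_per_contig - 1), so one-SNP-per-contig
#'   thinning has work to do.
#' @param pop_labels population labels; parsed as `origin-state`.
#' @param contig_prefix prefix for simulated contig names.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 4,
                       n_ind_per_pop = 10,
                       n_neutral_loci = 1000,
                       n_outlier_loci = 0,
                       fst_neutral = 0.02,
                       fst_outlier = 0.5,
                       origin_effect = TRUE,
                       missing_rate = 0.05,
                       mean_depth = 20,
                       depth_dispersion = 5,
                       clone_pairs = 1,
                       clone_error_rate = 0.01,
                       clone_pop = NULL,
                       loci_per_contig = 3,
                       pop_labels = c("VA-B", "VA-W", "RI-B", "RI-W"),
                       contig_prefix = "contig",
                       seed = 1L) {
  cfg <- list(n_pops = n_pops, n_ind_per_pop = n_ind_per_pop,
              n_neutral_loci = n_neutral_loci, n_outlier_loci = n_outlier_loci,
              fst_neutral = fst_neutral, fst_outlier = fst_outlier,
              origin_effect = origin_effect, missing_rate = missing_rate,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              clone_pairs = clone_pairs, clone_error_rate = clone_error_rate,
              clone_pop = clone_pop, loci_per_contig = loci_per_contig,
              pop_labels = pop_labels[seq_len(n_pops)],
              contig_prefix = contig_prefix, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(missing = cfg$missing_rate, clone_error = cfg$clone_error_rate)
  if (any(probs < 0 | probs > 1))
    stop_holopop("probabilities must lie in [0,1]")
  if (cfg$fst_neutral < 0 || cfg$fst_neutral >= 1 ||
      cfg$fst_outlier < 0 || cfg$fst_outlier >= 1)
    stop_holopop("fst parameters must lie in [0,1)")
  if (cfg$n_outlier_loci > 0 && cfg$fst_outlier > 0 && cfg$fst_neutral > 0 &&
      cfg$fst_outlier <= cfg$fst_neutral)
    stop_holopop("fst_outlier must exceed fst_neutral")
  if (anyNA(cfg$pop_labels) || length(cfg$pop_labels) != cfg$n_pops)
    stop_holopop("need %d population labels", cfg$n_pops)
  origins <- sub("-.*$", "", cfg$pop_labels)
  if (cfg$origin_effect && cfg$n_outlier_loci > 0 &&
      (length(unique(origins)) != 2 || cfg$n_pops != 4))
    stop_holopop("origin_effect requires the 2-origin x 2-state layout (4 populations)")
  if (cfg$loci_per_contig < 1)
    stop_holopop("loci_per_contig must be >= 1")
  invisible(cfg)
}

## one Balding-Nichols draw per (locus, unit); F = 0 degenerates to p itself
rbalding_nichols <- function(p, f) {
  if (f == 0) return(p)
  shape <- (1 - f) / f
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

#' Simulate genotypes under the dual-class holobiont design
#'
#' Draws ancestral frequencies Uniform(0.05, 0.95); population frequencies
#' by Balding-Nichols (see [sim_config()]); genotypes Binomial(2, p_pop);
#' per-genotype depths NegBin(mean, size); MCAR missingness; and appends
#' clone ramets that copy a donor's genotypes with per-allele-copy error.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `gm` (a [geno_matrix()]) and `truth`
#'   (list: `loci` data.frame with `locus_id`, `contig_id`, `is_outlier`,
#'   `ancestral_freq` and one `freq_<pop>` column per population;
#'   `clones` data.frame with `donor`, `ramet`, `pop`).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    J <- cfg$n_pops
    L <- cfg$n_neutral_loci + cfg$n_outlier_loci
    if (L < 1) stop_holopop("need at least one locus")
    is_outlier <- rep(c(FALSE, TRUE), c(cfg$n_neutral_loci, cfg$n_outlier_loci))
    p_anc <- stats::runif(L, 0.05, 0.95)
    origins <- sub("-.*$", "", cfg$pop_labels)

    ## population frequency matrix J x L
    pfreq <- matrix(NA_real_, J, L, dimnames = list(cfg$pop_labels, NULL))
    neu <- which(!is_outlier)
    for (j in seq_len(J))
      pfreq[j, neu] <- rbalding_nichols(p_anc[neu], cfg$fst_neutral)
    out <- which(is_outlier)
    if (length(out)) {
      if (cfg$origin_effect) {
        for (og in unique(origins)) {
          draw <- rbalding_nichols(p_anc[out], cfg$fst_outlier)
          for (j in which(origins == og)) pfreq[j, out] <- draw
        }
      } else {
        for (j in seq_len(J))
          pfreq[j, out] <- rbalding_nichols(p_anc[out], cfg$fst_outlier)
      }
    }

    ## genotypes
    n <- cfg$n_ind_per_pop
    samples <- unlist(lapply(cfg$pop_labels, function(pl)
      sprintf("%s_%02d", gsub("-", "_", pl), seq_len(n))))
    calls <- matrix(NA_integer_, J * n, L, dimnames = list(samples, NULL))
    for (j in seq_len(J)) {
      rows <- (j - 1L) * n + seq_len(n)
      calls[rows, ] <- matrix(stats::rbinom(n * L, 2L, rep(pfreq[j, ], each = n)),
                              n, L)
    }
    pm <- pop_map(samples,
                  origin = rep(origins, each = n),
                  state = rep(sub("^.*-", "", cfg$pop_labels), each = n))

    ## planted clones: extra ramet samples within one population
    clones <- data.frame(donor = character(0), ramet = character(0),
                         pop = character(0), stringsAsFactors = FALSE)
    if (cfg$clone_pairs > 0) {
      ## default clone population mirrors a symbiotic northern-edge site
      clone_pop <- cfg$clone_pop %||%
        (if ("RI-B" %in% cfg$pop_labels) "RI-B" else cfg$pop_labels[J])
      donors_pool <- pm$sample[pm$pop == clone_pop]
      if (cfg$clone_pairs > length(donors_pool))
        stop_holopop("more clone pairs than individuals in %s", clone_pop)
      donors <- sample(donors_pool, cfg$clone_pairs)
      for (d in donors) {
        ramet <- paste0(d, "_clone")
        g <- calls[d, ]
        if (cfg$clone_error_rate > 0) {
          ## flip each of the two allele copies independently
          flips <- matrix(stats::rbinom(2L * L, 1L, cfg$clone_error_rate), 2L, L)
          a1 <- as.integer(g >= 1L); a2 <- as.integer(g == 2L)
          g <- as.integer(abs(a1 - flips[1L, ]) + abs(a2 - flips[2L, ]))
          g[is.na(calls[d, ])] <- NA_integer_
        }
        calls <- rbind(calls, matrix(g, 1L, L, dimnames = list(ramet, NULL)))
        clones <- rbind(clones, data.frame(donor = d, ramet = ramet,
                                           pop = clone_pop, stringsAsFactors = FALSE))
      }
      if (nrow(clones)) {
        pm <- pop_map(c(pm$sample, clones$ramet),
                      c(pm$origin, sub("-.*$", "", clones$pop)),
                      c(pm$state, sub("^.*-", "", clones$pop)))
      }
    }
    n_tot <- nrow(calls)

    ## depth and missingness
    depth <- matrix(stats::rnbinom(n_tot * L, mu = cfg$mean_depth,
                                   size = cfg$depth_dispersion), n_tot, L)
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(n_tot * L) < cfg$missing_rate, n_tot, L)
      calls[miss] <- NA_integer_
      depth[miss] <- 0L
    }

    ## contig layout: contig sizes 1 + Poisson(mean - 1)
    contig_of <- integer(L); k <- 0L; i <- 1L
    while (i <= L) {
      k <- k + 1L
      size <- 1L + stats::rpois(1L, cfg$loci_per_contig - 1)
      contig_of[i:min(L, i + size - 1L)] <- k
      i <- i + size
    }
    contigs <- sprintf("%s%05d", cfg$contig_prefix, contig_of)
    pos <- integer(L)
    for (cid in unique(contig_of)) {
      idx <- which(contig_of == cid)
      pos[idx] <- sort(sample.int(2000L, length(idx))) + 100L
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    qual <- round(stats::runif(L, 31, 3000), 1)

    loci <- data.frame(contig = contigs, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    gm <- geno_matrix(calls, loci, depth = depth, qual = qual)
    truth_loci <- data.frame(locus_id = gm_loci(gm), contig_id = contigs,
                             is_outlier = is_outlier, ancestral_freq = p_anc,
                             stringsAsFactors = FALSE)
    for (j in seq_len(J))
      truth_loci[[paste0("freq_", cfg$pop_labels[j])]] <- pfreq[j, ]
    list(gm = gm, pm = pm, truth = list(loci = truth_loci, clones = clones))
  })
}

#' Simulate pseudo-observed data (POD) from a fitted covariance model
#'
#' Draws loci from the null model used for outlier-threshold calibration:
#' per locus an ancestral frequency pi from `pi_dist`, a population frequency
#' vector from MVN(pi, pi (1 - pi) Omega) truncated to [0,1], and diploid
#' genotypes Binomial(2, p_pop) with the observed per-population sample
#' sizes.
#'
#' @param omega positive semi-definite scaled covariance matrix (pops x pops).
#' @param pi_dist numeric vector: the empirical distribution of ancestral
#'   frequencies, resampled with replacement (a single value is recycled).
#' @param sample_sizes named integer vector of individuals per population.
#' @param n_loci number of POD loci.
#' @param seed integer seed.
#' @return a list with `gm` (a [geno_matrix()], no depth/qual) and `pm`.
#' @export
simulate_pod <- function(omega, pi_dist, sample_sizes, n_loci, seed = 1L) {
  omega <- as.matrix(omega)
  J <- nrow(omega)
  if (!isSymmetric(unname(omega), tol = 1e-8))
    stop_holopop("omega must be symmetric")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop_holopop("omega must be positive semi-definite")
  if (any(sample_sizes <= 0)) stop_holopop("sample_sizes must be positive")
  if (length(sample_sizes) != J)
    stop_holopop("sample_sizes must match omega dimension")
  pops <- names(sample_sizes) %||% rownames(omega) %||% paste0("pop", seq_len(J))

  with_seed(seed, {
    pis <- if (length(pi_dist) == 1L) rep(pi_dist, n_loci) else
      sample(pi_dist, n_loci, replace = TRUE)
    ## MVN via eigen square root (robust to PSD-but-singular omega)
    es <- eigen(omega, symmetric = TRUE)
    sq <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
    zn <- matrix(stats::rnorm(J * n_loci), J, n_loci)
    pfreq <- rep(pis, each = J) +
      sq %*% zn * rep(sqrt(pis * (1 - pis)), each = J)
    pfreq <- pmin(pmax(pfreq, 0), 1)

    n_tot <- sum(sample_sizes)
    samples <- unlist(lapply(seq_len(J), function(j)
      sprintf("%s_pod%02d", gsub("-", "_", pops[j]), seq_len(sample_sizes[j]))))
    calls <- matrix(NA_integer_, n_tot, n_loci, dimnames = list(samples, NULL))
    row0 <- 0L
    for (j in seq_len(J)) {
      nj <- sample_sizes[j]
      calls[row0 + seq_len(nj), ] <-
        matrix(stats::rbinom(nj * n_loci, 2L, rep(pfreq[j, ], each = nj)), nj, n_loci)
      row0 <- row0 + nj
    }
    loci <- data.frame(contig = sprintf("pod%06d", seq_len(n_loci)),
                       pos = rep(1L, n_loci),
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
    pm <- pop_map(samples,
                  origin = rep(sub("-.*$", "", pops), sample_sizes),
                  state = rep(sub("^.*-", "", pops), sample_sizes))
    list(gm = geno_matrix(calls, loci), pm = pm)
  })
}
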
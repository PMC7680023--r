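#' Per-population allele frequencies and standardized residuals
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @return list: `p` (pops x loci sample alt-allele frequencies), `pi`
#'   (per-locus unweighted cross-population mean), `z` (standardized
#'   residuals (p - pi)/sqrt(pi(1-pi)); NA where pi is 0 or 1), `n`
#'   (pops x loci genotyped counts), `pops`.
#' @keywords internal
pop_freqs <- function(gm, pm) {
  pops <- pop_labels(gm, pm)
  upops <- unique(pops)
  L <- ncol(gm$calls)
  p <- matrix(NA_real_, length(upops), L, dimnames = list(upops, gm_loci(gm)))
  nmat <- matrix(0L, length(upops), L, dimnames = dimnames(p))
  for (j in seq_along(upops)) {
    sub <- gm$calls[pops == upops[j], , drop = FALSE]
    n <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    p[j, ] <- ifelse(n > 0, alt / (2 * n), NA_real_)
    nmat[j, ] <- n
  }
  pi_l <- colMeans(p, na.rm = TRUE)
  denom <- sqrt(pi_l * (1 - pi_l))
  z <- sweep(p, 2, pi_l, "-")
  z <- sweep(z, 2, denom, "/")
  z[, denom == 0 | !is.finite(denom)] <- NA_real_
  list(p = p, pi = pi_l, z = z, n = nmat, pops = upops)
}

#' Estimate the scaled covariance of population allele frequencies (Omega)
#'
#' Method-of-moments estimator of the shared-drift covariance matrix: for
#' each locus the per-population standardized frequency residual z_j =
#' (p_j - pi) / sqrt(pi(1-pi)) is formed (pi the unweighted mean across
#' populations), and Omega = (1/L) sum_l z_l z_l' over usable loci, with a
#' small ridge on the diagonal to guarantee invertibility. Loci
#' monomorphic across all populations carry no information and are
#' skipped.
#'
#' Sample allele frequencies carry binomial noise on top of the drift
#' covariance: E[z z'] = Omega_drift + D with D_jj the standardized
#' sampling variance p(1-p)/(2n) / (pi(1-pi)). By default that noise term
#' (estimated unbiasedly as p(1-p)/(2n-1) per locus and averaged) is
#' subtracted, so `omega` estimates the latent drift covariance — the
#' quantity the pseudo-observed-data simulator must use, since POD
#' generation adds binomial sampling back on top. Without the subtraction
#' POD would be over-dispersed and the outlier threshold anticonservative
#' in the other direction (inflated). Eigenvalues are floored at `ridge`
#' to keep the matrix invertible.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param ridge eigenvalue floor / regularization (default 1e-4).
#' @param subtract_sampling subtract the binomial sampling-noise term
#'   (default TRUE).
#' @return list of class `covariance_model`: `omega` (drift covariance),
#'   `omega_raw` (uncorrected), `pop_labels`, `n_loci_used`, `pi_hat`
#'   (per-locus means of the usable loci).
#' @export
estimate_omega <- function(gm, pm, ridge = 1e-4, subtract_sampling = TRUE) {
  pf <- pop_freqs(gm, pm)
  if (length(pf$pops) < 2) stop_holopop("need at least 2 populations")
  usable <- colSums(is.na(pf$z)) == 0
  if (sum(usable) < 2)
    stop_holopop("fewer than 2 usable (polymorphic, fully observed) loci")
  z <- pf$z[, usable, drop = FALSE]
  raw <- tcrossprod(z) / ncol(z)
  omega <- raw
  if (subtract_sampling) {
    p <- pf$p[, usable, drop = FALSE]
    n <- pf$n[, usable, drop = FALSE]
    pivar <- pf$pi[usable] * (1 - pf$pi[usable])
    d <- p * (1 - p) / pmax(2 * n - 1, 1)
    d <- sweep(d, 2, pivar, "/")
    omega <- raw - diag(rowMeans(d), nrow(raw))
  }
  ## PSD projection with an eigenvalue floor
  es <- eigen(omega, symmetric = TRUE)
  omega <- es$vectors %*% (pmax(es$values, ridge) * t(es$vectors))
  dimnames(omega) <- dimnames(raw)
  ## metric for the XtX quadratic form: the full (drift + sampling noise)
  ## covariance of the observed standardized frequencies. POD loci are
  ## scored in the same metric, so threshold calibration is unaffected,
  ## while outlier-contaminated directions are only mildly down-weighted
  ## (the sampling-noise diagonal dominates at these sample sizes).
  omega_xtx <- raw + diag(ridge, nrow(raw))
  dimnames(omega_xtx) <- dimnames(raw)
  structure(list(omega = omega, omega_raw = raw, omega_xtx = omega_xtx,
                 pop_labels = pf$pops,
                 n_loci_used = ncol(z), pi_hat = pf$pi[usable]),
            class = "covariance_model")
}

#' Per-locus XtX differentiation statistic
#'
#' XtX is a SNP-specific Fst analog corrected for the covariance of
#' population allele frequencies: the quadratic form z' Omega^-1 z of the
#' standardized residuals in the inverse of the fitted covariance matrix.
#' Shared drift (population-tree structure) inflates plain Fst; weighting
#' by Omega^-1 discounts it, so XtX ranks loci by differentiation beyond
#' what demography explains. Loci monomorphic across populations get
#' XtX = 0 and are flagged.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param model a `covariance_model` from [estimate_omega()].
#' @return data.frame: `locus_id`, `xtx`, `monomorphic`.
#' @export
xtx <- function(gm, pm, model) {
  pf <- pop_freqs(gm, pm)
  if (!identical(sort(pf$pops), sort(model$pop_labels)))
    stop_holopop("model populations do not match the data")
  z <- pf$z[model$pop_labels, , drop = FALSE]
  metric <- model$omega_xtx %||% model$omega
  oinv <- tryCatch(solve(metric),
                   error = function(e) stop_holopop("omega is singular"))
  mono <- colSums(is.na(z)) > 0
  zz <- z; zz[, mono] <- 0
  scores <- colSums(zz * (oinv %*% zz))
  data.frame(locus_id = gm_loci(gm), xtx = as.numeric(scores),
             monomorphic = mono, row.names = NULL, stringsAsFactors = FALSE)
}

#' Calibrate the outlier threshold with pseudo-observed data
#'
#' Simulates `n_pod_loci` loci from the fitted null ([simulate_pod()]:
#' multivariate-normal frequencies with covariance pi(1-pi) Omega, binomial
#' sampling at the observed per-population sample sizes), scores them with
#' [xtx()] under the same model, and returns the empirical (1 - fdr)
#' quantile (linear interpolation) as the outlier threshold.
#'
#' @param gm a [geno_matrix()] (supplies per-population sample sizes).
#' @param pm a [pop_map()].
#' @param model a `covariance_model`.
#' @param n_pod_loci POD size (default 10000).
#' @param fdr target false-discovery proportion under the null
#'   (default 0.005, i.e. a 0.5% FDR threshold).
#' @param seed integer seed.
#' @return list: `threshold`, `fdr`, `n_pod_loci`, `pod_xtx` (scores).
#' @export
pod_calibrate <- function(gm, pm, model, n_pod_loci = 10000, fdr = 0.005,
                          seed = 1L) {
  pops <- pop_labels(gm, pm)
  sizes <- vapply(model$pop_labels, function(p) sum(pops == p), integer(1))
  pod <- simulate_pod(model$omega, model$pi_hat, sizes, n_pod_loci, seed = seed)
  scores <- xtx(pod$gm, pod$pm, model)
  thr <- as.numeric(stats::quantile(scores$xtx, probs = 1 - fdr, type = 7,
                                    names = FALSE))
  list(threshold = thr, fdr = fdr, n_pod_loci = n_pod_loci,
       pod_xtx = scores$xtx)
}

#' Classify loci as neutral or high outlier
#'
#' Strict exceedance of the POD threshold makes a locus a high outlier;
#' everything else (ties included) is neutral.
#'
#' @param scores data.frame from [xtx()].
#' @param threshold POD-calibrated cutoff.
#' @return data.frame of class `outlier_scores`: scores plus `class`
#'   ("neutral"/"high_outlier"); the threshold is attached as an attribute.
#' @export
classify_outliers <- function(scores, threshold) {
  if (!is.finite(threshold)) stop_holopop("threshold must be finite")
  scores$class <- ifelse(scores$xtx > threshold, "high_outlier", "neutral")
  attr(scores, "threshold") <- threshold
  class(scores) <- c("outlier_scores", "data.frame")
  scores
}

#' Split a genotype matrix into neutral and outlier locus sets
#'
#' @param gm a [geno_matrix()].
#' @param scores an `outlier_scores` data.frame aligned with `gm`.
#' @return list with `neutral` and `outlier` matrices (NULL when empty).
#' @export
split_by_class <- function(gm, scores) {
  stopifnot(identical(scores$locus_id, gm_loci(gm)))
  out_i <- which(scores$class == "high_outlier")
  neu_i <- which(scores$class == "neutral")
  list(neutral = if (length(neu_i)) gm_subset(gm, loci = neu_i),
       outlier = if (length(out_i)) gm_subset(gm, loci = out_i))
}

#' Write outlier scores with threshold sidecar
#'
#' @param scores an `outlier_scores` data.frame.
#' @param model the `covariance_model` used.
#' @param path TSV path; a `.json` sidecar with threshold and Omega is
#'   written alongside.
#' @export
write_outlier_scores <- function(scores, model, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(threshold = attr(scores, "threshold"),
         omega = unname(as.matrix(model$omega)),
         pop_labels = model$pop_labels,
         n_loci_used = model$n_loci_used),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
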
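#' Weir-Cockerham variance components per locus
#'
#' For each locus, computes the among-population (a), among-individual-
#' within-population (b) and within-individual (c) components of allelic
#' variance from per-population sample sizes, alt-allele frequencies and
#' observed heterozygote proportions. Only populations with at least one
#' genotyped individual at a locus contribute; loci with fewer than two
#' such populations are skipped.
#'
#' @param calls genotype call matrix (samples x loci).
#' @param pop_idx list of row-index vectors, one per population.
#' @return list of numeric vectors `a`, `b`, `c` (per locus; NA where the
#'   locus is unusable).
#' @keywords internal
wc_components <- function(calls, pop_idx) {
  pre <- wc_precompute(calls)
  J <- length(pop_idx)
  M <- matrix(0, nrow(calls), J)
  for (j in seq_len(J)) M[pop_idx[[j]], j] <- 1
  wc_components_pre(pre, M)
}

## cross-permutation reusable matrices (loci x samples)
wc_precompute <- function(calls) {
  obs <- !is.na(calls)
  x <- calls; x[!obs] <- 0L
  list(tO = t(obs) * 1, tX = t(x) * 1, tH = t(x == 1L & obs) * 1)
}

## membership matrix M (samples x pops) -> per-locus variance components
wc_components_pre <- function(pre, M) {
  nmat <- pre$tO %*% M          # loci x pops genotyped counts
  altm <- pre$tX %*% M
  hetm <- pre$tH %*% M
  present <- nmat > 0
  r <- rowSums(present)
  nsum <- rowSums(nmat)
  nbar <- nsum / r
  ## n_c = (N - sum n_i^2 / N) / (r - 1)
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pmat <- altm / (2 * nmat); pmat[!present] <- 0
  pbar <- rowSums(altm) / (2 * nsum)
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(hetm) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(cc))
}

fst_from_components <- function(comp) {
  ok <- is.finite(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom == 0) return(NA_real_)
  sum(comp$a[ok]) / denom
}

#' Global Fst (AMOVA-style, Weir-Cockerham estimator)
#'
#' Multi-locus Fst as the ratio of summed among-population variance
#' components to summed total components across loci ("ratio of sums"),
#' the standard variance-component (AMOVA) estimator for biallelic SNPs
#' under the allele-within-individual-within-population hierarchy. Can be
#' slightly negative when populations are effectively undifferentiated.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param by grouping passed to [pop_labels()].
#' @return numeric Fst (NaN-equivalent NA when no locus is usable).
#' @export
global_fst <- function(gm, pm, by = "pop") {
  pops <- pop_labels(gm, pm, by = by)
  if (length(unique(pops)) < 2) stop_holopop("need at least 2 populations")
  pop_idx <- split(seq_along(pops), pops)
  fst_from_components(wc_components(gm$calls, pop_idx))
}

#' Permutation test for population differentiation
#'
#' Permutes individuals among populations (sizes preserved), recomputes
#' Fst, and reports p = (1 + #{perm >= observed}) / (n_perm + 1), so the
#' smallest attainable p with 999 permutations is 0.001.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param by grouping passed to [pop_labels()].
#' @return list: `fst` (observed), `p_value`, `n_perm`, `perm_fst`.
#' @export
permutation_test <- function(gm, pm, n_perm = 999, seed = 1L, by = "pop") {
  stopifnot(n_perm >= 1)
  pops <- pop_labels(gm, pm, by = by)
  pop_idx <- split(seq_along(pops), pops)
  pre <- wc_precompute(gm$calls)
  M <- matrix(0, length(pops), length(pop_idx))
  for (j in seq_along(pop_idx)) M[pop_idx[[j]], j] <- 1
  obs <- fst_from_components(wc_components_pre(pre, M))
  n <- length(pops)
  perm_fst <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      fst_from_components(wc_components_pre(pre, M[sample.int(n), , drop = FALSE]))
    }, numeric(1))
  })
  p <- (1 + sum(perm_fst >= obs, na.rm = TRUE)) / (n_perm + 1)
  list(fst = obs, p_value = p, n_perm = n_perm, perm_fst = perm_fst)
}

#' Pairwise Fst with permutation p-values
#'
#' [global_fst()] and [permutation_test()] restricted to each population
#' pair; the layout mirrors a pairwise differentiation table with the Fst
#' value and its permutation p-value per pair, plus a `significant` flag
#' at `alpha`.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param n_perm permutations per pair (default 999).
#' @param seed integer seed (a child seed is derived per pair).
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame: `pop_1`, `pop_2`, `fst`, `p_value`, `significant`.
#' @export
pairwise_fst <- function(gm, pm, n_perm = 999, seed = 1L, alpha = 0.05) {
  pops <- pop_labels(gm, pm)
  upops <- unique(pops)
  if (length(upops) < 2) stop_holopop("need at least 2 populations")
  rows <- list()
  k <- 0L
  for (i in seq_len(length(upops) - 1L)) {
    for (j in seq((i + 1L), length(upops))) {
      k <- k + 1L
      keep <- pops %in% c(upops[i], upops[j])
      if (sum(pops == upops[i]) < 2 || sum(pops == upops[j]) < 2) next
      sub <- gm_subset(gm, samples = which(keep))
      pt <- permutation_test(sub, pm, n_perm = n_perm, seed = child_seed(seed, k))
      rows[[length(rows) + 1L]] <- data.frame(
        pop_1 = upops[i], pop_2 = upops[j], fst = pt$fst,
        p_value = pt$p_value, significant = pt$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Observed and expected heterozygosity per population
#'
#' Per population: Ho is the observed heterozygote frequency; Hs is Nei's
#' unbiased within-population expected heterozygosity,
#' Hs = n/(n-1) * (1 - sum p^2 - Ho/(2n)) with n the genotyped individuals
#' at the locus, which corrects for sampling a limited number of
#' individuals. Both are averaged over loci with at least 2 genotyped
#' individuals.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @return data.frame: `pop`, `n_ind`, `Ho`, `Hs`.
#' @export
heterozygosity <- function(gm, pm) {
  pops <- pop_labels(gm, pm)
  res <- lapply(unique(pops), function(p) {
    sub <- gm$calls[pops == p, , drop = FALSE]
    n <- colSums(!is.na(sub))
    ok <- n >= 2
    het <- colSums(sub == 1L, na.rm = TRUE)
    alt <- colSums(sub, na.rm = TRUE)
    ho <- het[ok] / n[ok]
    pa <- alt[ok] / (2 * n[ok])
    hs <- n[ok] / (n[ok] - 1) * (1 - pa^2 - (1 - pa)^2 - ho / (2 * n[ok]))
    data.frame(pop = p, n_ind = sum(pops == p),
               Ho = mean(ho), Hs = mean(hs), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Differentiation summary for one locus set
#'
#' Bundles global and pairwise Fst (with permutation p-values) and
#' per-population diversity for a labelled locus set.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [pop_map()].
#' @param locus_set label recorded in the output ("neutral"/"outlier").
#' @param n_perm,seed forwarded to the permutation machinery.
#' @return list of class `structure_report`: `locus_set`, `global`
#'   (fst, p_value), `pairwise` (data.frame), `diversity` (data.frame).
#' @export
structure_report <- function(gm, pm, locus_set = "neutral", n_perm = 999,
                             seed = 1L) {
  gl <- permutation_test(gm, pm, n_perm = n_perm, seed = child_seed(seed, 1000L))
  pw <- pairwise_fst(gm, pm, n_perm = n_perm, seed = seed)
  dv <- heterozygosity(gm, pm)
  structure(list(locus_set = locus_set,
                 global = list(fst = gl$fst, p_value = gl$p_value,
                               n_perm = n_perm),
                 pairwise = pw, diversity = dv),
            class = "structure_report")
}

#' Write pairwise Fst tables in the neutral-over-outlier layout
#'
#' @param neutral,outlier `structure_report`s (outlier may be NULL).
#' @param path output TSV path.
#' @export
write_fst_table <- function(neutral, outlier, path) {
  fmt <- function(r) {
    df <- r$pairwise
    df$locus_set <- r$locus_set
    df
  }
  out <- fmt(neutral)
  if (!is.null(outlier)) out <- rbind(out, fmt(outlier))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
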
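#' Pairwise allelic distance between multilocus genotypes
#'
#' Distances count allelic differences between two diploid individuals:
#' `hamming` sums |a_i - a_j| over allele-dosage codes (AA vs Aa = 1, AA vs
#' aa = 2); `prevosti` divides by twice the number of loci both individuals
#' were genotyped at, giving a relative dissimilarity in [0,1];
#' `manhattan` is the Manhattan (city-block) distance on the dosage codes,
#' which coincides with hamming on {0,1,2} codes but is kept as a separate
#' metric for robustness runs. Loci missing in either member of a pair are
#' excluded pairwise.
#'
#' @param gm a [geno_matrix()] with at least 2 samples.
#' @param metric one of "hamming", "prevosti", "manhattan".
#' @return a list of class `allelic_dist`: `values` (symmetric matrix,
#'   zero diagonal), `shared` (pairwise genotyped-locus counts), `metric`.
#' @export
allelic_distance <- function(gm, metric = c("hamming", "prevosti", "manhattan")) {
  metric <- match.arg(metric)
  calls <- gm$calls
  n <- nrow(calls)
  if (n < 2) stop_holopop("need at least 2 samples")
  x <- calls; x[is.na(x)] <- 0L
  obs <- !is.na(calls)
  storage.mode(x) <- "double"; storage.mode(obs) <- "double"
  shared <- obs %*% t(obs)
  ## sum |x_i - x_j| over shared loci, via the {0,1,2} code decomposition:
  ## |a-b| = a + b - 2*min(a,b); min over codes = ge1_i*ge1_j + eq2_i*eq2_j
  ge1 <- (x >= 1) * obs; eq2 <- (x == 2) * obs
  sum_i <- (x * obs) %*% t(obs)
  d <- sum_i + t(sum_i) - 2 * (ge1 %*% t(ge1) + eq2 %*% t(eq2))
  zero_shared <- shared == 0 & upper.tri(shared)
  if (any(zero_shared)) {
    bad <- which(zero_shared, arr.ind = TRUE)[1, ]
    stop_holopop("samples %s and %s share no genotyped loci",
                 rownames(calls)[bad[1]], rownames(calls)[bad[2]])
  }
  values <- switch(metric,
                   hamming = d,
                   manhattan = d,
                   prevosti = d / (2 * shared))
  diag(values) <- 0
  dimnames(values) <- list(rownames(calls), rownames(calls))
  dimnames(shared) <- dimnames(values)
  structure(list(values = values, shared = shared, metric = metric),
            class = "allelic_dist")
}

#' Detect clonal ramets from a distance matrix
#'
#' Pairs whose distance, normalised by the maximum possible allelic
#' difference over their shared loci (2 per locus), falls strictly below
#' `threshold` are flagged as putative clones. Flagged pairs are merged
#' into clone groups (connected components); within each group one member
#' is retained (chosen by seeded RNG, mirroring a random removal of
#' ramets) and the rest are listed for removal. A complete-linkage
#' dendrogram is returned for visual confirmation.
#'
#' @param dm an `allelic_dist` from [allelic_distance()].
#' @param threshold clone-calling cutoff as a fraction of the maximum
#'   possible allelic differences (default 0.05).
#' @param seed RNG seed for the retained-member choice.
#' @return list of class `clone_report`: `pairs` (data.frame sample_1,
#'   sample_2, distance, normalized), `groups` (list of clone groups),
#'   `remove` (samples to drop), `keep` (retained member per group),
#'   `hclust` (the dendrogram), `threshold`.
#' @export
detect_clones <- function(dm, threshold = 0.05, seed = 1L) {
  if (threshold <= 0) stop_holopop("threshold must be positive")
  v <- dm$values
  norm <- if (dm$metric == "prevosti") v else v / (2 * dm$shared)
  n <- nrow(v)
  hc <- stats::hclust(stats::as.dist(v), method = "complete")
  idx <- which(upper.tri(norm) & norm < threshold, arr.ind = TRUE)
  pairs <- data.frame(sample_1 = rownames(v)[idx[, 1]],
                      sample_2 = colnames(v)[idx[, 2]],
                      distance = v[idx],
                      normalized = norm[idx],
                      stringsAsFactors = FALSE)
  ## connected components over flagged pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(idx[k, 1]); b <- find(idx[k, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(rownames(v), roots)
  groups <- unname(groups[lengths(groups) > 1])
  keep <- character(0); remove <- character(0)
  with_seed(seed, {
    for (g in groups) {
      kept <- sample(g, 1L)
      keep <- c(keep, kept)
      remove <- c(remove, setdiff(g, kept))
    }
  })
  structure(list(pairs = pairs, groups = groups, keep = keep,
                 remove = remove, hclust = hc, threshold = threshold),
            class = "clone_report")
}

#' Check clone calls for concordance across distance metrics
#'
#' Reruns [detect_clones()] under hamming, Prevosti and Manhattan distance
#' and reports whether the flagged sample sets coincide.
#'
#' @param gm a [geno_matrix()].
#' @param threshold,seed forwarded to [detect_clones()].
#' @return list: `per_metric` (clone groups per metric), `concordant`
#'   (logical), `discordant_samples` (samples flagged under some but not
#'   all metrics).
#' @export
metric_concordance <- function(gm, threshold = 0.05, seed = 1L) {
  metrics <- c("hamming", "prevosti", "manhattan")
  reports <- lapply(metrics, function(m)
    detect_clones(allelic_distance(gm, m), threshold, seed))
  names(reports) <- metrics
  flagged <- lapply(reports, function(r) sort(unique(unlist(r$groups))))
  concordant <- all(vapply(flagged[-1], identical, logical(1), flagged[[1]]))
  all_flagged <- unique(unlist(flagged))
  in_all <- Reduce(intersect, flagged)
  list(per_metric = lapply(reports, `[[`, "groups"),
       concordant = concordant,
       discordant_samples = setdiff(all_flagged, in_all))
}

#' Write a clone dendrogram in Newick format
#' @param report a `clone_report`.
#' @param path output path.
#' @export
write_clone_dendrogram <- function(report, path) {
  ape::write.tree(ape::as.phylo(report$hclust), file = path)
  invisible(path)
}

#' Write a clone report as TSV
#' @param report a `clone_report`.
#' @param path output path.
#' @export
write_clone_report <- function(report, path) {
  df <- report$pairs
  df$decision <- ifelse(df$sample_1 %in% report$remove, "remove_sample_1",
                 ifelse(df$sample_2 %in% report$remove, "remove_sample_2", "keep_both"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
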
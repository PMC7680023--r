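#' Principal component analysis of a genotype matrix
#'
#' Missing calls are imputed with the per-locus mean (the standard
#' genotype-PCA convention), columns are centered and optionally scaled by
#' sqrt(p(1-p)), and the sample covariance is eigendecomposed. Loci with
#' no observed calls are dropped with a warning. Component signs are
#' arbitrary; downstream comparisons should use absolute projections.
#'
#' @param gm a [geno_matrix()] with >= 2 samples.
#' @param scaling "center" (default) or "center_scale".
#' @return list of class `pca_result`: `coordinates` (samples x
#'   components), `eigenvalues` (descending), `pct_variance`.
#' @export
gm_pca <- function(gm, scaling = c("center", "center_scale")) {
  scaling <- match.arg(scaling)
  calls <- gm$calls
  if (nrow(calls) < 2) stop_holopop("need at least 2 samples")
  all_missing <- colSums(!is.na(calls)) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d all-missing loci", sum(all_missing)))
    calls <- calls[, !all_missing, drop = FALSE]
  }
  x <- apply(calls, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scaling == "center_scale") {
    p <- colMeans(calls, na.rm = TRUE) / 2
    s <- sqrt(p * (1 - p))
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(coordinates = pc$x, eigenvalues = ev,
                 pct_variance = 100 * ev / sum(ev)),
            class = "pca_result")
}

#' Plot PC1 vs PC2 colored by population
#'
#' Scatter of the first two components, one color per population, axis
#' labels carrying percent variance explained; written as PDF or SVG by
#' file extension.
#'
#' @param res a `pca_result`.
#' @param pm a [pop_map()] covering every plotted sample.
#' @param path output path ending in .pdf or .svg.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plot_pca <- function(res, pm, path, main = "PCA") {
  ids <- rownames(res$coordinates)
  idx <- match(ids, pm$sample)
  if (anyNA(idx))
    stop_holopop("samples absent from population map: %s",
                 paste(ids[is.na(idx)], collapse = ", "))
  pops <- factor(pm$pop[idx])
  cols <- grDevices::hcl.colors(max(4L, nlevels(pops)), "Dark 3")[as.integer(pops)]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 6, height = 5),
         svg = grDevices::svg(path, width = 6, height = 5),
         stop_holopop("unsupported figure format: .%s (use .pdf or .svg)", ext))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(res$coordinates[, 1], res$coordinates[, 2], col = cols,
                 pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", res$pct_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", res$pct_variance[2]),
                 main = main)
  graphics::legend("topright", legend = levels(pops), col =
                     grDevices::hcl.colors(max(4L, nlevels(pops)), "Dark 3")[seq_len(nlevels(pops))],
                   pch = 19, bty = "n")
  invisible(path)
}

#' Silhouette-style separation of a grouping on one PC
#'
#' Mean silhouette width of a two-group labelling computed on a single
#' coordinate axis; used to quantify whether origins separate on PC1.
#'
#' @param coords numeric vector (one PC's coordinates).
#' @param labels grouping labels (two or more groups).
#' @return mean silhouette width in [-1, 1].
#' @export
axis_silhouette <- function(coords, labels) {
  labels <- as.character(labels)
  n <- length(coords)
  stopifnot(length(labels) == n, n >= 2)
  d <- abs(outer(coords, coords, "-"))
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    if (!any(same)) return(0)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
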
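#' Genotype matrix container
#'
#' The central data structure of the pipeline: diploid genotype calls for
#' `n` samples at `L` biallelic loci, coded as the count of alternate
#' alleles (0, 1, 2) with `NA` for missing, together with per-genotype read
#' depth and per-site quality.
#'
#' @param calls integer matrix, samples x loci, values in {0,1,2,NA}.
#'   Row names are sample ids, column names locus ids.
#' @param loci data.frame with one row per locus: columns `contig`, `pos`
#'   (1-based), `ref`, `alt`, and optionally `multiallelic` (logical).
#' @param depth integer matrix of per-genotype read depths, same shape as
#'   `calls`, or NULL if depth is unavailable.
#' @param qual numeric vector of per-site quality scores, or NULL.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, loci, depth = NULL, qual = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop_holopop("calls must have sample row names")
  stopifnot(is.data.frame(loci), nrow(loci) == ncol(calls))
  required <- c("contig", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols))
    stop_holopop("loci is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (is.null(loci$multiallelic)) loci$multiallelic <- FALSE
  ids <- locus_ids(loci)
  colnames(calls) <- ids
  rownames(loci) <- NULL
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop_holopop("genotype calls must be 0, 1, 2 or NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(calls)))
      stop_holopop("depth must have the same shape as calls")
    dimnames(depth) <- dimnames(calls)
  }
  if (!is.null(qual)) {
    qual <- as.numeric(qual)
    if (length(qual) != ncol(calls))
      stop_holopop("qual must have one value per locus")
  }
  structure(list(calls = calls, loci = loci, depth = depth, qual = qual),
            class = "geno_matrix")
}

locus_ids <- function(loci) paste(loci$contig, loci$pos, sep = "_")

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci (%d contigs)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$loci$contig))))
  cat(sprintf("  missing calls: %.1f%%; depth: %s; qual: %s\n",
              100 * mean(is.na(x$calls)),
              if (is.null(x$depth)) "absent" else "present",
              if (is.null(x$qual)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a `geno_matrix`.
#' @param samples character or logical/integer index over samples, or NULL.
#' @param loci logical/integer index over loci, or NULL.
#' @return a `geno_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(loci)) loci <- seq_len(ncol(gm$calls))
  if (is.character(samples)) {
    missing_s <- setdiff(samples, rownames(gm$calls))
    if (length(missing_s))
      stop_holopop("unknown samples: %s", paste(missing_s, collapse = ", "))
  }
  geno_matrix(gm$calls[samples, loci, drop = FALSE],
              gm$loci[loci, , drop = FALSE],
              depth = if (!is.null(gm$depth)) gm$depth[samples, loci, drop = FALSE],
              qual  = if (!is.null(gm$qual)) gm$qual[loci])
}

#' @rdname geno_matrix
#' @param gm a `geno_matrix`.
#' @export
gm_samples <- function(gm) rownames(gm$calls)

#' @rdname geno_matrix
#' @export
gm_loci <- function(gm) locus_ids(gm$loci)
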
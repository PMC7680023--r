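#' Read a contig/gene -> GO annotation table
#'
#' TSV with two columns: id and a `;`-separated list of GO term ids
#' (GO:NNNNNNN). Malformed term ids raise an error.
#'
#' @param path TSV path (no header).
#' @return named list: id -> character vector of GO terms.
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "terms"))
  terms <- strsplit(df$terms, ";", fixed = TRUE)
  terms <- lapply(terms, function(t) unique(trimws(t[nzchar(trimws(t))])))
  all_terms <- unlist(terms)
  bad <- all_terms[!grepl("^GO:[0-9]{7}$", all_terms)]
  if (length(bad))
    stop_holopop("malformed GO term ids: %s", paste(unique(bad), collapse = ", "))
  stats::setNames(terms, df$id)
}

#' Fisher's exact GO enrichment of outlier-bearing genes
#'
#' Each gene in the universe carries a binary indicator of whether it
#' bears an outlier SNP. Per GO term, a 2x2 table (in-term x
#' outlier-bearing) over the universe is tested one-sided for enrichment;
#' the one-sided Fisher p equals the hypergeometric tail
#' P(X >= k | N, K, n). Terms annotating no universe gene are skipped.
#'
#' @param outlier_genes character vector, subset of `universe`.
#' @param universe character vector of all analysed genes/contigs.
#' @param annot named list from [read_go_annotation()].
#' @param alpha significance level for the `significant` flag.
#' @param correction "BH" (Benjamini-Hochberg, default) or "none".
#' @return data.frame: `term`, `k` (outlier genes in term), `K` (universe
#'   genes in term), `n_outlier`, `n_universe`, `fraction` ("k/K"),
#'   `p`, `p_adj`, `significant`, sorted by p.
#' @export
fisher_enrichment <- function(outlier_genes, universe, annot,
                              alpha = 0.05, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  outlier_genes <- unique(outlier_genes)
  universe <- unique(universe)
  if (!all(outlier_genes %in% universe))
    stop_holopop("outlier_genes must be a subset of the universe")
  annot <- annot[names(annot) %in% universe]
  gene2terms <- annot
  term2genes <- split(rep(names(gene2terms), lengths(gene2terms)),
                      unlist(gene2terms))
  N <- length(universe)
  n <- length(outlier_genes)
  rows <- lapply(names(term2genes), function(tm) {
    genes <- unique(term2genes[[tm]])
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- sum(genes %in% outlier_genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n_outlier = n, n_universe = N,
               fraction = sprintf("%d/%d", k, K), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- out$p_adj < alpha
  out[order(out$p), , drop = FALSE]
}

#' Map outlier loci to outlier-bearing genes/contigs
#'
#' @param gm the full (pre-split) [geno_matrix()].
#' @param scores an `outlier_scores` data.frame aligned with `gm`.
#' @return list: `outlier_genes` (contigs bearing >= 1 high-outlier SNP),
#'   `universe` (all contigs with >= 1 analysed SNP).
#' @export
outlier_gene_sets <- function(gm, scores) {
  stopifnot(identical(scores$locus_id, gm_loci(gm)))
  list(outlier_genes = unique(gm$loci$contig[scores$class == "high_outlier"]),
       universe = unique(gm$loci$contig))
}
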
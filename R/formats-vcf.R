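#' Read a VCF (v4.2) into a genotype matrix
#'
#' Parses GT (required), DP (if present in FORMAT) and site QUAL. Genotype
#' codes count alternate alleles: 0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA;
#' phase separators are ignored. Half-missing diploid calls (e.g. "./0")
#' are treated as fully missing. Multiallelic records (ALT with a comma)
#' are retained with `multiallelic = TRUE` in the locus table — the basic
#' site filter removes them; their call codes count all non-reference
#' alleles.
#'
#' @param path path to an uncompressed VCF file.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM"))
    stop_holopop("%s: missing #CHROM header line", path)
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 10)
    stop_holopop("%s: VCF has no sample columns", path)
  samples <- header[-(1:9)]
  recs <- body[-1]
  recs <- recs[nzchar(recs)]
  if (!length(recs)) stop_holopop("%s: no variant records", path)
  fields <- strsplit(recs, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop_holopop("%s: malformed record at data line %d (%d fields, expected %d)",
                 path, which(nf != length(header))[1], nf[nf != length(header)][1],
                 length(header))
  m <- matrix(unlist(fields), nrow = length(recs), byrow = TRUE)

  fmt <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx))
    stop_holopop("%s: record without GT in FORMAT at data line %d",
                 path, which(is.na(gt_idx))[1])
  dp_idx <- vapply(fmt, function(f) match("DP", f), integer(1))
  have_dp <- !anyNA(dp_idx)

  L <- nrow(m); n <- length(samples)
  calls <- matrix(NA_integer_, n, L, dimnames = list(samples, NULL))
  depth <- if (have_dp) matrix(NA_integer_, n, L, dimnames = list(samples, NULL))
  for (l in seq_len(L)) {
    parts <- strsplit(m[l, -(1:9)], ":", fixed = TRUE)
    gts <- vapply(parts, `[`, character(1), gt_idx[l])
    alleles <- strsplit(gts, "[/|]")
    calls[, l] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
    if (have_dp) {
      dps <- vapply(parts, function(p)
        if (length(p) >= dp_idx[l]) p[dp_idx[l]] else ".", character(1))
      depth[, l] <- suppressWarnings(as.integer(dps))
    }
  }
  qual <- suppressWarnings(as.numeric(m[, 6]))
  loci <- data.frame(contig = m[, 1], pos = as.integer(m[, 2]),
                     ref = m[, 4], alt = m[, 5],
                     multiallelic = grepl(",", m[, 5], fixed = TRUE),
                     stringsAsFactors = FALSE)
  geno_matrix(calls, loci, depth = depth, qual = qual)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT:DP per genotype (GT only when the matrix has no depth) and the
#' stored per-site QUAL ("." when absent). Codes map back as 0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1, NA -> ./..
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- nrow(gm$calls); L <- ncol(gm$calls)
  have_dp <- !is.null(gm$depth)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=holopop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (have_dp)
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm_samples(gm)),
                      collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[gm$calls + 1L], n, L)
  gt[is.na(gm$calls)] <- "./."
  if (have_dp) {
    dp <- gm$depth
    dp[is.na(dp)] <- 0L
    gt <- matrix(paste(gt, dp, sep = ":"), n, L)
  }
  qual <- if (is.null(gm$qual)) rep(".", L) else
    vapply(gm$qual, function(q)
      if (is.na(q)) "." else formatC(q, format = "g", digits = 10), character(1))
  recs <- vapply(seq_len(L), function(l) {
    paste(c(gm$loci$contig[l], gm$loci$pos[l], ".", gm$loci$ref[l],
            gm$loci$alt[l], qual[l], "PASS", ".",
            if (have_dp) "GT:DP" else "GT", gt[, l]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
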
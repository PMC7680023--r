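#' Write a genotype matrix in genepop format
#'
#' Produces the genepop 4.x dialect used by most population-genetics tools:
#' a title line, one locus name per line (`contig_pos`), a `Pop` line before
#' each population block, and sample rows `id ,  aabbb...` with 3-digit
#' allele codes — allele 1 is REF ("001"), allele 2 is ALT ("002"), missing
#' is "000000".
#'
#' @param gm a biallelic [geno_matrix()].
#' @param pm a [pop_map()] covering every sample.
#' @param path output path.
#' @param title title line content.
#' @return the path, invisibly.
#' @export
write_genepop <- function(gm, pm, path, title = "holopop genotypes") {
  if (any(gm$loci$multiallelic))
    stop_holopop("genepop output requires a biallelic matrix (filter first)")
  pops <- pop_labels(gm, pm)
  code <- c("001001", "001002", "002002")
  enc <- matrix(code[gm$calls + 1L], nrow(gm$calls), ncol(gm$calls))
  enc[is.na(gm$calls)] <- "000000"
  lines <- c(title, gm_loci(gm))
  for (p in unique(pops)) {
    lines <- c(lines, "Pop")
    for (i in which(pops == p)) {
      lines <- c(lines, paste0(gm_samples(gm)[i], " ,  ",
                               paste(enc[i, ], collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genepop file back into a genotype matrix
#'
#' Inverse of [write_genepop()] for the dialect it emits (3-digit codes,
#' one locus name per line). Locus names of the form `contig_pos` are split
#' back into contig and position; REF/ALT are not recoverable and are set
#' to "A"/"T" placeholders.
#'
#' @param path genepop file path.
#' @return list with `gm` (a [geno_matrix()], no depth/qual) and `pops`
#'   (character vector: the population block index of each sample).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_rows <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_rows)) stop_holopop("%s: no Pop line found", path)
  loci <- trimws(lines[2:(pop_rows[1] - 1L)])
  ## loci may also be a single comma-separated line
  if (length(loci) == 1L && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  samples <- character(0); pops <- character(0)
  calls_rows <- list()
  block <- 0L
  for (i in seq((pop_rows[1] + 1L), length(lines))) {
    line <- lines[i]
    if (toupper(trimws(line)) == "POP") { next }
    block <- sum(pop_rows < i)
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop_holopop("%s: malformed sample line: %s", path, line)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop_holopop("%s: sample %s has %d genotypes, expected %d",
                   path, id, length(codes), length(loci))
    a1 <- as.integer(substr(codes, 1, 3))
    a2 <- as.integer(substr(codes, 4, 6))
    g <- (a1 == 2L) + (a2 == 2L)
    g[a1 == 0L | a2 == 0L] <- NA_integer_
    samples <- c(samples, id)
    pops <- c(pops, paste0("pop", block))
    calls_rows[[length(calls_rows) + 1L]] <- g
  }
  calls <- do.call(rbind, calls_rows)
  rownames(calls) <- samples
  has_pos <- grepl("_[0-9]+$", loci)
  contig <- ifelse(has_pos, sub("_[0-9]+$", "", loci), loci)
  pos <- ifelse(has_pos, as.integer(sub("^.*_", "", loci)), seq_along(loci))
  loci_df <- data.frame(contig = contig, pos = as.integer(pos),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  list(gm = geno_matrix(calls, loci_df), pops = pops)
}
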
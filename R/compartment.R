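#' Contig compartment assignment from BLAST hit tables
#'
#' A holobiont transcriptome mixes host (cnidarian) and symbiont
#' (Symbiodiniaceae) contigs. Contigs are classified from blastn hits
#' against four databases — "dirty" (holobiont-derived) and "clean"
#' (axenic/aposymbiotic) collections for each compartment — after removing
#' rRNA contamination and short contigs:
#'
#' * rRNA: any LSU/SSU hit covering at least `rrna_min_cover` of the contig
#'   over at least `rrna_min_len` bp removes the contig.
#' * Length: only contigs longer than `min_length` bp are kept (strict).
#' * Host: any qualifying hit (alignment longer than `min_overlap` bp at
#'   `min_identity` percent identity or better) to a coral database; the
#'   contig is dropped if it also has a qualifying clean-symbiont hit.
#' * Symbiont: symmetrically, with clean-coral hits as the veto.
#' * Contigs qualifying as both after vetoes are removed as ambiguous.
#'
#' @name compartment
NULL

BLAST_DBS <- c("dirty_coral", "dirty_sym", "clean_coral", "clean_sym",
               "rRNA_LSU", "rRNA_SSU")

#' Read a BLAST tabular (outfmt-6 style) hit file
#'
#' Expects at least five columns: query, subject, percent identity,
#' alignment length, e-value. Extra columns are ignored.
#'
#' @param path TSV path.
#' @param database which database the file was searched against (one of
#'   dirty_coral, dirty_sym, clean_coral, clean_sym, rRNA_LSU, rRNA_SSU).
#' @return data.frame with columns `query`, `subject`, `pct_identity`,
#'   `align_length`, `evalue`, `database`.
#' @export
read_blast_hits <- function(path, database) {
  if (!database %in% BLAST_DBS)
    stop_holopop("unknown database tag '%s' (expected one of: %s)",
                 database, paste(BLAST_DBS, collapse = ", "))
  empty <- data.frame(query = character(0), subject = character(0),
                      pct_identity = numeric(0), align_length = numeric(0),
                      evalue = numeric(0), database = character(0),
                      stringsAsFactors = FALSE)
  if (!file.size(path)) return(empty)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)
  if (ncol(df) < 5) stop_holopop("%s: expected >= 5 BLAST tabular columns", path)
  hits <- data.frame(query = as.character(df[[1]]),
                     subject = as.character(df[[2]]),
                     pct_identity = as.numeric(df[[3]]),
                     align_length = as.numeric(df[[4]]),
                     evalue = as.numeric(df[[5]]),
                     database = database,
                     stringsAsFactors = FALSE)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100, na.rm = TRUE))
    stop_holopop("%s: percent identity outside [0,100]", path)
  hits
}

#' rRNA contamination rule
#'
#' TRUE when any LSU/SSU hit aligns at least `min_len` bases and covers at
#' least `min_cover` of the contig.
#'
#' @param contig_length contig length in bases (> 0).
#' @param hits data.frame of hits for this contig (see [read_blast_hits()]);
#'   only rows with database rRNA_LSU/rRNA_SSU are considered.
#' @param min_cover minimum aligned fraction of the contig (default 0.78).
#' @param min_len minimum alignment length in bases (default 100).
#' @return logical flag.
#' @export
filter_rrna <- function(contig_length, hits, min_cover = 0.78, min_len = 100) {
  stopifnot(contig_length > 0)
  r <- hits[hits$database %in% c("rRNA_LSU", "rRNA_SSU"), , drop = FALSE]
  if (!nrow(r)) return(FALSE)
  any(r$align_length >= min_len &
      r$align_length / contig_length >= min_cover)
}

#' Contig length rule
#'
#' Kept iff strictly longer than `min_length` bases.
#'
#' @param contig_length contig length in bases (> 0).
#' @param min_length threshold (default 500).
#' @return logical: TRUE = kept.
#' @export
filter_length <- function(contig_length, min_length = 500) {
  stopifnot(all(contig_length > 0))
  contig_length > min_length
}

qualifying <- function(hits, dbs, min_overlap, min_identity) {
  h <- hits[hits$database %in% dbs, , drop = FALSE]
  nrow(h) > 0 && any(h$align_length > min_overlap & h$pct_identity >= min_identity)
}

#' Assign one contig to a compartment from its BLAST hits
#'
#' Applies the host/symbiont rules with clean-database vetoes; see
#' [compartment]. The contig is assumed to have already passed the rRNA
#' and length filters.
#'
#' @param hits data.frame of this contig's hits across the four
#'   compartment databases.
#' @param min_overlap minimum alignment length, exclusive (default 100).
#' @param min_identity minimum percent identity, inclusive (default 60).
#' @return list with `label` in {host, symbiont, ambiguous_removed,
#'   unassigned} and a human-readable `reason`.
#' @export
assign_contig <- function(hits, min_overlap = 100, min_identity = 60) {
  unknown <- setdiff(unique(hits$database), BLAST_DBS)
  if (length(unknown))
    stop_holopop("unknown database tag(s): %s", paste(unknown, collapse = ", "))
  coral <- qualifying(hits, c("dirty_coral", "clean_coral"), min_overlap, min_identity)
  sym <- qualifying(hits, c("dirty_sym", "clean_sym"), min_overlap, min_identity)
  clean_coral <- qualifying(hits, "clean_coral", min_overlap, min_identity)
  clean_sym <- qualifying(hits, "clean_sym", min_overlap, min_identity)
  ## a vetoed contig is removed outright, never reassigned to the other side
  if (coral && clean_sym)
    return(list(label = "ambiguous_removed",
                reason = "coral hit vetoed by clean symbiont hit"))
  if (sym && clean_coral)
    return(list(label = "ambiguous_removed",
                reason = "symbiont hit vetoed by clean coral hit"))
  if (coral && sym)
    return(list(label = "ambiguous_removed",
                reason = "qualifies as both coral and symbiont"))
  if (coral) return(list(label = "host", reason = "qualifying coral hit"))
  if (sym) return(list(label = "symbiont", reason = "qualifying symbiont hit"))
  list(label = "unassigned", reason = "no qualifying hit")
}

#' Classify every contig of a reference assembly
#'
#' Runs, in order: rRNA removal, length filter, host/symbiont assignment.
#'
#' @param contig_lengths named numeric vector: contig id -> length in bases.
#' @param hits data.frame of all hits (all six databases pooled), with a
#'   `query` column naming contigs.
#' @param min_length,rrna_min_cover,rrna_min_len,min_overlap,min_identity
#'   rule thresholds; see [compartment].
#' @return data.frame of class `compartment_assignment` with columns
#'   `contig`, `label`, `reason`; exactly one row per contig.
#' @export
assign_compartments <- function(contig_lengths, hits,
                                min_length = 500,
                                rrna_min_cover = 0.78, rrna_min_len = 100,
                                min_overlap = 100, min_identity = 60) {
  if (is.null(names(contig_lengths)))
    stop_holopop("contig_lengths must be named by contig id")
  by_contig <- split(hits, hits$query)
  empty <- hits[0, , drop = FALSE]
  res <- lapply(names(contig_lengths), function(cid) {
    h <- by_contig[[cid]] %||% empty
    len <- contig_lengths[[cid]]
    if (filter_rrna(len, h, rrna_min_cover, rrna_min_len))
      return(c(cid, "rRNA_removed", "rRNA database hit rule"))
    if (!filter_length(len, min_length))
      return(c(cid, "too_short", sprintf("length %g <= %g", len, min_length)))
    a <- assign_contig(h, min_overlap, min_identity)
    c(cid, a$label, a$reason)
  })
  out <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(out) <- c("contig", "label", "reason")
  class(out) <- c("compartment_assignment", "data.frame")
  out
}

#' Split a genotype matrix into host and symbiont variant sets
#'
#' Variants on host-labelled contigs go to the host matrix, symbiont-labelled
#' to the symbiont matrix; variants on removed/unassigned contigs are
#' dropped (counts reported).
#'
#' @param gm a [geno_matrix()].
#' @param assign a `compartment_assignment` covering every contig in `gm`.
#' @return list with `host`, `symbiont` (each a [geno_matrix()] or NULL if
#'   empty) and `dropped` (named counts by label).
#' @export
split_by_compartment <- function(gm, assign) {
  idx <- match(gm$loci$contig, assign$contig)
  if (anyNA(idx))
    stop_holopop("contigs absent from assignment: %s",
                 paste(unique(gm$loci$contig[is.na(idx)]), collapse = ", "))
  lab <- assign$label[idx]
  host_i <- which(lab == "host")
  sym_i <- which(lab == "symbiont")
  dropped <- table(lab[!(lab %in% c("host", "symbiont"))])
  list(host = if (length(host_i)) gm_subset(gm, loci = host_i),
       symbiont = if (length(sym_i)) gm_subset(gm, loci = sym_i),
       dropped = dropped)
}

#' Write a compartment assignment as TSV
#' @param assign a `compartment_assignment`.
#' @param path output path.
#' @export
write_compartments <- function(assign, path) {
  utils::write.table(assign, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
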
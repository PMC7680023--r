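#' Write a complete synthetic holobiont fixture bundle
#'
#' Emits everything the pipeline consumes, with known truth: a combined
#' host+symbiont VCF, a population map CSV, a contig FASTA (host, symbiont,
#' rRNA-contaminated, too-short, ambiguous and unassignable contigs with
#' known labels), BLAST hit tables consistent with those labels, a GO
#' annotation TSV, the truth tables, and a checksum manifest.
#'
#' The host compartment follows `cfg`; the symbiont compartment (present
#' only in symbiotic "brown" hosts — its calls are missing in white
#' samples) follows `cfg_sym`, which defaults to a two-population (VA-B,
#' RI-B) design with moderate neutral divergence, reflecting a symbiont
#' that is structured even where its host is panmictic.
#'
#' @param cfg host [sim_config()].
#' @param outdir output directory (created if needed).
#' @param cfg_sym symbiont [sim_config()] or NULL for the default above.
#' @return list: `manifest` (data.frame file/md5), `paths` (named list),
#'   `truth` (host and symbiont truth tables plus contig labels).
#' @export
write_fixture_bundle <- function(cfg, outdir, cfg_sym = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  host <- simulate_genotypes(cfg)
  if (is.null(cfg_sym)) {
    cfg_sym <- sim_config(n_pops = 2, n_ind_per_pop = cfg$n_ind_per_pop,
                          n_neutral_loci = max(50, cfg$n_neutral_loci %/% 10),
                          n_outlier_loci = 0,
                          fst_neutral = 0.09, clone_pairs = 0,
                          missing_rate = cfg$missing_rate,
                          mean_depth = cfg$mean_depth,
                          depth_dispersion = cfg$depth_dispersion,
                          loci_per_contig = cfg$loci_per_contig,
                          pop_labels = c("VA-B", "RI-B"),
                          contig_prefix = "sym", seed = child_seed(cfg$seed, 77L))
  }
  if (cfg_sym$contig_prefix == cfg$contig_prefix)
    stop_holopop("host and symbiont contig prefixes must differ")
  sym <- simulate_genotypes(cfg_sym)

  ## graft symbiont genotypes onto the brown host samples
  host_pm <- host$pm
  brown <- host_pm$sample[host_pm$state == "B" &
                          !(host_pm$sample %in% host$truth$clones$ramet)]
  if (nrow(sym$gm$calls) < length(brown))
    stop_holopop("symbiont design has fewer samples than brown hosts")
  sym_names_by_pop <- split(gm_samples(sym$gm), pop_labels(sym$gm, sym$pm))
  brown_by_pop <- split(brown, host_pm$pop[match(brown, host_pm$sample)])
  rename <- character(0)
  for (p in names(brown_by_pop)) {
    src <- sym_names_by_pop[[p]]
    if (is.null(src) || length(src) < length(brown_by_pop[[p]]))
      stop_holopop("symbiont design lacks samples for population %s", p)
    rename[src[seq_along(brown_by_pop[[p]])]] <- brown_by_pop[[p]]
  }
  n_host <- nrow(host$gm$calls)
  Ls <- ncol(sym$gm$calls)
  sym_calls <- matrix(NA_integer_, n_host, Ls,
                      dimnames = list(gm_samples(host$gm), NULL))
  sym_depth <- matrix(0L, n_host, Ls, dimnames = dimnames(sym_calls))
  src_rows <- names(rename)
  sym_calls[rename[src_rows], ] <- sym$gm$calls[src_rows, ]
  sym_depth[rename[src_rows], ] <- sym$gm$depth[src_rows, ]

  combined <- geno_matrix(cbind(host$gm$calls, sym_calls),
                          rbind(host$gm$loci, sym$gm$loci),
                          depth = cbind(host$gm$depth, sym_depth),
                          qual = c(host$gm$qual, sym$gm$qual))

  ## contig inventory: variant-bearing contigs plus known decoys
  with_seed(child_seed(cfg$seed, 99L), {
    host_contigs <- unique(host$gm$loci$contig)
    sym_contigs <- unique(sym$gm$loci$contig)
    decoys <- c(rrna = "decoy_rrna01", short = "decoy_short01",
                ambiguous = "decoy_ambig01", unassigned = "decoy_unk01")
    lengths <- c(
      stats::setNames(sample(600:1500, length(host_contigs), replace = TRUE),
                      host_contigs),
      stats::setNames(sample(600:1500, length(sym_contigs), replace = TRUE),
                      sym_contigs),
      stats::setNames(c(150L, 400L, 900L, 800L), decoys))
    seqs <- vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))

    hit_row <- function(q, s, pid, len, ev = 1e-50)
      sprintf("%s\t%s\t%.1f\t%d\t%.2g", q, s, pid, len, ev)
    hits <- list(dirty_coral = character(0), dirty_sym = character(0),
                 clean_coral = character(0), clean_sym = character(0),
                 rRNA_LSU = character(0), rRNA_SSU = character(0))
    for (cid in host_contigs)
      hits$dirty_coral <- c(hits$dirty_coral,
                            hit_row(cid, "cnidarian_ref", stats::runif(1, 70, 95), 150L))
    for (cid in sym_contigs)
      hits$clean_sym <- c(hits$clean_sym,
                          hit_row(cid, "symbiodinium_ref", stats::runif(1, 70, 95), 150L))
    hits$dirty_coral <- c(hits$dirty_coral,
                          hit_row(decoys[["ambiguous"]], "cnidarian_ref", 85, 150L))
    hits$clean_sym <- c(hits$clean_sym,
                        hit_row(decoys[["ambiguous"]], "symbiodinium_ref", 85, 150L))
    ## unassigned decoy: hit too short to qualify
    hits$dirty_coral <- c(hits$dirty_coral,
                          hit_row(decoys[["unassigned"]], "cnidarian_ref", 85, 80L))
    hits$rRNA_LSU <- c(hits$rRNA_LSU,
                       hit_row(decoys[["rrna"]], "LSU_ref", 95, 120L))

    go_pool <- sprintf("GO:%07d", c(3674, 5575, 8150, 6950, 9628, 15979,
                                    9765, 16020, 5515, 46872, 6810, 55114))
    go_lines <- vapply(host_contigs, function(cid)
      paste0(cid, "\t",
             paste(sample(go_pool, sample(1:3, 1)), collapse = ";")),
      character(1))

    paths <- list(
      vcf = file.path(outdir, "holobiont.vcf"),
      pop_map = file.path(outdir, "population_map.csv"),
      fasta = file.path(outdir, "reference_contigs.fasta"),
      go = file.path(outdir, "go_annotation.tsv"),
      truth_loci = file.path(outdir, "truth_loci.tsv"),
      truth_clones = file.path(outdir, "truth_clones.tsv"),
      truth_contigs = file.path(outdir, "truth_contigs.tsv"))
    for (db in names(hits))
      paths[[paste0("blast_", db)]] <- file.path(outdir,
                                                 paste0("blast_", db, ".tsv"))

    write_vcf(combined, paths$vcf)
    write_population_map(host_pm, paths$pop_map)
    writeLines(paste0(">", names(seqs), "\n", seqs), paths$fasta)
    writeLines(go_lines, paths$go)
    utils::write.table(host$truth$loci, paths$truth_loci, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(host$truth$clones, paths$truth_clones, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    contig_truth <- data.frame(
      contig = names(lengths),
      length = unname(lengths),
      truth_label = c(rep("host", length(host_contigs)),
                      rep("symbiont", length(sym_contigs)),
                      "rRNA_removed", "too_short", "ambiguous_removed",
                      "unassigned"),
      stringsAsFactors = FALSE)
    utils::write.table(contig_truth, paths$truth_contigs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (db in names(hits))
      writeLines(hits[[db]], paths[[paste0("blast_", db)]])

    files <- unlist(paths, use.names = FALSE)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(manifest = manifest, paths = paths,
         truth = list(host = host$truth, symbiont = sym$truth,
                      contigs = contig_truth, sym_truth_loci = sym$truth$loci))
  })
}

#' Read contig lengths from a FASTA file
#'
#' @param path FASTA path.
#' @return named integer vector contig -> length.
#' @export
read_fasta_lengths <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  grp <- cumsum(hdr)
  lens <- tapply(nchar(lines[!hdr]), grp[!hdr], sum)
  stats::setNames(as.integer(lens), ids)
}
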
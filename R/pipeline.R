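#' Pipeline configuration
#'
#' @param vcf path to the (unfiltered, combined) VCF.
#' @param pop_map path to the population map CSV.
#' @param fasta path to the reference contig FASTA (for lengths), or NULL
#'   when `assignment` is given.
#' @param blast named list of BLAST hit table paths keyed by database tag
#'   (dirty_coral, dirty_sym, clean_coral, clean_sym, rRNA_LSU, rRNA_SSU),
#'   or NULL when `assignment` is given.
#' @param assignment path to a precomputed contig assignment TSV, or NULL.
#' @param annotation path to the GO annotation TSV, or NULL to skip
#'   enrichment.
#' @param params a [filter_params()].
#' @param fdr outlier false-discovery proportion (default 0.005).
#' @param n_pod_loci POD size (default 10000).
#' @param n_perm permutations for Fst tests (default 999).
#' @param clone_threshold clone-calling cutoff (default 0.05).
#' @param groupings host analysis groupings to run (subset of
#'   "all", "VA-only", "RI-only").
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, pop_map, fasta = NULL, blast = NULL,
                            assignment = NULL, annotation = NULL,
                            params = filter_params(), fdr = 0.005,
                            n_pod_loci = 10000, n_perm = 999,
                            clone_threshold = 0.05,
                            groupings = c("all", "VA-only", "RI-only"),
                            seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("vcf", "pop_map")) {
    if (!file.exists(cfg[[f]])) stop_holopop("%s file not found: %s", f, cfg[[f]])
  }
  if (is.null(assignment) && (is.null(fasta) || is.null(blast)))
    stop_holopop("provide either an assignment TSV or fasta + blast tables")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON config path; relative paths are resolved against the
#'   config file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  fp <- do.call(filter_params, as.list(j$params %||% list()))
  pipeline_config(vcf = rel(j$vcf), pop_map = rel(j$pop_map),
                  fasta = rel(j$fasta),
                  blast = if (!is.null(j$blast)) lapply(j$blast, rel),
                  assignment = rel(j$assignment), annotation = rel(j$annotation),
                  params = fp, fdr = j$fdr %||% 0.005,
                  n_pod_loci = j$n_pod_loci %||% 10000,
                  n_perm = j$n_perm %||% 999,
                  clone_threshold = j$clone_threshold %||% 0.05,
                  groupings = j$groupings %||% c("all", "VA-only", "RI-only"),
                  seed = as.integer(j$seed %||% 1L))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_holopop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

analyse_compartment <- function(gm, pm, cfg, label, outdir, check_clones) {
  art <- list()
  cas <- stage(paste0(label, ":filter"), run_cascade(gm, pm, cfg$params))
  write_filter_report(cas$report,
                      file.path(outdir, paste0(label, "_filter_report.tsv")))
  g <- cas$gm
  if (check_clones && nrow(g$calls) >= 3) {
    cr <- stage(paste0(label, ":clones"), {
      dm <- allelic_distance(g, "hamming")
      detect_clones(dm, cfg$clone_threshold, seed = child_seed(cfg$seed, 11L))
    })
    write_clone_report(cr, file.path(outdir, paste0(label, "_clones.tsv")))
    write_clone_dendrogram(cr, file.path(outdir, paste0(label, "_dendrogram.nwk")))
    if (length(cr$remove))
      g <- gm_subset(g, samples = setdiff(gm_samples(g), cr$remove))
    art$clones <- cr
  }
  model <- stage(paste0(label, ":omega"), estimate_omega(g, pm))
  sc <- stage(paste0(label, ":xtx"), xtx(g, pm, model))
  pod <- stage(paste0(label, ":pod"),
               pod_calibrate(g, pm, model, n_pod_loci = cfg$n_pod_loci,
                             fdr = cfg$fdr, seed = child_seed(cfg$seed, 21L)))
  sc <- classify_outliers(sc, pod$threshold)
  write_outlier_scores(sc, model,
                       file.path(outdir, paste0(label, "_xtx.tsv")))
  sets <- split_by_class(g, sc)
  reports <- list()
  for (cls in c("neutral", "outlier")) {
    sgm <- sets[[cls]]
    if (is.null(sgm) || ncol(sgm$calls) < 2) next
    thin <- thin_one_snp_per_contig(sgm, seed = child_seed(cfg$seed, 31L))
    rep_k <- stage(paste0(label, ":stats:", cls),
                   structure_report(thin, pm, locus_set = cls,
                                    n_perm = cfg$n_perm,
                                    seed = child_seed(cfg$seed, 41L)))
    pca <- stage(paste0(label, ":pca:", cls), gm_pca(thin))
    utils::write.table(
      data.frame(sample = rownames(pca$coordinates),
                 pca$coordinates[, seq_len(min(6, ncol(pca$coordinates)))]),
      file.path(outdir, paste0(label, "_", cls, "_pca.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ## SVG: deterministic output (the pdf device embeds a creation date)
    plot_pca(pca, pm, file.path(outdir, paste0(label, "_", cls, "_pca.svg")),
             main = paste(label, cls))
    reports[[cls]] <- list(stats = rep_k, pca = pca, n_loci = ncol(thin$calls),
                           n_loci_unthinned = ncol(sgm$calls))
  }
  write_fst_table(reports$neutral$stats, reports$outlier$stats,
                  file.path(outdir, paste0(label, "_fst.tsv")))
  c(art, list(gm = g, model = model, scores = sc, threshold = pod$threshold,
              reports = reports))
}

#' Run the full holobiont analysis pipeline
#'
#' Compartment split, filter cascade, clone removal, outlier detection,
#' one-SNP-per-contig thinning, population structure and diversity, PCA
#' and GO enrichment — once for the host (plus per-origin reruns) and once
#' for the symbiont (brown hosts only, two populations). All artifacts and
#' a checksum manifest land in `outdir`.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir run directory (created).
#' @return list: per-grouping results, `overlap` (shared outlier loci
#'   between per-origin reruns, when run), `manifest`.
#' @export
run_pipeline <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- stage("read_vcf", read_vcf(cfg$vcf))
  pm <- stage("read_pop_map", read_population_map(cfg$pop_map))

  assign <- stage("compartment", {
    if (!is.null(cfg$assignment)) {
      df <- utils::read.delim(cfg$assignment, stringsAsFactors = FALSE)
      class(df) <- c("compartment_assignment", "data.frame")
      df
    } else {
      lens <- read_fasta_lengths(cfg$fasta)
      hits <- do.call(rbind, lapply(names(cfg$blast), function(db)
        read_blast_hits(cfg$blast[[db]], db)))
      assign_compartments(lens, hits)
    }
  })
  write_compartments(assign, file.path(outdir, "compartments.tsv"))
  parts <- stage("split_vcf", split_by_compartment(gm, assign))

  results <- list()
  if (!is.null(parts$host)) {
    for (grp in cfg$groupings) {
      sub <- gm_grouping(parts$host, pm, grp)
      label <- paste0("host_", gsub("-", "", grp))
      results[[label]] <- analyse_compartment(sub, pm, cfg, label, outdir,
                                              check_clones = (grp == "all"))
    }
  }
  if (!is.null(parts$symbiont)) {
    sym <- gm_grouping(parts$symbiont, pm, "brown-only")
    ## drop samples with no symbiont data at all (e.g. clone ramets)
    has_data <- rowMeans(is.na(sym$calls)) < 1
    sym <- gm_subset(sym, samples = which(has_data))
    results$symbiont <- analyse_compartment(sym, pm, cfg, "symbiont", outdir,
                                            check_clones = FALSE)
  }

  if (!is.null(cfg$annotation) && !is.null(results$host_all)) {
    enr <- stage("enrichment", {
      annot <- read_go_annotation(cfg$annotation)
      sets <- outlier_gene_sets(results$host_all$gm, results$host_all$scores)
      fisher_enrichment(sets$outlier_genes, sets$universe, annot)
    })
    if (!is.null(enr))
      utils::write.table(enr, file.path(outdir, "go_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    results$enrichment <- enr
  }

  per_origin <- intersect(c("host_VAonly", "host_RIonly"), names(results))
  if (length(per_origin) >= 2) {
    sets <- lapply(results[per_origin], function(r)
      r$scores$locus_id[r$scores$class == "high_outlier"])
    results$overlap <- report_overlap(sets)
    utils::write.table(results$overlap$summary,
                       file.path(outdir, "outlier_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  invisible(results)
}

#' Shared outlier loci between analysis groupings
#'
#' @param outlier_sets named list of character vectors (locus ids,
#'   contig_position) per grouping.
#' @return list: `shared` (locus ids in every grouping), `summary`
#'   (data.frame of per-grouping and shared counts).
#' @export
report_overlap <- function(outlier_sets) {
  if (length(outlier_sets) < 2) stop_holopop("need at least 2 groupings")
  shared <- Reduce(intersect, outlier_sets)
  summary <- data.frame(
    grouping = c(names(outlier_sets), "shared"),
    n_outliers = c(vapply(outlier_sets, length, integer(1)), length(shared)),
    stringsAsFactors = FALSE)
  list(shared = shared, summary = summary)
}
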
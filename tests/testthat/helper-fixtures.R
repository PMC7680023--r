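# Fixtures built in code and independent brute-force oracles.

# A tiny hand-written genotype matrix: 6 samples (2 pops) x 5 loci on 3 contigs.
tiny_gm <- function() {
  calls <- rbind(
    A1 = c(0L, 1L, 2L, 0L, NA),
    A2 = c(0L, 1L, 1L, 0L, 1L),
    A3 = c(1L, 2L, 1L, 0L, 0L),
    B1 = c(2L, 0L, 0L, 1L, 2L),
    B2 = c(2L, 0L, 1L, NA, 2L),
    B3 = c(1L, 0L, 0L, 0L, 1L))
  loci <- data.frame(contig = c("c1", "c1", "c2", "c2", "c3"),
                     pos = c(10L, 40L, 5L, 77L, 12L),
                     ref = c("A", "C", "G", "T", "A"),
                     alt = c("T", "G", "A", "C", "G"),
                     stringsAsFactors = FALSE)
  depth <- matrix(20L, 6, 5, dimnames = list(rownames(calls), NULL))
  geno_matrix(calls, loci, depth = depth, qual = c(100, 50, 31, 200, 60))
}

tiny_pm <- function() {
  pop_map(c("A1", "A2", "A3", "B1", "B2", "B3"),
          origin = rep(c("VA", "RI"), each = 3),
          state = rep("B", 6))
}

# random small genotype matrix for property tests
random_gm <- function(n = 12, L = 40, miss = 0.1, seed = 1) {
  withr::with_seed(seed, {
    calls <- matrix(sample(c(0:2, NA), n * L, replace = TRUE,
                           prob = c((1 - miss) * c(0.4, 0.35, 0.25), miss)),
                    n, L, dimnames = list(sprintf("s%02d", 1:n), NULL))
    storage.mode(calls) <- "integer"
    depth <- matrix(rpois(n * L, 15), n, L)
    loci <- data.frame(contig = sprintf("c%03d", sample(1:(max(2, L %/% 3)),
                                                        L, replace = TRUE)),
                       pos = sample(1e4, L), ref = "A", alt = "T",
                       stringsAsFactors = FALSE)
    geno_matrix(calls, loci, depth = depth, qual = runif(L, 20, 500))
  })
}

random_pm <- function(gm, n_pops = 2, seed = 1) {
  n <- nrow(gm$calls)
  withr::with_seed(seed, {
    pops <- sort(rep_len(seq_len(n_pops), n))
    pop_map(gm_samples(gm), origin = paste0("O", pops), state = "B")
  })
}

# --- independent oracles -----------------------------------------------------

# allelic distance by explicit pairwise looping
bf_allelic_dist <- function(calls, metric) {
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    ham <- sum(abs(calls[i, ok] - calls[j, ok]))
    d[i, j] <- switch(metric,
                      hamming = ham,
                      manhattan = ham,
                      prevosti = ham / (2 * sum(ok)))
  }
  d
}

# exact HWE genotype-configuration distribution by counting arrangements:
# the number of ways to realize (n0, n1, n2) from the allele counts is
# n! / (n0! n1! n2!) * 2^n1; probabilities follow by normalizing over all
# heterozygote counts compatible with the allele counts.
enum_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n0 + n1
  nb <- 2 * n2 + n1
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logw <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
      lfactorial((nb - h) / 2) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  pobs <- p[match(n1, hets)]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]))
}

# brute-force per-step filter predicates (independent of the package's
# vectorized implementations)
bf_site_keep_basic <- function(gm, params) {
  vapply(seq_len(ncol(gm$calls)), function(l) {
    if (!is.na(gm$qual[l]) && gm$qual[l] <= params$qual_min) return(FALSE)
    if (params$biallelic_only && gm$loci$multiallelic[l]) return(FALSE)
    if (params$drop_indels &&
        (nchar(gm$loci$ref[l]) != 1 || nchar(gm$loci$alt[l]) != 1)) return(FALSE)
    g <- gm$calls[, l]; g <- g[!is.na(g)]
    alt <- sum(g); tot <- 2 * length(g)
    min(alt, tot - alt) >= params$mac_min
  }, logical(1))
}

bf_ind_keep <- function(gm, thr) {
  vapply(seq_len(nrow(gm$calls)), function(i)
    mean(is.na(gm$calls[i, ])) <= thr, logical(1))
}

bf_site_keep_secondary <- function(gm, params) {
  vapply(seq_len(ncol(gm$calls)), function(l) {
    g <- gm$calls[, l]
    if (mean(is.na(g)) > params$site_missing_max) return(FALSE)
    gg <- g[!is.na(g)]
    alt <- sum(gg); tot <- 2 * length(gg)
    if (tot == 0 || min(alt, tot - alt) / tot < params$maf_min) return(FALSE)
    mean(gm$depth[, l]) >= params$mean_depth_min
  }, logical(1))
}

# brute-force contig assignment re-evaluation
bf_assign <- function(hits, min_overlap = 100, min_identity = 60) {
  q <- function(dbs) {
    h <- hits[hits$database %in% dbs, , drop = FALSE]
    any(h$align_length > min_overlap & h$pct_identity >= min_identity)
  }
  coral <- q(c("dirty_coral", "clean_coral"))
  sym <- q(c("dirty_sym", "clean_sym"))
  if (coral && q("clean_sym")) return("ambiguous_removed")
  if (sym && q("clean_coral")) return("ambiguous_removed")
  if (coral && sym) return("ambiguous_removed")
  if (coral) return("host")
  if (sym) return("symbiont")
  "unassigned"
}
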
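#' Population map
#'
#' Maps each sample to an origin (e.g. VA or RI) and a symbiotic state
#' (B = symbiotic "brown", W = aposymbiotic "white"). The population label is
#' `origin-state`, giving the four-population layout (VA-B, VA-W, RI-B, RI-W)
#' and, by grouping, the two-origin layout.
#'
#' @param sample character vector of sample ids.
#' @param origin character vector of origins.
#' @param state character vector of states.
#' @return a data.frame of class `pop_map` with columns `sample`, `origin`,
#'   `state`, `pop`.
#' @export
pop_map <- function(sample, origin, state) {
  origin <- rep_len(origin, length(sample))
  state <- rep_len(state, length(sample))
  if (anyDuplicated(sample)) stop_holopop("duplicated sample ids in population map")
  pm <- data.frame(sample = as.character(sample),
                   origin = as.character(origin),
                   state = as.character(state),
                   stringsAsFactors = FALSE)
  pm$pop <- paste(pm$origin, pm$state, sep = "-")
  class(pm) <- c("pop_map", "data.frame")
  pm
}

#' Read a population map from CSV
#'
#' Expects columns `sample,origin,state`.
#'
#' @param path CSV file path.
#' @return a `pop_map`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "origin", "state")
  if (!all(need %in% names(df)))
    stop_holopop("population map must have columns: %s", paste(need, collapse = ", "))
  pop_map(df$sample, df$origin, df$state)
}

#' Write a population map to CSV
#' @param pm a `pop_map`.
#' @param path output path.
#' @export
write_population_map <- function(pm, path) {
  utils::write.csv(pm[, c("sample", "origin", "state")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population labels for the samples of a genotype matrix
#'
#' @param gm a `geno_matrix`.
#' @param pm a `pop_map` covering every sample of `gm`.
#' @param by grouping: "pop" (origin-state, the four-population analysis)
#'   or "origin" (two-population analysis).
#' @return character vector of labels, one per sample of `gm`, in sample order.
#' @export
pop_labels <- function(gm, pm, by = c("pop", "origin")) {
  by <- match.arg(by)
  ids <- gm_samples(gm)
  idx <- match(ids, pm$sample)
  if (anyNA(idx))
    stop_holopop("samples absent from population map: %s",
                 paste(ids[is.na(idx)], collapse = ", "))
  pm[[by]][idx]
}

#' Restrict a genotype matrix to one analysis grouping
#'
#' Groupings mirror the study design: the host is analysed as four
#' populations, then rerun per origin; the symbiont exists only in brown
#' (symbiotic) hosts and is analysed as the two B populations.
#'
#' @param gm a `geno_matrix`.
#' @param pm a `pop_map`.
#' @param grouping one of "all", "VA-only", "RI-only", "brown-only".
#' @return a `geno_matrix` with the selected samples.
#' @export
gm_grouping <- function(gm, pm, grouping = c("all", "VA-only", "RI-only", "brown-only")) {
  grouping <- match.arg(grouping)
  idx <- match(gm_samples(gm), pm$sample)
  keep <- switch(grouping,
    "all" = rep(TRUE, nrow(gm$calls)),
    "VA-only" = pm$origin[idx] == "VA",
    "RI-only" = pm$origin[idx] == "RI",
    "brown-only" = pm$state[idx] == "B")
  gm_subset(gm, samples = which(keep))
}
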
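#' Construct a diet profile
#'
#' A per-predator vector of prey proportions, on either the relative
#' frequency of occurrence (`rfo`) or relative biomass (`biomass`) basis.
#' Input values are normalized to sum to 1, so percent columns and raw
#' counts are equally acceptable.
#'
#' @param x named non-negative numeric vector (proportions, percents or
#'   counts).
#' @param predator predator label.
#' @param basis `"rfo"` or `"biomass"`.
#' @return object of class `diet_profile`: named proportions summing to 1
#'   with attributes `predator` and `basis`.
#' @export
diet_profile <- function(x, predator = NA_character_,
                         basis = c("rfo", "biomass")) {
  basis <- match.arg(basis)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("diet profile values must be named by prey species")
  if (any(x < 0)) stop("diet proportions must be non-negative")
  if (sum(x) <= 0) stop("all-zero diet profile")
  p <- x / sum(x)
  names(p) <- canonical_name(names(p))
  structure(p, predator = canonical_name(predator), basis = basis,
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, digits = 2, ...) {
  cat("Diet profile (", attr(x, "basis"), ") for ",
      attr(x, "predator"), " [%]:\n", sep = "")
  print(round(100 * unclass(x), digits))
  invisible(x)
}

#' Convert a diet profile to percent
#'
#' @param profile a `diet_profile`.
#' @param digits decimal places for reporting (default 2; internal values
#'   keep full precision).
#' @return named numeric vector of percentages.
#' @export
as_percent <- function(profile, digits = 2) {
  stats::setNames(round(100 * as.numeric(profile), digits), names(profile))
}

#' Relative frequency of occurrence profile
#'
#' RFO_i = occurrences of prey i / total occurrences of all prey items
#' across the predator's scats.
#'
#' @param freq a `frequency_table` from [occurrence_counts()].
#' @return a `diet_profile` with basis `"rfo"`.
#' @export
rfo_profile <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  if (freq$total_occurrences <= 0)
    stop("frequency table has zero total occurrences")
  diet_profile(freq$counts, predator = freq$predator, basis = "rfo")
}

# look up origin class for each profile species, erroring on gaps
.origin_of <- function(species, attributes) {
  idx <- match(species, attributes$species)
  if (anyNA(idx))
    stop("prey species without an origin class: ",
         paste(species[is.na(idx)], collapse = ", "))
  attributes$origin[idx]
}

#' Wild vs. domestic aggregate of a diet profile
#'
#' Sums profile proportions over the wild and the domestic (livestock,
#' including dog) prey classes. Works on both RFO and biomass profiles.
#'
#' @param profile a `diet_profile`.
#' @param attributes prey-attributes data.frame (see
#'   [read_prey_attributes()]) with `species` and `origin`.
#' @return named numeric vector `c(wild = , domestic = )` in percent.
#' @export
origin_aggregate <- function(profile, attributes) {
  stopifnot(inherits(profile, "diet_profile"))
  org <- .origin_of(names(profile), attributes)
  wild <- 100 * sum(profile[org == "wild"])
  c(wild = wild, domestic = 100 - wild)
}

#' Scat-level composition summary
#'
#' Per-scat descriptive statistics for one predator: the distribution of
#' per-scat prey richness, the percentage of scats containing exclusively
#' wild prey or exclusively livestock, and the wild/domestic split of the
#' RFO diet.
#'
#' @param dataset a `scat_dataset`.
#' @param predator predator label.
#' @param attributes prey-attributes data.frame.
#' @return object of class `composition_summary`.
#' @export
scat_level_summary <- function(dataset, predator, attributes) {
  m <- occurrence_matrix(dataset, predator)
  org <- .origin_of(colnames(m), attributes)
  richness <- rowSums(m)
  rich_tab <- table(richness)
  pct_rich <- stats::setNames(100 * as.numeric(rich_tab) / nrow(m),
                              names(rich_tab))
  wild_only <- 100 * mean(rowSums(m[, org == "domestic", drop = FALSE]) == 0)
  dom_only  <- 100 * mean(rowSums(m[, org == "wild", drop = FALSE]) == 0)
  agg <- origin_aggregate(rfo_profile(occurrence_counts(dataset, predator)),
                          attributes)
  structure(list(predator = canonical_name(predator),
                 n_scats = nrow(m),
                 pct_scats_by_richness = pct_rich,
                 pct_scats_wild_only = wild_only,
                 pct_scats_livestock_only = dom_only,
                 pct_diet_wild = agg[["wild"]],
                 pct_diet_domestic = agg[["domestic"]]),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Composition summary for", x$predator, "(", x$n_scats, "scats )\n")
  cat("  scats by prey richness [%]:\n")
  print(round(x$pct_scats_by_richness, 2))
  cat(sprintf("  wild-only scats: %.2f%%  livestock-only scats: %.2f%%\n",
              x$pct_scats_wild_only, x$pct_scats_livestock_only))
  cat(sprintf("  diet (RFO) wild: %.2f%%  domestic: %.2f%%\n",
              x$pct_diet_wild, x$pct_diet_domestic))
  invisible(x)
}

#' Prey accumulation curve (sample-sufficiency check)
#'
#' Randomized accumulation of prey richness against number of scats: for
#' m = 1..N, the mean and sd over `n_reps` random scat orderings of the
#' number of unique prey species seen in the first m scats. A plateau before
#' m = N indicates the sample was large enough to capture the diet's
#' species richness.
#'
#' @param dataset a `scat_dataset`.
#' @param predator predator label.
#' @param n_reps number of random orderings (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `n_scats`, `mean_richness`,
#'   `sd_richness`.
#' @export
accumulation_curve <- function(dataset, predator, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  m <- occurrence_matrix(dataset, predator)
  n <- nrow(m)
  set.seed(seed)
  acc <- matrix(0, nrow = n, ncol = n_reps)
  for (r in seq_len(n_reps)) {
    ord <- sample.int(n)
    seen <- apply(m[ord, , drop = FALSE], 2L, cummax)
    if (n == 1L) seen <- matrix(seen, nrow = 1L)
    acc[, r] <- rowSums(seen)
  }
  data.frame(n_scats = seq_len(n),
             mean_richness = rowMeans(acc),
             sd_richness = apply(acc, 1L, stats::sd))
}
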
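#' Pianka's dietary niche overlap
#'
#' DO = sum_i p_i q_i / sqrt(sum_i p_i^2 * sum_i q_i^2), the cosine
#' similarity of the two diet proportion vectors over the union of their
#' prey species (a species absent from one diet contributes 0). Ranges from
#' 0 (no shared prey) to 1 (identical diets); symmetric and scale-invariant.
#'
#' @param p,q `diet_profile` objects (or named non-negative vectors, which
#'   are normalized).
#' @return object of class `overlap_result`: list with `value`, `basis`,
#'   `predators`.
#' @examples
#' ref <- load_reference_diet()
#' p <- diet_profile(setNames(ref$snow_leopard$rb, ref$snow_leopard$species),
#'                   "snow_leopard", basis = "biomass")
#' q <- diet_profile(setNames(ref$wolf$rb, ref$wolf$species),
#'                   "wolf", basis = "biomass")
#' pianka_overlap(p, q)$value  # 0.937
#' @export
pianka_overlap <- function(p, q) {
  if (!inherits(p, "diet_profile")) p <- diet_profile(p)
  if (!inherits(q, "diet_profile")) q <- diet_profile(q)
  species <- union(names(p), names(q))
  pv <- qv <- stats::setNames(numeric(length(species)), species)
  pv[names(p)] <- p
  qv[names(q)] <- q
  if (sum(pv) == 0 || sum(qv) == 0) stop("all-zero diet profile")
  value <- sum(pv * qv) / sqrt(sum(pv^2) * sum(qv^2))
  basis <- if (identical(attr(p, "basis"), attr(q, "basis")))
    attr(p, "basis") else "mixed"
  structure(list(value = value, basis = basis,
                 predators = c(attr(p, "predator"), attr(q, "predator"))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Pianka dietary overlap (%s basis) between %s and %s: %.3f\n",
              x$basis, x$predators[1], x$predators[2], x$value))
  invisible(x)
}

#' Levins niche breadth
#'
#' B = 1 / sum_i p_i^2, ranging from 1 (single-resource specialist) to k
#' (uniform use of all k resources). The standardized form
#' B_A = (B - 1)/(k - 1) in [0, 1] is available via `standardized = TRUE`.
#'
#' @param p a `diet_profile` (or named non-negative vector, normalized).
#' @param standardized return B_A instead of B.
#' @return numeric scalar.
#' @export
levins_breadth <- function(p, standardized = FALSE) {
  if (!inherits(p, "diet_profile")) p <- diet_profile(p)
  b <- 1 / sum(unclass(p)^2)
  if (standardized) {
    k <- length(p)  # categories in the profile's universe, including zeros
    if (k < 2L) return(0)
    b <- (b - 1) / (k - 1)
  }
  b
}

# internal: Levins breadth per column of a prey-by-replicate count matrix
.levins_of_counts <- function(counts) {
  tot <- colSums(counts)
  props <- sweep(counts, 2L, tot, "/")
  1 / colSums(props^2)
}

#' Cluster-bootstrap confidence interval for Levins breadth
#'
#' Resamples whole scats (the independent sampling unit) with replacement,
#' recomputes the RFO profile and its Levins breadth per replicate, and
#' returns a percentile interval. Occurrences within one scat are not
#' independent, so the scat, not the occurrence, is the resampling unit.
#'
#' @param dataset a `scat_dataset`.
#' @param predator predator label.
#' @param n_boot bootstrap replicates (default 10000, minimum 100).
#' @param alpha two-sided miscoverage (default 0.05 for a 95% interval).
#' @param seed integer seed.
#' @return object of class `niche_breadth_result`: list with `value` (point
#'   estimate from the observed profile), `ci_low`, `ci_high`, `n_boot`,
#'   `alpha`, `seed`, `predator`.
#' @export
bootstrap_breadth_ci <- function(dataset, predator, n_boot = 10000L,
                                 alpha = 0.05, seed = 1L) {
  stopifnot(n_boot >= 100L, alpha > 0, alpha < 1)
  m <- occurrence_matrix(dataset, predator)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 scats for a bootstrap interval")
  value <- levins_breadth(rfo_profile(occurrence_counts(dataset, predator)))
  set.seed(seed)
  # resampling scats with replacement == multinomial weights over scats
  w <- stats::rmultinom(n_boot, n, rep.int(1, n))
  counts <- crossprod(m, w)                 # prey x n_boot occurrence counts
  b <- .levins_of_counts(counts)
  ci <- stats::quantile(b, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(value = value, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed),
                 predator = canonical_name(predator)),
            class = "niche_breadth_result")
}

#' @export
print.niche_breadth_result <- function(x, ...) {
  cat(sprintf(
    "Levins niche breadth for %s: %.2f (%.0f%% bootstrap CI %.2f-%.2f, %d reps)\n",
    x$predator, x$value, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Permutation test for an interspecific difference in niche breadth
#'
#' Statistic: |B_a - B_b| on the two predators' RFO profiles. The null
#' distribution is built by pooling all scats and randomly reassigning
#' predator labels while preserving group sizes; the p-value includes the
#' observed statistic in the null set: p = (1 + #{null >= obs}) /
#' (n_perm + 1), so p is never 0.
#'
#' @param dataset a `scat_dataset`.
#' @param pred_a,pred_b the two predator labels.
#' @param n_perm permutations (default 9999, minimum 99).
#' @param seed integer seed.
#' @return object of class `breadth_difference_test`: list with
#'   `observed_diff`, `p_value`, `n_perm`, `seed`, plus the two observed
#'   breadths.
#' @export
breadth_difference_test <- function(dataset, pred_a, pred_b,
                                    n_perm = 9999L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  ma <- occurrence_matrix(dataset, pred_a)
  mb <- occurrence_matrix(dataset, pred_b)
  b_a <- levins_breadth(rfo_profile(occurrence_counts(dataset, pred_a)))
  b_b <- levins_breadth(rfo_profile(occurrence_counts(dataset, pred_b)))
  obs <- abs(b_a - b_b)
  pooled <- rbind(ma, mb)
  n <- nrow(pooled)
  na <- nrow(ma)
  if (sum(colSums(pooled) > 0) < 2L) {
    warning("pooled dataset contains a single prey species; ",
            "breadth difference is degenerate")
    p <- 1
  } else {
    set.seed(seed)
    # 0/1 assignment matrix: each column selects na scats for group a
    z <- matrix(0L, nrow = n, ncol = n_perm)
    for (r in seq_len(n_perm)) z[sample.int(n, na), r] <- 1L
    tot <- colSums(pooled)                       # pooled prey occurrence
    ca <- crossprod(pooled, z)                   # prey x n_perm, group a
    cb <- tot - ca
    null <- abs(.levins_of_counts(ca) - .levins_of_counts(cb))
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
  }
  structure(list(observed_diff = obs, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 breadth_a = b_a, breadth_b = b_b,
                 predators = canonical_name(c(pred_a, pred_b))),
            class = "breadth_difference_test")
}

#' @export
print.breadth_difference_test <- function(x, ...) {
  cat(sprintf(
    "Breadth difference %s vs %s: |%.2f - %.2f| = %.3f, p = %.4f (%d permutations)\n",
    x$predators[1], x$predators[2], x$breadth_a, x$breadth_b,
    x$observed_diff, x$p_value, x$n_perm))
  invisible(x)
}
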
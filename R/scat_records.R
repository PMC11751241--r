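#' @keywords internal
"_PACKAGE"

# Known predator labels used throughout; user-supplied datasets may extend
# this set via the `predators` argument of read_scat_table().
.default_predators <- c("snow_leopard", "wolf")

#' Canonicalize prey or predator names
#'
#' Lowercases, trims, and converts runs of spaces/hyphens to underscores so
#' that display names ("Blue Sheep") match registry keys ("blue_sheep").
#'
#' @param x character vector of names.
#' @return character vector of canonical keys.
#' @examples
#' canonical_name(c("Blue Sheep", " Snow Leopard "))
#' @export
canonical_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

#' Construct a scat dataset
#'
#' A scat dataset holds one row per (scat, prey item) in long format together
#' with a prey registry. The scat is the sampling unit: a prey species
#' contributes at most one occurrence per scat (presence/absence), so
#' duplicate (scat_id, prey_species) rows are collapsed.
#'
#' @param records data.frame with columns `scat_id`, `predator`,
#'   `prey_species` and optionally `transect_id`.
#' @param prey_registry character vector of allowed prey names; defaults to
#'   the prey observed in `records`.
#' @param predators character vector of allowed predator labels.
#' @return an object of class `scat_dataset`.
#' @export
scat_dataset <- function(records, prey_registry = NULL,
                         predators = .default_predators) {
  stopifnot(is.data.frame(records))
  need <- c("scat_id", "predator", "prey_species")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L)
    stop("records is empty: a scat dataset needs at least one (scat, prey) row")

  records$scat_id      <- as.character(records$scat_id)
  records$predator     <- canonical_name(records$predator)
  records$prey_species <- canonical_name(records$prey_species)

  bad <- setdiff(unique(records$predator), canonical_name(predators))
  if (length(bad) > 0L)
    stop("unknown predator label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(predators, collapse = ", "))

  dup <- duplicated(records[, c("scat_id", "prey_species")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (scat_id, prey_species) row(s) collapsed ",
            "to single occurrences")
    records <- records[!dup, , drop = FALSE]
  }
  # a scat belongs to exactly one predator
  per_scat <- tapply(records$predator, records$scat_id,
                     function(p) length(unique(p)))
  if (any(per_scat > 1L))
    stop("scat id(s) assigned to more than one predator: ",
         paste(names(per_scat)[per_scat > 1L], collapse = ", "))

  if (is.null(prey_registry)) {
    prey_registry <- sort(unique(records$prey_species))
  } else {
    prey_registry <- canonical_name(prey_registry)
    unknown <- setdiff(unique(records$prey_species), prey_registry)
    if (length(unknown) > 0L)
      stop("prey species not in registry: ", paste(unknown, collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 prey_registry = prey_registry,
                 predators = canonical_name(predators)),
            class = "scat_dataset")
}

#' @export
print.scat_dataset <- function(x, ...) {
  ns <- table(x$records$predator[!duplicated(x$records$scat_id)])
  cat("Scat dataset:", length(unique(x$records$scat_id)), "scats,",
      length(x$prey_registry), "prey species in registry\n")
  for (p in names(ns)) cat("  ", p, ": ", ns[[p]], " scats\n", sep = "")
  invisible(x)
}

#' Read a long-format scat table
#'
#' Expects a UTF-8 CSV with a header and columns `scat_id`, `predator`,
#' `prey_species` (optional `transect_id`), one row per prey item found in a
#' scat. Rows sharing a `scat_id` form one scat record; duplicated
#' (scat, prey) rows collapse with a warning.
#'
#' @inheritParams scat_dataset
#' @param path path to the CSV file.
#' @return a `scat_dataset`.
#' @export
read_scat_table <- function(path, prey_registry = NULL,
                            predators = .default_predators) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty scat table: ", path)
  scat_dataset(df, prey_registry = prey_registry, predators = predators)
}

#' Write a scat dataset back to long-format CSV
#'
#' @param dataset a `scat_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scat_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "scat_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an availability table
#'
#' Prey availability in the environment, as counts (e.g., transect sightings
#' or census records; multiple sources are merged by summation) and the
#' derived proportions \eqn{\pi_i}.
#'
#' @param counts named non-negative numeric vector of availability counts, or
#'   `NULL` when `proportions` are supplied directly.
#' @param proportions named numeric vector summing to 1; derived from
#'   `counts` when absent.
#' @return an object of class `availability_table`.
#' @export
availability_table <- function(counts = NULL, proportions = NULL) {
  if (is.null(counts) && is.null(proportions))
    stop("supply counts or proportions")
  if (!is.null(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be a named vector")
    names(counts) <- canonical_name(names(counts))
    if (any(counts < 0)) stop("availability counts must be non-negative")
    if (sum(counts) <= 0) stop("availability counts sum to zero")
    proportions <- counts / sum(counts)
  } else {
    names(proportions) <- canonical_name(names(proportions))
    if (abs(sum(proportions) - 1) > 1e-9)
      stop("availability proportions must sum to 1")
  }
  structure(list(counts = counts, proportions = proportions),
            class = "availability_table")
}

#' Read an availability table from CSV
#'
#' Columns: `prey_species`, `count`. Repeated species rows (e.g., transect
#' sightings plus park census) are summed.
#'
#' @param path path to the CSV file.
#' @return an `availability_table`.
#' @export
read_availability <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("prey_species", "count") %in% names(df)))
    stop("availability file needs columns prey_species, count")
  counts <- tapply(df$count, canonical_name(df$prey_species), sum)
  availability_table(counts = stats::setNames(as.numeric(counts),
                                              names(counts)))
}

#' Read a prey-attributes table
#'
#' Columns: `species` (or `prey_species`), `origin` (`wild`/`domestic`) and
#' optionally `mean_mass_kg`. Masses are needed only for biomass analyses.
#'
#' @param path path to the CSV file.
#' @return data.frame with canonical `species`, `origin`, `mean_mass_kg`.
#' @export
read_prey_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("prey_species" %in% names(df) && !"species" %in% names(df))
    names(df)[names(df) == "prey_species"] <- "species"
  if (!all(c("species", "origin") %in% names(df)))
    stop("prey attributes file needs columns species, origin")
  df$species <- canonical_name(df$species)
  df$origin <- tolower(trimws(df$origin))
  bad <- setdiff(unique(df$origin), c("wild", "domestic"))
  if (length(bad) > 0L)
    stop("origin must be 'wild' or 'domestic'; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicated species in prey attributes: ",
         paste(df$species[duplicated(df$species)], collapse = ", "))
  if (!"mean_mass_kg" %in% names(df)) df$mean_mass_kg <- NA_real_
  if (any(!is.na(df$mean_mass_kg) & df$mean_mass_kg <= 0))
    stop("mean_mass_kg must be positive where present")
  df[, c("species", "origin", "mean_mass_kg")]
}

#' Load the packaged reference diet table
#'
#' The published diet summary for sympatric snow leopards and wolves in
#' Shey Phoksundo National Park, Nepal: per-predator relative frequency of
#' occurrence (FO, %) and relative biomass consumed (RB, %) for 11 prey
#' species (6 wild, 5 domestic). The mountain weasel was not found in wolf
#' scats; its wolf cells are structural zeros (the species is absent from
#' the wolf diet, not missing data) and the wolf tables therefore carry 10
#' entries.
#'
#' @return list with elements `species` (data.frame of species, common
#'   label, origin), `snow_leopard` and `wolf` (data.frames of species,
#'   `fo`, `rb` in percent).
#' @examples
#' ref <- load_reference_diet()
#' ref$snow_leopard[ref$snow_leopard$species == "blue_sheep", ]
#' @export
load_reference_diet <- function() {
  path <- system.file("extdata", "reference_diet_table.csv",
                      package = "scatdiet", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sl <- data.frame(species = df$species, fo = df$fo_snow_leopard,
                   rb = df$rb_snow_leopard)
  wf <- df[!is.na(df$fo_wolf), ]
  wolf <- data.frame(species = wf$species, fo = wf$fo_wolf, rb = wf$rb_wolf)
  list(species = df[, c("species", "common_label", "origin")],
       snow_leopard = sl, wolf = wolf)
}

#' Per-predator prey occurrence counts
#'
#' Counts each prey species once per scat in which it appears
#' (presence/absence); the total is the summed per-scat prey richness and is
#' the denominator of relative frequency of occurrence.
#'
#' @param dataset a `scat_dataset`.
#' @param predator predator label.
#' @return object of class `frequency_table`: list with `predator`, `counts`
#'   (named integer vector over the prey registry), `total_occurrences`,
#'   `n_scats`.
#' @export
occurrence_counts <- function(dataset, predator) {
  stopifnot(inherits(dataset, "scat_dataset"))
  predator <- canonical_name(predator)
  rec <- dataset$records[dataset$records$predator == predator, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no scat records for predator: ", predator)
  counts <- table(factor(rec$prey_species, levels = dataset$prey_registry))
  counts <- stats::setNames(as.integer(counts), dataset$prey_registry)
  structure(list(predator = predator,
                 counts = counts,
                 total_occurrences = sum(counts),
                 n_scats = length(unique(rec$scat_id))),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Occurrence counts for", x$predator, "(", x$n_scats, "scats,",
      x$total_occurrences, "occurrences )\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

# scats x prey presence matrix for one predator; rows are scats (the
# independent resampling unit), columns follow the prey registry.
occurrence_matrix <- function(dataset, predator) {
  predator <- canonical_name(predator)
  rec <- dataset$records[dataset$records$predator == predator, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no scat records for predator: ", predator)
  ids <- unique(rec$scat_id)
  m <- matrix(0L, nrow = length(ids), ncol = length(dataset$prey_registry),
              dimnames = list(ids, dataset$prey_registry))
  m[cbind(match(rec$scat_id, ids),
          match(rec$prey_species, dataset$prey_registry))] <- 1L
  m
}
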
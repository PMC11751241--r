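#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis: predator labels, the
#' basis for the headline overlap, the familywise alpha, resampling sizes,
#' the master seed, per-predator biomass correction models, and input
#' paths.
#'
#' @param predators character vector of predator labels (default the two
#'   study predators).
#' @param overlap_basis `"biomass"` (default, the headline basis) or
#'   `"rfo"` for the Pianka overlap.
#' @param alpha familywise type-I error rate, in (0, 0.5).
#' @param n_boot bootstrap replicates for breadth CIs (>= 99).
#' @param n_perm permutations for the breadth-difference test (>= 99).
#' @param seed master seed; stage seeds are derived from it.
#' @param correction_models named list of [biomass_model()] objects.
#' @param paths named list of input paths: `scats`, `availability`,
#'   `attributes` (prey origins and optional masses).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(predators = .default_predators,
                            overlap_basis = c("biomass", "rfo"),
                            alpha = 0.05, n_boot = 10000L, n_perm = 9999L,
                            seed = 1L,
                            correction_models = default_correction_models(),
                            paths = list()) {
  overlap_basis <- match.arg(overlap_basis)
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must be in (0, 0.5)")
  if (n_boot < 99L || n_perm < 99L) stop("n_boot and n_perm must be >= 99")
  structure(list(predators = canonical_name(predators),
                 overlap_basis = overlap_basis, alpha = alpha,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 correction_models = correction_models,
                 paths = paths),
            class = "analysis_config")
}

# derive distinct reproducible stage seeds from the master seed
.stage_seed <- function(seed, stage) {
  (seed * 1009L + stage * 9973L) %% .Machine$integer.max
}

#' Run the full dietary-niche analysis
#'
#' Composes every stage: per predator, occurrence counts, RFO profile,
#' composition summary, accumulation curve, Levins breadth with a cluster
#' bootstrap CI, and (when masses are available) a relative-biomass
#' profile; jointly, Pianka overlap on both bases, the breadth-difference
#' permutation test, G-tests of use versus availability, and
#' Bonferroni-adjusted selection ratios. Every stochastic stage records its
#' seed. All computation completes before anything is written, so a failed
#' stage leaves no partial output.
#'
#' @param config an [analysis_config()]; its `paths` entries are used
#'   unless `dataset`/`availability`/`attributes` are supplied directly.
#' @param dataset optional `scat_dataset` (overrides `paths$scats`).
#' @param availability optional `availability_table`.
#' @param attributes optional prey-attributes data.frame.
#' @param out optional output directory; when given, writes `report.json`
#'   and `report.md` via [write_report()].
#' @return object of class `analysis_report` (nested list).
#' @export
run_full_analysis <- function(config = analysis_config(), dataset = NULL,
                              availability = NULL, attributes = NULL,
                              out = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("[", label, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(dataset))
    dataset <- stage("read_scats",
                     read_scat_table(config$paths$scats,
                                     predators = config$predators))
  if (is.null(availability) && !is.null(config$paths$availability))
    availability <- stage("read_availability",
                          read_availability(config$paths$availability))
  if (is.null(attributes))
    attributes <- stage("read_attributes",
                        read_prey_attributes(config$paths$attributes))

  preds <- intersect(config$predators, unique(dataset$records$predator))
  if (length(preds) == 0L) stop("[inputs] no configured predator has records")
  have_mass <- all(dataset$prey_registry %in%
                     attributes$species[!is.na(attributes$mean_mass_kg)])

  per_pred <- list()
  rfo <- list(); biomass <- list()
  for (i in seq_along(preds)) {
    p <- preds[i]
    freq <- stage(p, occurrence_counts(dataset, p))
    prof <- rfo_profile(freq)
    rfo[[p]] <- prof
    bio <- NULL
    if (have_mass && !is.null(config$correction_models[[p]]))
      bio <- stage(p, relative_biomass(freq, config$correction_models[[p]],
                                       attributes))
    if (!is.null(bio)) biomass[[p]] <- bio
    boot <- stage(p, bootstrap_breadth_ci(
      dataset, p, n_boot = config$n_boot, alpha = config$alpha,
      seed = .stage_seed(config$seed, 10L + i)))
    per_pred[[p]] <- list(
      n_scats = freq$n_scats,
      occurrence_counts = as.list(freq$counts),
      rfo_percent = as.list(as_percent(prof)),
      biomass_percent = if (is.null(bio)) "skipped: masses unavailable"
                        else as.list(as_percent(bio)),
      origin_rfo = as.list(origin_aggregate(prof, attributes)),
      origin_biomass = if (is.null(bio)) "skipped: masses unavailable"
                       else as.list(origin_aggregate(bio, attributes)),
      levins = boot$value,
      levins_ci = c(boot$ci_low, boot$ci_high),
      boot_seed = boot$seed,
      composition = unclass(stage(p, scat_level_summary(dataset, p,
                                                        attributes))),
      accumulation = stage(p, accumulation_curve(
        dataset, p, n_reps = 100L,
        seed = .stage_seed(config$seed, 20L + i))))
  }

  joint <- list()
  if (length(preds) == 2L) {
    joint$pianka_rfo <- pianka_overlap(rfo[[preds[1]]],
                                       rfo[[preds[2]]])$value
    if (!is.null(biomass[[preds[1]]]) && !is.null(biomass[[preds[2]]]))
      joint$pianka_biomass <-
        pianka_overlap(biomass[[preds[1]]], biomass[[preds[2]]])$value
    joint$overlap_basis <- config$overlap_basis
    bdt <- stage("breadth_difference", breadth_difference_test(
      dataset, preds[1], preds[2], n_perm = config$n_perm,
      seed = .stage_seed(config$seed, 30L)))
    joint$breadth_difference <- unclass(bdt)
  }
  if (!is.null(availability)) {
    joint$selection <- lapply(preds, function(p) {
      freq <- occurrence_counts(dataset, p)
      g <- stage(p, g_test(freq, availability))
      sel <- stage(p, selection_ratios(freq, availability,
                                       alpha = config$alpha))
      list(g_test = unclass(g),
           ratios = as.data.frame(sel),
           z = attr(sel, "z"))
    })
    names(joint$selection) <- preds
  }

  report <- structure(list(
    config = list(predators = preds, overlap_basis = config$overlap_basis,
                  alpha = config$alpha, n_boot = config$n_boot,
                  n_perm = config$n_perm, seed = config$seed),
    n_records = nrow(dataset$records),
    predators = per_pred,
    joint = joint), class = "analysis_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Write an analysis report as JSON and markdown
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Dietary niche analysis report", "",
          sprintf("- records: %d", report$n_records),
          sprintf("- seed: %d", report$config$seed), "")
  for (p in names(report$predators)) {
    x <- report$predators[[p]]
    md <- c(md, sprintf("## %s", p),
            sprintf("- scats: %d", x$n_scats),
            sprintf("- Levins breadth: %.2f (CI %.2f-%.2f)",
                    x$levins, x$levins_ci[1], x$levins_ci[2]),
            sprintf("- diet wild/domestic (RFO): %.2f%% / %.2f%%",
                    x$origin_rfo$wild, x$origin_rfo$domestic), "")
  }
  if (!is.null(report$joint$pianka_biomass))
    md <- c(md, sprintf("Pianka overlap (biomass): %.3f",
                        report$joint$pianka_biomass))
  if (!is.null(report$joint$pianka_rfo))
    md <- c(md, sprintf("Pianka overlap (RFO): %.3f",
                        report$joint$pianka_rfo))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Validate an analysis report against the shipped schema
#'
#' Structural validation: checks that the required fields listed in the
#' packaged `report_schema.json` are present with the right types.
#'
#' @param report an `analysis_report` or a list parsed from `report.json`.
#' @return TRUE invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "scatdiet",
                                            mustWork = TRUE))
  for (f in names(schema$required_top_level))
    if (is.null(report[[f]]))
      stop("report missing required field: ", f)
  for (f in unlist(schema$required_per_predator))
    for (p in names(report$predators))
      if (is.null(report$predators[[p]][[f]]))
        stop("report predator '", p, "' missing field: ", f)
  invisible(TRUE)
}

#' Demonstration run on the packaged reference diet table
#'
#' Recomputes the headline statistics from the packaged reference table and
#' checks them against their published values: Pianka overlap on the
#' biomass basis (0.937), Levins breadth for the snow leopard (6.45) and
#' wolf (5.98), snow-leopard wild RFO share (55.28%), and wolf domestic RFO
#' share (67.89%). Read-only with respect to package data.
#'
#' @param table a reference-diet list as returned by
#'   [load_reference_diet()]; exposed so corrupted input can be exercised.
#' @param quiet suppress the PASS/FAIL lines.
#' @return integer exit status, invisibly: 0 when all checks pass.
#' @export
run_demo <- function(table = load_reference_diet(), quiet = FALSE) {
  status <- 0L
  say <- function(ok, label, got, want) {
    if (!ok) status <<- 1L
    if (!quiet)
      cat(sprintf("%s  %-38s got %8.3f  expected %8.3f\n",
                  if (ok) "PASS" else "FAIL", label, got, want))
  }
  res <- tryCatch({
    sl_fo <- diet_profile(stats::setNames(table$snow_leopard$fo,
                                          table$snow_leopard$species),
                          "snow_leopard", "rfo")
    wf_fo <- diet_profile(stats::setNames(table$wolf$fo,
                                          table$wolf$species),
                          "wolf", "rfo")
    sl_rb <- diet_profile(stats::setNames(table$snow_leopard$rb,
                                          table$snow_leopard$species),
                          "snow_leopard", "biomass")
    wf_rb <- diet_profile(stats::setNames(table$wolf$rb,
                                          table$wolf$species),
                          "wolf", "biomass")
    attrs <- data.frame(species = table$species$species,
                        origin = table$species$origin,
                        mean_mass_kg = NA_real_)
    say(abs(pianka_overlap(sl_rb, wf_rb)$value - 0.937) <= 0.0005 + 1e-12,
        "Pianka overlap (biomass basis)",
        pianka_overlap(sl_rb, wf_rb)$value, 0.937)
    say(round(levins_breadth(sl_fo), 2) == 6.45,
        "Levins breadth, snow leopard (RFO)", levins_breadth(sl_fo), 6.45)
    say(round(levins_breadth(wf_fo), 2) == 5.98,
        "Levins breadth, wolf (RFO)", levins_breadth(wf_fo), 5.98)
    say(abs(origin_aggregate(sl_fo, attrs)[["wild"]] - 55.28) <= 0.05,
        "Snow leopard wild diet share (RFO %)",
        origin_aggregate(sl_fo, attrs)[["wild"]], 55.28)
    say(abs(origin_aggregate(wf_fo, attrs)[["domestic"]] - 67.89) <= 0.05,
        "Wolf domestic diet share (RFO %)",
        origin_aggregate(wf_fo, attrs)[["domestic"]], 67.89)
    status
  }, error = function(e) {
    if (!quiet) cat("FAIL  demo aborted:", conditionMessage(e), "\n")
    1L
  })
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `demo` (reproduce the published headline statistics from
#' the packaged table), `simulate --seed S --out DIR` (write a synthetic
#' scats.csv and availability.csv under the default study conditions), and
#' `run --scats PATH --availability PATH --attributes PATH --out DIR
#' [--seed S] [--n-boot B] [--n-perm P]` (full analysis).
#'
#' @param args character vector of arguments (default: the command line).
#' @return integer exit status, invisibly.
#' @export
scatdiet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  flag <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  if (length(args) == 0L) {
    cat("usage: scatdiet <demo|simulate|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  status <- switch(
    cmd,
    demo = run_demo(),
    simulate = {
      seed <- as.integer(flag("--seed", "1"))
      out <- flag("--out", "simulation")
      write_simulation(generate_dataset(default_generator_config(seed)), out)
      cat("wrote scats.csv and availability.csv to", out, "\n")
      0L
    },
    run = {
      cfg <- analysis_config(
        seed = as.integer(flag("--seed", "1")),
        n_boot = as.integer(flag("--n-boot", "10000")),
        n_perm = as.integer(flag("--n-perm", "9999")),
        paths = list(scats = flag("--scats"),
                     availability = flag("--availability"),
                     attributes = flag("--attributes")))
      report <- run_full_analysis(cfg, out = flag("--out", "analysis_out"))
      cat("report written; Pianka (RFO) =",
          round(report$joint$pianka_rfo, 3), "\n")
      0L
    },
    {
      cat("unknown subcommand:", cmd, "\n")
      1L
    })
  invisible(status)
}
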
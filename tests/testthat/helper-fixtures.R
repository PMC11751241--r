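# shared fixture builders; everything is generated in code, no files needed

# quick long-format dataset: prey_sets is a named list scat_id -> prey vector,
# predators a parallel named vector scat_id -> label
make_dataset <- function(prey_sets, predators, ...) {
  df <- do.call(rbind, lapply(names(prey_sets), function(id)
    data.frame(scat_id = id, predator = predators[[id]],
               prey_species = prey_sets[[id]])))
  scat_dataset(df, ...)
}

# n_a scats of each prey set in sets_a for predator a, likewise b
make_two_predator_dataset <- function(sets_a, sets_b,
                                      pred_a = "snow_leopard",
                                      pred_b = "wolf", ...) {
  ids_a <- paste0("a", seq_along(sets_a))
  ids_b <- paste0("b", seq_along(sets_b))
  sets <- c(stats::setNames(sets_a, ids_a), stats::setNames(sets_b, ids_b))
  preds <- stats::setNames(c(rep(pred_a, length(sets_a)),
                             rep(pred_b, length(sets_b))),
                           c(ids_a, ids_b))
  make_dataset(sets, preds, ...)
}

# reference diet table unpacked into profiles + attributes
reference_profiles <- function() {
  ref <- load_reference_diet()
  list(
    sl_fo = diet_profile(stats::setNames(ref$snow_leopard$fo,
                                         ref$snow_leopard$species),
                         "snow_leopard", "rfo"),
    wf_fo = diet_profile(stats::setNames(ref$wolf$fo, ref$wolf$species),
                         "wolf", "rfo"),
    sl_rb = diet_profile(stats::setNames(ref$snow_leopard$rb,
                                         ref$snow_leopard$species),
                         "snow_leopard", "biomass"),
    wf_rb = diet_profile(stats::setNames(ref$wolf$rb, ref$wolf$species),
                         "wolf", "biomass"),
    attrs = data.frame(species = ref$species$species,
                       origin = ref$species$origin,
                       mean_mass_kg = NA_real_))
}

# independent G-test oracle: direct evaluation of 2 * sum O * ln(O/E)
g_oracle <- function(o, pi_i) {
  e <- sum(o) * pi_i
  keep <- o > 0
  2 * sum(o[keep] * log(o[keep] / e[keep]))
}

# independent cosine-similarity oracle for Pianka
cosine_oracle <- function(p, q) {
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}
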
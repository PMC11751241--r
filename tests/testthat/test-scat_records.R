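test_that("read_scat_table merges rows per scat and validates labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scat_id,predator,prey_species",
               "s1,snow_leopard,blue_sheep",
               "s1,snow_leopard,yak",
               "s2,wolf,goat"), f)
  ds <- read_scat_table(f)
  expect_s3_class(ds, "scat_dataset")
  expect_equal(length(unique(ds$records$scat_id)), 2L)
  expect_setequal(ds$records$prey_species[ds$records$scat_id == "s1"],
                  c("blue_sheep", "yak"))

  # duplicated (scat, prey) rows collapse to one occurrence with a warning
  writeLines(c("scat_id,predator,prey_species",
               "s1,snow_leopard,blue_sheep",
               "s1,snow_leopard,blue_sheep"), f)
  expect_warning(ds2 <- read_scat_table(f), "collapsed")
  expect_equal(nrow(ds2$records), 1L)

  # unknown predator label names the offender and the allowed set
  writeLines(c("scat_id,predator,prey_species",
               "s1,lynx,blue_sheep"), f)
  expect_error(read_scat_table(f), "lynx.*snow_leopard.*wolf")

  writeLines("scat_id,predator,prey_species", f)
  expect_error(read_scat_table(f), "empty")
  expect_error(read_scat_table("no_such_file.csv"), "not found")
})

test_that("scat table round-trips through write/read", {
  ds <- make_two_predator_dataset(
    sets_a = list(c("blue_sheep", "yak"), "pika"),
    sets_b = list("domestic_goat", c("yak", "horse", "dog")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scat_table(ds, f)
  back <- read_scat_table(f)
  key <- function(d) sort(paste(d$records$scat_id, d$records$prey_species))
  expect_identical(key(back), key(ds))
  expect_setequal(back$prey_registry, ds$prey_registry)
})

test_that("occurrence_counts follows presence/absence semantics", {
  ds <- make_dataset(list(s1 = c("a", "b"), s2 = "a"),
                     c(s1 = "wolf", s2 = "wolf"))
  ft <- occurrence_counts(ds, "wolf")
  expect_equal(ft$counts, c(a = 2L, b = 1L))
  expect_equal(ft$total_occurrences, 3L)
  expect_equal(ft$n_scats, 2L)
  expect_error(occurrence_counts(ds, "snow_leopard"), "no scat records")

  # single-scat identity
  ds1 <- make_dataset(list(s1 = "a"), c(s1 = "wolf"))
  expect_equal(occurrence_counts(ds1, "wolf")$counts, c(a = 1L))

  # invariant to row order
  rec <- ds$records[c(3, 1, 2), ]
  ds_shuf <- scat_dataset(rec)
  expect_equal(occurrence_counts(ds_shuf, "wolf")$counts, ft$counts)
})

test_that("occurrence totals equal summed per-scat richness (98-scat mix)", {
  # 53 x 1-prey + 41 x 2-prey + 4 x 3-prey scats -> 147 occurrences
  prey <- paste0("sp", 1:5)
  sets <- c(lapply(1:53, function(i) prey[1]),
            lapply(1:41, function(i) prey[1:2]),
            lapply(1:4, function(i) prey[1:3]))
  names(sets) <- paste0("s", seq_along(sets))
  ds <- make_dataset(sets, stats::setNames(rep("snow_leopard", 98),
                                           names(sets)))
  expect_equal(occurrence_counts(ds, "snow_leopard")$total_occurrences, 147L)
})

test_that("reference diet fixture matches the published table", {
  ref <- load_reference_diet()
  expect_equal(nrow(ref$snow_leopard), 11L)
  expect_equal(nrow(ref$wolf), 10L)  # mountain weasel absent from wolf diet
  expect_false("mountain_weasel" %in% ref$wolf$species)
  expect_equal(ref$snow_leopard$fo[ref$snow_leopard$species == "blue_sheep"],
               24.83)
  expect_equal(ref$wolf$rb[ref$wolf$species == "yak"], 43.68)
  # printed FO columns each sum to 100 up to printed rounding
  expect_lt(abs(sum(ref$snow_leopard$fo) - 100), 0.05)
  expect_lt(abs(sum(ref$wolf$fo) - 100), 0.05)
  expect_setequal(unique(ref$species$origin), c("wild", "domestic"))
  expect_equal(sum(ref$species$origin == "domestic"), 5L)
})

test_that("availability tables normalize counts and merge sources", {
  av <- availability_table(counts = c(a = 30, b = 70))
  expect_equal(av$proportions, c(a = 0.3, b = 0.7))
  expect_error(availability_table(counts = c(a = -1, b = 2)), "non-negative")
  expect_error(availability_table(proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prey_species,count", "a,10", "b,20", "a,5"), f)
  merged <- read_availability(f)  # repeated species rows sum
  expect_equal(merged$counts, c(a = 15, b = 20))
})

test_that("prey attributes are validated on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,origin,mean_mass_kg",
               "blue_sheep,wild,55", "yak,domestic,300"), f)
  at <- read_prey_attributes(f)
  expect_equal(at$origin, c("wild", "domestic"))
  writeLines(c("species,origin", "x,feral"), f)
  expect_error(read_prey_attributes(f), "feral")
  writeLines(c("species,origin,mean_mass_kg", "x,wild,0"), f)
  expect_error(read_prey_attributes(f), "positive")
})
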
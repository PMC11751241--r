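test_that("pianka_overlap has the Cauchy-Schwarz endpoints and symmetry", {
  p <- diet_profile(c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(pianka_overlap(p, p)$value, 1.0)
  q <- diet_profile(c(d = 0.6, e = 0.4))
  expect_equal(pianka_overlap(p, q)$value, 0.0)
  r <- diet_profile(c(a = 0.1, b = 0.1, c = 0.8))
  expect_equal(pianka_overlap(p, r)$value, pianka_overlap(r, p)$value)
  # scale invariance: percent and proportion inputs agree
  expect_equal(pianka_overlap(c(a = 50, b = 30, c = 20), r)$value,
               pianka_overlap(p, r)$value)
})

test_that("pianka_overlap reproduces the published overlap on both bases", {
  rp <- reference_profiles()
  expect_equal(round(pianka_overlap(rp$sl_rb, rp$wf_rb)$value, 3), 0.937)
  # on the RFO basis the overlap is lower; frozen independent-formula value
  expect_equal(pianka_overlap(rp$sl_fo, rp$wf_fo)$value, 0.8634,
               tolerance = 1e-4)
})

test_that("pianka_overlap equals cosine similarity on random profiles", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    p <- stats::setNames(rgamma(k, 1), paste0("sp", 1:k))
    q <- stats::setNames(rgamma(k, 1), paste0("sp", 1:k))
    expect_equal(pianka_overlap(p, q)$value,
                 cosine_oracle(p / sum(p), q / sum(q)), tolerance = 1e-12)
  }
})

test_that("levins_breadth spans specialist to uniform and matches print", {
  expect_equal(levins_breadth(diet_profile(
    c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))), 4.0)
  expect_equal(levins_breadth(diet_profile(c(a = 1))), 1.0)
  rp <- reference_profiles()
  expect_equal(round(levins_breadth(rp$sl_fo), 2), 6.45)
  expect_equal(round(levins_breadth(rp$wf_fo), 2), 5.98)
  # standardized form lands in [0, 1]
  ba <- levins_breadth(rp$sl_fo, standardized = TRUE)
  expect_equal(ba, (6.450713 - 1) / (11 - 1), tolerance = 1e-4)
})

test_that("levins_breadth never decreases under evening (Schur-concavity)", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(3:10, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    b0 <- levins_breadth(diet_profile(stats::setNames(p, paste0("s", 1:k))))
    # mean-preserving evening of the two most extreme entries
    hi <- which.max(p); lo <- which.min(p)
    eps <- runif(1, 0, (p[hi] - p[lo]) / 2)
    p[hi] <- p[hi] - eps; p[lo] <- p[lo] + eps
    b1 <- levins_breadth(diet_profile(stats::setNames(p, paste0("s", 1:k))))
    expect_gte(b1, b0 - 1e-12)
  }
})

test_that("bootstrap breadth CI is degenerate, reproducible and ordered", {
  ds <- make_dataset(stats::setNames(rep(list("a"), 5), paste0("s", 1:5)),
                     stats::setNames(rep("wolf", 5), paste0("s", 1:5)))
  r <- bootstrap_breadth_ci(ds, "wolf", n_boot = 200, seed = 1)
  expect_equal(r$value, 1.0)
  expect_equal(c(r$ci_low, r$ci_high), c(1.0, 1.0))

  sim <- generate_dataset(default_generator_config(seed = 4))
  r1 <- bootstrap_breadth_ci(sim$dataset, "snow_leopard", 500, seed = 7)
  r2 <- bootstrap_breadth_ci(sim$dataset, "snow_leopard", 500, seed = 7)
  expect_identical(r1[c("value", "ci_low", "ci_high")],
                   r2[c("value", "ci_low", "ci_high")])
  expect_lte(r1$ci_low, r1$ci_high)
  # resampling scats: interval brackets plausible breadths
  expect_gte(r1$ci_low, 1)
  expect_lte(r1$ci_high, length(sim$dataset$prey_registry))

  # invariant to scat ordering
  rec <- sim$dataset$records
  shuf <- scat_dataset(rec[sample.int(nrow(rec)), ],
                       prey_registry = sim$dataset$prey_registry)
  r3 <- bootstrap_breadth_ci(shuf, "snow_leopard", 500, seed = 7)
  expect_equal(r3$value, r1$value)
})

test_that("breadth difference test handles null, power and degeneracy", {
  # identical single-prey diets: degenerate pooled data, p = 1 with warning
  ds0 <- make_two_predator_dataset(rep(list("a"), 5), rep(list("a"), 5))
  expect_warning(r0 <- breadth_difference_test(ds0, "snow_leopard", "wolf",
                                               n_perm = 99, seed = 1),
                 "single prey")
  expect_equal(r0$observed_diff, 0)
  expect_equal(r0$p_value, 1)

  # clearly different breadths (2 resources vs 8) are detected
  set.seed(55)
  narrow <- lapply(1:120, function(i) sample(c("a", "b"), 1))
  broad <- lapply(1:120, function(i) sample(paste0("s", 1:8), 1))
  ds <- make_two_predator_dataset(narrow, broad)
  r <- breadth_difference_test(ds, "snow_leopard", "wolf",
                               n_perm = 499, seed = 2)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$observed_diff, 3)

  # fixed seed reproducibility, and p always in (0, 1]
  r2 <- breadth_difference_test(ds, "snow_leopard", "wolf",
                                n_perm = 499, seed = 2)
  expect_identical(r$p_value, r2$p_value)
  expect_gt(r$p_value, 0)
})
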
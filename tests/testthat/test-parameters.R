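test_that("packaged configuration loads with the expected values and flags", {
  p <- default_pset()
  tab <- p$table
  expect_equal(tab$mean[tab$id == "tp.well.index_revision.LLIF"], 0.0169)
  expect_equal(tab$mean[tab$id == "tp.well.adjacent_revision.PLIF"], 0.0237)
  expect_equal(tab$mean[tab$id == "u.well.LLIF"], 0.840)
  expect_equal(tab$low[tab$id == "u.well.LLIF"], 0.756)

  # inconsistent printed rows load verbatim but are flagged
  expect_true(tab$flag_mean_outside[tab$id == "tp.index_revision.well.LLIF"])
  expect_true(tab$flag_mean_outside[tab$id == "u.adjacent_revision.PLIF"])
  expect_true(tab$flag_range_rule[tab$id == "u.well.PLIF"])
  expect_true(any(grepl("tp.index_revision.well.LLIF", p$warnings)))

  # zero-width non-medical rows are degenerate
  expect_true(all(tab$degenerate[tab$id %in% c("c.food_ipd", "c.transport")]))
})

test_that("schema violations abort with the offending path", {
  src <- jsonlite::read_json(system.file("extdata", "model_parameters.json",
                                         package = "lumbarCUA"),
                             simplifyVector = TRUE)
  tmp <- file.path(tempdir(), "broken.json")
  file.copy(system.file("extdata", "mortality_calibrated.csv",
                        package = "lumbarCUA"),
            file.path(tempdir(), "mortality_calibrated.csv"),
            overwrite = TRUE)

  broken <- src
  broken$parameters <-
    broken$parameters[broken$parameters$id != "tp.index_revision.well.LLIF", ]
  jsonlite::write_json(broken, tmp, auto_unbox = TRUE)
  expect_error(load_parameters(tmp), "transition.index_revision.well.*LLIF")

  broken <- src
  broken$parameters$mean[broken$parameters$id == "u.well.LLIF"] <- 1.4
  jsonlite::write_json(broken, tmp, auto_unbox = TRUE)
  expect_error(load_parameters(tmp), "outside \\[0,1\\]")

  broken <- src
  broken$parameters$family[1] <- "lognormal"
  jsonlite::write_json(broken, tmp, auto_unbox = TRUE)
  expect_error(load_parameters(tmp), "unknown distribution family")

  broken <- src
  broken$settings$discount_rate <- -0.01
  jsonlite::write_json(broken, tmp, auto_unbox = TRUE)
  expect_error(load_parameters(tmp), "discount_rate")
})

test_that("configuration round-trips bit-exactly", {
  p <- default_pset()
  tmp <- file.path(tempdir(), "roundtrip.json")
  src <- jsonlite::read_json(p$path, simplifyVector = TRUE)
  jsonlite::write_json(src, tmp, auto_unbox = TRUE, digits = NA)
  file.copy(system.file("extdata", "mortality_calibrated.csv",
                        package = "lumbarCUA"),
            file.path(tempdir(), "mortality_calibrated.csv"),
            overwrite = TRUE)
  p2 <- load_parameters(tmp)
  expect_identical(p$table$mean, p2$table$mean)
  expect_identical(p$table$low, p2$table$low)
  expect_identical(p$table$high, p2$table$high)
  expect_identical(p$mortality$qx, p2$mortality$qx)
})

test_that("beta moment matching reproduces mean and implied variance", {
  sp <- dist_spec("beta", 0.84, 0.756, 0.924)
  hp <- beta_hyperparameters(sp)
  expect_equal(unname(hp["shape1"]), 60.63, tolerance = 1e-3)
  expect_equal(unname(hp["shape2"]), 11.55, tolerance = 1e-3)
  # closed-form moments of the fitted distribution
  m <- hp[1] / sum(hp)
  v <- hp[1] * hp[2] / (sum(hp)^2 * (sum(hp) + 1))
  expect_equal(unname(m), 0.84, tolerance = 1e-12)
  expect_equal(unname(sqrt(v)), (0.924 - 0.756) / (2 * 1.96),
               tolerance = 1e-12)
  # sample-moment cross-check
  set.seed(7)
  x <- rbeta(2e5, hp[1], hp[2])
  expect_equal(mean(x), 0.84, tolerance = 2e-3)

  # symmetric spec forces equal shapes
  hp2 <- beta_hyperparameters(dist_spec("beta", 0.5, 0.3, 0.7))
  expect_equal(unname(hp2["shape1"]), unname(hp2["shape2"]))

  # under the 95%-interval reading no in-support beta range is moment
  # infeasible (SE is at most (1-0)/3.92, well below the binomial bound);
  # even the widest range fits, with small shapes
  hp_wide <- beta_hyperparameters(dist_spec("beta", 0.9, 0, 1))
  expect_true(all(hp_wide > 0))
  expect_equal(unname(hp_wide["shape1"] / sum(hp_wide)), 0.9)
  expect_error(beta_hyperparameters(dist_spec("beta", 0.5, 0.5, 0.5)),
               "degenerate")
})

test_that("gamma moment matching is exact in mean and SD", {
  hp <- gamma_hyperparameters(dist_spec("gamma", 4041, 4001, 4081))
  expect_equal(unname(hp["shape"]), 3.92e4, tolerance = 1e-2)
  expect_equal(unname(hp["rate"]), 9.70, tolerance = 1e-2)
  expect_equal(unname(hp["shape"] / hp["rate"]), 4041, tolerance = 1e-12)

  hp2 <- gamma_hyperparameters(dist_spec("gamma", 1563, 1548, 1579))
  expect_equal(unname(hp2["shape"] / hp2["rate"]), 1563, tolerance = 1e-12)

  # definition round-trip: range (m - 1.96 s, m + 1.96 s) gives SD s
  for (s in c(0.5, 3, 40)) {
    hp3 <- gamma_hyperparameters(dist_spec("gamma", 100, 100 - 1.96 * s,
                                           100 + 1.96 * s))
    expect_equal(unname(sqrt(hp3["shape"]) / hp3["rate"]), s,
                 tolerance = 1e-9)
  }
  expect_error(gamma_hyperparameters(dist_spec("gamma", 0, 0, 1)),
               "positive")
})

test_that("every non-degenerate table row fits with its printed mean", {
  tab <- default_pset()$table
  for (i in which(tab$sample_ok)) {
    fitted_mean <- if (tab$family[i] == "beta")
      tab$hp1[i] / (tab$hp1[i] + tab$hp2[i])
    else tab$hp1[i] / tab$hp2[i]
    expect_equal(fitted_mean, tab$mean[i], tolerance = 1e-9,
                 label = tab$id[i])
  }
})

test_that("utility ranges follow the +/-10% rule except the two typo rows", {
  tab <- default_pset()$table
  ut <- tab[tab$category == "utility", ]
  bad <- ut$id[ut$flag_range_rule | ut$flag_mean_outside]
  expect_setequal(bad, c("u.well.PLIF", "u.adjacent_revision.PLIF"))
  ok <- ut[!ut$id %in% bad, ]
  expect_equal(ok$low, round(0.9 * ok$mean, 3), tolerance = 5e-4)
  expect_equal(ok$high, round(pmin(1, 1.1 * ok$mean), 3), tolerance = 5e-4)
  # rule helper caps at full health
  expect_equal(unname(utility_range(0.95)["high"]), 1)
  expect_equal(unname(utility_range(0.84)["low"]), 0.756)
})

test_that("parameter sampling respects support, determinism and the mean", {
  sp <- dist_spec("beta", 0.84, 0.756, 0.924)
  set.seed(11); a <- sample_parameter(sp, n = 50)
  set.seed(11); b <- sample_parameter(sp, n = 50)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))

  set.seed(3)
  big <- sample_parameter(sp, n = 1e5)
  expect_equal(mean(big), 0.84, tolerance = 2e-3)

  g <- sample_parameter(dist_spec("gamma", 850, 841, 858), u = c(0.01, 0.99))
  expect_true(all(g > 0))
  # inverse-CDF draws are monotone in u
  expect_true(g[1] < g[2])
})
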
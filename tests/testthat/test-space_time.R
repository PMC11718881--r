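test_that("time budgets normalise within individual and bin", {
  g <- synth_generate(synth_config(days = 2, scans_per_day = 12, seed = 22))
  tb <- time_budget(g$scans)
  sums <- aggregate(proportion ~ individual + bin, tb, sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-9))
  # direct tally oracle, overall rows
  sc <- g$scans$scans
  for (id in c("ind01", "ind07")) {
    own <- sc[sc$individual == id, ]
    for (cat in c("foraging", "rest")) {
      got <- tb$proportion[tb$individual == id & tb$bin == "all" &
                             tb$behaviour_category == cat]
      expect_equal(got, mean(own$behaviour_category == cat))
    }
  }
  # an all-grazing individual scores foraging 1 in every occupied bin
  beh <- list(A = rep("foraging", 4), B = rep("rest", 4))
  x <- toy_scans(list(rep(list(list("A", "B")), 4)), beh)
  tbx <- time_budget(x)
  a_f <- tbx[tbx$individual == "A" & tbx$behaviour_category == "foraging" &
               tbx$bin != "all", ]
  expect_true(all(a_f$proportion[a_f$n > 0] == 1))
  # scans outside every bin are flagged
  expect_warning(time_budget(x, bins = data.frame(bin = "late",
                                                  start = 1000, end = 1100)),
                 "outside all bins")
  expect_error(time_budget(x, bins = data.frame(bin = c("a", "b"),
                                                start = c(0, 50),
                                                end = c(60, 100))),
               "overlap")
})

test_that("electivity spans [-1, 1] with the stated endpoints", {
  zones <- zone_map(data.frame(zone = c("z1", "z2", "z3"), area = 100,
                               has_hay = FALSE, has_water = FALSE,
                               enclosure = "I"))
  x <- toy_scans(list(rep(list(list("A")), 9)),
                 zones = c(A = "z1"))
  # exclusive use of one of three equal zones; e = 1/3
  ei <- electivity(x, zones)
  expect_equal(ei$ei[ei$zone == "z1"], (1 - 1 / 3) / (1 + 1 / 3))
  expect_equal(ei$ei[ei$zone == "z2"], -1)  # never used
  # observed equal to expected everywhere -> EI 0
  sc <- data.frame(day = "2015-07-21", time = 300 + 10 * (0:8),
                   individual = "A", behaviour_category = "foraging",
                   activity_pattern = "graze",
                   zone = rep(c("z1", "z2", "z3"), 3))
  x3 <- scan_dataset(sc)
  ei3 <- electivity(x3, zones)
  expect_true(all(abs(ei3$ei) < 1e-12))
  expect_true(all(ei$ei >= -1 & ei$ei <= 1))
  expect_error(electivity(x, zone_map(data.frame(zone = "q", area = 1,
                                                 has_hay = FALSE,
                                                 has_water = FALSE,
                                                 enclosure = "I"))),
               "outside the availability set")
})

test_that("spread of participation matches Dickens' formula", {
  expect_equal(spread_of_participation(rep(5, 22)), 0)       # uniform
  expect_equal(spread_of_participation(c(44, rep(0, 21))), 1)  # one zone
  expect_equal(spread_of_participation(c(10, 5, 5)), 0.25)   # hand-derived
  expect_error(spread_of_participation(c(a = 4)), "single available zone")
  expect_error(spread_of_participation(c(0, 0, 0)), "at least one")
  # monotone towards uniformity
  seqs <- list(c(40, 0, 0, 0), c(28, 4, 4, 4), c(16, 8, 8, 8),
               c(10, 10, 10, 10))
  spis <- vapply(seqs, spread_of_participation, numeric(1))
  expect_true(all(diff(spis) < 0))
})

test_that("availability split partitions scans and trims the zone set", {
  cfg <- synth_config(days = 6, scans_per_day = 6, seed = 25)
  g <- synth_generate(cfg)
  cut <- sort(unique(g$scans$scans$day))[3]
  # synthetic zone preferences keep using enclosure II after the
  # cutover, which the split flags
  sp <- suppressWarnings(availability_split(g$scans, cut))
  expect_equal(nrow(sp$period_a$scans) + nrow(sp$period_b$scans),
               nrow(g$scans$scans))
  expect_false(any(sp$zones_b$enclosure == "II"))
  expect_setequal(sp$zones_b$zone, paste0(rep(c("A", "B", "C"), each = 6), 1:6))
  expect_error(availability_split(g$scans, "2020-01-01"), "interior")
  # identical spatial distribution in both periods -> equal SPI
  zones <- zone_map(data.frame(zone = c("z1", "z2"), area = 100,
                               has_hay = FALSE, has_water = FALSE,
                               enclosure = "I"))
  beh <- NULL
  days <- rep_days(rep(list(list("A")), 4), 4)
  x <- toy_scans(days, zones = c(A = "z1"))
  x$scans$zone <- rep(c("z1", "z1", "z1", "z2"), 4)
  sp2 <- availability_split(x, sort(unique(x$scans$day))[2], zones)
  spi_a <- space_use_profile(sp2$period_a, zones)$spi
  spi_b <- space_use_profile(sp2$period_b, zones)$spi
  expect_equal(spi_a, spi_b)
})

test_that("the per-scan model table carries cluster, bin and hay flags", {
  g <- synth_generate(synth_config(days = 2, scans_per_day = 6, seed = 26))
  mt <- scan_model_table(g$scans, g$truth$true_partition,
                         cutover_day = sort(unique(g$scans$scans$day))[1])
  expect_equal(nrow(mt), nrow(g$scans$scans))
  expect_setequal(unique(mt$period), c("two_enclosures", "one_enclosure"))
  expect_true(all(mt$cluster %in% paste0("cluster", 1:3)))
  expect_type(mt$hay_zone, "logical")
})
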
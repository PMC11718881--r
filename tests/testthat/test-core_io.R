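test_that("scan dataset validation rejects malformed input", {
  scans <- data.frame(day = "2015-07-21", time = 300,
                      individual = c("A", "B"),
                      behaviour_category = "foraging",
                      activity_pattern = "graze", zone = NA)
  expect_s3_class(scan_dataset(scans), "scan_dataset")
  expect_error(scan_dataset(scans[, -2]), "lacks column")
  bad <- scans; bad$behaviour_category <- "rest"
  expect_error(scan_dataset(bad), "mismatch at scan row")
  bad <- scans; bad$time <- c(300, 2000)
  expect_error(scan_dataset(bad), "malformed scan time")
  # pair referencing an individual with no record at that scan
  pairs <- data.frame(day = "2015-07-21", time = 300,
                      id_a = "A", id_b = "C")
  expect_error(scan_dataset(scans, pairs), "no scan record")
  # well-formed 2-individual 3-scan table -> 6 records
  s3 <- do.call(rbind, lapply(c(300, 310, 320), function(t) {
    s <- scans; s$time <- t; s
  }))
  expect_equal(nrow(scan_dataset(s3)$scans), 6)
})

test_that("scan datasets round-trip through CSV exactly", {
  g <- synth_generate(synth_config(days = 2, scans_per_day = 6, seed = 11))
  sp <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_scan_dataset(g$scans, sp, pp)
  back <- read_scan_dataset(sp, pp)
  expect_equal(back$scans$individual, g$scans$scans$individual)
  expect_equal(back$scans$behaviour_category,
               g$scans$scans$behaviour_category)
  expect_equal(back$scans$time, g$scans$scans$time)
  expect_equal(back$scans$zone, g$scans$scans$zone)
  ord <- function(p) p[order(p$day, p$time, p$id_a, p$id_b), ]
  expect_equal(ord(back$pairs)$id_a, ord(g$scans$pairs)$id_a)
  expect_equal(ord(back$pairs)$id_b, ord(g$scans$pairs)$id_b)
})

test_that("packaged matrices match the published tables", {
  ai <- load_fixture("ai")
  expect_false(is_directed(ai))
  expect_equal(dyad_values(ai)["Lovelas", "Vernij"], 0.665)
  expect_equal(dyad_values(ai)["Losk", "Palats"], 0.529)
  af <- load_fixture("affil_rates")
  expect_true(is_directed(af))
  expect_equal(dyad_values(af)["Losk", "Zakat"], 1.077)
  expect_equal(dyad_values(af)["Zakat", "Losk"], 0.077)
  bsi <- load_fixture("bsi")
  expect_equal(dyad_values(bsi)["Lovelas", "Vernij"], 0.881)
  # transcription checksum: row sums pinned when the tables were copied
  expect_equal(unname(round(rowSums(dyad_values(ai)), 3)),
               c(0.706, 0.332, 0.787, 0.665, 0.804, 0.728, 0.665,
                 0.699, 0.476))
  expect_equal(round(mean(offdiag_values(bsi)), 4), 0.3738)
  expect_error(load_fixture("nope"))
})

test_that("interaction events validate against the ethogram", {
  ev <- toy_events("A", "B", "bite")
  expect_equal(ev$kind, "agonistic")
  expect_equal(ev$role_class, "offensive")
  expect_error(toy_events("A", "A", "bite"), "actor equals recipient")
  expect_error(toy_events("A", "B", "cuddle"), "unknown interaction subtype")
  bad <- data.frame(day = "d", time = 1, actor = "A", recipient = "B",
                    subtype = "bite", kind = "affiliative")
  expect_error(validate_events(bad), "contradicts subtype")
})

test_that("reports serialize deterministically with matrices as CSV", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.json"); p2 <- file.path(d, "r2.json")
  res <- list(b_stat = 2L, a_matrix = load_fixture("ai"),
              nested = list(seed = 7L, n_perm = 100L))
  write_report(res, p1)
  write_report(res, p2)
  expect_true(file.exists(file.path(d, "r1_a_matrix.csv")))
  j1 <- readLines(p1); j2 <- readLines(p2)
  expect_identical(sub("r1", "rX", j1), sub("r2", "rX", j2))
  # empty results still give a valid document with a metadata block
  write_report(list(), file.path(d, "empty.json"))
  doc <- jsonlite::read_json(file.path(d, "empty.json"))
  expect_equal(doc$metadata$package, "herdnet")
  expect_error(write_report(list(f = sum), file.path(d, "bad.json")),
               "unserializable")
})

test_that("observation log enforces window consistency", {
  expect_equal(obs_log(data.frame(day = c("d1", "d1"),
                                  start = c(300, 600),
                                  end = c(500, 700)))$total_hours, 5)
  expect_error(obs_log(data.frame(day = "d1", start = 300, end = 300)),
               "nonpositive")
  expect_error(obs_log(data.frame(day = c("d1", "d1"),
                                  start = c(300, 400), end = c(450, 500))),
               "overlapping")
})
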
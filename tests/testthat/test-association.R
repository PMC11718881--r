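test_that("proximity pairs chain into groups via connected components", {
  g <- scan_groups(c("A", "B", "C", "D"),
                   data.frame(id_a = c("A", "B"), id_b = c("B", "C")))
  g <- lapply(g, sort)
  expect_length(g, 2)
  expect_true(any(vapply(g, identical, logical(1), c("A", "B", "C"))))
  expect_true(any(vapply(g, identical, logical(1), "D")))
  # no pairs -> all singletons
  empty <- scan_groups(c("A", "B"), data.frame(id_a = character(),
                                               id_b = character()))
  expect_equal(lengths(empty), c(1, 1))
  # disjoint pairs -> two groups of two
  two <- scan_groups(c("A", "B", "C", "D"),
                     data.frame(id_a = c("A", "C"), id_b = c("B", "D")))
  expect_equal(sort(lengths(two)), c(2, 2))
})

test_that("association index is the joint-group share of joint scans", {
  # 10 scans, dyad A-B grouped in 3, both always visible -> 0.300
  day <- c(rep(list(list(c("A", "B"), "C")), 3),
           rep(list(list("A", "B", "C")), 7))
  x <- toy_scans(list(day))
  ai <- association_matrix(x)
  expect_equal(dyad_values(ai)["A", "B"], 0.3)
  expect_equal(dyad_values(ai)["A", "C"], 0)
  expect_equal(attr(ai, "counts")["A", "B"], 10)
  # chained dyad counts as associated
  x2 <- toy_scans(list(list(list(c("A", "B", "C")))))
  expect_equal(dyad_values(association_matrix(x2))["A", "C"], 1)
})

test_that("association matrix matches a brute-force per-scan tally", {
  g <- synth_generate(synth_config(days = 3, scans_per_day = 8, seed = 21))
  ai <- association_matrix(g$scans)
  ids <- g$scans$ids
  # independent oracle: per scan, components from igraph on the pair
  # graph, then a plain tally
  num <- den <- matrix(0, length(ids), length(ids),
                       dimnames = list(ids, ids))
  skey <- unique(g$scans$scans[c("day", "time")])
  for (r in seq_len(nrow(skey))) {
    sel <- g$scans$pairs$day == skey$day[r] & g$scans$pairs$time == skey$time[r]
    present <- g$scans$scans$individual[
      g$scans$scans$day == skey$day[r] & g$scans$scans$time == skey$time[r]]
    gr <- igraph::graph_from_data_frame(
      g$scans$pairs[sel, c("id_a", "id_b")], directed = FALSE,
      vertices = data.frame(name = present))
    comp <- igraph::components(gr)$membership
    den[present, present] <- den[present, present] + 1
    for (cc in unique(comp)) {
      mm <- names(comp)[comp == cc]
      num[mm, mm] <- num[mm, mm] + 1
    }
  }
  oracle <- num / den
  diag(oracle) <- 0
  expect_equal(dyad_values(ai), oracle)
})

test_that("interaction rates divide event counts by contact hours", {
  log65 <- obs_log(data.frame(day = sprintf("d%02d", 1:13),
                              start = 300, end = 600))
  expect_equal(log65$total_hours, 65)
  ev <- toy_events(rep("Losk", 70), rep("Zakat", 70), "mutual_grooming")
  m <- interaction_rate_matrix(ev, log65, "affiliative",
                               ids = c("Losk", "Zakat", "Bulat"))
  expect_equal(round(dyad_values(m)["Losk", "Zakat"], 3), 1.077)
  expect_equal(dyad_values(m)["Zakat", "Losk"], 0)
  one <- interaction_rate_matrix(toy_events("A", "B", "bite"), log65,
                                 "agonistic")
  expect_equal(round(dyad_values(one)["A", "B"], 4), 0.0154)
  none <- interaction_rate_matrix(toy_events("A", "B", "bite"), log65,
                                  "affiliative", ids = c("A", "B"))
  expect_true(all(dyad_values(none) == 0))
  expect_error(interaction_rate_matrix(ev,
    structure(list(total_hours = 0), class = "obs_log"), "affiliative"),
    "contact hours")
})

test_that("event composition summaries give within-kind percentages", {
  ev <- toy_events(
    actor = rep("A", 465), recipient = rep("B", 465),
    subtype = c(rep("mutual_grooming", 335), rep("mutual_sniffing", 23),
                rep("avoidance", 62), rep("kick", 3),
                rep("harassment", 33), rep("bite", 9)))
  s <- summarise_events(ev)
  groom <- s$by_subtype[s$by_subtype$subtype == "mutual_grooming", ]
  expect_equal(groom$n, 335)
  expect_equal(round(groom$pct_of_kind, 1), 93.6)  # 335 of 358
  subm <- s$by_role[s$by_role$role_class == "defensive", ]
  expect_equal(subm$n, 65)
  expect_equal(round(subm$pct_of_agonistic, 1), 60.7)  # 65 of 107
})
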
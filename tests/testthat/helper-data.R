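# Fixtures built in code: tiny scan datasets with known group structure.

# representative activity per category, ethogram-consistent
act_for <- c(foraging = "graze", rest = "stand", locomotion = "walk",
             social = "mutual_grooming", vigilance = "observe",
             other = "scratch")

# Build a scan_dataset from a nested list: days -> scans -> list of
# groups (character vectors of ids). Pairs chain consecutive members
# of each group (a-b, b-c, ...), exercising the gambit-of-the-group
# closure. `behaviour` maps id -> vector of categories over scans (in
# stream order); defaults to all-foraging.
toy_scans <- function(days, behaviour = NULL, zones = NULL) {
  ids <- sort(unique(unlist(days)))
  scans <- list(); pairs <- list(); s <- 0L
  for (d in seq_along(days)) {
    day <- sprintf("2015-07-%02d", 20 + d)
    for (sc in seq_along(days[[d]])) {
      s <- s + 1L
      time <- 300 + (sc - 1) * 10
      members <- unlist(days[[d]][[sc]])
      cat_of <- vapply(members, function(id) {
        if (is.null(behaviour)) "foraging" else behaviour[[id]][s]
      }, character(1))
      scans[[length(scans) + 1]] <- data.frame(
        day = day, time = time, individual = members,
        behaviour_category = cat_of,
        activity_pattern = act_for[cat_of],
        zone = if (is.null(zones)) NA_character_ else zones[members],
        stringsAsFactors = FALSE)
      for (g in days[[d]][[sc]]) {
        if (length(g) >= 2)
          pairs[[length(pairs) + 1]] <- data.frame(
            day = day, time = time,
            id_a = g[-length(g)], id_b = g[-1],
            stringsAsFactors = FALSE)
      }
    }
  }
  scan_dataset(do.call(rbind, scans),
               if (length(pairs)) do.call(rbind, pairs) else NULL,
               ids = ids)
}

# Repeat the same per-day scan layout over several days.
rep_days <- function(scan_list, n_days) rep(list(scan_list), n_days)

# Small event table builder.
toy_events <- function(actor, recipient, subtype, day = "2015-07-21",
                       time = 400) {
  validate_events(data.frame(day = day, time = time, actor = actor,
                             recipient = recipient, subtype = subtype,
                             stringsAsFactors = FALSE))
}

# The published three-cluster membership of the worked-example group.
bachelor_partition <- function() {
  social_partition(c(Bulat = 1, Parus = 1, Vitjaz = 1,
                     Lepet = 2, Losk = 2, Palats = 2, Zakat = 2,
                     Lovelas = 3, Vernij = 3))
}
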
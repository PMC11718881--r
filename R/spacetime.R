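#' Default time-of-day bins
#'
#' Morning 05:00--10:00, afternoon 10:10--15:00, evening 15:10--20:30,
#' in minutes since midnight (the field protocol's observation blocks).
#'
#' @return data.frame with columns `bin`, `start`, `end` (inclusive)
#' @export
default_time_bins <- function() {
  data.frame(bin = c("morning", "afternoon", "evening"),
             start = c(300, 610, 910),
             end = c(600, 900, 1230),
             stringsAsFactors = FALSE)
}

#' Time budget by individual, behaviour category and time-of-day bin
#'
#' Proportion of each individual's scan records falling in each
#' behavioural category, within each time-of-day bin and overall.
#' Proportions sum to 1 within every individual-by-bin cell. Scans
#' outside all bins are collected in an `"unbinned"` bucket and
#' flagged with a warning.
#'
#' @param x a `scan_dataset`
#' @param bins data.frame with columns `bin`, `start`, `end` (minutes,
#'   inclusive, non-overlapping); default [default_time_bins()]
#' @return data.frame with columns `individual`, `bin`,
#'   `behaviour_category`, `n`, `proportion`; overall rows carry
#'   `bin = "all"`
#' @export
time_budget <- function(x, bins = default_time_bins()) {
  if (nrow(bins) > 1) {
    b <- bins[order(bins$start), ]
    if (any(b$start[-1] <= b$end[-nrow(b)]))
      stop("time bins overlap")
  }
  sc <- x$scans
  bin_of <- rep("unbinned", nrow(sc))
  for (k in seq_len(nrow(bins)))
    bin_of[sc$time >= bins$start[k] & sc$time <= bins$end[k]] <- bins$bin[k]
  if (any(bin_of == "unbinned"))
    warning(sum(bin_of == "unbinned"), " scan record(s) outside all bins")
  cats <- behaviour_categories()
  tally <- function(sub, binlab) {
    tab <- table(factor(sub$individual, x$ids),
                 factor(sub$behaviour_category, cats))
    tot <- rowSums(tab)
    d <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(d) <- c("individual", "behaviour_category", "n")
    d$bin <- binlab
    d$proportion <- ifelse(tot[d$individual] > 0,
                           d$n / tot[d$individual], NA_real_)
    d[c("individual", "bin", "behaviour_category", "n", "proportion")]
  }
  out <- tally(sc, "all")
  for (b in unique(bin_of))
    out <- rbind(out, tally(sc[bin_of == b, , drop = FALSE], b))
  rownames(out) <- NULL
  out
}

#' Electivity index of zone use
#'
#' Ivlev's electivity per individual and zone:
#' `EI_z = (o_z - e_z) / (o_z + e_z)` with `o_z` the observed share of
#' the individual's zone-recorded scans in zone z and `e_z` the
#' expected share, proportional to zone area over the available zones.
#' EI is -1 for a zone never used, 0 when used exactly as expected,
#' and approaches +1 for near-exclusive use of a small zone.
#'
#' @param x a `scan_dataset`
#' @param zones a [zone_map()] restricted to the zones available in
#'   the period analysed
#' @return data.frame with columns `individual`, `zone`, `n`,
#'   `observed`, `expected`, `ei`
#' @export
electivity <- function(x, zones = default_zone_map()) {
  if (any(zones$area <= 0)) stop("zone with zero area")
  sc <- x$scans[!is.na(x$scans$zone) & x$scans$zone != "", , drop = FALSE]
  if (!nrow(sc)) stop("no zone-recorded scans")
  unknown <- setdiff(unique(sc$zone), zones$zone)
  if (length(unknown))
    stop("scan in zone(s) outside the availability set: ",
         paste(unknown, collapse = ", "))
  e <- zones$area / sum(zones$area)
  tab <- unclass(table(factor(sc$individual, x$ids),
                       factor(sc$zone, zones$zone)))
  tot <- rowSums(tab)
  d <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(d) <- c("individual", "zone", "n")
  # individuals with no zone-recorded scans get NA, not -1
  d$observed <- ifelse(tot[d$individual] > 0, d$n / tot[d$individual],
                       NA_real_)
  d$expected <- e[match(d$zone, zones$zone)]
  d$ei <- (d$observed - d$expected) / (d$observed + d$expected)
  d
}

#' Spread of participation index
#'
#' Dickens' SPI over zone counts:
#' `SPI = (M (n_b - n_a) + (F_a - F_b)) / (2 (N - M))` with `N` total
#' observations, `M = N / n_zones` the per-zone mean, `n_a`/`n_b` the
#' numbers of zones with counts above/below `M`, and `F_a`/`F_b` the
#' total counts in those zones. 0 means all zones used equally, 1 a
#' single zone used exclusively. Zones in the availability set with no
#' observations count as below-mean zones.
#'
#' @param counts named (by zone) vector of observation counts for one
#'   individual, covering the available zones (zeros included)
#' @return SPI in `[0, 1]`
#' @export
#' @examples
#' spread_of_participation(c(a = 10, b = 5, c = 5))  # 0.25
spread_of_participation <- function(counts) {
  Z <- length(counts)
  if (Z < 2) stop("SPI undefined with a single available zone")
  N <- sum(counts)
  if (N <= 0) stop("SPI needs at least one observation")
  M <- N / Z
  above <- counts > M
  below <- counts < M
  num <- M * (sum(below) - sum(above)) + (sum(counts[above]) - sum(counts[below]))
  num / (2 * (N - M))
}

#' Per-individual space-use profile (zone counts, EI, SPI)
#'
#' @param x a `scan_dataset`
#' @param zones availability set for the period (a [zone_map()])
#' @return list with `counts` (individuals x zones), `ei` (data.frame
#'   from [electivity()]), `spi` (named vector)
#' @export
space_use_profile <- function(x, zones = default_zone_map()) {
  ei <- electivity(x, zones)
  sc <- x$scans[!is.na(x$scans$zone) & x$scans$zone != "", , drop = FALSE]
  tab <- unclass(table(factor(sc$individual, x$ids),
                       factor(sc$zone, zones$zone)))
  spi <- apply(tab, 1, function(r)
    if (sum(r) > 0) spread_of_participation(r) else NA_real_)
  list(counts = tab, ei = ei, spi = spi)
}

#' Split a dataset by enclosure availability period
#'
#' Period A runs up to and including `cutover_day` (both enclosures
#' available, full zone set); period B is the remainder (second
#' enclosure closed). Scans recorded in enclosure-II zones after the
#' cutover trigger a validation warning.
#'
#' @param x a `scan_dataset`
#' @param cutover_day last day (as in `x$scans$day`, compared as
#'   character dates) of the two-enclosure period
#' @param zones full [zone_map()] with the `enclosure` flag
#' @return list with `period_a`, `period_b` (`scan_dataset`s),
#'   `zones_a`, `zones_b` (availability sets)
#' @export
availability_split <- function(x, cutover_day, zones = default_zone_map()) {
  days <- sort(unique(x$scans$day))
  if (!(as.character(cutover_day) %in% days) ||
      as.character(cutover_day) == days[length(days)])
    stop("cutover_day must be an interior observation day")
  in_a <- x$scans$day <= as.character(cutover_day)
  pa_in <- x$pairs$day <= as.character(cutover_day)
  a <- scan_dataset(x$scans[in_a, , drop = FALSE],
                    x$pairs[pa_in, , drop = FALSE], ids = x$ids)
  b <- scan_dataset(x$scans[!in_a, , drop = FALSE],
                    x$pairs[!pa_in, , drop = FALSE], ids = x$ids)
  zb <- zones[zones$enclosure != "II", , drop = FALSE]
  late_ii <- !is.na(b$scans$zone) &
    b$scans$zone %in% zones$zone[zones$enclosure == "II"]
  if (any(late_ii))
    warning(sum(late_ii), " scan(s) recorded in enclosure-II zones ",
            "after the cutover")
  list(period_a = a, period_b = b, zones_a = zones, zones_b = zone_map(zb))
}

#' Tidy per-scan table for external mixed-model analysis
#'
#' One row per scan record with the covariates the group-level models
#' use: individual, social cluster, time-of-day bin, availability
#' period, behaviour category and activity, zone, and whether the zone
#' holds hay. Response indicators for any behaviour can be derived by
#' the caller; model fitting itself is out of scope here.
#'
#' @param x a `scan_dataset`
#' @param partition a `social_partition` or labelled membership vector
#' @param cutover_day last day of the two-enclosure period (optional)
#' @param zones a [zone_map()]
#' @param bins time bins, see [time_budget()]
#' @return data.frame
#' @export
scan_model_table <- function(x, partition, cutover_day = NULL,
                             zones = default_zone_map(),
                             bins = default_time_bins()) {
  mem <- partition_membership(partition, x$ids)
  sc <- x$scans
  bin_of <- rep("unbinned", nrow(sc))
  for (k in seq_len(nrow(bins)))
    bin_of[sc$time >= bins$start[k] & sc$time <= bins$end[k]] <- bins$bin[k]
  data.frame(
    individual = sc$individual,
    cluster = paste0("cluster", mem[match(sc$individual, x$ids)]),
    day = sc$day, time = sc$time, bin = bin_of,
    period = if (is.null(cutover_day)) "all"
             else ifelse(sc$day <= as.character(cutover_day), "two_enclosures",
                         "one_enclosure"),
    behaviour_category = sc$behaviour_category,
    activity_pattern = sc$activity_pattern,
    zone = sc$zone,
    hay_zone = zones$has_hay[match(sc$zone, zones$zone)],
    stringsAsFactors = FALSE)
}
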
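#' Dyadic matrix container
#'
#' A square individual-by-individual matrix with a defined-as-zero
#' diagonal. Symmetric for association, synchrony and kinship values;
#' directed (rows = actors) for interaction rates and win counts.
#'
#' @param values square numeric matrix with matching row/column names,
#'   or an unnamed matrix plus `ids`.
#' @param directed logical; if `FALSE` the matrix must be symmetric.
#' @param ids optional character vector of individual ids.
#' @param counts optional companion matrix of per-dyad sample sizes
#'   (e.g. joint-visibility scan counts behind each association index).
#' @return object of class `dyad_matrix` (a named matrix with
#'   attributes `directed` and, optionally, `counts`).
#' @export
#' @examples
#' m <- dyad_matrix(matrix(c(0, .2, .2, 0), 2), ids = c("a", "b"))
#' dyad_values(m)["a", "b"]
dyad_matrix <- function(values, directed = FALSE, ids = NULL, counts = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dyad_matrix must be square")
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  if (is.null(rownames(values))) stop("dyad_matrix needs individual ids")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids differ")
  if (anyDuplicated(rownames(values))) stop("duplicate individual ids")
  diag(values) <- 0
  if (!directed && !isTRUE(all.equal(values, t(values), tolerance = 1e-8)))
    stop("undirected dyad_matrix must be symmetric")
  if (any(values < 0)) stop("dyadic values must be nonnegative")
  structure(values, class = c("dyad_matrix", "matrix", "array"),
            directed = directed, counts = counts)
}

#' @rdname dyad_matrix
#' @param m a `dyad_matrix`
#' @export
dyad_values <- function(m) {
  v <- unclass(m)
  attributes(v) <- attributes(v)[c("dim", "dimnames")]
  v
}

#' @rdname dyad_matrix
#' @export
is_directed <- function(m) isTRUE(attr(m, "directed"))

#' @rdname dyad_matrix
#' @export
dyad_ids <- function(m) rownames(m)

#' Off-diagonal dyadic values
#'
#' Upper-triangle values for a symmetric matrix, all ordered off-diagonal
#' pairs for a directed one — the dyad set every summary statistic
#' (mean, CV, Mantel, assortment) is defined over.
#'
#' @param m a `dyad_matrix`
#' @return numeric vector
#' @export
offdiag_values <- function(m) {
  v <- dyad_values(m)
  if (is_directed(m)) v[row(v) != col(v)] else v[upper.tri(v)]
}

#' @export
print.dyad_matrix <- function(x, ...) {
  cat(sprintf("<dyad_matrix: %d individuals, %s>\n", nrow(x),
              if (is_directed(x)) "directed" else "symmetric"))
  print(round(dyad_values(x), 3))
  invisible(x)
}

#' Scan-sampling dataset
#'
#' Bundles instantaneous scan records (one row per visible individual
#' per scan) with the proximity pairs flagged at each scan (unordered id
#' pairs within one horse body length). Scans are identified by
#' calendar `day` and `time` in minutes since midnight.
#'
#' @param scans data.frame with columns `day`, `time`, `individual`,
#'   `behaviour_category`, `activity_pattern`, `zone` (`zone` may be NA).
#' @param pairs data.frame with columns `day`, `time`, `id_a`, `id_b`.
#' @param ids optional character vector fixing the id universe and order;
#'   defaults to the sorted ids seen in `scans`.
#' @return object of class `scan_dataset`
#' @export
scan_dataset <- function(scans, pairs = NULL, ids = NULL) {
  need <- c("day", "time", "individual", "behaviour_category",
            "activity_pattern", "zone")
  miss <- setdiff(need, names(scans))
  if (length(miss))
    stop("scan table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(pairs))
    pairs <- data.frame(day = scans$day[0], time = integer(),
                        id_a = character(), id_b = character())
  pneed <- c("day", "time", "id_a", "id_b")
  pmiss <- setdiff(pneed, names(pairs))
  if (length(pmiss))
    stop("pairs table lacks column(s): ", paste(pmiss, collapse = ", "))
  scans$day <- as.character(scans$day)
  pairs$day <- as.character(pairs$day)
  scans$individual <- as.character(scans$individual)
  if (is.null(ids)) ids <- sort(unique(scans$individual))
  if (!all(scans$individual %in% ids))
    stop("scan records reference ids outside the id universe")
  bad_time <- !is.finite(scans$time) | scans$time < 0 | scans$time >= 1440
  if (any(bad_time))
    stop("malformed scan time at row(s) ",
         paste(head(which(bad_time)), collapse = ", "))
  eth <- ethogram_activities()
  key <- match(scans$activity_pattern, eth$activity_pattern)
  if (anyNA(key))
    stop("unknown activity_pattern at row(s) ",
         paste(head(which(is.na(key))), collapse = ", "))
  mism <- eth$behaviour_category[key] != scans$behaviour_category
  if (any(mism))
    stop("activity_pattern/behaviour_category mismatch at scan row(s) ",
         paste(head(which(mism)), collapse = ", "))
  dup <- duplicated(scans[c("day", "time", "individual")])
  if (any(dup))
    stop("duplicate scan record for an individual at row(s) ",
         paste(head(which(dup)), collapse = ", "))
  # every pair member must have a scan record at that sample
  if (nrow(pairs)) {
    pairs$id_a <- as.character(pairs$id_a)
    pairs$id_b <- as.character(pairs$id_b)
    if (any(pairs$id_a == pairs$id_b)) stop("self-pair in proximity pairs")
    swap <- pairs$id_a > pairs$id_b
    tmp <- pairs$id_a[swap]; pairs$id_a[swap] <- pairs$id_b[swap]
    pairs$id_b[swap] <- tmp
    pairs <- unique(pairs)
    skey <- paste(scans$day, scans$time, scans$individual)
    ka <- paste(pairs$day, pairs$time, pairs$id_a) %in% skey
    kb <- paste(pairs$day, pairs$time, pairs$id_b) %in% skey
    if (!all(ka & kb))
      stop("proximity pair references an individual with no scan record ",
           "at pairs row(s) ", paste(head(which(!(ka & kb))), collapse = ", "))
  }
  structure(list(scans = scans, pairs = pairs, ids = ids),
            class = "scan_dataset")
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat(sprintf(
    "<scan_dataset: %d individuals, %d scan records, %d proximity pairs, %d days>\n",
    length(x$ids), nrow(x$scans), nrow(x$pairs),
    length(unique(x$scans$day))))
  invisible(x)
}

#' Number of distinct scan samples in a dataset
#' @param x a `scan_dataset`
#' @return integer
#' @export
n_scan_samples <- function(x) {
  nrow(unique(x$scans[c("day", "time")]))
}

#' Validate an interaction event table
#'
#' Checks actor/recipient distinctness and subtype consistency with the
#' interaction ethogram; fills `kind` and `role_class` from the subtype.
#'
#' @param events data.frame with columns `day`, `time`, `actor`,
#'   `recipient`, `subtype` (and optionally `kind`, `role_class`).
#' @return validated data.frame with `kind` and `role_class` columns
#' @export
validate_events <- function(events) {
  need <- c("day", "time", "actor", "recipient", "subtype")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  events$day <- as.character(events$day)
  eth <- ethogram_interactions()
  key <- match(events$subtype, eth$subtype)
  if (anyNA(key))
    stop("unknown interaction subtype at row(s) ",
         paste(head(which(is.na(key))), collapse = ", "))
  if (any(events$actor == events$recipient))
    stop("actor equals recipient at row(s) ",
         paste(head(which(events$actor == events$recipient)), collapse = ", "))
  if (!is.null(events$kind) && any(events$kind != eth$kind[key]))
    stop("event kind contradicts subtype at row(s) ",
         paste(head(which(events$kind != eth$kind[key])), collapse = ", "))
  events$kind <- eth$kind[key]
  events$role_class <- eth$role_class[key]
  events
}

#' Observation log
#'
#' Per-day observation windows (minutes since midnight); total contact
#' hours are the denominator of every interaction rate.
#'
#' @param windows data.frame with columns `day`, `start`, `end`.
#' @return object of class `obs_log` with a `total_hours` field
#' @export
obs_log <- function(windows) {
  need <- c("day", "start", "end")
  if (length(setdiff(need, names(windows))))
    stop("observation log needs columns day, start, end")
  windows$day <- as.character(windows$day)
  if (any(windows$end <= windows$start))
    stop("observation window with nonpositive length")
  for (d in unique(windows$day)) {
    w <- windows[windows$day == d, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping observation windows on day ", d)
  }
  structure(list(windows = windows,
                 total_hours = sum(windows$end - windows$start) / 60),
            class = "obs_log")
}

#' Zone map of the enclosures
#'
#' @param zones data.frame with columns `zone`, `area` (m^2), `has_hay`,
#'   `has_water`, `enclosure` ("I" or "II").
#' @return validated data.frame of class `zone_map`
#' @export
zone_map <- function(zones) {
  need <- c("zone", "area", "has_hay", "has_water", "enclosure")
  if (length(setdiff(need, names(zones))))
    stop("zone map needs columns zone, area, has_hay, has_water, enclosure")
  if (anyDuplicated(zones$zone)) stop("duplicate zone ids")
  if (any(zones$area <= 0)) stop("zone areas must be positive")
  class(zones) <- c("zone_map", "data.frame")
  zones
}

#' Default zone map: two enclosures split into 22 equal quadrats
#'
#' Enclosure I holds 18 zones (A1--A6, B1--B6, C1--C6), enclosure II the
#' four zones D1--D2 and E1--E2; each quadrat is 30 x 70 m. Hay piles
#' sit in A3--A6 and B3--B6 and the water container in C6.
#'
#' @return a `zone_map`
#' @export
default_zone_map <- function() {
  z <- c(paste0("A", 1:6), paste0("B", 1:6), paste0("C", 1:6),
         paste0("D", 1:2), paste0("E", 1:2))
  zone_map(data.frame(
    zone = z,
    area = 30 * 70,
    has_hay = z %in% c(paste0("A", 3:6), paste0("B", 3:6)),
    has_water = z == "C6",
    enclosure = ifelse(substr(z, 1, 1) %in% c("D", "E"), "II", "I"),
    stringsAsFactors = FALSE
  ))
}

#' Partition of individuals into social clusters
#'
#' @param membership named vector (names = ids) of cluster labels
#' @param modularity optional modularity score of this partition
#' @return object of class `social_partition`
#' @export
social_partition <- function(membership, modularity = NA_real_) {
  if (is.null(names(membership))) stop("membership must be named by id")
  structure(list(membership = setNames(as.integer(factor(membership)),
                                       names(membership)),
                 labels = membership,
                 modularity = modularity),
            class = "social_partition")
}

#' @export
print.social_partition <- function(x, ...) {
  cat(sprintf("<social_partition: %d clusters, Q = %.3f>\n",
              length(unique(x$membership)), x$modularity))
  print(split(names(x$membership), x$membership))
  invisible(x)
}
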
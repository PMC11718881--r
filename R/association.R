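#' Spatial groups at one scan sample (gambit of the group)
#'
#' Chains the proximity pairs of a single scan into groups: the
#' connected components of the pair graph, so that when more than two
#' animals are linked through a common neighbour all of them count as
#' associated. Individuals recorded at the scan but in no pair form
#' singleton groups.
#'
#' @param members character vector of ids recorded at the scan
#' @param pairs data.frame with columns `id_a`, `id_b` (that scan only)
#' @return list of character vectors, one per group
#' @export
#' @examples
#' scan_groups(c("A", "B", "C", "D"),
#'             data.frame(id_a = c("A", "B"), id_b = c("B", "C")))
scan_groups <- function(members, pairs) {
  comp <- setNames(seq_along(members), members)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- comp[[pairs$id_a[k]]]
      b <- comp[[pairs$id_b[k]]]
      if (a != b) comp[comp == b] <- a
    }
  }
  unname(split(members, comp))
}

#' Group stream of a scan dataset
#'
#' Resolves every scan sample into its chained groups. This is the
#' stream the association matrix is tallied from and the unit the
#' data-stream permutation swaps operate on.
#'
#' @param x a `scan_dataset`
#' @return data.frame with columns `day`, `time`, `scan` (integer scan
#'   index), `group` (integer group index, unique across the stream),
#'   `individual`
#' @export
group_stream <- function(x) {
  skey <- paste(x$scans$day, x$scans$time)
  pkey <- paste(x$pairs$day, x$pairs$time)
  scans <- unique(x$scans[c("day", "time")])
  scans <- scans[order(scans$day, scans$time), , drop = FALSE]
  ukey <- paste(scans$day, scans$time)
  out <- vector("list", nrow(scans))
  gid <- 0L
  for (s in seq_len(nrow(scans))) {
    members <- x$scans$individual[skey == ukey[s]]
    prs <- x$pairs[pkey == ukey[s], c("id_a", "id_b"), drop = FALSE]
    gs <- scan_groups(members, prs)
    n <- lengths(gs)
    out[[s]] <- data.frame(
      day = scans$day[s], time = scans$time[s], scan = s,
      group = gid + rep(seq_along(gs), n),
      individual = unlist(gs), stringsAsFactors = FALSE)
    gid <- gid + length(gs)
  }
  do.call(rbind, out)
}

#' Association-index matrix from scan samples
#'
#' AI(i,j) = number of scan samples in which i and j were members of
#' the same chained group, divided by the number of samples at which
#' both were recorded (joint visibility). Dyads never jointly observed
#' get AI 0 and are flagged in the `zero_joint` attribute.
#'
#' @param x a `scan_dataset`
#' @param ids optional id order for the matrix (default `x$ids`)
#' @return symmetric `dyad_matrix` in `[0, 1]` with a `counts`
#'   attribute holding per-dyad joint-visibility sample counts
#' @export
association_matrix <- function(x, ids = x$ids) {
  if (!all(x$ids %in% ids)) stop("unknown individual in id set")
  gs <- group_stream(x)
  n <- length(ids)
  num <- den <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (s in unique(gs$scan)) {
    rows <- gs[gs$scan == s, , drop = FALSE]
    idx <- match(rows$individual, ids)
    # joint visibility
    den[idx, idx] <- den[idx, idx] + 1L
    for (g in unique(rows$group)) {
      gi <- idx[rows$group == g]
      num[gi, gi] <- num[gi, gi] + 1L
    }
  }
  ai <- ifelse(den > 0, num / den, 0)
  diag(ai) <- 0
  m <- dyad_matrix(ai, directed = FALSE, counts = den)
  attr(m, "zero_joint") <- which(den == 0 & row(den) != col(den), arr.ind = TRUE)
  m
}

#' Directed interaction-rate matrix
#'
#' rate(i -> j) = number of events of the requested kind with actor i
#' and recipient j, divided by the total contact hours of the
#' observation log. Dyads with no recorded interaction get rate 0.
#'
#' @param events validated event data.frame (see [validate_events()])
#' @param log an [obs_log()]
#' @param kind `"affiliative"` or `"agonistic"`
#' @param ids id order for the matrix
#' @return directed `dyad_matrix` of rates (events/hour)
#' @export
interaction_rate_matrix <- function(events, log, kind = c("affiliative", "agonistic"),
                                    ids = NULL) {
  kind <- match.arg(kind)
  if (log$total_hours <= 0) stop("total contact hours must be positive")
  ev <- events[events$kind == kind, , drop = FALSE]
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$recipient)))
  if (nrow(ev) && !all(c(ev$actor, ev$recipient) %in% ids))
    stop("event references an individual outside the id set")
  n <- length(ids)
  cnt <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(ev)) {
    tab <- table(factor(ev$actor, ids), factor(ev$recipient, ids))
    cnt <- cnt + unclass(tab)
  }
  dyad_matrix(cnt / log$total_hours, directed = TRUE, counts = cnt)
}

#' Tabulate an event stream by kind and subtype
#'
#' Counts and within-kind percentage shares of each interaction
#' subtype, plus the offensive/defensive split of agonistic events —
#' the descriptive composition summaries usually reported alongside
#' rate matrices.
#'
#' @param events validated event data.frame
#' @return list with data.frames `by_subtype` (kind, subtype, n,
#'   pct_of_kind) and `by_role` (role_class, n, pct_of_agonistic)
#' @export
summarise_events <- function(events) {
  events <- validate_events(events)
  tab <- aggregate(list(n = events$actor),
                   by = list(kind = events$kind, subtype = events$subtype),
                   FUN = length)
  kt <- tapply(tab$n, tab$kind, sum)
  tab$pct_of_kind <- 100 * tab$n / as.numeric(kt[tab$kind])
  ag <- events[events$kind == "agonistic", , drop = FALSE]
  by_role <- if (nrow(ag)) {
    rt <- aggregate(list(n = ag$actor), by = list(role_class = ag$role_class),
                    FUN = length)
    rt$pct_of_agonistic <- 100 * rt$n / nrow(ag)
    rt
  } else data.frame(role_class = character(), n = integer(),
                    pct_of_agonistic = numeric())
  list(by_subtype = tab[order(tab$kind, -tab$n), ], by_role = by_role)
}
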
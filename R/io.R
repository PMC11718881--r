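#' Read a scan-sampling dataset from CSV
#'
#' `scans_path` holds one row per visible individual per scan sample
#' (columns day,time,individual,behaviour_category,activity_pattern,zone);
#' the companion `pairs_path` holds the proximity pairs flagged at each
#' scan (columns day,time,id_a,id_b). Both UTF-8, comma-separated, with
#' a header row. Validation rejects unknown activity patterns, category
#' mismatches against the ethogram, malformed times, and pairs that
#' reference an individual with no record at that scan.
#'
#' @param scans_path path to the scan CSV
#' @param pairs_path optional path to the pairs CSV
#' @param ids optional id universe
#' @return a [scan_dataset()]
#' @export
read_scan_dataset <- function(scans_path, pairs_path = NULL, ids = NULL) {
  scans <- read.csv(scans_path, stringsAsFactors = FALSE)
  pairs <- if (!is.null(pairs_path))
    read.csv(pairs_path, stringsAsFactors = FALSE)
  scan_dataset(scans, pairs, ids = ids)
}

#' Write a scan-sampling dataset to CSV
#'
#' Inverse of [read_scan_dataset()]; a write/read round trip reproduces
#' records and pairs exactly.
#'
#' @param x a `scan_dataset`
#' @param scans_path,pairs_path output paths
#' @export
write_scan_dataset <- function(x, scans_path, pairs_path) {
  write.csv(x$scans, scans_path, row.names = FALSE, quote = FALSE)
  write.csv(x$pairs, pairs_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Read an all-occurrence interaction event stream from CSV
#'
#' @param path CSV with columns day,time,actor,recipient,subtype
#' @return validated event data.frame (see [validate_events()])
#' @export
read_events <- function(path) {
  validate_events(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a pedigree from CSV
#'
#' @param path CSV with columns id,sire,dam (empty string or NA for an
#'   unknown parent; founders have both unknown)
#' @return data.frame with character columns id, sire, dam
#' @export
read_pedigree <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("id", "sire", "dam"), names(ped))))
    stop("pedigree needs columns id, sire, dam")
  for (col in c("id", "sire", "dam")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][ped[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  if (any(both & ped$sire == ped$dam))
    stop("sire equals dam for id ", ped$id[which(both & ped$sire == ped$dam)[1]])
  ped
}

#' Read a dyadic matrix from labelled CSV
#'
#' Expects an `id` column plus one column per individual, ids matching.
#'
#' @param path CSV path
#' @param directed is the matrix directed (rows = actors)?
#' @return a [dyad_matrix()]
#' @export
read_dyad_matrix <- function(path, directed = FALSE) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  dyad_matrix(m, directed = directed)
}

#' Write a dyadic matrix as labelled CSV
#'
#' @param m a `dyad_matrix`
#' @param path output path
#' @export
write_dyad_matrix <- function(m, path) {
  d <- data.frame(id = dyad_ids(m), dyad_values(m), check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(m)
}

#' Packaged worked-example data: a bachelor group of nine stallions
#'
#' Matrices and tables transcribed from a published observational study
#' of nine adult Przewalski's horse bachelor stallions (65 contact
#' hours of 10-min scan sampling and all-occurrence interaction
#' sampling in two steppe enclosures). Available fixtures:
#'
#' * `"ai"` — symmetric association-index matrix (proportion of scan
#'   samples spent within one horse body length, gambit of the group);
#' * `"affil_rates"` — directed affiliative interaction rates,
#'   events/hour, rows = initiators;
#' * `"bsi"` — symmetric dyadic behavioural synchronization indices
#'   (mean over activities);
#' * `"node_measures"` — per-individual strength, weighted degree
#'   (association and affiliation networks), dominance index, and
#'   social cluster as published;
#' * `"pedigree"` — one-generation pedigree (parents treated as
#'   founders).
#'
#' @param name one of `"ai"`, `"affil_rates"`, `"bsi"`,
#'   `"node_measures"`, `"pedigree"`
#' @return a `dyad_matrix` for the three matrices, a data.frame otherwise
#' @export
#' @examples
#' ai <- load_fixture("ai")
#' dyad_values(ai)["Lovelas", "Vernij"]  # 0.665
load_fixture <- function(name = c("ai", "affil_rates", "bsi",
                                  "node_measures", "pedigree")) {
  name <- match.arg(name)
  path <- system.file("extdata", "bachelor", paste0(name, ".csv"),
                      package = "herdnet", mustWork = TRUE)
  switch(name,
    ai = read_dyad_matrix(path, directed = FALSE),
    affil_rates = read_dyad_matrix(path, directed = TRUE),
    bsi = read_dyad_matrix(path, directed = FALSE),
    node_measures = read.csv(path, stringsAsFactors = FALSE),
    pedigree = read_pedigree(path)
  )
}

#' Write an analysis report as JSON (+ labelled CSV matrices)
#'
#' Serializes a nested list of results deterministically (keys sorted,
#' fixed numeric formatting). Any `dyad_matrix` encountered is written
#' as a labelled CSV next to the JSON file and replaced in the JSON by
#' its file name. Seeds and permutation counts present in `results`
#' are serialized as-is, so a rerun under the same seed and
#' configuration produces a byte-identical report body (the optional
#' metadata timestamp is excluded from that guarantee).
#'
#' @param results nested named list
#' @param path output JSON path
#' @param timestamp logical; include a wall-clock timestamp in metadata
#' @return invisibly, the path
#' @export
write_report <- function(results, path, timestamp = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sub("\\.json$", "", basename(path))
  csv_i <- 0L
  strip <- function(x, key) {
    if (inherits(x, "dyad_matrix")) {
      csv_i <<- csv_i + 1L
      fn <- sprintf("%s_%s.csv", stem, key)
      write_dyad_matrix(x, file.path(dir, fn))
      return(list(matrix_csv = fn))
    }
    if (inherits(x, "social_partition"))
      return(list(membership = as.list(x$membership),
                  modularity = x$modularity))
    if (is.function(x)) stop("report error: unserializable function in results")
    if (is.environment(x)) stop("report error: unserializable environment")
    if (is.list(x) && !is.data.frame(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      return(mapply(strip, x, if (is.null(names(x))) rep("", length(x))
                    else names(x), SIMPLIFY = FALSE))
    }
    x
  }
  body <- strip(results, "results")
  doc <- list(metadata = list(
    package = "herdnet",
    version = as.character(utils::packageVersion("herdnet"))
  ))
  if (timestamp) doc$metadata$created <- format(Sys.time(), tz = "UTC")
  doc$results <- body
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
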
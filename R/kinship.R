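#' Pedigree kinship coefficients
#'
#' Kinship (coancestry) by the tabular method: individuals are ordered
#' so parents precede offspring, the additive relationship matrix A is
#' filled by `a_ii = 1 + a_{sd}/2` and
#' `a_ij = (a_{s_i j} + a_{d_i j}) / 2`, and the kinship coefficient is
#' `phi = A / 2` — so an outbred founder has `phi(i,i) = 0.5`, full
#' sibs of unrelated parents 0.25, half sibs 0.125. Founders (unknown
#' parents) are assumed pairwise unrelated; a missing single parent
#' contributes zero.
#'
#' @param ped pedigree data.frame with character columns `id`, `sire`,
#'   `dam` (NA for unknown); see [read_pedigree()]
#' @param ids subset of ids the matrix is returned for (default: all)
#' @return symmetric `dyad_matrix` of kinship coefficients, diagonal
#'   kept (self-kinship), values in `[0, 1]`
#' @export
#' @examples
#' ped <- load_fixture("pedigree")
#' k <- kinship_matrix(ped, c("Lovelas", "Vernij"))
#' dyad_values(k)["Lovelas", "Vernij"]  # full sibs: 0.25
kinship_matrix <- function(ped, ids = ped$id) {
  if (!all(ids %in% ped$id)) stop("ids missing from pedigree")
  parents <- c(ped$sire, ped$dam)
  if (!all(parents[!is.na(parents)] %in% ped$id))
    stop("pedigree references unknown parent id(s)")
  n <- nrow(ped)
  # topological order: repeatedly emit individuals whose parents are placed
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$sire) | ped$sire %in% ped$id[placed]) &
      (is.na(ped$dam) | ped$dam %in% ped$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree cycle involving id(s): ",
         paste(ped$id[!placed], collapse = ", "))
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    s <- ped$sire[i]; d <- ped$dam[i]
    id <- ped$id[i]
    prior <- ped$id[ord[seq_len(match(i, ord) - 1)]]
    for (j in prior) {
      aij <- 0
      if (!is.na(s)) aij <- aij + A[s, j] / 2
      if (!is.na(d)) aij <- aij + A[d, j] / 2
      A[id, j] <- A[j, id] <- aij
    }
    A[id, id] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  if (anyDuplicated(ids)) stop("duplicate ids")
  phi <- A[ids, ids, drop = FALSE] / 2
  # built directly (not via dyad_matrix()) to keep the self-kinship diagonal
  structure(phi, class = c("dyad_matrix", "matrix", "array"),
            directed = FALSE, counts = NULL)
}

#' Monte Carlo kinship by gene dropping
#'
#' Independent check on the tabular recursion: founder alleles are
#' labelled uniquely, genotypes are dropped through the pedigree by
#' Mendelian sampling, and the kinship of a pair is estimated as the
#' probability that one allele drawn from each is identical by
#' descent, averaged over `n_drop` replicates.
#'
#' @inheritParams kinship_matrix
#' @param n_drop number of gene-dropping replicates
#' @param seed integer seed
#' @return symmetric matrix of kinship estimates for `ids`
#' @export
kinship_gene_drop <- function(ped, ids = ped$id, n_drop = 1e5, seed = 1) {
  if (!all(ids %in% ped$id)) stop("ids missing from pedigree")
  n <- nrow(ped)
  placed <- logical(n); ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$sire) | ped$sire %in% ped$id[placed]) &
      (is.na(ped$dam) | ped$dam %in% ped$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready)); placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree cycle")
  set.seed(seed)
  # allele matrices: rows = drops, one column pair per individual
  a1 <- matrix(0L, n_drop, n); a2 <- matrix(0L, n_drop, n)
  colnames(a1) <- colnames(a2) <- ped$id
  next_allele <- 0L
  for (i in ord) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      a1[, i] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drop) < 0.5
      a1[, i] <- ifelse(pick, a1[, s], a2[, s])
    }
    if (is.na(d)) {
      a2[, i] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drop) < 0.5
      a2[, i] <- ifelse(pick, a1[, d], a2[, d])
    }
  }
  k <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in i:length(ids)) {
    u1 <- a1[, ids[i]]; u2 <- a2[, ids[i]]
    v1 <- a1[, ids[j]]; v2 <- a2[, ids[j]]
    p <- ((u1 == v1) + (u1 == v2) + (u2 == v1) + (u2 == v2)) / 4
    if (i == j) p <- (1 + (u1 == u2)) / 2  # draw with replacement from self
    k[i, j] <- k[j, i] <- mean(p)
  }
  k
}
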
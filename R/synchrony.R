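#' @keywords internal
label_matrix <- function(x, level = c("category", "activity")) {
  level <- match.arg(level)
  col <- if (level == "category") "behaviour_category" else "activity_pattern"
  scans <- unique(x$scans[c("day", "time")])
  scans <- scans[order(scans$day, scans$time), , drop = FALSE]
  skey <- paste(scans$day, scans$time)
  L <- matrix(NA_character_, length(x$ids), nrow(scans),
              dimnames = list(x$ids, NULL))
  idx_s <- match(paste(x$scans$day, x$scans$time), skey)
  idx_i <- match(x$scans$individual, x$ids)
  L[cbind(idx_i, idx_s)] <- x$scans[[col]]
  L
}

#' @keywords internal
bsi_from_labels <- function(L, restrict_to = NULL) {
  n <- nrow(L)
  bsi <- matrix(0, n, n, dimnames = list(rownames(L), rownames(L)))
  joint <- matrix(0L, n, n, dimnames = dimnames(bsi))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(L[i, ]) & !is.na(L[j, ])
    joint[i, j] <- joint[j, i] <- sum(ok)
    if (!any(ok)) next
    if (is.null(restrict_to)) {
      val <- mean(L[i, ok] == L[j, ok])
    } else {
      both <- sum(L[i, ok] == restrict_to & L[j, ok] == restrict_to)
      either <- sum(L[i, ok] == restrict_to | L[j, ok] == restrict_to)
      val <- if (either > 0) both / either else 0
    }
    bsi[i, j] <- bsi[j, i] <- val
  }
  list(bsi = bsi, joint = joint)
}

#' Behavioural synchronization index matrix
#'
#' Overall BSI(i,j) is the proportion of the dyad's joint scan samples
#' in which both individuals showed the same behaviour label (category
#' by default, fine activity pattern with `level = "activity"`). With
#' `restrict_to`, the per-behaviour BSI is the share of joint scans
#' where both showed that behaviour among the scans where at least one
#' did (a Jaccard-style denominator, keeping values in `[0, 1]` and 0
#' when the behaviour is absent). Dyads with no joint scans get 0 and
#' are flagged in the `zero_joint` attribute.
#'
#' @param x a `scan_dataset`
#' @param level `"category"` or `"activity"`
#' @param restrict_to optional single behaviour label at that level
#' @return symmetric `dyad_matrix` with joint scan counts in `counts`
#' @export
bsi_matrix <- function(x, level = c("category", "activity"),
                       restrict_to = NULL) {
  L <- label_matrix(x, level)
  if (!is.null(restrict_to) && !any(L == restrict_to, na.rm = TRUE))
    warning("behaviour '", restrict_to, "' never observed")
  r <- bsi_from_labels(L, restrict_to)
  m <- dyad_matrix(r$bsi, directed = FALSE, counts = r$joint)
  attr(m, "zero_joint") <-
    which(r$joint == 0 & row(r$joint) != col(r$joint), arr.ind = TRUE)
  m
}

#' Randomization null for the synchronization index
#'
#' In each permutation one individual is chosen uniformly, `shuffle_n`
#' of its scan samples are selected without replacement (all of them if
#' it has fewer), and its behaviour labels are permuted among those
#' samples — preserving the individual's marginal behaviour
#' distribution while breaking temporal alignment. The BSI matrix is
#' recomputed each time. One-tailed p-values compare permuted indices
#' with observed ones: the group-mean p is the plain proportion of
#' permuted means at or above the observed mean, while each dyad's p
#' is computed over the permutations that shuffled one of its two
#' members (shuffling any other individual cannot change that dyad's
#' index, so unconditional proportions would be dominated by ties),
#' with the add-one small-sample correction `(k + 1) / (n + 1)`.
#'
#' @inheritParams bsi_matrix
#' @param n_perm number of permutations
#' @param shuffle_n number of scan samples shuffled per permutation
#' @param seed integer seed
#' @return list with `observed` (`dyad_matrix`), `p_dyad` (symmetric
#'   matrix), and `mean_result` (a `permutation_result` for the mean
#'   dyadic BSI)
#' @export
bsi_null <- function(x, n_perm = 1000, shuffle_n = 100, seed = 1,
                     level = c("category", "activity"), restrict_to = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  L <- label_matrix(x, level)
  obs <- bsi_from_labels(L, restrict_to)
  obs_mean <- mean(obs$bsi[upper.tri(obs$bsi)])
  n <- nrow(L)
  ge <- matrix(0L, n, n)
  n_rel <- matrix(0L, n, n)  # permutations involving the dyad
  null_means <- numeric(n_perm)
  set.seed(seed)
  for (k in seq_len(n_perm)) {
    i <- sample.int(n, 1L)
    Lk <- L
    seen <- which(!is.na(L[i, ]))
    take <- if (length(seen) > shuffle_n)
      sample(seen, shuffle_n) else seen
    Lk[i, take] <- L[i, sample(take)]
    perm <- obs$bsi
    for (j in seq_len(n)[-i]) {
      ok <- !is.na(Lk[i, ]) & !is.na(Lk[j, ])
      if (!any(ok)) next
      val <- if (is.null(restrict_to)) mean(Lk[i, ok] == Lk[j, ok])
      else {
        both <- sum(Lk[i, ok] == restrict_to & Lk[j, ok] == restrict_to)
        either <- sum(Lk[i, ok] == restrict_to | Lk[j, ok] == restrict_to)
        if (either > 0) both / either else 0
      }
      perm[i, j] <- perm[j, i] <- val
    }
    ge[i, ] <- ge[i, ] + (perm[i, ] >= obs$bsi[i, ])
    ge[, i] <- ge[, i] + (perm[, i] >= obs$bsi[, i])
    ge[i, i] <- 0L
    n_rel[i, ] <- n_rel[i, ] + 1L
    n_rel[, i] <- n_rel[, i] + 1L
    n_rel[i, i] <- 0L
    null_means[k] <- mean(perm[upper.tri(perm)])
  }
  p_dyad <- ifelse(n_rel > 0, (ge + 1) / (n_rel + 1), NA_real_)
  diag(p_dyad) <- NA_real_
  dimnames(p_dyad) <- dimnames(obs$bsi)
  list(
    observed = dyad_matrix(obs$bsi, directed = FALSE, counts = obs$joint),
    p_dyad = p_dyad,
    mean_result = permutation_result(obs_mean, null_means,
                                     mean(null_means >= obs_mean),
                                     seed, "greater"),
    n_perm = n_perm, shuffle_n = shuffle_n, seed = seed)
}

#' Within- vs between-cluster synchrony contrast
#'
#' Means of the dyadic synchronization index over within-cluster and
#' between-cluster dyads, per-cluster means, their difference, and a
#' node-label permutation p-value (proportion of membership shuffles
#' whose within-minus-between difference is at least the observed one).
#'
#' @param bsi symmetric `dyad_matrix` of synchronization indices
#' @param partition a `social_partition` or labelled membership vector
#' @param n_perm number of membership permutations
#' @param seed integer seed
#' @return list with `cluster_means`, `within_mean`, `between_mean`,
#'   `difference`, `p_value`, `null_stats`
#' @export
cluster_synchrony <- function(bsi, partition, n_perm = 1000, seed = 1) {
  v <- dyad_values(bsi)
  mem <- partition_membership(partition, dyad_ids(bsi))
  if (length(unique(mem)) < 2)
    stop("between-cluster mean undefined for a single cluster")
  if (all(table(mem) == 1))
    stop("within-cluster mean undefined for singleton-only clusters")
  contrast <- function(mm) {
    same <- outer(mm, mm, "==")
    wi <- mean(v[upper.tri(v) & same])
    be <- mean(v[upper.tri(v) & !same])
    c(within = wi, between = be, diff = wi - be)
  }
  obs <- contrast(mem)
  cl_means <- vapply(sort(unique(mem)), function(cl) {
    sel <- mem == cl
    if (sum(sel) < 2) return(NA_real_)
    sub <- v[sel, sel]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm),
                       function(k) contrast(mem[sample.int(length(mem))])["diff"],
                       numeric(1))
  list(cluster_means = setNames(cl_means, paste0("cluster", sort(unique(mem)))),
       within_mean = unname(obs["within"]),
       between_mean = unname(obs["between"]),
       difference = unname(obs["diff"]),
       p_value = mean(null_stats >= obs["diff"]),
       null_stats = unname(null_stats), n_perm = n_perm, seed = seed)
}
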
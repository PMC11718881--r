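#' @keywords internal
permutation_result <- function(observed, null_stats, p_value, seed,
                               alternative, extra = list()) {
  structure(c(list(observed_stat = observed, null_stats = null_stats,
                   p_value = p_value, n_perm = length(null_stats),
                   seed = seed, alternative = alternative), extra),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result: observed = %.4f, p = %.4f (%s, n_perm = %d, seed = %s)>\n",
    x$observed_stat, x$p_value, x$alternative, x$n_perm,
    format(x$seed)))
  invisible(x)
}

#' Coefficient of variation of dyadic values
#'
#' Sample standard deviation divided by the mean of the off-diagonal
#' dyadic values (upper triangle for a symmetric matrix, all ordered
#' pairs for a directed one). The test statistic of the non-randomness
#' permutation test: social preferences inflate the spread of
#' association indices relative to an exchangeable null.
#'
#' @param m a `dyad_matrix`, or a plain square matrix (treated as
#'   symmetric when it is, directed otherwise)
#' @return the coefficient of variation
#' @export
cv_statistic <- function(m) {
  v <- if (inherits(m, "dyad_matrix")) offdiag_values(m)
  else if (isTRUE(all.equal(m, t(m), tolerance = 1e-8))) m[upper.tri(m)]
  else m[row(m) != col(m)]
  if (length(v) < 2) stop("need at least two off-diagonal values")
  mu <- mean(v)
  if (mu == 0) stop("CV undefined: zero mean of dyadic values")
  sd(v) / mu
}

# Mutable swap-chain state over the group stream of a scan dataset.
# Conserved margins: per-scan group sizes and each individual's number
# of observations per day. Swap legality forbids duplicate presence
# within a scan sample, so presence stays 0/1 throughout the chain;
# under full visibility only swaps between two groups of the same
# scan are legal, under partial visibility an individual's
# observation may also move between scans of the same day.
#' @keywords internal
swap_state <- function(x) {
  gs <- group_stream(x)
  ids <- x$ids
  n <- length(ids)
  S <- max(gs$scan)
  groups <- split(match(gs$individual, ids), gs$group)
  ginfo <- unique(gs[c("group", "day", "scan")])
  ginfo <- ginfo[order(ginfo$group), ]
  gday <- ginfo$day
  gscan <- ginfo$scan
  day_groups <- split(seq_along(groups), gday)
  day_groups <- day_groups[lengths(day_groups) >= 2]
  scan_groups_ix <- split(seq_along(groups), gscan)
  pres <- matrix(0L, n, S)
  num <- matrix(0L, n, n)
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    pres[cbind(mem, gscan[g])] <- pres[cbind(mem, gscan[g])] + 1L
    num[mem, mem] <- num[mem, mem] + 1L
  }
  diag(num) <- 0L
  P01 <- pres > 0
  den <- (P01 + 0L) %*% t(P01 + 0L)
  diag(den) <- 0L
  full_vis <- all(pres == 1L)
  # scans with >= 2 groups, per day (group counts are conserved by swaps)
  multi <- names(scan_groups_ix)[lengths(scan_groups_ix) >= 2]
  scan_day <- gday[!duplicated(gscan)][order(unique(gscan))]
  day_scans <- split(as.integer(multi), scan_day[as.integer(multi)])
  day_scans <- day_scans[lengths(day_scans) >= 1]
  list(ids = ids, n = n, groups = groups, gday = gday, gscan = gscan,
       day_groups = day_groups, scan_groups_ix = scan_groups_ix,
       day_scans = day_scans, full_vis = full_vis,
       pres = pres, P01 = P01, num = num, den = den)
}

#' @keywords internal
state_ai <- function(st) {
  ai <- ifelse(st$den > 0, st$num / st$den, 0)
  diag(ai) <- 0
  dimnames(ai) <- list(st$ids, st$ids)
  ai
}

# One legal swap attempt; returns updated state or NULL if rejected.
#' @keywords internal
try_swap <- function(st) {
  if (st$full_vis) {
    # under full visibility only same-scan swaps are legal; propose
    # directly within a scan (group counts per scan are conserved, so
    # this kernel is symmetric too)
    if (!length(st$day_scans)) return(NULL)
    d <- sample(length(st$day_scans), 1L)
    ss <- st$day_scans[[d]]
    s1 <- s2 <- ss[sample.int(length(ss), 1L)]
    gg <- st$scan_groups_ix[[as.character(s1)]]
    pick <- sample(length(gg), 2L)
    g1 <- gg[pick[1]]; g2 <- gg[pick[2]]
  } else {
    d <- sample(length(st$day_groups), 1L)
    gg <- st$day_groups[[d]]
    pick <- sample(length(gg), 2L)
    g1 <- gg[pick[1]]; g2 <- gg[pick[2]]
    s1 <- st$gscan[g1]; s2 <- st$gscan[g2]
  }
  M1 <- st$groups[[g1]]; M2 <- st$groups[[g2]]
  # members drawn uniformly (not only among legal ones) and illegal
  # proposals rejected: group sizes are conserved, so the proposal
  # kernel is symmetric and the chain's stationary distribution is
  # uniform over the constrained group streams
  a <- M1[sample.int(length(M1), 1L)]
  b <- M2[sample.int(length(M2), 1L)]
  if (a == b) return(NULL)
  # no duplicate presence within a scan sample
  if (s1 == s2) {
    if (a %in% M2 || b %in% M1) return(NULL)
  } else {
    if (st$pres[a, s2] > 0L || st$pres[b, s1] > 0L) return(NULL)
  }
  M1p <- M1[M1 != a]; M2p <- M2[M2 != b]
  num <- st$num
  if (length(M1p)) { num[a, M1p] <- num[a, M1p] - 1L; num[M1p, a] <- num[M1p, a] - 1L }
  if (length(M2p)) { num[b, M2p] <- num[b, M2p] - 1L; num[M2p, b] <- num[M2p, b] - 1L }
  if (length(M2p)) { num[a, M2p] <- num[a, M2p] + 1L; num[M2p, a] <- num[M2p, a] + 1L }
  if (length(M1p)) { num[b, M1p] <- num[b, M1p] + 1L; num[M1p, b] <- num[M1p, b] + 1L }
  st$num <- num
  st$groups[[g1]] <- c(M1p, b)
  st$groups[[g2]] <- c(M2p, a)
  if (s1 != s2) {
    st$pres[a, s1] <- 0L; st$pres[a, s2] <- 1L
    st$pres[b, s2] <- 0L; st$pres[b, s1] <- 1L
    st$P01[c(a, b), c(s1, s2)] <- st$pres[c(a, b), c(s1, s2)] > 0
    for (x in c(a, b)) {
      dx <- as.integer((st$P01 + 0L) %*% (st$P01[x, ] + 0L))
      dx[x] <- 0L
      st$den[x, ] <- dx
      st$den[, x] <- dx
    }
  }
  st
}

#' Day-restricted data-stream permutation test
#'
#' Bejder-style cumulative swap chain over the group stream: each step
#' selects a day, two distinct groups observed on that day, and
#' exchanges one individual between them, rejecting swaps that would
#' duplicate an individual within a scan sample. Swaps preserve per-scan group
#' sizes and each individual's number of observations per day. The
#' test statistic is recomputed on the association matrix after every
#' accepted swap (no burn-in discard) and the empirical p-value
#' compares the observed statistic with the chain.
#'
#' @param x a `scan_dataset`
#' @param n_perm number of accepted swaps (chain length)
#' @param seed integer seed
#' @param statistic function of the (named, symmetric) association
#'   matrix returning a scalar; default [cv_statistic()]
#' @param thin number of accepted swaps between recorded statistics;
#'   1 records after every swap, larger values improve chain mixing
#'   per recorded sample
#' @param alternative `"greater"` (default; observed larger than null),
#'   `"less"`, or `"two.sided"`
#' @param max_attempts rejection-sampling cap per step
#' @return a `permutation_result`
#' @export
datastream_permute <- function(x, n_perm = 1000, seed = 1,
                               statistic = cv_statistic,
                               alternative = c("greater", "less", "two.sided"),
                               thin = 1, max_attempts = 1000) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1")
  st <- swap_state(x)
  if (!length(st$day_groups) || !swap_possible(st))
    stop("degenerate group stream: no legal swap exists")
  observed <- statistic(state_ai(st))
  set.seed(seed)
  null_stats <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    for (t in seq_len(thin)) {
      ok <- NULL
      for (att in seq_len(max_attempts)) {
        ok <- try_swap(st)
        if (!is.null(ok)) break
      }
      if (is.null(ok))
        stop("degenerate group stream: no legal swap found in ",
             max_attempts, " attempts")
      st <- ok
    }
    null_stats[k] <- statistic(state_ai(st))
  }
  p <- switch(alternative,
    greater = mean(null_stats >= observed),
    less = mean(null_stats <= observed),
    two.sided = mean(abs(null_stats - mean(null_stats)) >=
                       abs(observed - mean(null_stats))))
  permutation_result(observed, null_stats, p, seed, alternative)
}

#' @keywords internal
swap_possible <- function(st) {
  for (gg in st$day_groups) {
    for (i in seq_along(gg)[-length(gg)]) {
      for (j in (i + 1):length(gg)) {
        g1 <- gg[i]; g2 <- gg[j]
        M1 <- st$groups[[g1]]; M2 <- st$groups[[g2]]
        s1 <- st$gscan[g1]; s2 <- st$gscan[g2]
        ca <- if (s1 == s2) setdiff(M1, M2) else M1[st$pres[M1, s2] == 0L]
        cb <- if (s1 == s2) setdiff(M2, M1) else M2[st$pres[M2, s1] == 0L]
        if (length(ca) && length(cb) &&
            length(unique(c(ca, cb))) >= 2) return(TRUE)
      }
    }
  }
  FALSE
}

#' Preferred / avoided dyad classification
#'
#' Runs the data-stream swap chain and, per dyad, computes `p_high` =
#' proportion of permuted association indices at least as large as the
#' observed one. Dyads with `p_high <= preferred_alpha` are labelled
#' `preferred` (more association than chance), dyads with `p_high >=
#' avoided_alpha` are `avoided` (the same one-tailed distribution read
#' at its other end), the rest `neutral`.
#'
#' @inheritParams datastream_permute
#' @param preferred_alpha,avoided_alpha classification thresholds
#' @return list with the observed `ai` matrix, symmetric matrix
#'   `p_high`, character matrix `label`, and data.frame `dyads`
#' @export
classify_dyads <- function(x, n_perm = 1000, seed = 1,
                           preferred_alpha = 0.05, avoided_alpha = 0.95,
                           thin = 1, max_attempts = 1000) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  st <- swap_state(x)
  if (!length(st$day_groups) || !swap_possible(st))
    stop("degenerate group stream: no legal swap exists")
  obs <- state_ai(st)
  set.seed(seed)
  ge <- matrix(0L, st$n, st$n)
  for (k in seq_len(n_perm)) {
    for (t in seq_len(thin)) {
      ok <- NULL
      for (att in seq_len(max_attempts)) {
        ok <- try_swap(st)
        if (!is.null(ok)) break
      }
      if (is.null(ok))
        stop("degenerate group stream: no legal swap found in ",
             max_attempts, " attempts")
      st <- ok
    }
    ge <- ge + (state_ai(st) >= obs)
  }
  p_high <- ge / n_perm
  diag(p_high) <- NA_real_
  dimnames(p_high) <- dimnames(obs)
  label <- matrix("neutral", st$n, st$n, dimnames = dimnames(obs))
  label[p_high <= preferred_alpha] <- "preferred"
  label[p_high >= avoided_alpha] <- "avoided"
  diag(label) <- NA_character_
  ut <- which(upper.tri(obs), arr.ind = TRUE)
  dyads <- data.frame(
    id_a = rownames(obs)[ut[, 1]], id_b = colnames(obs)[ut[, 2]],
    ai = obs[ut], p_high = p_high[ut], label = label[ut],
    stringsAsFactors = FALSE)
  list(ai = obs, p_high = p_high, label = label, dyads = dyads,
       n_perm = n_perm, seed = seed)
}

#' Mantel test of matrix correlation
#'
#' Pearson (default) correlation between the upper triangles of two
#' symmetric dyadic matrices on the same individuals, with a null
#' built by simultaneous row/column permutation of the second matrix.
#' Directed matrices must be symmetrized upstream (e.g. by summing the
#' two directions). For small groups the full permutation group can be
#' enumerated (`exhaustive = TRUE`), in which case the p-value is the
#' exact proportion over all n! relabellings (identity included).
#'
#' @param a,b symmetric `dyad_matrix` objects sharing ids
#' @param n_perm number of random permutations (ignored if exhaustive)
#' @param seed integer seed
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`
#' @param method correlation type passed to [stats::cor()]
#' @param exhaustive enumerate all permutations (requires <= 8 ids)
#' @return a `permutation_result`
#' @export
mantel_test <- function(a, b, n_perm = 1000, seed = 1,
                        alternative = c("two.sided", "greater", "less"),
                        method = "pearson", exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  if (is_directed(a) || is_directed(b))
    stop("mantel_test needs symmetric matrices; symmetrize directed input first")
  if (!identical(dyad_ids(a), dyad_ids(b))) {
    if (!setequal(dyad_ids(a), dyad_ids(b)))
      stop("matrices must share the same individuals")
    bv <- dyad_values(b)[dyad_ids(a), dyad_ids(a)]
    b <- dyad_matrix(bv, directed = FALSE)
  }
  av <- dyad_values(a); bv <- dyad_values(b)
  xa <- av[upper.tri(av)]
  if (sd(xa) == 0 || sd(bv[upper.tri(bv)]) == 0)
    stop("undefined correlation: constant matrix")
  observed <- cor(xa, bv[upper.tri(bv)], method = method)
  n <- nrow(av)
  stat_for <- function(perm) {
    bp <- bv[perm, perm]
    cor(xa, bp[upper.tri(bp)], method = method)
  }
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to 8 individuals")
    perms <- all_permutations(n)
    null_stats <- vapply(perms, stat_for, numeric(1))
  } else {
    set.seed(seed)
    null_stats <- vapply(seq_len(n_perm),
                         function(k) stat_for(sample.int(n)), numeric(1))
  }
  p <- switch(alternative,
    greater = mean(null_stats >= observed),
    less = mean(null_stats <= observed),
    two.sided = mean(abs(null_stats) >= abs(observed)))
  permutation_result(observed, null_stats, p, if (exhaustive) NA else seed,
                     alternative, extra = list(method = method,
                                               exhaustive = exhaustive))
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Symmetrize a directed matrix by summing directions
#'
#' @param m directed `dyad_matrix`
#' @return symmetric `dyad_matrix` with values `m[i,j] + m[j,i]`
#' @export
symmetrize <- function(m) {
  v <- dyad_values(m)
  dyad_matrix(v + t(v), directed = FALSE)
}
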
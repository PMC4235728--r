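# ANOSIM statistic on a dissimilarity matrix given a grouping vector.
# Ranks use mid-ranks for ties; R = (mean between-rank - mean within-rank)
# divided by M/2, M = n(n-1)/2.
anosim_r_stat <- function(ranks, within, M) {
  (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
}

# All distinct permutations of a label multiset, as a matrix (rows = labelings).
multiset_permutations <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  if (n == 1) return(matrix(labels, 1, 1))
  uniq <- unique(labels)
  do.call(rbind, lapply(uniq, function(u) {
    rest <- labels[-match(u, labels)]
    cbind(u, multiset_permutations(rest), deparse.level = 0)
  }))
}

# number of distinct labelings of a grouping vector
n_distinct_labelings <- function(grouping) {
  counts <- table(grouping)
  round(exp(lgamma(length(grouping) + 1) - sum(lgamma(counts + 1))))
}

#' Analysis of similarity (ANOSIM)
#'
#' Tests whether between-group dissimilarities are larger than within-group
#' dissimilarities, on the ranks of all n(n-1)/2 pairwise values (mid-ranks
#' for ties). Significance is one-sided (large R) by label permutation with
#' the +1 convention, p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm); when the
#' number of distinct labelings is at most `n_perm` the null is enumerated
#' exhaustively and p has that count as its denominator.
#'
#' @param D a `dist_matrix`.
#' @param meta [sample_metadata()] (or a grouping vector named by sample).
#' @param n_perm maximum number of permutations (default 9999).
#' @param seed RNG seed for sampled permutations; recorded in the result.
#' @return An `anosim_result`: list(R, p, n_permutations, exhaustive, groups,
#'   seed).
#' @export
anosim <- function(D, meta, n_perm = 9999, seed = 1) {
  grouping <- groups_for(meta, rownames(D))
  sizes <- table(grouping)
  if (length(sizes) < 2) validation_error("ANOSIM needs at least two groups")
  if (any(sizes < 2)) {
    validation_error(paste0("group(s) with a single sample: ",
                            paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  n <- nrow(D)
  lt <- lower.tri(unclass(D))
  ranks <- rank(unclass(D)[lt])
  M <- n * (n - 1) / 2
  pair_i <- row(unclass(D))[lt]
  pair_j <- col(unclass(D))[lt]
  r_obs <- anosim_r_stat(ranks, grouping[pair_i] == grouping[pair_j], M)
  n_lab <- n_distinct_labelings(grouping)
  eps <- 1e-12
  if (n_lab <= n_perm) {
    perms <- multiset_permutations(grouping)
    r_null <- apply(perms, 1, function(g) {
      anosim_r_stat(ranks, g[pair_i] == g[pair_j], M)
    })
    p <- sum(r_null >= r_obs - eps) / nrow(perms)
    res <- list(R = r_obs, p = p, n_permutations = nrow(perms),
                exhaustive = TRUE, null_R = r_null)
  } else {
    r_null <- withr::with_seed(seed, replicate(n_perm, {
      g <- sample(grouping)
      anosim_r_stat(ranks, g[pair_i] == g[pair_j], M)
    }))
    p <- (1 + sum(r_null >= r_obs - eps)) / (1 + n_perm)
    res <- list(R = r_obs, p = p, n_permutations = n_perm,
                exhaustive = FALSE, null_R = r_null)
  }
  res$groups <- names(sizes)
  res$seed <- seed
  structure(res, class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.5g (%s, %d labelings)\n",
              x$R, x$p, if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Pairwise ANOSIM with Bonferroni correction
#'
#' Runs [anosim()] on the sample submatrix of every unordered group pair and
#' Bonferroni-corrects the p-values by the number of pairs.
#'
#' @inheritParams anosim
#' @return A `pairwise_anosim` data.frame: group_a, group_b, R, p,
#'   p_bonferroni, n_permutations, exhaustive.
#' @export
pairwise_anosim <- function(D, meta, n_perm = 9999, seed = 1) {
  grouping <- groups_for(meta, rownames(D))
  groups <- unique(grouping)
  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    idx <- which(grouping %in% c(g1, g2))
    sub <- dist_matrix(unclass(D)[idx, idx], metric = attr(D, "metric"))
    res <- anosim(sub, meta, n_perm = n_perm, seed = seed + k)
    data.frame(group_a = g1, group_b = g2, R = res$R, p = res$p,
               p_bonferroni = bonferroni(res$p, m),
               n_permutations = res$n_permutations,
               exhaustive = res$exhaustive)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("pairwise_anosim", "data.frame")
  out
}

#' Square layout of pairwise ANOSIM results
#'
#' R statistics in the lower-left triangle, Bonferroni-corrected p-values in
#' the upper-right, zeros on the diagonal.
#'
#' @param pairwise a `pairwise_anosim` data.frame.
#' @param group_order optional ordering of the groups along the axes.
#' @return A square numeric matrix.
#' @export
anosim_table <- function(pairwise, group_order = NULL) {
  groups <- group_order %||% unique(c(pairwise$group_a, pairwise$group_b))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (k in seq_len(nrow(pairwise))) {
    i <- match(pairwise$group_a[k], groups)
    j <- match(pairwise$group_b[k], groups)
    lo <- max(i, j); hi <- min(i, j)
    m[lo, hi] <- pairwise$R[k]
    m[hi, lo] <- pairwise$p_bonferroni[k]
  }
  m
}
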
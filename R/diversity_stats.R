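#' Observed OTU richness
#'
#' Per-sample counts of OTUs with abundance above zero; with metadata, also
#' the per-group totals (OTUs present in any sample of the group).
#'
#' @param table an [otu_table()].
#' @param meta optional [sample_metadata()].
#' @return list(`per_sample`: named integer vector; `per_group`: named integer
#'   vector of group totals, NULL without metadata).
#' @export
observed_otus <- function(table, meta = NULL) {
  per_sample <- as.integer(rowSums(unclass(table) > 0))
  names(per_sample) <- rownames(table)
  per_group <- NULL
  if (!is.null(meta)) {
    grp <- groups_for(meta, rownames(table))
    per_group <- vapply(split(seq_len(nrow(table)), grp), function(idx) {
      sum(colSums(unclass(table)[idx, , drop = FALSE] > 0) > 0)
    }, integer(1))
  }
  list(per_sample = per_sample, per_group = per_group)
}

#' Shannon-Wiener diversity H'
#'
#' H' = -sum(p_i * log(p_i)) over the positive proportions of each sample,
#' in natural-log units (nats).
#'
#' @param table an [otu_table()].
#' @return Named numeric vector of per-sample H'.
#' @export
shannon <- function(table) {
  m <- unclass(table)
  if (any(rowSums(m) <= 0)) {
    undefined_value_error(paste0("Shannon diversity undefined for all-zero sample(s): ",
                                 paste(rownames(m)[rowSums(m) <= 0], collapse = ", ")))
  }
  h <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  stats::setNames(as.numeric(h), rownames(m))
}

#' Bray-Curtis similarity and dissimilarity of two abundance vectors
#'
#' Dissimilarity = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y)); similarity is
#' its complement. Applied to relative intensities (ARISA) or proportions
#' (sequencing).
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return list(`similarity`, `dissimilarity`).
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) validation_error("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) validation_error("abundances must be non-negative")
  sx <- sum(x); sy <- sum(y)
  if (sx + sy <= 0) undefined_value_error("Bray-Curtis undefined for two all-zero vectors")
  d <- 1 - 2 * sum(pmin(x, y)) / (sx + sy)
  list(similarity = 1 - d, dissimilarity = d)
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Count tables are converted to per-sample proportions first; relative
#' intensity tables are used as-is. The pairwise computation is delegated to
#' \code{vegan::vegdist}.
#'
#' @param table an [otu_table()] with at least two samples.
#' @return A `dist_matrix` of Bray-Curtis dissimilarities.
#' @export
distance_matrix <- function(table) {
  if (nrow(table) < 2) validation_error("need at least two samples for a distance matrix")
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    undefined_value_error(paste0("all-zero sample(s): ",
                                 paste(rownames(m)[rs <= 0], collapse = ", ")))
  }
  if (abundance_kind(table) == "read_count") m <- m / rs
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dist_matrix(d, metric = "bray_curtis")
}

#' Within-group Bray-Curtis similarity summary
#'
#' Mean and SD of (1 - D) over the within-group sample pairs of each group.
#' Groups with a single pair get SD 0 with a warning; singleton groups are
#' skipped with a warning.
#'
#' @param D a `dist_matrix`.
#' @param meta [sample_metadata()].
#' @return data.frame group, n_pairs, mean_similarity, sd_similarity.
#' @export
within_group_similarity <- function(D, meta) {
  grp <- groups_for(meta, rownames(D))
  out <- lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has one sample; skipped")
      return(NULL)
    }
    sims <- 1 - unclass(D)[idx, idx][lower.tri(diag(length(idx)))]
    sdv <- if (length(sims) < 2) {
      warning("group '", g, "' has a single pair; SD set to 0")
      0
    } else stats::sd(sims)
    data.frame(group = g, n_pairs = length(sims),
               mean_similarity = mean(sims), sd_similarity = sdv)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Pair-level within-group similarities, used for the between-method test.
within_group_pairs <- function(D, meta) {
  grp <- groups_for(meta, rownames(D))
  do.call(rbind, lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2) return(NULL)
    data.frame(group = g,
               similarity = 1 - unclass(D)[idx, idx][lower.tri(diag(length(idx)))])
  }))
}

#' Compare two methods' within-group similarities
#'
#' For each group, a Welch t-test on the pair-level Bray-Curtis similarities
#' from the two distance matrices (same samples, two measurement methods).
#'
#' @param D1,D2 `dist_matrix` objects over the same samples.
#' @param meta [sample_metadata()].
#' @param labels method names for the output columns.
#' @return data.frame per group: means for both methods, t, df, p.
#' @export
compare_within_group_similarity <- function(D1, D2, meta,
                                            labels = c("method1", "method2")) {
  if (!identical(rownames(D1), rownames(D2))) join_error("distance matrices must share labels and order")
  p1 <- within_group_pairs(D1, meta)
  p2 <- within_group_pairs(D2, meta)
  out <- lapply(unique(p1$group), function(g) {
    a <- p1$similarity[p1$group == g]
    b <- p2$similarity[p2$group == g]
    tt <- welch_t_test(a, b)
    df <- data.frame(group = g, m1 = mean(a), m2 = mean(b),
                     t = tt$t, df = tt$df, p = tt$p)
    names(df)[2:3] <- paste0("mean_", labels)
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# enumerate all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Correlate the pairwise-similarity vectors of two distance matrices
#'
#' Pearson correlation over the n(n-1)/2 sample-pair similarities of two
#' methods. Because the pairs are not independent, a Mantel-style permutation
#' p (joint row/column permutations of one matrix, one-sided for positive
#' association) is reported alongside the parametric p; the permutation null
#' is enumerated exhaustively when n! <= `n_perm`.
#'
#' @param D1,D2 `dist_matrix` objects with identical labels and order.
#' @param n_perm number of Mantel permutations (default 999).
#' @param seed RNG seed for sampled permutations.
#' @return list(pearson_r, r_squared, p_parametric, p_mantel, n_pairs,
#'   exhaustive).
#' @export
correlate_similarity_vectors <- function(D1, D2, n_perm = 999, seed = 1) {
  if (!identical(rownames(D1), rownames(D2))) {
    join_error("distance matrices must share labels and order")
  }
  n <- nrow(D1)
  ut <- upper.tri(unclass(D1))
  s1 <- 1 - unclass(D1)[ut]
  s2 <- 1 - unclass(D2)[ut]
  r <- stats::cor(s1, s2)
  ct <- stats::cor.test(s1, s2)
  m2 <- unclass(D2)
  r_for <- function(perm) {
    stats::cor(s1, 1 - m2[perm, perm][ut])
  }
  if (factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, r_for)
    p_mantel <- mean(rs >= r - 1e-12)
    exhaustive <- TRUE
  } else {
    rs <- withr::with_seed(seed, replicate(n_perm, r_for(sample.int(n))))
    p_mantel <- (1 + sum(rs >= r - 1e-12)) / (1 + n_perm)
    exhaustive <- FALSE
  }
  list(pearson_r = r, r_squared = r^2,
       p_parametric = unname(ct$p.value), p_mantel = p_mantel,
       n_pairs = length(s1), exhaustive = exhaustive)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test, two-sided, with Welch-Satterthwaite degrees of
#' freedom. When both groups have zero variance and equal means the test is
#' degenerate and p = 1 by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list(t, df, p).
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) validation_error("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of comparisons (default: `length(p)`).
#' @return min(1, m * p), elementwise.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)
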
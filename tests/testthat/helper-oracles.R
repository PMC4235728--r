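# Independent brute-force oracles. These re-derive expected results by the
# most literal route available (per-record loops, explicit enumeration,
# direct numerical minimization) and deliberately share no code with the
# package implementation.

# --- ARISA pipeline oracle -------------------------------------------------

# Explicit bin list for the default scheme: 3-bp bins anchored at 200 up to
# 700, 5-bp bins to 1000, 10-bp bins to 1150; half-open, last bin closed.
oracle_bins <- function() {
  lo <- c(seq(200, 698, by = 3), seq(700, 995, by = 5), seq(1000, 1140, by = 10))
  hi <- c(pmin(seq(200, 698, by = 3) + 3, 700), seq(705, 1000, by = 5),
          seq(1010, 1150, by = 10))
  data.frame(lo = lo, hi = hi)
}

# One sample/replicate profile: peaks (size, intensity) -> named vector of
# renormalized relative intensities keyed by "lo" of the bin.
oracle_process_profile <- function(size, intensity, min_rfu = 10, min_rel = 0.001) {
  bins <- oracle_bins()
  lo <- bins$lo; hi <- bins$hi
  sums <- numeric(nrow(bins))
  for (i in seq_along(size)) {
    if (intensity[i] <= min_rfu) next
    if (size[i] < 200 || size[i] > 1150) next
    hit <- which(lo <= size[i] & (size[i] < hi | (size[i] == 1150 & hi == 1150)))
    stopifnot(length(hit) == 1)
    sums[hit] <- sums[hit] + intensity[i]
  }
  total <- sum(sums)
  rel <- sums / total
  keep <- rel >= min_rel
  out <- rel[keep] / sum(rel[keep])
  names(out) <- bins$lo[keep]
  out
}

# random single-profile peak table
random_peaks <- function(n, sample_id = "S1", replicate_id = "rep1") {
  data.frame(sample_id = sample_id, replicate_id = replicate_id,
             size_bp = runif(n, 150, 1250),
             intensity_rfu = rexp(n, 1 / 50),
             stringsAsFactors = FALSE)
}

# package pipeline on one profile, as a named rel-intensity vector keyed by
# the bin's lower bound (parsed from the package's labels)
package_process_profile <- function(df, params = filter_params()) {
  pt <- peak_table(df)
  prof <- relative_intensity_filter(
    assign_bins(clip_to_window(filter_min_rfu(pt, params)), binning_scheme()),
    params)
  lo <- as.numeric(sub("bp0*([0-9]+)_.*", "\\1", prof$bin))
  stats::setNames(prof$rel_intensity, lo)[order(lo)]
}

# --- ANOSIM oracle ---------------------------------------------------------

# literal double-loop ANOSIM R
oracle_anosim_r <- function(D, grouping) {
  n <- nrow(D)
  d <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, D[i, j])
    within <- c(within, grouping[i] == grouping[j])
  }
  r <- rank(d)
  (mean(r[!within]) - mean(r[within])) / (length(d) / 2)
}

# exhaustive permutation p by explicit recursion over distinct labelings
oracle_all_labelings <- function(labels) {
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (tail in oracle_all_labelings(rest)) out[[length(out) + 1]] <- c(u, tail)
  }
  out
}

oracle_anosim_p <- function(D, grouping) {
  r_obs <- oracle_anosim_r(D, grouping)
  labs <- oracle_all_labelings(sort(grouping))
  r_all <- vapply(labs, function(g) oracle_anosim_r(D, g), numeric(1))
  sum(r_all >= r_obs - 1e-12) / length(labs)
}

# --- permutations (for the Mantel exhaustive check) ------------------------

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# --- Procrustes oracle -----------------------------------------------------

# minimize 1 - max_Q tr(X' Y Q) over 3-D rotations (Euler angles) and the
# reflection branch, after the same centering and unit-norm scaling
oracle_m2_3d <- function(X, Y) {
  prep <- function(m) {
    m <- scale(m, center = TRUE, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  X <- prep(X); Y <- prep(Y)
  rotmat <- function(a) {
    Rz <- rbind(c(cos(a[1]), -sin(a[1]), 0), c(sin(a[1]), cos(a[1]), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[3]), -sin(a[3])), c(0, sin(a[3]), cos(a[3])))
    Rz %*% Ry %*% Rx
  }
  best <- -Inf
  for (refl in c(1, -1)) {
    Yr <- Y %*% diag(c(1, 1, refl))
    obj <- function(a) -sum(diag(crossprod(X, Yr %*% rotmat(a))))
    for (start in list(c(0, 0, 0), c(1, 1, 1), c(2, -1, 0.5), c(-2, 0.3, -1))) {
      fit <- stats::optim(start, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      best <- max(best, -fit$value)
    }
  }
  1 - best^2
}

# --- misc ------------------------------------------------------------------

# a tiny OTU table fixture
toy_table <- function(kind = "read_count") {
  m <- rbind(S1 = c(5, 3, 0, 7), S2 = c(0, 2, 1, 4), S3 = c(1, 1, 1, 1))
  colnames(m) <- paste0("otu", 1:4)
  otu_table(m, kind)
}

random_dist_matrix <- function(n, labels = sprintf("S%02d", seq_len(n))) {
  p <- matrix(runif(n * 6), n)
  p <- p / rowSums(p)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - sum(pmin(p[i, ], p[j, ]))
  }
  dist_matrix(d)
}
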
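test_that("observed richness counts positive-abundance OTUs per sample and group", {
  m <- rbind(S1 = c(0, 3, 0, 7), S2 = c(0, 2, 1, 0))
  colnames(m) <- c("A", "B", "C", "D")
  tab <- otu_table(m, "read_count")
  meta <- sample_metadata(c("S1", "S2"), c("g1", "g1"))
  res <- observed_otus(tab, meta)
  expect_equal(unname(res$per_sample), c(2, 2))
  # supports {B,D} and {B,C} -> group total 3
  expect_equal(unname(res$per_group), 3)

  # brute-force support enumeration on a random binary table
  set.seed(21)
  b <- matrix(rbinom(60, 1, 0.4), 6, dimnames = list(paste0("S", 1:6), paste0("o", 1:10)))
  bt <- otu_table(b, "read_count")
  want <- vapply(1:6, function(i) sum(b[i, ] > 0), integer(1))
  expect_equal(unname(observed_otus(bt)$per_sample), want)
})

test_that("Shannon H' matches closed forms and errors on all-zero samples", {
  u <- matrix(rep(1, 10), 1, dimnames = list("S1", paste0("o", 1:10)))
  expect_equal(unname(shannon(otu_table(u, "read_count"))), log(10), tolerance = 1e-12)

  single <- matrix(c(42, 0), 1, dimnames = list("S1", c("a", "b")))
  expect_equal(unname(shannon(otu_table(single, "read_count"))), 0)

  # counts (2,1,1): H = -(1/2 ln 1/2 + 2 * 1/4 ln 1/4) = 1.0397208
  tri <- matrix(c(2, 1, 1), 1, dimnames = list("S1", c("a", "b", "c")))
  expect_equal(unname(shannon(otu_table(tri, "read_count"))), 1.039721,
               tolerance = 1e-6)

  zero <- matrix(c(0, 0), 1, dimnames = list("S1", c("a", "b")))
  expect_error(shannon(otu_table(zero, "read_count")),
               class = "arisacomp_undefined_value_error")
})

test_that("Shannon is maximal at the uniform distribution for fixed richness", {
  set.seed(8)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    x <- rexp(k) + 1e-6
    m <- rbind(uneven = x, even = rep(1, k))
    colnames(m) <- paste0("o", seq_len(k))
    h <- shannon(otu_table(m, "read_count"))
    expect_lte(h[["uneven"]], h[["even"]] + 1e-12)
  }
})

test_that("Bray-Curtis matches hand values and halves the L1 distance on proportions", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3))$dissimilarity, 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0))$dissimilarity, 1)
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 1, 1))$dissimilarity, 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "arisacomp_undefined_value_error")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), class = "arisacomp_validation_error")

  set.seed(13)
  for (i in 1:200) {
    k <- sample(2:40, 1)
    x <- rexp(k); x <- x / sum(x)
    y <- rexp(k); y <- y / sum(y)
    expect_equal(bray_curtis(x, y)$dissimilarity, sum(abs(x - y)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("distance_matrix is symmetric, zero-diagonal and matches pairwise values", {
  m <- rbind(S1 = c(4, 0, 2), S2 = c(4, 0, 2), S3 = c(0, 5, 1))
  colnames(m) <- c("a", "b", "c")
  tab <- otu_table(m, "read_count")
  D <- distance_matrix(tab)
  expect_equal(unclass(D)["S1", "S2"], 0, tolerance = 1e-12)
  # hand: proportions p1 = (2/3, 0, 1/3), p3 = (0, 5/6, 1/6)
  expect_equal(unclass(D)["S1", "S3"], 1 - 2 * (1 / 6) / 2, tolerance = 1e-12)
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(diag(unclass(D)) == 0))

  # counts are converted to proportions: scaling a row must not matter
  m2 <- m; m2[3, ] <- m2[3, ] * 10
  D2 <- distance_matrix(otu_table(m2, "read_count"))
  expect_equal(unclass(D2), unclass(D), tolerance = 1e-12, ignore_attr = TRUE)

  # agreement with the vector-level primitive on random tables
  set.seed(31)
  r <- matrix(rpois(8 * 12, 6), 8, dimnames = list(paste0("S", 1:8), paste0("o", 1:12)))
  Dr <- distance_matrix(otu_table(r, "read_count"))
  p <- r / rowSums(r)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(unclass(Dr)[i, j], bray_curtis(p[i, ], p[j, ])$dissimilarity,
                 tolerance = 1e-12)
  }
})

test_that("within-group similarity summarizes pairs and handles degenerate groups", {
  set.seed(17)
  D <- random_dist_matrix(7)
  meta <- sample_metadata(rownames(D), c("g1", "g1", "g1", "g2", "g2", "g3", "g3"))
  w <- testthat::capture_warnings(res <- within_group_similarity(D, meta))
  expect_equal(res$n_pairs, c(3, 1, 1))
  # brute-force pair enumeration for g1
  sims <- c(1 - unclass(D)[1, 2], 1 - unclass(D)[1, 3], 1 - unclass(D)[2, 3])
  expect_equal(res$mean_similarity[1], mean(sims), tolerance = 1e-12)
  expect_equal(res$sd_similarity[1], sd(sims), tolerance = 1e-12)
  # a single pair gets SD 0 with a warning
  expect_true(any(grepl("single pair", w)))
  expect_equal(res$sd_similarity[2], 0)

  # all-identical samples: similarity 1, SD 0
  ident <- dist_matrix(matrix(0, 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3))))
  m2 <- sample_metadata(paste0("S", 1:3), rep("g", 3))
  r2 <- within_group_similarity(ident, m2)
  expect_equal(r2$mean_similarity, 1)
  expect_equal(r2$sd_similarity, 0)

  # singleton group is skipped with a warning
  meta3 <- sample_metadata(rownames(D), c("g1", "g1", "g1", "g1", "g1", "g1", "lone"))
  expect_warning(r3 <- within_group_similarity(D, meta3), "one sample")
  expect_equal(r3$group, "g1")
})

test_that("similarity-vector correlation: identities, affine invariance, Mantel enumeration", {
  set.seed(23)
  D1 <- random_dist_matrix(5)
  expect_equal(correlate_similarity_vectors(D1, D1)$pearson_r, 1, tolerance = 1e-12)

  # positive affine transform of the similarities leaves r = 1
  s <- 1 - unclass(D1)
  d2 <- 1 - (0.1 + 0.5 * s); diag(d2) <- 0
  D2 <- dist_matrix(d2)
  res <- correlate_similarity_vectors(D1, D2)
  expect_equal(res$pearson_r, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, res$pearson_r^2, tolerance = 1e-12)

  # exhaustive Mantel p at n = 5 equals enumeration over all 120 permutations
  D3 <- random_dist_matrix(5, labels = rownames(D1))
  res3 <- correlate_similarity_vectors(D1, D3, n_perm = 999)
  expect_true(res3$exhaustive)
  ut <- upper.tri(unclass(D1))
  s1 <- 1 - unclass(D1)[ut]
  m3 <- unclass(D3)
  rs <- vapply(oracle_perms(5), function(p) {
    cor(s1, 1 - m3[p, p][ut])
  }, numeric(1))
  expect_equal(res3$p_mantel, mean(rs >= res3$pearson_r - 1e-12), tolerance = 1e-12)

  bad <- random_dist_matrix(5, labels = paste0("X", 1:5))
  expect_error(correlate_similarity_vectors(D1, bad), class = "arisacomp_join_error")
})

test_that("Welch t-test matches its closed form and Bonferroni caps at 1", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- welch_t_test(a, b)
  # closed form: t = (mean a - mean b) / sqrt(va/na + vb/nb)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$df, df, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(res$t), df, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(res$p, 0.01)

  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.4, 6), 1)
  p <- runif(20)
  expect_true(all(bonferroni(p, 3) >= p))
  expect_true(all(bonferroni(p, 3) <= 1))
})
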
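test_that("z-score normalisation centres and scales columns", {
  expect_equal(unname(zscore_normalize(cbind(a = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  z <- zscore_normalize(cbind(x = c(10, 20, 40, 50)))
  expect_equal(unname(z[, 1]), (c(10, 20, 40, 50) - 30) / 18.2574,
               tolerance = 1e-4)
  expect_equal(unname(zscore_normalize(z)), unname(z), tolerance = 1e-12)
  expect_warning(zc <- zscore_normalize(cbind(a = 1:4, b = rep(2, 4))),
                 "constant")
  expect_equal(colnames(zc), "a")
  expect_error(zscore_normalize(cbind(a = rep(1, 4))), "constant")
})

test_that("parameter screening flags group-linked parameters only", {
  cfg <- default_sim_config(seed = 31)
  co <- simulate_cohort(cfg)
  co$flat <- 7  # identical in every sample: never selected
  sc <- screen_parameters(co)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  expect_equal(sc$p_value[sc$parameter == "flat"], 1)
  expect_false(sc$significant[sc$parameter == "flat"])
  # strongly BMI-linked parameters are picked up
  expect_true(sc$significant[sc$parameter == "insulin"])
  # BMI itself separates the BMI-defined groups overwhelmingly
  sca <- screen_parameters(co, include_anthropometric = TRUE)
  expect_lt(sca$p_value[sca$parameter == "bmi"], 0.001)
  co$sparse <- ifelse(seq_len(nrow(co)) <= 40, co$glucose, NA)
  expect_warning(screen_parameters(co), "sparse")
  expect_error(screen_parameters(co[1:2, ]), "two groups")
})

test_that("null clinical parameters are selected at about the nominal rate", {
  hits <- vapply(1:200, function(s) {
    co <- simulate_cohort(default_sim_config(seed = s))
    sc <- screen_parameters(co)
    sc$significant[sc$parameter == "sodium"]   # planted slope 0
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("jaccard distance matches worked values and the metric axioms", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 3)
  expect_equal(jaccard_distance(c(0, 0), c(0, 0)), 0)  # empty-profile convention
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "length")
  set.seed(5)
  for (r in 1:200) {
    x <- rbinom(12, 1, 0.4); y <- rbinom(12, 1, 0.4); z <- rbinom(12, 1, 0.4)
    dxy <- jaccard_distance(x, y)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(dxy, jaccard_distance(y, x))
    if (!all(x == y)) expect_gt(dxy, 0) else expect_equal(dxy, 0)
    expect_lte(dxy, jaccard_distance(x, z) + jaccard_distance(z, y) + 1e-12)
  }
})

test_that("pairwise jaccard matrix agrees with the base binary distance", {
  set.seed(6)
  m <- matrix(rbinom(10 * 15, 1, 0.5), 10, 15)
  m[1, ] <- 1  # no all-zero rows for the cross-check
  expect_equal(as.numeric(jaccard_dist_matrix(m)),
               as.numeric(dist(m, method = "binary")), tolerance = 1e-12)
  m0 <- rbind(a = rep(0L, 4), b = rep(0L, 4), c = c(1L, 0L, 0L, 0L))
  dm <- as.matrix(jaccard_dist_matrix(m0))
  expect_equal(dm["a", "b"], 0)  # two empty profiles coincide
  expect_equal(dm["a", "c"], 1)
})

test_that("ward linkage reproduces forced merges and the naive oracle", {
  d2 <- dist(c(0, 3))
  h <- ward_linkage(d2)
  expect_equal(h$height, 3)
  h4 <- ward_linkage(dist(c(0, 1, 4, 5)))
  p2 <- cut_tree(h4, 2)
  expect_equal(unname(p2), c(1, 1, 2, 2))
  expect_error(ward_linkage(dist(numeric(1))), "two")
  set.seed(8)
  for (r in 1:25) {
    n <- sample(4:8, 1)
    d <- dist(matrix(rnorm(n * 3), n))
    o <- naive_ward_oracle(d)
    h <- ward_linkage(d)
    expect_equal(sort(h$height), sort(o$heights), tolerance = 1e-9)
    expect_true(all(diff(h$height) >= -1e-9))  # Ward heights monotone
    for (step in seq_len(n - 1))
      expect_equal(adjusted_rand_index(o$partitions[[step]],
                                       unname(cutree(h, n - step))), 1)
  }
})

test_that("cutting a tree spans singletons to one cluster", {
  h <- ward_linkage(dist(c(0, 1, 4, 5)))
  expect_equal(unname(cut_tree(h, 1)), rep(1, 4))
  expect_equal(sort(unname(cut_tree(h, 4))), 1:4)
  expect_error(cut_tree(h, 0), "between")
  expect_error(cut_tree(h, 5), "between")
})

test_that("adjusted Rand index reproduces worked contingency examples", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # degenerate 0/0 cases are defined as perfect agreement
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
  expect_error(adjusted_rand_index(c(a = 1, b = 2), c(a = 1, c = 2)),
               "different ids")
})

test_that("ARI is relabel-invariant, near zero under shuffling, and matches mclust", {
  set.seed(9)
  p <- sample(1:3, 40, replace = TRUE)
  q <- sample(1:4, 40, replace = TRUE)
  relab <- c(3, 1, 2)[p]
  expect_equal(adjusted_rand_index(p, q), adjusted_rand_index(relab, q))
  shuffled <- vapply(1:1000, function(i)
    adjusted_rand_index(p, sample(q)), numeric(1))
  expect_lt(abs(mean(shuffled)), 0.01)
  skip_if_not_installed("mclust")
  for (r in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("cluster-vs-complement BMI comparison matches exact rank enumeration", {
  co <- data.frame(sample_id = c("a", "b", "c", "d"),
                   bmi = c(40, 42, 20, 22))
  part <- setNames(c(1, 1, 2, 2), co$sample_id)
  r <- compare_cluster_bmi(part, co, 1)
  expect_equal(r$mean_in, 41)
  expect_equal(r$mean_out, 21)
  expect_equal(r$p_value, 2 / choose(4, 2))  # smallest attainable two-sided p
  swapped <- compare_cluster_bmi(part, co, 2)
  expect_equal(swapped$p_value, r$p_value)
  expect_equal(swapped$mean_in, r$mean_out)
  expect_error(compare_cluster_bmi(setNames(c(1, 1, 1, 1), co$sample_id), co, 1),
               "nonempty")
})

test_that("the BMI comparison holds its size under the null", {
  set.seed(10)
  rejections <- vapply(1:200, function(r) {
    co <- data.frame(sample_id = sprintf("s%d", 1:40), bmi = rnorm(40, 30, 5))
    part <- setNames(rep(2, 40), co$sample_id)
    part[sample(40, 20)] <- 1
    compare_cluster_bmi(part, co, 1)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("discriminative patterns rank perfect separators first and nest in alpha", {
  set.seed(11)
  m <- matrix(rbinom(20 * 10, 1, 0.5), 20, 10,
              dimnames = list(sprintf("s%d", 1:20), sprintf("P%05d", 1:10)))
  m[, 1] <- rep(c(1L, 0L), each = 10)   # present in all of cluster 1, none of 2
  m[, 2] <- rep(c(1L, 0L), 10)          # identical prevalence both sides
  storage.mode(m) <- "integer"
  part <- setNames(rep(c(1, 2), each = 10), rownames(m))
  pat <- extract_discriminative_pattern(m, part, 1)
  expect_equal(pat$table$protein[1], "P00001")
  expect_true("P00001" %in% pat$pattern)
  expect_false("P00002" %in% pat$pattern)
  expect_length(extract_discriminative_pattern(m, part, 1, alpha = 0)$pattern, 0)
  alphas <- c(0.01, 0.05, 0.2, 1)
  pats <- lapply(alphas, function(a)
    extract_discriminative_pattern(m, part, 1, alpha = a)$pattern)
  for (i in seq_len(length(pats) - 1))
    expect_true(all(pats[[i]] %in% pats[[i + 1]]))
  expect_true(all(pat$table$p_adj >= pat$table$p_value))
})

test_that("planted informative proteins are recovered from the sample dendrogram", {
  cfg <- default_sim_config(seed = 3, informative_slope = 3)
  recovered <- vapply(1:100, function(s) {
    cfg$seed <- s
    co <- simulate_cohort(cfg)
    pr <- simulate_proteome(co, cfg)
    f <- filter_proteins(pr$matrix)
    part <- cut_tree(ward_linkage(jaccard_dist_matrix(f)), 2)
    hi <- high_bmi_cluster(part, co)
    pat <- extract_discriminative_pattern(f, part, hi)
    sum(pr$truth %in% pat$pattern)
  }, numeric(1))
  expect_gte(mean(recovered >= 10), 0.8)
})

test_that("principal components behave on collinear, isotropic and rotated data", {
  x <- cbind(a = 1:20, b = 2 * (1:20) + 3)
  p <- pca_scores(x, 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  set.seed(12)
  g <- matrix(rnorm(2e4), ncol = 2)
  pg <- pca_scores(g, 2)
  expect_equal(pg$explained, c(0.5, 0.5), tolerance = 0.03)
  expect_true(all(diff(pg$explained) <= 0))
  x4 <- matrix(rnorm(200), 50, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  s1 <- pca_scores(x4, 4, normalize = FALSE)$explained
  s2 <- pca_scores(x4 %*% q, 4, normalize = FALSE)$explained
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_warning(pca_scores(cbind(a = 1:5 + rnorm(5), b = 1:5), 3), "rank|trunc")
})
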
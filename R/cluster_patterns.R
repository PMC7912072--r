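# Hierarchical clustering of clinical and proteomic profiles, partition
# agreement (ARI), cluster-vs-BMI testing and discriminative patterns.

#' Column z-score normalisation
#'
#' Centres each column to mean 0 and scales to unit sample sd (n-1
#' denominator). Constant columns are dropped with a warning; an
#' all-constant matrix is an error.
#'
#' @param x numeric matrix.
#' @return normalised matrix (possibly fewer columns).
#' @export
zscore_normalize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (all(constant)) stop("all columns are constant; nothing to normalise")
  if (any(constant))
    warning("dropping constant column(s): ",
            paste(colnames(x)[constant], collapse = ", "))
  x <- x[, !constant, drop = FALSE]
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Screen clinical parameters for between-group differences
#'
#' Tests each clinical parameter (optionally plus the anthropometric
#' columns age/height/weight/bmi) for differences across the cohort's
#' BMI groups, Kruskal-Wallis by default (one-way ANOVA as alternative).
#' Parameters missing in more than half the samples are excluded with a
#' warning.
#'
#' @param cohort cohort data frame with at least 2 groups of >= 2 samples.
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.05).
#' @param test "kruskal" (default) or "anova".
#' @param include_anthropometric also screen age, height, weight, bmi.
#' @return data frame: parameter, statistic, p_value, significant.
#' @export
screen_parameters <- function(cohort, alpha = 0.05,
                              test = c("kruskal", "anova"),
                              include_anthropometric = FALSE) {
  test <- match.arg(test)
  grp <- droplevels(cohort$group)
  if (nlevels(grp) < 2 || sum(table(grp) >= 2) < 2)
    stop("need at least two groups with at least two samples each")
  params <- clinical_parameters(cohort)
  if (include_anthropometric)
    params <- c("age", "height", "weight", "bmi", params)
  res <- lapply(params, function(p) {
    v <- cohort[[p]]
    if (mean(is.na(v)) > 0.5) {
      warning("parameter '", p, "' missing in >50% of samples; excluded")
      return(NULL)
    }
    ok <- !is.na(v)
    if (sd(v[ok]) == 0)   # identical everywhere: no evidence of a difference
      return(data.frame(parameter = p, statistic = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    if (test == "kruskal") {
      ht <- kruskal.test(v[ok], grp[ok])
      data.frame(parameter = p, statistic = unname(ht$statistic),
                 p_value = ht$p.value, stringsAsFactors = FALSE)
    } else {
      ft <- anova(aov(v[ok] ~ grp[ok]))
      data.frame(parameter = p, statistic = ft$`F value`[1],
                 p_value = ft$`Pr(>F)`[1], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(parameter = character(), statistic = numeric(),
                      p_value = numeric())
  out$significant <- out$p_value < alpha
  out
}

#' Jaccard distance between binary vectors
#'
#' `1 - |x AND y| / |x OR y|`; two all-zero vectors are at distance 0 by
#' convention (identical empty profiles).
#'
#' @param x,y binary vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  u <- sum(x | y)
  if (u == 0) return(0)
  1 - sum(x & y) / u
}

#' Pairwise Jaccard distances between matrix rows
#'
#' @param m binary matrix (rows are profiles).
#' @return a `dist` object.
#' @export
jaccard_dist_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  as.dist(d)
}

#' Ward agglomerative clustering
#'
#' Agglomeration with the Ward criterion via the Lance-Williams
#' recurrence applied to squared input distances, with merge heights
#' reported back on the distance scale (the "D2" dialect; the unsquared
#' "D" update is selectable). Tie-breaking is deterministic.
#'
#' @param d a `dist` object or square distance matrix, n >= 2.
#' @param dialect "D2" (default) or "D".
#' @return an `hclust` merge tree.
#' @export
ward_linkage <- function(d, dialect = c("D2", "D")) {
  dialect <- match.arg(dialect)
  if (!inherits(d, "dist")) d <- as.dist(d)
  if (attr(d, "Size") < 2) stop("need at least two observations")
  hclust(d, method = if (dialect == "D2") "ward.D2" else "ward.D")
}

#' Cut a merge tree into k flat clusters
#'
#' Removes the k-1 highest merges and labels the connected components.
#'
#' @param dend an `hclust` tree.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return named integer vector of cluster labels in `1..k`.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  cutree(dend, k = k)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions, about 0 for independent ones. Computed
#' from the contingency table; the degenerate 0/0 case (both partitions
#' single-class or both all-singleton) is defined as 1.
#'
#' @param p,q partitions as vectors of cluster labels; if both are
#'   named, items are matched by name, otherwise by position.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) stop("partitions cover different ids")
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("partitions cover different numbers of items")
  }
  n <- length(p)
  tab <- table(p, q)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Compare BMI inside a cluster against its complement
#'
#' Two-sided Mann-Whitney U test (Welch t-test as alternative) of BMI,
#' cluster vs all remaining samples; group means reported for both sides.
#'
#' @param part named partition vector (sample id -> cluster label).
#' @param cohort cohort data frame.
#' @param cluster_id which cluster to test.
#' @param test "wilcox" (default) or "t".
#' @return list: mean_in, mean_out, p_value, n_in, n_out.
#' @export
compare_cluster_bmi <- function(part, cohort, cluster_id,
                                test = c("wilcox", "t")) {
  test <- match.arg(test)
  ids_in <- names(part)[part == cluster_id]
  ids_out <- names(part)[part != cluster_id]
  if (!length(ids_in) || !length(ids_out))
    stop("cluster must be nonempty and not the whole sample set")
  bmi <- setNames(cohort$bmi, cohort$sample_id)
  x <- bmi[ids_in]
  y <- bmi[ids_out]
  ht <- if (test == "wilcox") {
    suppressWarnings(wilcox.test(x, y, exact = TRUE))
  } else {
    t.test(x, y)
  }
  list(mean_in = mean(x), mean_out = mean(y), p_value = ht$p.value,
       n_in = length(x), n_out = length(y))
}

#' Identify the high-BMI cluster of a partition
#'
#' @param part named partition vector.
#' @param cohort cohort data frame.
#' @return label of the cluster with the largest mean BMI.
#' @export
high_bmi_cluster <- function(part, cohort) {
  bmi <- setNames(cohort$bmi, cohort$sample_id)[names(part)]
  means <- tapply(bmi, part, mean)
  names(means)[which.max(means)]
}

#' Extract a discriminative protein pattern for a cluster
#'
#' Per protein, a two-sided Fisher exact test on the 2x2 table of
#' presence by cluster membership, with Benjamini-Hochberg adjustment
#' across proteins. The pattern is the set of proteins with adjusted
#' p <= alpha, ranked by absolute prevalence difference. When a cohort
#' is supplied, the cluster-vs-complement BMI comparison is attached.
#'
#' @param m (filtered) presence matrix.
#' @param part named partition vector over the rows of `m`.
#' @param cluster_id cluster whose pattern is sought.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param cohort optional cohort for the BMI comparison.
#' @return list: `table` (per-protein prevalences, p, p_adj, in pattern
#'   order first), `pattern` (protein ids), and optionally `bmi`
#'   (output of [compare_cluster_bmi()]).
#' @export
extract_discriminative_pattern <- function(m, part, cluster_id, alpha = 0.05,
                                           cohort = NULL) {
  validate_presence_matrix(m)
  part <- part[rownames(m)]
  inside <- part == cluster_id
  if (!any(inside) || all(inside))
    stop("cluster must be nonempty and not the whole sample set")
  if (ncol(m) == 0) {
    tab <- data.frame(protein = character(), prev_in = numeric(),
                      prev_out = numeric(), p_value = numeric(),
                      p_adj = numeric())
  } else {
    n_in <- sum(inside)
    n_out <- sum(!inside)
    pres_in <- colSums(m[inside, , drop = FALSE])
    pres_out <- colSums(m[!inside, , drop = FALSE])
    pv <- vapply(seq_len(ncol(m)), function(j) {
      fisher.test(matrix(c(pres_in[j], n_in - pres_in[j],
                           pres_out[j], n_out - pres_out[j]), 2))$p.value
    }, numeric(1))
    tab <- data.frame(protein = colnames(m),
                      prev_in = pres_in / n_in,
                      prev_out = pres_out / n_out,
                      p_value = pv,
                      p_adj = p.adjust(pv, "BH"),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-abs(tab$prev_in - tab$prev_out), tab$p_adj,
                     tab$protein), ]
    rownames(tab) <- NULL
  }
  in_pattern <- tab$p_adj <= alpha
  out <- list(table = tab, pattern = tab$protein[in_pattern],
              cluster_id = cluster_id)
  if (!is.null(cohort))
    out$bmi <- compare_cluster_bmi(part, cohort, cluster_id)
  out
}

#' Principal component scores of a normalised matrix
#'
#' The input is z-scored columnwise first; scores are projections onto
#' the top right-singular directions.
#'
#' @param x numeric matrix, at least 2 rows and columns.
#' @param n_components number of components (truncated to the rank with
#'   a warning if too large).
#' @param normalize z-score the columns first (default TRUE); with
#'   FALSE the columns are only centred, which preserves the
#'   explained-variance spectrum under orthogonal rotations.
#' @return list: `scores` (n x k) and `explained` (variance fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_scores <- function(x, n_components = 2, normalize = TRUE) {
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least a 2x2 matrix")
  z <- if (normalize) zscore_normalize(x) else
    scale(as.matrix(x), center = TRUE, scale = FALSE)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components)
    warning("n_components exceeds rank; truncated to ", k)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)])
}
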
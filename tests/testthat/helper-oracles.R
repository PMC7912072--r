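# Independent oracles and small fixture builders shared by the tests.

# Naive O(n^3) Ward agglomeration via the Lance-Williams recurrence on
# squared distances ("D2": heights reported back on the distance scale;
# "D": recurrence on raw distances). Ties broken by lowest pair index.
# Returns merge heights and the flat partition after each merge.
naive_ward_oracle <- function(d, dialect = c("D2", "D")) {
  dialect <- match.arg(dialect)
  D <- as.matrix(d)
  if (dialect == "D2") D <- D^2
  n <- nrow(D)
  sizes <- rep(1, n)
  labels <- seq_len(n)        # current cluster id of each original point
  alive <- rep(TRUE, n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(alive)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      v <- D[idx[a], idx[b]]
      if (v < best) { best <- v; bi <- idx[a]; bj <- idx[b] }
    }
    heights[step] <- if (dialect == "D2") sqrt(best) else best
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      upd <- ((ni + nk) * D[bi, k] + (nj + nk) * D[bj, k] - nk * best) /
        (ni + nj + nk)
      D[bi, k] <- D[k, bi] <- upd
    }
    sizes[bi] <- ni + nj
    alive[bj] <- FALSE
    labels[labels == bj] <- bi
    partitions[[step]] <- match(labels, sort(unique(labels)))
  }
  list(heights = heights, partitions = partitions)
}

# Brute-force catalog counts straight from an identification map.
brute_catalog_counts <- function(idmap, groups) {
  all_prot <- sort(unique(unlist(idmap)))
  list(
    n_total = length(all_prot),
    n_core = sum(vapply(all_prot, function(p)
      all(vapply(idmap, function(s) p %in% s, logical(1))), logical(1))),
    per_group = vapply(split(names(idmap), groups), function(ids)
      length(unique(unlist(idmap[ids]))), integer(1))
  )
}

# Tiny deterministic cohort for io/clustering tests.
toy_cohort <- function(n = 8, seed = 42) {
  set.seed(seed)
  bmi <- seq(20, 45, length.out = n)
  height <- rnorm(n, 172, 7)
  data.frame(
    sample_id = sprintf("T%02d", seq_len(n)),
    group = assign_group(bmi),
    sex = rep_len(c("f", "m"), n),
    age = rnorm(n, 32, 6),
    height = height,
    weight = bmi * (height / 100)^2,
    bmi = bmi,
    glucose = rnorm(n, 5, 0.5),
    stringsAsFactors = FALSE
  )
}
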
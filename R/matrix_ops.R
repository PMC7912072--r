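# Catalog filtering and descriptive summaries of the protein matrix.

#' Drop unrepresentative and non-specific proteins
#'
#' Removes columns identified in at most one sample (singletons, and
#' zero-occurrence columns of externally supplied matrices) and columns
#' identified in every sample (non-specific, carrying no contrast).
#' Rows are untouched; surviving columns keep their order. The operation
#' is idempotent.
#'
#' @param m presence matrix.
#' @return filtered presence matrix (possibly zero columns).
#' @export
filter_proteins <- function(m) {
  validate_presence_matrix(m)
  if (ncol(m) == 0) return(m)
  counts <- colSums(m)
  keep <- counts > 1 & counts < nrow(m)
  m[, keep, drop = FALSE]
}

#' Summarise a protein catalog
#'
#' @param m presence matrix (pre-filter; summaries describe the catalog
#'   as identified).
#' @param cohort cohort data frame covering every sample of `m`.
#' @param merge_groups optional named list of group-label vectors, e.g.
#'   `list(OBESE = c("OW","OB1","OB2","OB3"))`, adding merged unions.
#' @return list with `n_total` (distinct proteins), `n_core` (present in
#'   every sample), `per_group_union` (named count of proteins seen in at
#'   least one sample of each group, plus merged groups), and
#'   `n_after_filter` (columns surviving [filter_proteins()]).
#' @export
summarize_catalog <- function(m, cohort, merge_groups = NULL) {
  validate_presence_matrix(m)
  missing_samples <- setdiff(rownames(m), cohort$sample_id)
  if (length(missing_samples))
    stop("sample(s) in matrix but not in cohort: ",
         paste(missing_samples, collapse = ", "))
  grp <- cohort$group[match(rownames(m), cohort$sample_id)]
  union_count <- function(rows) {
    if (!length(rows)) return(0L)
    sum(colSums(m[rows, , drop = FALSE]) > 0)
  }
  groups_present <- intersect(GROUP_LEVELS, as.character(unique(grp)))
  per_group <- vapply(groups_present,
                      function(g) union_count(which(grp == g)), integer(1))
  for (nm in names(merge_groups))
    per_group[[nm]] <- union_count(which(as.character(grp) %in% merge_groups[[nm]]))
  list(
    n_total = ncol(m),
    n_core = if (nrow(m)) sum(colSums(m) == nrow(m)) else 0L,
    per_group_union = per_group,
    n_after_filter = ncol(filter_proteins(m))
  )
}

#' Remove sample groups and re-filter the matrix
#'
#' Drops all samples belonging to `exclude_groups` from both the matrix
#' and the cohort. Because occurrence counts change after subsetting,
#' the singleton/ubiquitous filter is re-applied by default.
#'
#' @param m presence matrix.
#' @param cohort cohort data frame.
#' @param exclude_groups character vector of group labels to remove.
#' @param refilter re-apply [filter_proteins()] after subsetting
#'   (default TRUE).
#' @return list with `matrix` and `cohort`.
#' @export
subset_samples <- function(m, cohort, exclude_groups = character(0),
                           refilter = TRUE) {
  validate_presence_matrix(m)
  bad <- setdiff(exclude_groups, GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  keep_cohort <- cohort[!(as.character(cohort$group) %in% exclude_groups), ,
                        drop = FALSE]
  keep_rows <- intersect(rownames(m), keep_cohort$sample_id)
  m2 <- m[keep_rows, , drop = FALSE]
  if (nrow(m2) == 0) warning("no samples remain after group exclusion")
  if (refilter) m2 <- filter_proteins(m2)
  list(matrix = m2, cohort = keep_cohort)
}
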
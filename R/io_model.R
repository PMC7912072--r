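#' @rdname assign_group
#' @export
GROUP_LEVELS <- c("NORM", "OW", "OB1", "OB2", "OB3")

# Core (non-clinical) cohort columns; everything else is a clinical parameter.
COHORT_CORE_COLUMNS <- c("sample_id", "group", "sex", "age", "height",
                         "weight", "bmi")

#' Compute body mass index
#'
#' BMI is weight in kilograms divided by squared height in metres.
#'
#' @param weight numeric vector, kg. Must be positive.
#' @param height numeric vector, cm. Must be positive.
#' @return numeric vector of BMI values in kg/m^2.
#' @examples
#' compute_bmi(100, 200)  # 25
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)))
    stop("weight and height must be finite")
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(height <= 0)) stop("height must be positive")
  weight / (height / 100)^2
}

#' Assign a WHO-style BMI group
#'
#' Maps BMI to one of the study groups using half-open intervals:
#' NORM \eqn{[18.5, 25)}, OW \eqn{[25, 30)}, OB1 \eqn{[30, 35)},
#' OB2 \eqn{[35, 40)}, OB3 \eqn{[40, \infty)}. Values below the study
#' inclusion floor of 18.5 are returned as `NA` with a warning rather
#' than silently grouped.
#'
#' @param bmi numeric vector, kg/m^2.
#' @return factor with levels `GROUP_LEVELS`; `NA` for out-of-inclusion BMI.
#' @export
assign_group <- function(bmi) {
  if (any(!is.finite(bmi))) stop("bmi must be finite")
  below <- bmi < 18.5
  if (any(below))
    warning(sprintf("%d BMI value(s) below the 18.5 inclusion floor set to NA: %s",
                    sum(below), paste(format(bmi[below]), collapse = ", ")))
  g <- cut(bmi, breaks = c(18.5, 25, 30, 35, 40, Inf),
           labels = GROUP_LEVELS, right = FALSE)
  factor(as.character(g), levels = GROUP_LEVELS)
}

#' Names of the clinical parameter columns of a cohort table
#'
#' @param cohort a cohort data frame.
#' @return character vector (possibly empty) of clinical column names.
#' @export
clinical_parameters <- function(cohort) {
  setdiff(colnames(cohort), COHORT_CORE_COLUMNS)
}

#' Validate a cohort table
#'
#' Checks id uniqueness, positivity of height/weight, BMI consistency
#' (within 0.5 kg/m^2 of weight/(height/100)^2) and group/BMI agreement.
#'
#' @param cohort a data frame with columns `sample_id`, `group`, `sex`,
#'   `age`, `height`, `weight`, `bmi` plus clinical parameter columns.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "sex", "age", "height", "weight", "bmi", "group")
  miss <- setdiff(need, colnames(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  dup <- cohort$sample_id[duplicated(cohort$sample_id)]
  if (length(dup))
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  if (nrow(cohort)) {
    if (any(cohort$height <= 0)) stop("non-positive height in cohort")
    if (any(cohort$weight <= 0)) stop("non-positive weight in cohort")
    expect <- compute_bmi(cohort$weight, cohort$height)
    off <- abs(expect - cohort$bmi) > 0.5
    if (any(off))
      stop("bmi inconsistent with weight/height for sample(s): ",
           paste(cohort$sample_id[off], collapse = ", "))
  }
  invisible(cohort)
}

#' Read a cohort metadata table from TSV
#'
#' Expects a header with at least `sample_id`, `sex`, `age`, `height`
#' (cm) and `weight` (kg). `bmi` is computed when absent and `group`
#' assigned from BMI when absent; any further numeric columns are kept
#' as clinical parameters (missing values allowed as empty cells or NA).
#'
#' @param path path to a tab-separated file, UTF-8, "." decimal point.
#' @return validated cohort data frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("sample_id", "sex", "age", "height", "weight")
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  numeric_cols <- setdiff(colnames(df), c("sample_id", "sex", "group"))
  for (cl in numeric_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(suppress))
      if (length(bad))
        stop(sprintf("unparsable numeric value in column '%s', row %d: '%s'",
                     cl, bad[1], v[bad[1]]))
      v <- suppress
    }
    df[[cl]] <- v
  }
  if (is.null(df$bmi)) df$bmi <- compute_bmi(df$weight, df$height)
  if (is.null(df$group)) {
    df$group <- assign_group(df$bmi)
  } else {
    bad <- setdiff(unique(df$group), GROUP_LEVELS)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    df$group <- factor(df$group, levels = GROUP_LEVELS)
  }
  df <- df[c(intersect(COHORT_CORE_COLUMNS, colnames(df)),
             setdiff(colnames(df), COHORT_CORE_COLUMNS))]
  validate_cohort(df)
  df
}

#' Write a cohort table to TSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @export
write_cohort_table <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample protein identification lists
#'
#' Long-format TSV with two columns `sample_id` and `accession`; one row
#' per identification. Duplicate identifications within a sample are
#' collapsed. Accessions not matching the UniProt-like pattern are kept
#' verbatim with a warning.
#'
#' @param path path to a two-column TSV.
#' @return named list mapping sample_id to a character vector of unique
#'   accessions.
#' @export
read_identifications <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  miss <- setdiff(c("sample_id", "accession"), colnames(df))
  if (length(miss))
    stop("identification file is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("identification file ", path, " has no rows")
    return(structure(list(), names = character(0)))
  }
  odd <- !grepl("^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$",
                df$accession)
  if (any(odd))
    warning(sum(odd), " accession(s) do not look like UniProt ids ",
            "(kept verbatim), e.g. ", df$accession[which(odd)[1]])
  lapply(split(df$accession, df$sample_id), function(x) sort(unique(x)))
}

#' Build a binary presence/absence matrix from identification lists
#'
#' @param idmap named list: sample id -> character vector of accessions.
#' @param sample_order character vector giving the row order; every entry
#'   must be a name of `idmap` (an empty accession set is allowed, absence
#'   from the map is an error so "no proteins" and "no data" stay distinct).
#' @return integer matrix of 0/1 with `sample_order` rownames and
#'   lexicographically sorted accession colnames.
#' @export
build_presence_matrix <- function(idmap, sample_order = names(idmap)) {
  missing_samples <- setdiff(sample_order, names(idmap))
  if (length(missing_samples))
    stop("sample(s) in order but absent from identification map: ",
         paste(missing_samples, collapse = ", "))
  proteins <- sort(unique(unlist(idmap[sample_order], use.names = FALSE)))
  m <- matrix(0L, nrow = length(sample_order), ncol = length(proteins),
              dimnames = list(sample_order, proteins))
  for (s in sample_order) m[s, idmap[[s]]] <- 1L
  m
}

#' Validate a presence/absence matrix
#'
#' @param m matrix with 0/1 entries, unique rownames (samples) and
#'   colnames (UniProt accessions).
#' @return the matrix, invisibly.
#' @export
validate_presence_matrix <- function(m) {
  if (!is.matrix(m)) stop("presence matrix must be a matrix")
  if (length(m) && !all(m %in% c(0L, 1L))) stop("entries must be 0/1")
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    stop("rownames must be unique sample ids")
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    stop("colnames must be unique protein accessions")
  invisible(m)
}

#' Read / write a presence matrix as TSV
#'
#' The file has a `sample_id` first column; remaining columns are
#' accessions with 0/1 cells.
#'
#' @param path file path.
#' @return `read_presence_matrix`: integer matrix with dimnames.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("first column of a presence-matrix TSV must be 'sample_id'")
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$sample_id)
  validate_presence_matrix(m)
  m
}

#' @rdname read_presence_matrix
#' @param m presence matrix.
#' @export
write_presence_matrix <- function(m, path) {
  validate_presence_matrix(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
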
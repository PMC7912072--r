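# Synthetic cohorts and proteomes with known ground truth.
#
# Group demographics default to the published characteristics of a
# 104-subject obesity cohort in five BMI strata; protein occurrence
# follows a logistic model in standardised BMI so that downstream
# clustering and stability selection have a recoverable truth.

#' Default per-group demographic specification
#'
#' Group sizes, BMI mean/sd, BMI ranges, age, height and sex ratio of the
#' emulated 104-subject cohort (NORM/OW/OB1/OB2/OB3).
#'
#' @return data frame with one row per group.
#' @export
group_spec_defaults <- function() {
  data.frame(
    group = GROUP_LEVELS,
    n = c(22L, 21L, 19L, 21L, 21L),
    bmi_mean = c(21.73, 27.52, 32.51, 36.81, 46.99),
    bmi_sd = c(1.90, 1.35, 1.69, 1.39, 5.81),
    bmi_low = c(18.5, 25, 30, 35, 40),
    bmi_high = c(25, 30, 35, 40, Inf),
    age_mean = c(30.54, 32.90, 29.89, 32.62, 34.05),
    age_sd = c(5.34, 6.66, 8.16, 7.92, 6.64),
    height_mean = c(172.65, 171.99, 170.15, 172.26, 172.08),
    height_sd = c(7.31, 11.81, 11.99, 9.74, 9.72),
    sex_ratio_f = c(13 / 22, 10 / 21, 10 / 19, 10 / 21, 11 / 21),
    stringsAsFactors = FALSE
  )
}

#' Default simulation configuration
#'
#' The default proteome has 15 informative proteins with BMI slopes of
#' magnitude 1 to 3 (alternating sign), 75 pure-noise proteins, 5
#' ubiquitous proteins (present essentially everywhere) and 10
#' singleton-ish proteins expected in about one sample — the latter two
#' classes exist to exercise the unrepresentative/non-specific filters.
#' Clinical parameters are linear in BMI (centred at 30) plus Gaussian
#' noise; two are null (zero slope).
#'
#' @param seed integer master seed.
#' @param n_informative,informative_slope number and BMI slope(s) of
#'   informative proteins; a single slope is recycled, otherwise
#'   magnitudes are spaced over `[1, 3]` with alternating sign.
#' @param n_noise,n_ubiquitous,n_singletonish counts of the other
#'   protein classes.
#' @return a `sim_config` list.
#' @export
default_sim_config <- function(seed = 1L, n_informative = 15L,
                               informative_slope = NULL,
                               n_noise = 75L, n_ubiquitous = 5L,
                               n_singletonish = 10L) {
  if (is.null(informative_slope)) {
    mag <- if (n_informative > 1)
      seq(1, 3, length.out = n_informative) else rep(2, n_informative)
    slope <- mag * rep_len(c(1, -1), n_informative)
  } else {
    slope <- rep_len(informative_slope, n_informative)
  }
  effects <- data.frame(
    protein_id = sprintf("P1%04d", seq_len(n_informative)),
    baseline_logit = rep(0, n_informative),
    bmi_slope = slope,
    stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    name = c("glucose", "triglycerides", "hdl_cholesterol", "crp",
             "alt", "insulin", "sodium", "tsh"),
    intercept = c(5.0, 1.3, 1.45, 2.0, 24, 10, 140, 2.0),
    bmi_slope = c(0.05, 0.06, -0.02, 0.30, 0.8, 0.9, 0, 0),
    noise_sd = c(0.5, 0.4, 0.25, 2.0, 8, 4, 2.5, 0.8),
    stringsAsFactors = FALSE
  )
  structure(list(
    groups = group_spec_defaults(),
    effects = effects,
    n_noise_proteins = as.integer(n_noise),
    n_ubiquitous = as.integer(n_ubiquitous),
    n_singletonish = as.integer(n_singletonish),
    noise_logit_range = c(-2, 2),
    clinical_params = clinical,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' Round-trips a `sim_config` through a YAML key/value tree so that
#' simulated studies can be driven from a config file.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config`: a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$groups <- as.list(as.data.frame(config$groups))
  x$effects <- as.list(as.data.frame(config$effects))
  x$clinical_params <- as.list(as.data.frame(config$clinical_params))
  yaml::write_yaml(x, path, precision = 17)  # lossless double round trip
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$groups <- as.data.frame(x$groups, stringsAsFactors = FALSE)
  # YAML has no Inf literal guarantee; tolerate the string form
  x$groups$bmi_high <- as.numeric(x$groups$bmi_high)
  x$effects <- as.data.frame(x$effects, stringsAsFactors = FALSE)
  x$clinical_params <- as.data.frame(x$clinical_params,
                                     stringsAsFactors = FALSE)
  x$n_noise_proteins <- as.integer(x$n_noise_proteins)
  x$n_ubiquitous <- as.integer(x$n_ubiquitous)
  x$n_singletonish <- as.integer(x$n_singletonish)
  x$seed <- as.integer(x$seed)
  structure(x, class = "sim_config")
}

# mean and sd of N(mu, sigma) truncated to [lower, upper)
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  pa <- if (is.finite(a)) dnorm(a) else 0
  pb <- if (is.finite(b)) dnorm(b) else 0
  Z <- pnorm(b) - pnorm(a)
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  delta <- (pa - pb) / Z
  m <- mu + sigma * delta
  ta <- if (is.finite(a)) a * pa else 0
  tb <- if (is.finite(b)) b * pb else 0
  v <- sigma^2 * (1 + (ta - tb) / Z - delta^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Calibrate a range-truncated normal to target moments
#'
#' Finds `(mu, sigma)` of an underlying normal such that its truncation
#' to `[lower, upper)` has the requested mean and sd, by numeric moment
#' matching. Needed because drawing group BMI from a naive truncated
#' normal would distort the published group moments.
#'
#' @param target_mean,target_sd moments the truncated distribution must
#'   attain (within `tol`).
#' @param lower,upper truncation range; either may be infinite.
#' @param tol moment-matching tolerance (default 1e-6).
#' @return named numeric vector `c(mu, sigma)`.
#' @export
calibrate_truncated_normal <- function(target_mean, target_sd, lower, upper,
                                       tol = 1e-6) {
  stopifnot(target_sd > 0, lower < upper)
  if (target_mean <= lower || target_mean >= upper)
    stop("target_mean must lie strictly inside the truncation range")
  if (!is.finite(lower) && !is.finite(upper))
    return(c(mu = target_mean, sigma = target_sd))
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    if (any(!is.finite(mo))) return(1e10)
    (mo[["mean"]] - target_mean)^2 + (mo[["sd"]] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 20000))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  mo <- truncnorm_moments(mu, sigma, lower, upper)
  if (abs(mo[["mean"]] - target_mean) > tol || abs(mo[["sd"]] - target_sd) > tol)
    stop(sprintf(
      "truncated-normal calibration infeasible for mean %.3f sd %.3f on [%s, %s)",
      target_mean, target_sd, format(lower), format(upper)))
  c(mu = mu, sigma = sigma)
}

#' Nearest attainable truncated normal for possibly infeasible moments
#'
#' Empirical group sds can exceed what any range-truncated normal
#' attains (the uniform limit bounds the sd on a finite range). This
#' calibrator matches the target mean exactly — solving the truncated
#' mean for `mu` at each candidate `sigma` — and picks the `sigma`
#' whose truncated sd is closest to the target. When the target is
#' feasible the result coincides with [calibrate_truncated_normal()].
#'
#' @inheritParams calibrate_truncated_normal
#' @param sigma_max cap on the underlying sigma (default 100), keeping
#'   the inverse-CDF sampler well conditioned in the near-uniform limit.
#' @return named numeric vector `c(mu, sigma)`.
#' @export
nearest_truncated_normal <- function(target_mean, target_sd, lower, upper,
                                     sigma_max = 100) {
  stopifnot(target_sd > 0, lower < upper)
  key <- paste(target_mean, target_sd, lower, upper, sigma_max, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (target_mean <= lower || target_mean >= upper)
    stop("target_mean must lie strictly inside the truncation range")
  if (!is.finite(lower) && !is.finite(upper))
    return(c(mu = target_mean, sigma = target_sd))
  mu_for <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, lower, upper)[["mean"]] -
      target_mean
    uniroot(f, c(target_mean - 5 * sigma, target_mean + 5 * sigma),
            extendInt = "yes", tol = 1e-10)$root
  }
  sd_gap <- function(lsig) {
    s <- exp(lsig)
    mo <- truncnorm_moments(mu_for(s), s, lower, upper)
    (mo[["sd"]] - target_sd)^2
  }
  opt <- optimize(sd_gap, c(log(target_sd / 50), log(sigma_max)),
                  tol = 1e-10)
  sigma <- exp(opt$minimum)
  res <- c(mu = mu_for(sigma), sigma = sigma)
  .calibration_cache[[key]] <- res
  res
}

# solved calibrations, keyed by their targets (deterministic, so safe to reuse)
.calibration_cache <- new.env(parent = emptyenv())

# inverse-CDF sampler for the truncated normal (uses the current RNG stream)
rtruncnorm <- function(n, mu, sigma, lower, upper) {
  plo <- pnorm(lower, mu, sigma)
  phi <- pnorm(upper, mu, sigma)
  qnorm(runif(n, plo, phi), mu, sigma)
}

#' Simulate a cohort of demographics and clinical parameters
#'
#' Per group, BMI is drawn from a moment-calibrated range-truncated
#' normal, height and age from normals, sex by the group's female ratio;
#' weight is derived as `bmi * (height/100)^2` so BMI consistency is
#' exact. Clinical parameter k is
#' `intercept_k + slope_k * (BMI - 30) + N(0, noise_sd_k)`.
#'
#' @param config a `sim_config`; see [default_sim_config()].
#' @return validated cohort data frame, fully reproducible from
#'   `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gs <- config$groups
  rows <- vector("list", nrow(gs))
  for (i in seq_len(nrow(gs))) {
    g <- gs[i, ]
    if (g$n == 0L) next
    cal <- nearest_truncated_normal(g$bmi_mean, g$bmi_sd, g$bmi_low, g$bmi_high)
    bmi <- rtruncnorm(g$n, cal[["mu"]], cal[["sigma"]], g$bmi_low, g$bmi_high)
    height <- rnorm(g$n, g$height_mean, g$height_sd)
    age <- rnorm(g$n, g$age_mean, g$age_sd)
    sex <- ifelse(runif(g$n) < g$sex_ratio_f, "f", "m")
    rows[[i]] <- data.frame(
      group = g$group, sex = sex, age = age, height = height,
      weight = bmi * (height / 100)^2, bmi = bmi,
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, rows)
  if (is.null(cohort))
    cohort <- data.frame(group = character(), sex = character(),
                         age = numeric(), height = numeric(),
                         weight = numeric(), bmi = numeric())
  cohort <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(cohort))), cohort)
  cohort$group <- factor(cohort$group, levels = GROUP_LEVELS)
  cp <- config$clinical_params
  for (i in seq_len(nrow(cp)))
    cohort[[cp$name[i]]] <- cp$intercept[i] +
      cp$bmi_slope[i] * (cohort$bmi - 30) +
      rnorm(nrow(cohort), 0, cp$noise_sd[i])
  if (nrow(cohort)) validate_cohort(cohort)
  cohort
}

#' Simulate a binary proteome with known informative proteins
#'
#' Protein j is present in sample i with probability
#' `plogis(a_j + b_j * z_i)` where `z_i = (BMI_i - 30) / 6` is a fixed
#' standardisation of BMI (not per-cohort, so effect sizes keep their
#' meaning across cohort sizes). Noise proteins have `b = 0` and
#' baseline logits drawn uniformly from `config$noise_logit_range`;
#' ubiquitous proteins have presence probability > 0.999; singleton-ish
#' proteins have expected occurrence of about one sample.
#'
#' @param cohort a cohort data frame (nonempty).
#' @param config a `sim_config`.
#' @param seed RNG seed for the proteome draw; defaults to
#'   `config$seed + 1` so cohort and proteome streams stay distinct.
#' @return list with `matrix` (presence matrix, columns sorted) and
#'   `truth` (character vector of informative protein ids).
#' @export
simulate_proteome <- function(cohort, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), nrow(cohort) > 0)
  set.seed(seed)
  n <- nrow(cohort)
  z <- (cohort$bmi - 30) / 6
  eff <- config$effects
  a <- eff$baseline_logit
  b <- eff$bmi_slope
  ids <- eff$protein_id
  if (config$n_noise_proteins > 0) {
    rng <- config$noise_logit_range
    a <- c(a, runif(config$n_noise_proteins, rng[1], rng[2]))
    b <- c(b, rep(0, config$n_noise_proteins))
    ids <- c(ids, sprintf("P2%04d", seq_len(config$n_noise_proteins)))
  }
  if (config$n_ubiquitous > 0) {
    a <- c(a, rep(10, config$n_ubiquitous))
    b <- c(b, rep(0, config$n_ubiquitous))
    ids <- c(ids, sprintf("P9%04d", seq_len(config$n_ubiquitous)))
  }
  if (config$n_singletonish > 0) {
    a <- c(a, rep(qlogis(1 / n), config$n_singletonish))
    b <- c(b, rep(0, config$n_singletonish))
    ids <- c(ids, sprintf("P0%04d", seq_len(config$n_singletonish)))
  }
  if (anyDuplicated(ids)) stop("duplicated protein ids in simulation config")
  prob <- plogis(outer(z, b) + matrix(a, n, length(a), byrow = TRUE))
  m <- matrix(rbinom(length(prob), 1L, prob), n, length(a),
              dimnames = list(cohort$sample_id, ids))
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  list(matrix = m,
       truth = sort(eff$protein_id[eff$bmi_slope != 0]))
}
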
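# Synthetic long-format feature tables and survival cohorts with the
# variance structure assumed by the downstream reproducibility and
# prognosis analyses.

#' Per-feature variance-component specification
#'
#' Describes the generating variance structure of one feature across the
#' reconstruction grid: value = mean + subject effect + thickness shift +
#' ASiR shift + noise. Component variances are in squared feature units and
#' use the sample-variance (k-1 denominator) convention over the fixed
#' levels, matching the pairwise-difference estimator used when the
#' components are recovered from a fitted mixed model.
#'
#' @param sigma_s2 Between-subject variance.
#' @param sigma_t2 Variance of the three slice-thickness level shifts.
#' @param sigma_a2 Variance of the seven ASiR level shifts.
#' @param sigma_e2 Residual (noise) variance.
#' @param mean Feature mean.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(sigma_s2, sigma_t2 = 0, sigma_a2 = 0, sigma_e2 = 0,
                        mean = 0) {
  v <- c(sigma_s2, sigma_t2, sigma_a2, sigma_e2)
  if (any(!is.finite(v)) || any(v < 0))
    abort("variance components must be finite and >= 0")
  structure(list(sigma_s2 = sigma_s2, sigma_t2 = sigma_t2,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, mean = mean),
            class = "effect_spec")
}

#' Analytic generalized CCC implied by an effect specification
#'
#' @param spec An [effect_spec()].
#' @return sigma_s2 / (sigma_s2 + sigma_t2 + sigma_e2); the ASiR component
#'   is excluded because it is controlled for as a fixed effect.
#' @export
true_generalized_ccc <- function(spec) {
  with(spec, sigma_s2 / (sigma_s2 + sigma_t2 + sigma_e2))
}

#' Generate a long-format feature table over the reconstruction grid
#'
#' For every subject and every cell of the full 3 thickness x 7 ASiR grid,
#' draws feature values with the additive structure value = mean +
#' subject + thickness shift + ASiR shift + noise. Thickness shifts are the
#' fixed, monotone-in-thickness levels `(-d, 0, d)` with `d = sqrt(sigma_t2)`
#' (sample variance over levels = sigma_t2 exactly); ASiR shifts are a
#' linear ramp over the seven levels scaled the same way. Monotone shifts
#' make the widest thickness gap the least concordant pair by construction.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effects Named list of [effect_spec()]s, one per feature.
#' @param seed RNG seed; generation is a pure function of its arguments.
#' @param roi,extractor Tags attached to every record.
#' @return A data.frame with columns `subject_id`, `slice_thickness_mm`,
#'   `asir_percent`, `roi`, `extractor`, `feature`, `value`: 21 records per
#'   subject per feature.
#' @export
generate_feature_table <- function(n_subjects, effects, seed = 1,
                                   roi = "tumor", extractor = "synth") {
  if (n_subjects < 2) abort("need at least 2 subjects")
  if (is.null(names(effects)) || any(names(effects) == ""))
    abort("effects must be a named list of effect_spec objects")
  grid <- reconstruction_grid()
  k <- nrow(grid)  # 21
  subj <- sprintf("S%03d", seq_len(n_subjects))
  t_idx <- match(grid$slice_thickness_mm, THICKNESS_GRID)
  a_idx <- match(grid$asir_percent, ASIR_GRID)
  with_seed(seed, {
    out <- lapply(names(effects), function(f) {
      es <- effects[[f]]
      if (!inherits(es, "effect_spec")) abort("effects[['%s']] is not an effect_spec", f)
      s_eff <- stats::rnorm(n_subjects, sd = sqrt(es$sigma_s2))
      d <- sqrt(es$sigma_t2)
      t_shift <- c(-d, 0, d)                       # sample var = d^2
      ramp <- (seq_along(ASIR_GRID) - mean(seq_along(ASIR_GRID)))
      a_shift <- if (es$sigma_a2 > 0) ramp * sqrt(es$sigma_a2 / stats::var(ramp)) else ramp * 0
      eps <- stats::rnorm(n_subjects * k, sd = sqrt(es$sigma_e2))
      value <- es$mean + rep(s_eff, each = k) +
        rep(t_shift[t_idx], times = n_subjects) +
        rep(a_shift[a_idx], times = n_subjects) + eps
      data.frame(subject_id = rep(subj, each = k),
                 slice_thickness_mm = rep(grid$slice_thickness_mm, times = n_subjects),
                 asir_percent = rep(grid$asir_percent, times = n_subjects),
                 roi = roi, extractor = extractor, feature = f,
                 value = value, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Compose / parse feature identifiers
#'
#' Cohort feature columns are keyed by the triple (roi, extractor, feature),
#' encoded as `"roi|extractor|feature"`.
#'
#' @param roi,extractor,feature Character vectors.
#' @return `make_feature_id`: character vector of ids.
#' @export
make_feature_id <- function(roi, extractor, feature) {
  paste(roi, extractor, feature, sep = "|")
}

#' @rdname make_feature_id
#' @param id Character vector of ids.
#' @return `parse_feature_id`: data.frame with columns `id`, `roi`,
#'   `extractor`, `feature`.
#' @export
parse_feature_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  data.frame(id = id,
             roi = vapply(parts, `[`, "", 1),
             extractor = vapply(parts, `[`, "", 2),
             feature = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Survival cohort generator specification
#'
#' @param n_subjects Cohort size (>= 20).
#' @param betas Named numeric vector of true log-hazard coefficients, keyed
#'   by feature id; features not named have coefficient 0. At least one
#'   nonzero entry required.
#' @param baseline_rate Exponential baseline hazard (1/months).
#' @param censor_window Upper bound of the uniform administrative censoring
#'   time (months).
#' @param seed RNG seed.
#' @return A `survival_gen_spec` list.
#' @export
survival_gen_spec <- function(n_subjects, betas, baseline_rate = 0.02,
                              censor_window = 120, seed = 1) {
  if (n_subjects < 20) abort("n_subjects must be >= 20")
  if (censor_window <= 0) abort("censor_window must be > 0")
  if (length(betas) == 0 || all(betas == 0)) abort("at least one nonzero beta required")
  if (is.null(names(betas))) abort("betas must be named by feature id")
  structure(list(n_subjects = as.integer(n_subjects), betas = betas,
                 baseline_rate = baseline_rate,
                 censor_window = censor_window, seed = as.integer(seed)),
            class = "survival_gen_spec")
}

#' Generate an i.i.d. standard-normal cohort feature matrix
#'
#' @param n_subjects Number of subjects.
#' @param ids Feature ids (column names).
#' @param seed RNG seed.
#' @return Numeric matrix `n_subjects x length(ids)`.
#' @export
generate_cohort_features <- function(n_subjects, ids, seed = 1) {
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_subjects * length(ids)), n_subjects, length(ids))
    colnames(m) <- ids
    m
  })
}

#' Generate a right-censored survival cohort from a feature matrix
#'
#' Event times are exponential with subject-specific rate
#' `baseline_rate * exp(sum(beta * x))`; censoring times are uniform on
#' `(0, censor_window)`; the observed time is the minimum of the two.
#'
#' @param spec A [survival_gen_spec()].
#' @param features Numeric matrix (subjects x features) with feature-id
#'   column names; `spec$betas` must reference existing columns.
#' @return A `survival_cohort`: list with `subjects` (data.frame
#'   `subject_id`, `time_months`, `event`), `features` matrix,
#'   `feature_info` (parsed ids) and logical `all_censored` flag.
#' @export
generate_survival_cohort <- function(spec, features) {
  stopifnot(inherits(spec, "survival_gen_spec"))
  features <- as.matrix(features)
  if (nrow(features) != spec$n_subjects)
    abort("feature matrix has %d rows but spec$n_subjects is %d",
          nrow(features), spec$n_subjects)
  missing <- setdiff(names(spec$betas), colnames(features))
  if (length(missing))
    abort("betas reference unknown features: %s", paste(missing, collapse = ", "))
  lp <- as.numeric(features[, names(spec$betas), drop = FALSE] %*% spec$betas)
  cohort <- with_seed(spec$seed, {
    etime <- stats::rexp(spec$n_subjects, rate = spec$baseline_rate * exp(lp))
    ctime <- stats::runif(spec$n_subjects, 0, spec$censor_window)
    time <- pmin(etime, ctime)
    event <- as.integer(etime <= ctime)
    list(time = time, event = event)
  })
  all_cens <- sum(cohort$event) == 0
  if (all_cens) warning("survival cohort draw contains zero events")
  structure(list(
    subjects = data.frame(subject_id = sprintf("P%04d", seq_len(spec$n_subjects)),
                          time_months = cohort$time, event = cohort$event,
                          stringsAsFactors = FALSE),
    features = features,
    feature_info = parse_feature_id(colnames(features)),
    all_censored = all_cens), class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort> %d subjects, %d features, %d events (%.0f%% censored)\n",
              nrow(x$subjects), ncol(x$features), sum(x$subjects$event),
              100 * mean(x$subjects$event == 0)))
  invisible(x)
}

#' Write / read the standard CSV serializations
#'
#' Feature tables use columns `subject_id, slice_thickness_mm, asir_percent,
#' roi, extractor, feature, value`; survival tables use `subject_id,
#' time_months, event`.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @return `path` invisibly (writers); data.frame (readers).
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
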
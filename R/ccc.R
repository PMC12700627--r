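# Reproducibility analysis: pairwise Lin's CCC across slice-thickness
# pairs, paired Wilcoxon signed-rank comparisons, and the generalized CCC
# from linear-mixed-model variance components.

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments. Symmetric in its arguments; 1 for
#' perfect agreement, -1 for perfect reversal.
#'
#' @param x,y Paired numeric vectors, equal length >= 3, finite.
#' @return The CCC, or `NA` if both vectors are constant with equal means
#'   (zero denominator).
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite")
  denom <- pop_var(x) + pop_var(y) + (mean(x) - mean(y))^2
  if (denom == 0) return(NA_real_)
  2 * pop_cov(x, y) / denom
}

#' Pairwise CCC across slice-thickness pairs
#'
#' For every (feature, roi, extractor) stream in a long feature table,
#' computes Lin's CCC between each pair of slice thicknesses at a fixed
#' reference ASiR level, matching subjects by id. Subjects missing either
#' member of a pair are dropped with a message.
#'
#' @param table Long feature table (see [generate_feature_table()] for the
#'   column contract).
#' @param asir_fixed Reference ASiR level (default 20).
#' @return data.frame with columns `feature`, `roi`, `extractor`,
#'   `comparison` (e.g. `"2.5_vs_5"`), `ccc`, `n_subjects`.
#' @export
pairwise_ccc_table <- function(table, asir_fixed = 20) {
  tab <- table[table$asir_percent == asir_fixed, , drop = FALSE]
  if (nrow(tab) == 0) abort("no records at ASiR %s", asir_fixed)
  pairs <- utils::combn(sort(unique(tab$slice_thickness_mm)), 2, simplify = FALSE)
  grp <- interaction(tab$feature, tab$roi, tab$extractor, drop = TRUE)
  out <- lapply(split(tab, grp), function(g) {
    wide <- stats::reshape(g[, c("subject_id", "slice_thickness_mm", "value")],
                           idvar = "subject_id", timevar = "slice_thickness_mm",
                           direction = "wide")
    do.call(rbind, lapply(pairs, function(p) {
      c1 <- paste0("value.", p[1]); c2 <- paste0("value.", p[2])
      ok <- !is.na(wide[[c1]]) & !is.na(wide[[c2]])
      if (sum(!ok) > 0)
        message(sprintf("pairwise_ccc_table: dropped %d subject(s) missing %g/%g mm (%s)",
                        sum(!ok), p[1], p[2], g$feature[1]))
      data.frame(feature = g$feature[1], roi = g$roi[1], extractor = g$extractor[1],
                 comparison = paste0(p[1], "_vs_", p[2]),
                 ccc = lin_ccc(wide[[c1]][ok], wide[[c2]][ok]),
                 n_subjects = sum(ok), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of zero median difference. Zero differences are dropped
#' (the classical convention); the p-value is exact (signed-rank
#' distribution) for n <= 25 without ties in the absolute differences, and
#' otherwise uses the normal approximation with continuity and tie
#' corrections.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Two-sided p-value. All-zero differences give p = 1 with a
#'   warning.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  if (n < 5) warning("fewer than 5 nonzero differences; test has little power")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 14) {
    # fully exact: enumerate all 2^n sign assignments (handles tied ranks)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.numeric(signs %*% r)
    p <- 2 * min(mean(Wall <= W), mean(Wall >= W))
    return(min(1, p))
  }
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sig2 <= 0) { warning("degenerate ranks; p = 1"); return(1) }
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Fit variance components for one feature over the reconstruction grid
#'
#' Fits `value ~ thickness + ASiR + (1 | subject)` by REML: subject is a
#' random intercept, slice thickness and ASiR are fixed effects. The
#' subject and residual variances come directly from the fit; the
#' thickness and ASiR components are the dispersions of the estimated
#' fixed-effect levels, in the pairwise-difference form
#' `sum_{i<j} (b_i - b_j)^2 / (k (k - 1))` over the k levels (equal to the
#' sample variance of the level effects). Components are truncated at 0.
#' If the mixed model cannot be fit (degenerate data), a fixed-effects
#' method-of-moments fallback is used and flagged.
#'
#' @param values Long data.frame with columns `subject_id`,
#'   `slice_thickness_mm`, `asir_percent`, `value` for a single feature.
#' @return A `variance_components` object: `sigma_s2`, `sigma_t2`,
#'   `sigma_a2`, `sigma_e2`, `method` (`"REML"` or `"moments"`).
#' @export
fit_variance_components <- function(values) {
  req <- c("subject_id", "slice_thickness_mm", "asir_percent", "value")
  if (!all(req %in% names(values))) abort("missing columns: %s",
                                          paste(setdiff(req, names(values)), collapse = ", "))
  df <- data.frame(y = values$value,
                   s = factor(values$subject_id),
                   t = factor(values$slice_thickness_mm),
                   a = factor(values$asir_percent))
  # degenerate (noise-free) data breaks REML; detect an exact additive fit
  # and read the components straight off the balanced-design level means
  ybar <- mean(df$y)
  ms <- tapply(df$y, df$s, mean); mt <- tapply(df$y, df$t, mean)
  ma <- tapply(df$y, df$a, mean)
  resid_add <- df$y - ms[df$s] - mt[df$t] - ma[df$a] + 2 * ybar
  if (mean(resid_add^2) <= 1e-12 * max(pop_var(df$y), 1e-12)) {
    level_disp0 <- function(eff) if (length(eff) < 2) 0 else stats::var(as.numeric(eff))
    out <- list(sigma_s2 = level_disp0(ms), sigma_t2 = level_disp0(mt),
                sigma_a2 = level_disp0(ma), sigma_e2 = mean(resid_add^2),
                method = "moments")
    class(out) <- "variance_components"
    return(out)
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ t + a + (1 | s), data = df, REML = TRUE)),
    error = function(e) NULL, warning = function(w) NULL)
  # refit keeping harmless convergence warnings
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ t + a + (1 | s), data = df, REML = TRUE))),
      error = function(e) NULL)
  }
  if (!is.null(fit) && is.finite(lme4::fixef(fit)[1])) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_s2 <- vc$vcov[vc$grp == "s"]
    sigma_e2 <- stats::sigma(fit)^2
    fe <- lme4::fixef(fit)
    t_eff <- c(0, fe[grep("^t", names(fe))])
    a_eff <- c(0, fe[grep("^a", names(fe))])
    method <- "REML"
  } else {
    lmfit <- stats::lm(y ~ s + t + a, data = df)
    sigma_e2 <- mean(stats::residuals(lmfit)^2) * length(df$y) /
      max(1, stats::df.residual(lmfit))
    cf <- stats::coef(lmfit); cf[is.na(cf)] <- 0
    s_eff <- c(0, cf[grep("^s", names(cf))])
    t_eff <- c(0, cf[grep("^t", names(cf))])
    a_eff <- c(0, cf[grep("^a", names(cf))])
    n_rec <- length(df$y) / nlevels(df$s)
    sigma_s2 <- max(0, stats::var(s_eff) - sigma_e2 / n_rec)
    method <- "moments"
  }
  level_disp <- function(eff) {
    k <- length(eff)
    if (k < 2) return(0)
    # sum_{i<j} (b_i - b_j)^2 / (k(k-1)) == sample variance of the levels
    sum(outer(eff, eff, "-")[upper.tri(matrix(0, k, k))]^2) / (k * (k - 1))
  }
  out <- list(sigma_s2 = max(0, sigma_s2),
              sigma_t2 = max(0, level_disp(t_eff)),
              sigma_a2 = max(0, level_disp(a_eff)),
              sigma_e2 = max(0, sigma_e2),
              method = method)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> s2=%.4g t2=%.4g a2=%.4g e2=%.4g (%s)\n",
              x$sigma_s2, x$sigma_t2, x$sigma_a2, x$sigma_e2, x$method))
  invisible(x)
}

#' Generalized CCC from variance components
#'
#' `sigma_s2 / (sigma_s2 + sigma_t2 + sigma_e2)`. The ASiR component is
#' deliberately excluded from the denominator: ASiR is controlled for as a
#' fixed effect, so its dispersion does not count against agreement across
#' slice thicknesses.
#'
#' @param vc A `variance_components` object (or list with the four fields).
#' @return Value in `[0, 1]`; `NA` if all components are zero.
#' @export
generalized_ccc <- function(vc) {
  denom <- vc$sigma_s2 + vc$sigma_t2 + vc$sigma_e2
  if (denom == 0) return(NA_real_)
  vc$sigma_s2 / denom
}

#' Generalized CCC for every feature stream in a long table
#'
#' @param table Long feature table over the full reconstruction grid.
#' @return data.frame with one row per (feature, roi, extractor):
#'   `comparison = "generalized"`, `ccc`, the four variance components and
#'   the fit method.
#' @export
generalized_ccc_table <- function(table) {
  grp <- interaction(table$feature, table$roi, table$extractor, drop = TRUE)
  out <- lapply(split(table, grp), function(g) {
    vc <- fit_variance_components(g)
    data.frame(feature = g$feature[1], roi = g$roi[1], extractor = g$extractor[1],
               comparison = "generalized", ccc = generalized_ccc(vc),
               sigma_s2 = vc$sigma_s2, sigma_t2 = vc$sigma_t2,
               sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2,
               method = vc$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
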
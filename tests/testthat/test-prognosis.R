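test_that("Harrell's C-index matches hand enumerations and the pair oracle", {
  # times (1,2,3), events (1,0,1), scores (3,1,2): both comparable pairs concordant
  expect_equal(harrell_cindex(c(3, 1, 2), c(1, 2, 3), c(1, 0, 1)), 1)
  # perfect ranking without censoring
  tt <- 1:6
  expect_equal(harrell_cindex(rev(tt), tt, rep(1, 6)), 1)
  # constant scores tie everywhere
  expect_equal(harrell_cindex(rep(2, 6), tt, rep(1, 6)), 0.5)
  # orientation symmetry: C(-s) = 1 - C(s) (no score ties)
  sv <- random_surv(7, 40)
  expect_equal(harrell_cindex(-sv$score, sv$time, sv$event),
               1 - harrell_cindex(sv$score, sv$time, sv$event))
  # O(n^2) oracle on random censored data
  for (s in 1:10) {
    sv <- random_surv(s, sample(10:50, 1))
    expect_equal(harrell_cindex(sv$score, sv$time, sv$event),
                 oracle_cindex(sv$score, sv$time, sv$event),
                 info = sprintf("seed %d", s))
  }
  # agreement with the survival package on a larger instance
  sv <- random_surv(77, 150)
  ref <- survival::concordance(survival::Surv(sv$time, sv$event) ~ sv$score,
                               reverse = TRUE)$concordance
  expect_equal(harrell_cindex(sv$score, sv$time, sv$event), ref)
  # no comparable pairs
  expect_warning(cc <- harrell_cindex(c(1, 2), c(5, 6), c(0, 0)), "comparable")
  expect_true(is.na(cc))
})

test_that("feature orientation reflects and is idempotent", {
  sv <- random_surv(3, 60)
  # force a discriminative feature with c < 0.5
  x <- sv$time + rnorm(60, 0, 2)  # higher x ~ later event -> c < 0.5
  o <- orient_feature(x, sv$time, sv$event)
  craw <- harrell_cindex(x, sv$time, sv$event)
  if (craw < 0.5) {
    expect_equal(o$sign, -1)
    expect_equal(o$cindex, 1 - craw)
  }
  expect_gte(o$cindex, 0.5)
  # idempotent
  o2 <- orient_feature(o$values, sv$time, sv$event)
  expect_equal(o2$sign, 1)
  expect_equal(o2$values, o$values)
})

test_that("univariate Cox is calibrated under the null and recovers signal", {
  # type-I error of the p < 0.1 filter under the null
  set.seed(11)
  n <- 1000
  et <- rexp(n, 0.05); ct <- runif(n, 0, 40)
  tt <- pmin(et, ct); ee <- as.integer(et <= ct)
  rej <- mean(replicate(400, univariate_cox(rnorm(n), tt, ee)$p < 0.1))
  expect_lt(abs(rej - 0.1), 0.03)
  # recovery: binary covariate with log HR = log 2
  set.seed(12)
  x <- rbinom(n, 1, 0.5)
  et <- rexp(n, 0.05 * exp(log(2) * x)); tt <- pmin(et, ct); ee <- as.integer(et <= ct)
  fit <- univariate_cox(x, tt, ee)
  expect_gte(fit$beta, 0.53)
  expect_lte(fit$beta, 0.86)
  expect_error(univariate_cox(rep(1, n), tt, ee), "constant")
})

test_that("multivariable Cox recovers independent effects and is order-invariant", {
  set.seed(21)
  n <- 1000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  lp <- log(2) * X[, 1] - log(2) * X[, 2]
  et <- rexp(n, 0.05 * exp(lp)); ct <- runif(n, 0, 60)
  tt <- pmin(et, ct); ee <- as.integer(et <= ct)
  m <- fit_cox(X, tt, ee)
  expect_lt(abs(m$betas["a"] - log(2)), 0.15)
  expect_lt(abs(m$betas["b"] + log(2)), 0.15)
  # permuting subjects leaves coefficients unchanged
  perm <- sample(n)
  m2 <- fit_cox(X[perm, ], tt[perm], ee[perm])
  expect_equal(m2$betas, m$betas, tolerance = 1e-6)
  # single binary covariate consistent with the univariate fit
  xb <- rbinom(n, 1, 0.5)
  mu <- fit_cox(matrix(xb, ncol = 1, dimnames = list(NULL, "x")), tt, ee)
  expect_equal(unname(mu$betas), univariate_cox(xb, tt, ee)$beta, tolerance = 1e-6)
})

test_that("ridge fallback handles collinear designs", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  X <- cbind(a = x, b = x)  # perfectly collinear
  et <- rexp(n, 0.05 * exp(x)); ct <- runif(n, 0, 60)
  m <- fit_cox(X, pmin(et, ct), as.integer(et <= ct))
  expect_true(m$flagged)
  expect_true(all(is.finite(m$betas)))
})

test_that("the candidate filter applies CCC, C-index and p-value stages in order", {
  set.seed(41)
  n <- 300
  # f_signal: prognostic; f_weak: borderline C; f_noise: nothing
  f_signal <- rnorm(n); f_signal2 <- rnorm(n); f_noise <- rnorm(n)
  lp <- 0.8 * f_signal + 0.8 * f_signal2
  et <- rexp(n, 0.03 * exp(lp)); ct <- runif(n, 0, 80)
  tt <- pmin(et, ct); ee <- as.integer(et <= ct)
  X <- cbind(s1 = f_signal, s2 = f_signal2, noise = f_noise)
  ccc <- c(s1 = 0.9, s2 = 0.7, noise = 0.95)
  # threshold 0.85 removes s2 despite its signal; noise passes CCC but fails C
  flt <- filter_features(X, tt, ee, ccc, ccc_threshold = 0.85)
  expect_equal(flt$features, "s1")
  expect_equal(unname(flt$counts), c(3, 2, 1, 1))
  # threshold 0 admits everything with signal
  flt0 <- filter_features(X, tt, ee, ccc, ccc_threshold = 0)
  expect_setequal(flt0$features, c("s1", "s2"))
  # stage survivors agree with direct recomputation of the rules
  craw <- sapply(colnames(X), function(j) harrell_cindex(X[, j], tt, ee))
  cori <- ifelse(craw < 0.5, 1 - craw, craw)
  manual <- names(cori)[cori >= 0.55]
  manual <- manual[sapply(manual, function(j) {
    univariate_cox(ifelse(craw[j] < 0.5, -1, 1) * X[, j], tt, ee)$p < 0.1
  })]
  expect_setequal(flt0$features, manual)
  # monotone availability in the threshold
  counts <- sapply(c(0, 0.8, 0.9, 0.99), function(th)
    length(filter_features(X, tt, ee, ccc, ccc_threshold = th)$features))
  expect_true(all(diff(counts) <= 0))
  # all-noise input yields an empty list
  Xn <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  fltn <- filter_features(Xn, tt, ee, c(a = 1, b = 1, c = 1), ccc_threshold = 0,
                          c_min = 0.55)
  expect_length(fltn$features, 0)
})

test_that("mRMR maximizes relevance first and avoids redundant picks", {
  set.seed(51)
  n <- 200
  base <- rnorm(n)
  X <- cbind(a = base, dup = base, b = rnorm(n), c = rnorm(n))
  rel <- c(a = 0.12, dup = 0.12, b = 0.09, c = 0.05)
  # k = 1: pure argmax relevance
  expect_equal(mrmr_select(X, rel, 1), "a")
  # the duplicate (|cor| = 1 with "a") is never chosen while positive-score
  # candidates remain
  expect_equal(mrmr_select(X, rel, 3), c("a", "b", "c"))
  # agreement with exhaustive evaluation of the greedy criterion
  for (s in 1:6) {
    set.seed(s)
    Z <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, letters[1:5]))
    Z[, 2] <- Z[, 1] * 0.9 + Z[, 2] * 0.1
    relz <- setNames(runif(5, 0.01, 0.2), letters[1:5])
    got <- mrmr_select(Z, relz, 3)
    sel <- character(0); remaining <- letters[1:5]
    for (step in 1:3) {
      scores <- sapply(remaining, function(f) {
        if (length(sel) == 0) relz[f]
        else relz[f] - mean(abs(cor(Z[, f], Z[, sel, drop = FALSE])))
      })
      pick <- remaining[which.max(scores)]
      sel <- c(sel, pick); remaining <- setdiff(remaining, pick)
    }
    expect_equal(got, sel, info = sprintf("seed %d", s))
  }
  expect_error(mrmr_select(X, rel, 0), "k must be")
  # fewer candidates than k returns everything
  expect_setequal(mrmr_select(X[, 1:2], rel[1:2], 10), c("a", "dup"))
})

test_that("repeated CV is deterministic, leak-free at the component level, and honest under the null", {
  ids <- make_feature_id(rep(c("tumor", "parenchyma"), each = 10), "synth",
                         sprintf("F%02d", 1:20))
  X <- generate_cohort_features(150, ids, seed = 61)
  betas <- setNames(c(0.9, 0.9), ids[1:2])
  cohort <- generate_survival_cohort(survival_gen_spec(150, betas, seed = 62), X)
  ccc_tab <- data.frame(feature = sprintf("F%02d", 1:20),
                        roi = rep(c("tumor", "parenchyma"), each = 10),
                        extractor = "synth", ccc = 0.9)
  cfg <- cv_config("all", 0.85, 2, folds = 4, repeats = 3, seed = 63)
  r1 <- repeated_cv(cohort, ccc_tab, cfg)
  r2 <- repeated_cv(cohort, ccc_tab, cfg)
  expect_identical(r1$rep_cindex, r2$rep_cindex)
  expect_identical(r1$selection_freq, r2$selection_freq)
  # the planted features dominate selection
  sf <- r1$selection_freq
  top <- sf$id[order(-sf$freq)][1:2]
  expect_setequal(top, ids[1:2])
  expect_true(all(r1$rep_cindex > 0.5))
  # prop_liver reflects ROI provenance of selections (both planted are tumor)
  expect_lt(r1$prop_liver, 0.5)
  # leak-freedom: the training-side pipeline output is a function of the
  # training subjects only
  tr <- 1:100
  Xtr <- scale(cohort$features[tr, ])
  flt_a <- filter_features(Xtr, cohort$subjects$time_months[tr],
                           cohort$subjects$event[tr], NULL, 0)
  perm_out <- cohort
  perm_out$subjects$time_months[101:150] <- rev(perm_out$subjects$time_months[101:150])
  flt_b <- filter_features(Xtr, perm_out$subjects$time_months[tr],
                           perm_out$subjects$event[tr], NULL, 0)
  expect_identical(flt_a, flt_b)
  m_a <- fit_cox(Xtr[, flt_a$features, drop = FALSE],
                 cohort$subjects$time_months[tr], cohort$subjects$event[tr])
  m_b <- fit_cox(Xtr[, flt_b$features, drop = FALSE],
                 perm_out$subjects$time_months[tr], perm_out$subjects$event[tr])
  expect_identical(m_a$betas, m_b$betas)
})

test_that("a null cohort cross-validates to chance performance", {
  ids <- make_feature_id("tumor", "synth", sprintf("N%02d", 1:15))
  X <- generate_cohort_features(200, ids, seed = 71)
  cohort <- generate_survival_cohort(
    survival_gen_spec(200, setNames(1e-12, ids[1]), seed = 72), X)
  # no CCC filter, generous p to let noise through occasionally
  cfg <- cv_config("all", 0, 2, folds = 5, repeats = 6, c_min = 0, p_max = 1, seed = 73)
  res <- repeated_cv(cohort, NULL, cfg)
  expect_lt(abs(res$c_mean - 0.5), 0.04)
})

test_that("empty candidate cells are reported, not fatal", {
  ids <- make_feature_id("tumor", "synth", sprintf("F%02d", 1:5))
  X <- generate_cohort_features(80, ids, seed = 81)
  cohort <- generate_survival_cohort(
    survival_gen_spec(80, setNames(0.5, ids[1]), seed = 82), X)
  ccc_tab <- data.frame(feature = sprintf("F%02d", 1:5), roi = "tumor",
                        extractor = "synth", ccc = 0.7)
  res <- repeated_cv(cohort, ccc_tab, cv_config("all", 0.95, 2, folds = 3,
                                                repeats = 2, seed = 83))
  expect_equal(res$n_models, 0)
  expect_true(is.na(res$c_mean))
  expect_equal(res$n_skipped_folds, 6)
})

test_that("the experiment grid enumerates and pools feature sets correctly", {
  ids <- make_feature_id("tumor", rep(c("L2i", "S3"), each = 6), sprintf("F%02d", 1:12))
  X <- generate_cohort_features(100, ids, seed = 91)
  cohort <- generate_survival_cohort(
    survival_gen_spec(100, setNames(c(0.8, 0.8), ids[c(1, 7)]), seed = 92), X)
  ccc_tab <- data.frame(feature = sprintf("F%02d", 1:12),
                        roi = "tumor", extractor = rep(c("L2i", "S3"), each = 6),
                        ccc = 0.9)
  grid <- cv_grid_configs(feature_sets = c("L2i", "S3", "all"),
                          thresholds = c(0, 0.85), counts = c(1, 2))
  expect_equal(nrow(grid), 12)
  out <- experiment_grid(cohort, ccc_tab, grid = grid, folds = 3, repeats = 2, seed = 93)
  expect_equal(nrow(out$results), 12)
  expect_true(all(out$results$status %in% c("ok", "empty")))
  # determinism of the whole grid
  out2 <- experiment_grid(cohort, ccc_tab, grid = grid, folds = 3, repeats = 2, seed = 93)
  expect_identical(out$results, out2$results)
  # pooling arithmetic: "all" sees the union of per-extractor candidates
  r_all <- repeated_cv(cohort, ccc_tab, cv_config("all", 0, 1, folds = 3,
                                                  repeats = 1, seed = 94))
  expect_equal(nrow(r_all$selection_freq), 12)
  r_one <- repeated_cv(cohort, ccc_tab, cv_config("L2i", 0, 1, folds = 3,
                                                  repeats = 1, seed = 94))
  expect_equal(nrow(r_one$selection_freq), 6)
})
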
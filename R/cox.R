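# Cox proportional hazards wrappers (partial likelihood, Breslow ties).

#' Univariate Cox proportional hazards fit
#'
#' Single-covariate partial-likelihood fit with Breslow tie handling and a
#' two-sided Wald p-value.
#'
#' @param x Covariate (finite, non-constant).
#' @param time,event Survival outcome.
#' @return List with `beta`, `se`, `p`, and `flagged` (TRUE when the fit
#'   did not converge cleanly, e.g. monotone likelihood).
#' @export
univariate_cox <- function(x, time, event) {
  if (any(!is.finite(x))) abort("x must be finite")
  if (stats::sd(x) == 0) abort("x is constant")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))[1]
  if (!is.finite(beta) || !is.finite(se)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, flagged = TRUE))
  }
  list(beta = beta, se = unname(se), p = 2 * stats::pnorm(-abs(beta / se)),
       flagged = flagged)
}

#' Multivariable Cox proportional hazards fit
#'
#' Partial-likelihood fit (Breslow ties) of a standardized feature matrix.
#' If the fit fails or yields non-finite coefficients (singular Hessian,
#' monotone likelihood), a light ridge penalty (theta = 1e-4) is applied
#' and the model flagged.
#'
#' @param X Numeric matrix (subjects x features), ideally standardized.
#' @param time,event Survival outcome.
#' @return A `cox_model`: list with `betas` (named), `risk` (training
#'   linear predictor), `flagged`.
#' @export
fit_cox <- function(X, time, event) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  surv <- survival::Surv(time, event)
  flagged <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(surv ~ X, ties = "breslow",
                      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
      warning = function(w) { flagged <<- TRUE; invokeRestart("muffleWarning") }),
    error = function(e) NULL)
  betas <- if (!is.null(fit)) unname(stats::coef(fit)) else rep(NA_real_, ncol(X))
  if (is.null(fit) || any(!is.finite(betas)) || flagged) {
    fit2 <- tryCatch(
      suppressWarnings(
        survival::coxph(surv ~ survival::ridge(X, theta = 1e-4, scale = FALSE),
                        ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit2) || any(!is.finite(stats::coef(fit2))))
      abort("Cox fit failed even with ridge fallback")
    betas <- unname(stats::coef(fit2))
    flagged <- TRUE
  }
  betas <- stats::setNames(betas, colnames(X))
  structure(list(betas = betas, risk = as.numeric(X %*% betas),
                 flagged = flagged),
            class = "cox_model")
}

#' Risk score of a fitted Cox model on new data
#'
#' @param model A `cox_model` from [fit_cox()].
#' @param X New feature matrix with the model's columns.
#' @return Numeric linear predictor.
#' @export
risk_score <- function(model, X) {
  X <- as.matrix(X)
  as.numeric(X[, names(model$betas), drop = FALSE] %*% model$betas)
}
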
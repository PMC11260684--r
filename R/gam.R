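## Penalized-spline logistic additive mortality model with a hospital random
## intercept, wrapped as the package's central S3 class `ndhri_gam`.
##
## The smooth of the exposure (mean NDHRI or proportion-in-range) is a cubic
## penalized regression spline; smoothing parameters are selected by REML and
## the hospital random intercept is realized as an i.i.d. Gaussian penalized
## effect (`s(hospital, bs = "re")`), i.e. the smooth-as-random-effect
## formulation with a single variance component. Fitting is delegated to
## mgcv; everything the class reports (curves, contrasts, nadir, smooth
## significance) is computed from the fit's coefficients and Bayesian
## covariance.

#' Fit the NDHRI mortality model
#'
#' Fits `outcome ~ s(exposure) + covariates + (1 | hospital)` as a logistic
#' (default) generalized additive model. The exposure smooth is a cubic
#' penalized regression spline with basis dimension `k` and REML smoothing
#' selection; the hospital term is a Gaussian random intercept. With
#' `adjust = FALSE` the covariates are dropped (the "unadjusted" model row)
#' while the random intercept is retained.
#'
#' @param data data.frame containing the outcome, exposure, covariates and
#'   `hospital_id`.
#' @param outcome name of the binary outcome column
#'   (`"hospital_mortality"` or `"icu_mortality"`).
#' @param exposure name of the exposure column entering through the smooth
#'   (`"mean_ndhri"` or `"prop_in_range"`).
#' @param covariates linear adjustment terms; the default is the study set
#'   age, gender, BMI and APACHE IV.
#' @param adjust if `FALSE`, fit without covariates.
#' @param random_intercept include the per-hospital Gaussian intercept. With
#'   a single hospital in `data` this is downgraded to a fixed intercept with
#'   a warning.
#' @param k basis dimension of the exposure smooth (>= 4).
#' @param bs spline basis (default `"cr"`, cubic regression spline).
#' @param link `"logit"` (default; odds-ratio contrasts are natural) or
#'   `"log"`.
#' @param method smoothing-selection criterion passed to [mgcv::gam()]
#'   (default `"REML"`).
#' @return an object of class `ndhri_gam`.
#' @seealso [predict.ndhri_gam()], [contrast_odds_ratio()], [find_nadir()],
#'   [smooth_significance()]
#' @export
ndhri_gam <- function(data, outcome = "hospital_mortality",
                      exposure = "mean_ndhri",
                      covariates = c("age", "gender", "bmi", "apache_iv"),
                      adjust = TRUE, random_intercept = TRUE,
                      k = 10, bs = "cr", link = c("logit", "log"),
                      method = "REML") {
  link <- match.arg(link)
  if (k < 4) .stopf("basis dimension k must be >= 4")
  if (!adjust) covariates <- character(0)
  need <- c(outcome, exposure, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) .stopf("data is missing column(s): %s",
                           paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[need]), , drop = FALSE]
  if (nrow(df) < 10 * k)
    warning(sprintf("only %d rows for basis dimension %d (want >= %d)",
                    nrow(df), k, 10 * k), call. = FALSE)
  df$.y <- as.numeric(df[[outcome]])
  if (!all(df$.y %in% c(0, 1))) .stopf("outcome must be binary 0/1")
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])

  use_re <- isTRUE(random_intercept)
  if (use_re) {
    if (is.null(df$hospital_id))
      .stopf("data is missing column(s): hospital_id")
    df$.hospital <- factor(df$hospital_id)
    if (nlevels(df$.hospital) < 2) {
      warning("single hospital in data; random intercept downgraded to fixed intercept",
              call. = FALSE)
      use_re <- FALSE
    }
  }

  rhs <- sprintf("s(%s, bs = \"%s\", k = %d)", exposure, bs, k)
  if (length(covariates)) rhs <- paste(rhs, paste(covariates, collapse = " + "),
                                       sep = " + ")
  if (use_re) rhs <- paste(rhs, "s(.hospital, bs = \"re\")", sep = " + ")
  fml <- as.formula(paste(".y ~", rhs))

  fit <- mgcv::gam(fml, data = df, family = binomial(link = link),
                   method = method)
  if (!fit$converged)
    .stopf("GAM did not converge (outer iterations: %s); check for separation",
           paste(fit$outer.info$iter, collapse = " "))

  ref <- df[1, , drop = FALSE]
  for (v in covariates) {
    ref[[v]] <- if (is.numeric(df[[v]])) mean(df[[v]])
                else factor(.mode_value(df[[v]]), levels = levels(df[[v]]))
  }
  if (use_re) ref$.hospital <- factor(levels(df$.hospital)[1],
                                      levels = levels(df$.hospital))

  structure(list(fit = fit, outcome = outcome, exposure = exposure,
                 covariates = covariates, link = link, k = k,
                 random_intercept = use_re,
                 exposure_range = range(df[[exposure]]),
                 ref = ref, n = nrow(df), call = match.call()),
            class = "ndhri_gam")
}

# lpmatrix at exposure values x, covariates at the reference row, with the
# random-intercept columns zeroed (population-level linear predictor).
.lpmatrix_at <- function(object, x) {
  nd <- object$ref[rep(1, length(x)), , drop = FALSE]
  nd[[object$exposure]] <- x
  X <- predict(object$fit, newdata = nd, type = "lpmatrix")
  if (object$random_intercept) {
    for (sm in object$fit$smooth) {
      if (grepl("^s\\(\\.hospital\\)", sm$label))
        X[, sm$first.para:sm$last.para] <- 0
    }
  }
  X
}

#' Predicted mortality curve with 95% confidence band
#'
#' Pointwise predictions over an exposure grid, covariates held at their
#' reference values (continuous at the cohort mean, categorical at the mode)
#' and the hospital effect at its population mean of zero. The 95% band is
#' the link-scale Wald band from the fit's Bayesian covariance, mapped
#' through the inverse link, so it stays inside (0, 1).
#'
#' @param object an `ndhri_gam`.
#' @param exposure numeric grid (default: 200 points over the observed
#'   exposure range). Values outside the observed range are refused unless
#'   `force = TRUE`.
#' @param type `"response"` (probability scale, default) or `"link"`.
#' @param level confidence level of the band.
#' @param force allow extrapolation beyond the observed exposure range.
#' @param ... unused.
#' @return data.frame `exposure`, `fit`, `se` (link scale), `lo`, `hi`.
#' @export
predict.ndhri_gam <- function(object, exposure = NULL,
                              type = c("response", "link"), level = 0.95,
                              force = FALSE, ...) {
  type <- match.arg(type)
  rng <- object$exposure_range
  if (is.null(exposure)) exposure <- seq(rng[1], rng[2], length.out = 200)
  if (!force && (min(exposure) < rng[1] - 1e-9 || max(exposure) > rng[2] + 1e-9))
    .stopf("exposure grid extends beyond the observed range [%g, %g]; use force = TRUE to extrapolate",
           rng[1], rng[2])
  X <- .lpmatrix_at(object, exposure)
  beta <- coef(object$fit)
  V <- object$fit$Vp
  eta <- as.numeric(X %*% beta)
  se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(exposure = exposure, fit = eta, se = se,
                    lo = eta - z * se, hi = eta + z * se)
  if (type == "response") {
    inv <- object$fit$family$linkinv
    out$fit <- inv(out$fit); out$lo <- inv(out$lo); out$hi <- inv(out$hi)
  }
  out
}

#' Odds-ratio contrast between two exposure values
#'
#' Compares the fitted population-level linear predictor at `x1` against
#' `x0`: `OR = exp(f(x1) - f(x0))` with a delta-method (Wald) standard error
#' from the fit's Bayesian covariance, a 95% CI, and the Wald p-value for
#' `H0: f(x1) = f(x0)`. Under the logit link this is an odds ratio; no
#' refitting is involved. Antisymmetry holds exactly:
#' `OR(x1, x0) = 1 / OR(x0, x1)`.
#'
#' @param object an `ndhri_gam`.
#' @param x1,x0 exposure values inside the fitted range (vectorized).
#' @param level confidence level.
#' @return data.frame of class `ndhri_contrast`: `x1`, `x0`, `log_or`, `se`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `wald_p`.
#' @export
contrast_odds_ratio <- function(object, x1, x0, level = 0.95) {
  stopifnot(inherits(object, "ndhri_gam"))
  if (length(x0) == 1 && length(x1) > 1) x0 <- rep(x0, length(x1))
  if (length(x1) != length(x0)) .stopf("x1 and x0 must have equal length")
  rng <- object$exposure_range
  if (any(c(x1, x0) < rng[1] - 1e-9) || any(c(x1, x0) > rng[2] + 1e-9))
    .stopf("contrast points must lie inside the fitted exposure range [%g, %g]",
           rng[1], rng[2])
  Xd <- .lpmatrix_at(object, x1) - .lpmatrix_at(object, x0)
  beta <- coef(object$fit)
  V <- object$fit$Vp
  d <- as.numeric(Xd %*% beta)
  se <- sqrt(pmax(rowSums((Xd %*% V) * Xd), 0))
  z <- qnorm(1 - (1 - level) / 2)
  p <- ifelse(se > 0, 2 * pnorm(-abs(d) / se), 1)
  out <- data.frame(x1 = x1, x0 = x0, log_or = d, se = se,
                    odds_ratio = exp(d),
                    ci_lo = exp(d - z * se), ci_hi = exp(d + z * se),
                    wald_p = p)
  class(out) <- c("ndhri_contrast", "data.frame")
  out
}

#' @export
print.ndhri_contrast <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("OR(%.3f vs %.3f) = %.2f (%.2f-%.2f), Wald p = %.3g\n",
                x$x1[i], x$x0[i], x$odds_ratio[i], x$ci_lo[i], x$ci_hi[i],
                x$wald_p[i]))
  }
  invisible(x)
}

#' Locate the nadir of the fitted risk curve
#'
#' Argmin of the fitted population-level linear predictor over a dense grid
#' spanning the observed exposure range. A nadir on the grid edge (a
#' monotone fitted curve) sets `boundary = TRUE`.
#'
#' @param object an `ndhri_gam`.
#' @param step grid step in exposure units (default 0.001).
#' @return list with `nadir`, `boundary`, `step`.
#' @export
find_nadir <- function(object, step = 0.001) {
  stopifnot(inherits(object, "ndhri_gam"))
  rng <- object$exposure_range
  grid <- seq(rng[1], rng[2], by = step)
  eta <- as.numeric(.lpmatrix_at(object, grid) %*% coef(object$fit))
  i <- which.min(eta)
  list(nadir = grid[i], boundary = i == 1L || i == length(grid), step = step)
}

#' Significance of the exposure smooth
#'
#' Approximate p-value for the exposure smooth term against the constant
#' null, using the fit's Bayesian covariance and effective degrees of
#' freedom (the standard test reported by [mgcv::summary.gam()]).
#'
#' @param object an `ndhri_gam`.
#' @return the p-value (numeric scalar).
#' @export
smooth_significance <- function(object) {
  stopifnot(inherits(object, "ndhri_gam"))
  st <- summary(object$fit)$s.table
  row <- grep(sprintf("^s\\(%s\\)", object$exposure), rownames(st))
  if (!length(row)) .stopf("no smooth term for exposure '%s'", object$exposure)
  unname(st[row[1], "p-value"])
}

#' Estimated hospital random-intercept SD
#'
#' For the `s(hospital, bs = "re")` formulation with a binomial outcome the
#' random-effect SD is `1 / sqrt(lambda)` with `lambda` the term's smoothing
#' parameter.
#'
#' @param object an `ndhri_gam`.
#' @return the SD in log-odds units, or `NA` if no random intercept.
#' @export
random_intercept_sd <- function(object) {
  stopifnot(inherits(object, "ndhri_gam"))
  if (!object$random_intercept) return(NA_real_)
  sp <- object$fit$sp
  i <- grep("\\.hospital", names(sp))
  if (!length(i)) return(NA_real_)
  sqrt(1 / sp[[i[1]]])
}

#' @export
print.ndhri_gam <- function(x, ...) {
  cat(sprintf("NDHRI mortality GAM (%s link): %s ~ s(%s)%s%s\n",
              x$link, x$outcome, x$exposure,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              if (x$random_intercept) " + (1 | hospital)" else ""))
  st <- summary(x$fit)$s.table
  cat(sprintf("  n = %d, smooth edf = %.2f, smooth p = %.3g\n",
              x$n, st[1, "edf"], smooth_significance(x)))
  invisible(x)
}

#' @export
summary.ndhri_gam <- function(object, ...) {
  nad <- find_nadir(object)
  out <- list(model = object, nadir = nad,
              smooth_p = smooth_significance(object),
              re_sd = random_intercept_sd(object),
              mgcv_summary = summary(object$fit))
  class(out) <- "summary.ndhri_gam"
  out
}

#' @export
print.summary.ndhri_gam <- function(x, ...) {
  print(x$model)
  cat(sprintf("  nadir: %.3f%s\n", x$nadir$nadir,
              if (x$nadir$boundary) " (at boundary)" else ""))
  if (!is.na(x$re_sd))
    cat(sprintf("  hospital random-intercept SD: %.3f\n", x$re_sd))
  cat("\n")
  print(x$mgcv_summary)
  invisible(x)
}

#' @export
coef.ndhri_gam <- function(object, ...) coef(object$fit)

#' @export
vcov.ndhri_gam <- function(object, ...) object$fit$Vp

#' @export
residuals.ndhri_gam <- function(object, type = "deviance", ...) {
  residuals(object$fit, type = type)
}

#' @export
simulate.ndhri_gam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fit$fitted.values
  out <- as.data.frame(replicate(nsim, rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ndhri_gam <- function(x, n_grid = 200, ...) {
  cur <- predict(x)
  graphics::plot(cur$exposure, cur$fit, type = "n",
                 ylim = range(cur$lo, cur$hi),
                 xlab = x$exposure, ylab = sprintf("P(%s)", x$outcome), ...)
  graphics::polygon(c(cur$exposure, rev(cur$exposure)),
                    c(cur$lo, rev(cur$hi)),
                    col = "grey85", border = NA)
  graphics::lines(cur$exposure, cur$fit, lwd = 2)
  invisible(cur)
}
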
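# Polynomial repeated-measures regression of FFMQ-SF outcomes on a single
# engagement predictor: linear mixed model with a per-installation random
# intercept, fixed effects an orthogonal polynomial of the predictor
# (coefficients reported on the raw power-basis scale), REML estimation.
# One model per predictor: the engagement measures are strongly collinear,
# so joint models are deliberately not offered.

OUTCOME_VARS <- c("total", "observing", "acting_with_awareness",
                  "nonjudging", "nonreactivity")
PREDICTOR_VARS <- c("weeks_since_install", "active_minutes", "n_visits",
                    "n_events", "level_achieved", "log_active_minutes")

#' Assemble the occasion-level analysis table
#'
#' Joins scored assessment occasions to engagement profiles: one row per
#' occasion carrying the outcome scores, weeks since install, and the
#' engagement predictors.  Two predictor conventions are available:
#' end-of-study `"totals"` (each occasion carries the user's final totals;
#' the convention used for descriptive replication) and
#' `"cumulative"` (engagement accrued up to the occasion timestamp; the
#' causally cleaner option, requires `sess`).
#'
#' @param scores `ffmq_scores` from [extract_assessments()].
#' @param profiles profile table from [compute_profiles()].
#' @param mode `"totals"` or `"cumulative"`.
#' @param sess the `sessionized` object (required for `"cumulative"`).
#' @return data.frame, one row per occasion; attribute `n_users_unscored`
#'   counts profiled users contributing no occasion.  Orphan scores (no
#'   matching profile) are an error.
#' @export
assemble_long_table <- function(scores, profiles,
                                mode = c("totals", "cumulative"),
                                sess = NULL) {
  mode <- match.arg(mode)
  orphans <- setdiff(scores$install_id, profiles$install_id)
  if (length(orphans)) {
    stop(sprintf("score(s) with no engagement profile: %s",
                 paste(utils::head(orphans, 10L), collapse = ", ")))
  }
  i <- match(scores$install_id, profiles$install_id)
  out <- as.data.frame(scores)
  if (mode == "totals") {
    out$active_minutes <- profiles$active_minutes[i]
    out$n_visits <- profiles$n_visits[i]
    out$n_events <- profiles$n_events[i]
    out$level_achieved <- profiles$level_achieved[i]
  } else {
    if (is.null(sess)) stop("cumulative mode requires the sessionized stream")
    ev <- sess$events
    ord <- order(ev$install_id, ev$timestamp_ms, method = "radix")
    ev <- ev[ord, , drop = FALSE]
    cum_min <- group_cumsum(ev$capped_s * ev$countable, ev$install_id) / 60
    cum_ev <- group_cumsum(as.numeric(ev$countable), ev$install_id)
    key_ev <- paste0(ev$install_id, "\r")
    upto <- function(values) {
      vapply(seq_len(nrow(out)), function(k) {
        sel <- ev$install_id == out$install_id[k] &
          ev$timestamp_ms <= out$timestamp_ms[k]
        if (!any(sel)) return(0)
        values[max(which(sel))]
      }, numeric(1))
    }
    out$active_minutes <- upto(cum_min)
    out$n_events <- upto(cum_ev)
    out$n_visits <- upto(ev$visit_index)
    out$level_achieved <- out$level_at_assessment
  }
  out$log_active_minutes <- log1p(out$active_minutes)
  n_unscored <- sum(!profiles$install_id %in% scores$install_id)
  if (n_unscored > 0L) {
    message(sprintf("assemble_long_table: %d profiled user(s) have no scored occasion",
                    n_unscored))
  }
  attr(out, "n_users_unscored") <- n_unscored
  class(out) <- "data.frame"
  out
}

# Transform orthogonal-basis fixed effects (gamma, Vgamma) to raw
# power-basis coefficients.  Both bases span the same polynomials, so the
# map is exact: evaluate both designs at degree+1 distinct points and solve.
raw_from_orth <- function(poly_obj, gamma, vgamma, degree, x_range) {
  pts <- seq(x_range[1], x_range[2], length.out = degree + 1L)
  if (degree == 0L) pts <- x_range[1]
  Xr <- outer(pts, 0:degree, `^`)
  Z <- cbind(1, stats::predict(poly_obj, pts))
  M <- solve(Xr, Z)
  beta <- drop(M %*% gamma)
  V <- M %*% vgamma %*% t(M)
  names(beta) <- c("(Intercept)", paste0("x^", seq_len(degree)))[seq_len(degree + 1L)]
  list(beta = beta, V = V)
}

#' Fit a polynomial repeated-measures model
#'
#' Regresses an FFMQ-SF outcome on an orthogonal polynomial of one
#' engagement predictor with a random intercept per installation
#' (REML, via \pkg{lme4}).  When fewer than two installations contribute
#' two or more occasions the random intercept is unidentifiable and the fit
#' falls back to a single-level linear model with a warning.  Coefficients
#' are reported on the raw power-basis scale with exact covariance
#' transform; per-term p-values are Wald z tests.
#'
#' @param data occasion-level table from [assemble_long_table()].
#' @param outcome one of `r paste0('\x60', OUTCOME_VARS, '\x60', collapse = ", ")`.
#' @param predictor one of the engagement predictors (see
#'   [assemble_long_table()]); `log_active_minutes` is `log1p` of active
#'   minutes, appropriate for the heavily right-skewed dose.
#' @param degree polynomial degree, 1-3.
#' @param r2_method pseudo-R-squared definition, see [r_squared()].
#' @return object of class `ffmq_fit`.
#' @export
fit_polynomial <- function(data, outcome = "total",
                           predictor = "weeks_since_install", degree = 1L,
                           r2_method = c("corr", "variance")) {
  r2_method <- match.arg(r2_method)
  outcome <- match.arg(outcome, OUTCOME_VARS)
  predictor <- match.arg(predictor, PREDICTOR_VARS)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  y <- data[[outcome]]
  x <- data[[predictor]]
  keep <- stats::complete.cases(y, x, data$install_id)
  y <- y[keep]; x <- x[keep]
  id <- data$install_id[keep]
  n_distinct <- length(unique(x))
  if (n_distinct < degree + 2L) {
    stop(sprintf("need at least %d distinct predictor values for degree %d (have %d)",
                 degree + 2L, degree, n_distinct))
  }
  if (stats::var(y) == 0) stop("outcome has zero variance")
  occ_per_user <- table(id)
  mixed <- sum(occ_per_user >= 2L) >= 2L
  P <- stats::poly(x, degree)
  df_fit <- data.frame(y = y, install_id = id)
  pn <- paste0("P", seq_len(degree))
  for (j in seq_len(degree)) df_fit[[pn[j]]] <- P[, j]
  label <- sprintf("%s ~ poly(%s, %d)", outcome, predictor, degree)

  if (mixed) {
    form <- stats::as.formula(paste("y ~", paste(pn, collapse = " + "),
                                    "+ (1 | install_id)"))
    fit <- tryCatch(
      lme4::lmer(form, data = df_fit, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) stop(sprintf("mixed-model fit failed for %s: %s",
                                       label, conditionMessage(e)), call. = FALSE)
    )
    gamma <- lme4::fixef(fit)
    vg <- as.matrix(stats::vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == "install_id"]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    fixed_pred <- drop(cbind(1, P) %*% gamma)
  } else {
    warning("fewer than 2 installations with repeated occasions; fitting a single-level model",
            call. = FALSE)
    form <- stats::as.formula(paste("y ~", paste(pn, collapse = " + ")))
    fit <- stats::lm(form, data = df_fit)
    gamma <- stats::coef(fit)
    vg <- stats::vcov(fit)
    tau2 <- 0
    sigma2 <- summary(fit)$sigma^2
    fixed_pred <- stats::fitted(fit)
  }

  raw <- raw_from_orth(P, gamma, vg, degree, range(x))
  se <- sqrt(diag(raw$V))
  z <- raw$beta / se
  pvals <- 2 * stats::pnorm(-abs(z))

  r2 <- if (r2_method == "corr") {
    stats::cor(y, fixed_pred)^2
  } else {
    stats::var(fixed_pred) / (stats::var(fixed_pred) + tau2 + sigma2)
  }

  structure(list(
    coefficients = raw$beta, vcov = raw$V, se = se, z = z, p_values = pvals,
    gamma = gamma, vcov_gamma = vg, poly = P, degree = degree,
    outcome = outcome, predictor = predictor, mixed = mixed,
    ranef_var = tau2, resid_var = sigma2,
    r_squared = r2, r2_method = r2_method,
    n_occasions = length(y), n_users = length(occ_per_user),
    x = x, y = y, fixed_pred = fixed_pred, fit = fit, label = label
  ), class = "ffmq_fit")
}

#' Marginal pseudo-R-squared of a fitted model
#'
#' With a mixed model the familiar R-squared is undefined; two marginal
#' definitions are offered.  `"corr"` (default): squared correlation
#' between observed outcomes and fixed-effect predictions.  `"variance"`:
#' fixed-effect variance over total variance
#' (fixed + random intercept + residual), the variance-decomposition
#' marginal pseudo-R-squared.
#'
#' @param fit an `ffmq_fit`.
#' @param method `"corr"` or `"variance"`; default is whatever the fit was
#'   created with.
#' @return proportion in `[0, 1]`.
#' @export
r_squared <- function(fit, method = NULL) {
  stopifnot(inherits(fit, "ffmq_fit"))
  method <- method %||% fit$r2_method
  method <- match.arg(method, c("corr", "variance"))
  if (method == "corr") {
    if (stats::var(fit$fixed_pred) == 0) return(0)
    stats::cor(fit$y, fit$fixed_pred)^2
  } else {
    v <- stats::var(fit$fixed_pred)
    v / (v + fit$ranef_var + fit$resid_var)
  }
}

#' @method print ffmq_fit
#' @export
print.ffmq_fit <- function(x, ...) {
  cat(sprintf("<ffmq_fit> %s\n", x$label))
  cat(sprintf("  %s, %d occasions / %d users\n",
              if (x$mixed) "random intercept per installation (REML)"
              else "single-level (no repeated occasions)",
              x$n_occasions, x$n_users))
  cat(sprintf("  R^2 (%s) = %.3f\n", x$r2_method, x$r_squared))
  cat("  raw-scale coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @method summary ffmq_fit
#' @export
summary.ffmq_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients, se = object$se, z = object$z,
    p_value = object$p_values
  )
  out <- list(label = object$label, table = tab,
              ranef_var = object$ranef_var, resid_var = object$resid_var,
              r_squared = object$r_squared, r2_method = object$r2_method,
              n_occasions = object$n_occasions, n_users = object$n_users,
              mixed = object$mixed)
  class(out) <- "summary.ffmq_fit"
  out
}

#' @method print summary.ffmq_fit
#' @export
print.summary.ffmq_fit <- function(x, ...) {
  cat(sprintf("Polynomial repeated-measures fit: %s\n", x$label))
  cat(sprintf("%d occasions, %d users; %s\n", x$n_occasions, x$n_users,
              if (x$mixed) "random intercept per installation" else "single-level"))
  stats::printCoefmat(as.matrix(x$table), P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Random-intercept variance %.3f, residual variance %.3f\n",
              x$ranef_var, x$resid_var))
  cat(sprintf("R^2 (%s) = %.3f\n", x$r2_method, x$r_squared))
  invisible(x)
}

#' @export
coef.ffmq_fit <- function(object, ...) object$coefficients

#' @export
vcov.ffmq_fit <- function(object, ...) object$vcov

#' Fixed-effect predictions from a fitted polynomial model
#'
#' @param object an `ffmq_fit`.
#' @param newdata optional: numeric vector of predictor values, or a
#'   data.frame containing the predictor column.  Defaults to the fitted
#'   values at the training predictor values.
#' @param ... unused.
#' @return numeric vector of fixed-effect (population-level) predictions.
#' @export
predict.ffmq_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fixed_pred)
  x <- if (is.data.frame(newdata)) newdata[[object$predictor]] else newdata
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
residuals.ffmq_fit <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  if (type == "marginal" || !object$mixed) return(object$y - object$fixed_pred)
  object$y - stats::fitted(object$fit)
}

#' @export
plot.ffmq_fit <- function(x, n_grid = 200, ...) {
  xr <- range(x$x)
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("grey40", 0.5),
                 xlab = x$predictor, ylab = x$outcome,
                 main = x$label, ...)
  graphics::lines(grid, predict(x, grid), lwd = 2, col = "firebrick")
  invisible(x)
}

#' Derivative of the fitted polynomial
#'
#' Evaluates the first derivative of the fixed-effect polynomial at given
#' predictor values: the instantaneous change in the outcome per predictor
#' unit.  Used to check fitted trend shapes (e.g. rise / plateau / rise).
#'
#' @param fit an `ffmq_fit`.
#' @param x predictor values.
#' @return numeric vector of derivatives.
#' @export
fitted_derivative <- function(fit, x) {
  stopifnot(inherits(fit, "ffmq_fit"))
  b <- fit$coefficients[-1L]
  k <- seq_along(b)
  drop(outer(x, k - 1L, `^`) %*% (b * k))
}

#' Fit the full model battery
#'
#' Runs the reported model grid: a cubic time model for the total score and
#' each subscale, plus a model (default linear) of the total score on each
#' engagement predictor.  Per-model failures are captured, not propagated.
#'
#' @param data occasion-level table from [assemble_long_table()].
#' @param time_degree degree for the time-since-install models (default 3).
#' @param engagement_degree degree for the engagement models (default 1).
#' @param engagement_predictors predictors for the engagement models.
#' @param r2_method passed to [fit_polynomial()].
#' @return list of class `ffmq_battery`: `results` (one row per model and
#'   term: outcome, predictor, degree, term, estimate, se, p_value,
#'   r_squared, n_occasions, n_users, error) and `fits` (named list of
#'   `ffmq_fit` or `NULL` for failed cells).
#' @export
fit_battery <- function(data, time_degree = 3L, engagement_degree = 1L,
                        engagement_predictors = c("active_minutes", "n_visits",
                                                  "n_events", "level_achieved"),
                        r2_method = "corr") {
  grid <- rbind(
    data.frame(outcome = OUTCOME_VARS, predictor = "weeks_since_install",
               degree = time_degree, stringsAsFactors = FALSE),
    data.frame(outcome = "total", predictor = engagement_predictors,
               degree = engagement_degree, stringsAsFactors = FALSE)
  )
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    nm <- sprintf("%s~%s", g$outcome, g$predictor)
    res <- tryCatch(
      fit_polynomial(data, outcome = g$outcome, predictor = g$predictor,
                     degree = g$degree, r2_method = r2_method),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        outcome = g$outcome, predictor = g$predictor, degree = g$degree,
        term = NA_character_, estimate = NA_real_, se = NA_real_,
        p_value = NA_real_, r_squared = NA_real_,
        n_occasions = NA_integer_, n_users = NA_integer_,
        error = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(
        outcome = g$outcome, predictor = g$predictor, degree = g$degree,
        term = names(res$coefficients), estimate = unname(res$coefficients),
        se = res$se, p_value = res$p_values, r_squared = res$r_squared,
        n_occasions = res$n_occasions, n_users = res$n_users,
        error = NA_character_, stringsAsFactors = FALSE
      )
    }
    names(fits)[i] <- nm
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fits = fits), class = "ffmq_battery")
}

#' @method print ffmq_battery
#' @export
print.ffmq_battery <- function(x, ...) {
  ok <- !vapply(x$fits, is.null, logical(1))
  cat(sprintf("<ffmq_battery> %d model(s), %d failed\n", length(ok), sum(!ok)))
  r2 <- unique(x$results[, c("outcome", "predictor", "degree", "r_squared")])
  print(r2, row.names = FALSE)
  invisible(x)
}
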
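## design matrix of the continuous piecewise-linear model with hinge
## terms at the breakpoints psi
.hinge_design <- function(x, psi) {
  cbind(1, x, vapply(psi, function(p) pmax(x - p, 0), numeric(length(x))))
}

.seg_ls <- function(x, y, psi) {
  X <- .hinge_design(x, psi)
  fit <- stats::lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  list(coef = fit$coefficients, sse = sse, fitted = fit$fitted.values)
}

#' Exhaustive-search oracle for two breakpoints
#'
#' Brute-force global least squares of the continuous two-breakpoint
#' piecewise-linear model over all candidate breakpoint pairs on a grid
#' (quantile-spaced by default). Slow but exact on its grid; used as the
#' verification oracle for [fit_segmented()].
#'
#' @param x,y data (y typically log-odds on an x grid).
#' @param n_grid candidate points per axis (default 40, capped at 200).
#' @param grid optional explicit vector of candidate breakpoints.
#' @param min_sep minimum breakpoint separation (default one grid step).
#' @return list with `bp1`, `bp2`, `sse`.
#' @export
brute_force_breakpoints <- function(x, y, n_grid = 40, grid = NULL,
                                    min_sep = NULL) {
  if (is.null(grid)) {
    n_grid <- min(n_grid, 200)
    grid <- unique(stats::quantile(x, probs = seq(0.02, 0.98,
                                                  length.out = n_grid),
                                   names = FALSE))
  }
  if (is.null(min_sep)) min_sep <- min(diff(sort(grid)))
  best <- list(sse = Inf)
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] - grid[i] < min_sep) next
      f <- .seg_ls(x, y, c(grid[i], grid[j]))
      if (f$sse < best$sse)
        best <- list(bp1 = grid[i], bp2 = grid[j], sse = f$sse)
    }
  }
  best
}

#' Two-breakpoint segmented regression
#'
#' Continuous piecewise-linear least squares with estimated breakpoints,
#' by iterative linearization (the gap-variable update): at the current
#' breakpoints the model is refitted with hinge terms
#' \eqn{(x-\psi_k)_+} and indicator terms \eqn{-I(x>\psi_k)}, and each
#' breakpoint moves by (indicator coefficient)/(hinge coefficient), with
#' step halving when the SSE would worsen. Initialization is a coarse
#' grid search over quantile-spaced candidate pairs. Breakpoint CIs use
#' the delta method, \eqn{SE(\psi_k) = SE(\gamma_k)/|\beta_k|}.
#'
#' @param x ordered covariate grid (>= 20 points).
#' @param y response (log-odds predictions in the intended use).
#' @param n_breakpoints must be 2 (the supported model).
#' @param init_grid candidate points per axis for initialization
#'   (default 20).
#' @param max_iter maximum linearization iterations (default 50).
#' @param tol convergence tolerance on breakpoint movement (default
#'   1e-8).
#' @return object of class `segmented_fit`: list with `breakpoints`,
#'   `ci_bp1`, `ci_bp2`, `slopes` (three segment slopes), `intercept`,
#'   `r_squared`, `relative_se` (residual SE / mean |fitted|),
#'   `converged`, `sse`, `fitted`.
#' @export
fit_segmented <- function(x, y, n_breakpoints = 2, init_grid = 20,
                          max_iter = 50, tol = 1e-8) {
  if (n_breakpoints != 2)
    stop("only the two-breakpoint model is supported")
  if (length(x) < 20) stop("need >= 20 points")
  o <- order(x); x <- x[o]; y <- y[o]
  ## degenerate input: a straight line has no identifiable breakpoints
  line <- stats::lm.fit(cbind(1, x), y)
  sse_line <- sum(line$residuals^2)
  sst <- sum((y - mean(y))^2)
  init <- brute_force_breakpoints(x, y, n_grid = init_grid)
  if (sse_line <= sst * 1e-12 ||
      (sse_line - init$sse) <= sse_line * 1e-9)
    stop("input is indistinguishable from a single line: ",
         "no identifiable breakpoints")
  psi <- c(init$bp1, init$bp2)
  grid_step <- min(diff(sort(unique(stats::quantile(
    x, seq(0.02, 0.98, length.out = init_grid), names = FALSE)))))
  sse_cur <- init$sse
  converged <- FALSE
  rng <- range(x)
  for (it in seq_len(max_iter)) {
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
    V <- vapply(psi, function(p) -as.numeric(x > p), numeric(length(x)))
    X <- cbind(1, x, U, V)
    f <- stats::lm.fit(X, y)
    beta_u <- f$coefficients[3:4]
    gamma_v <- f$coefficients[5:6]
    gamma_v[is.na(gamma_v)] <- 0
    if (any(is.na(beta_u)) || any(abs(beta_u) < 1e-12)) break
    step <- gamma_v / beta_u
    ## step halving: accept the largest fraction that improves the SSE
    ## and keeps the breakpoints ordered inside the data range
    improved <- FALSE
    frac <- 1
    for (h in 1:8) {
      cand <- sort(psi + frac * step)
      if (cand[1] > rng[1] && cand[2] < rng[2] &&
          (cand[2] - cand[1]) > .Machine$double.eps) {
        sse_new <- .seg_ls(x, y, cand)$sse
        if (sse_new <= sse_cur + 1e-12) {
          if (max(abs(cand - psi)) < tol) {
            psi <- cand; sse_cur <- sse_new; converged <- TRUE
          } else {
            psi <- cand; sse_cur <- sse_new
          }
          improved <- TRUE
          break
        }
      }
      frac <- frac / 2
    }
    if (converged || !improved) {
      if (!improved && max(abs(step)) < tol) converged <- TRUE
      break
    }
  }
  if (psi[2] - psi[1] < grid_step * 1e-3)
    stop("breakpoints collapsed (separation below the grid step)")
  psi <- unname(psi)
  ## final fit and uncertainty at the converged breakpoints
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
  V <- vapply(psi, function(p) -as.numeric(x > p), numeric(length(x)))
  Xfull <- cbind(1, x, U, V)
  ffull <- stats::lm.fit(Xfull, y)
  cf <- ffull$coefficients
  sigma2 <- sum(ffull$residuals^2) / max(length(x) - ncol(Xfull), 1)
  Vc <- tryCatch(chol2inv(chol(crossprod(Xfull))) * sigma2,
                 error = function(e) matrix(NA_real_, 6, 6))
  beta_u <- cf[3:4]
  se_gamma <- sqrt(diag(Vc)[5:6])
  se_psi <- se_gamma / abs(beta_u)
  f <- .seg_ls(x, y, psi)
  n <- length(x)
  p_eff <- 6 # intercept + slope + 2 hinge coefs + 2 breakpoints
  sse <- f$sse
  r2 <- 1 - sse / sst
  res_se <- sqrt(sse / max(n - p_eff, 1))
  slopes <- cumsum(c(f$coef[2], f$coef[3], f$coef[4]))
  structure(list(breakpoints = psi,
                 ci_bp1 = psi[1] + c(-1.96, 1.96) * se_psi[1],
                 ci_bp2 = psi[2] + c(-1.96, 1.96) * se_psi[2],
                 slopes = unname(slopes), intercept = unname(f$coef[1]),
                 r_squared = r2,
                 relative_se = res_se / mean(abs(f$fitted)),
                 converged = converged, sse = sse, fitted = f$fitted,
                 x = x),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Segmented fit: breakpoints %.3f [%.3f, %.3f] and %.3f [%.3f, %.3f]\n",
    x$breakpoints[1], x$ci_bp1[1], x$ci_bp1[2],
    x$breakpoints[2], x$ci_bp2[1], x$ci_bp2[2]))
  cat(sprintf("  slopes %.3f / %.3f / %.3f; R2 = %.4f, relative SE = %.4f%s\n",
              x$slopes[1], x$slopes[2], x$slopes[3], x$r_squared,
              x$relative_se,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Percent gap between the two ecological thresholds
#'
#' `100 * (stable - crit) / crit`: how much higher the stable threshold
#' sits above the critical one.
#'
#' @param crit lower threshold (> 0).
#' @param stable upper threshold.
#' @return percent difference.
#' @examples
#' percent_between(2.82, 3.81) # ~35.1
#' @export
percent_between <- function(crit, stable) {
  if (any(crit <= 0)) stop("crit must be > 0")
  100 * (stable - crit) / crit
}

#' Estimate ecological thresholds from a fitted fitness model
#'
#' Composes the two-stage threshold procedure: extract the log-odds
#' prediction curve of the fitness outcome over the metabolic-index grid
#' (other covariates at their means, random intercepts zero), then fit
#' the two-breakpoint segmented regression to it. The lower breakpoint is
#' phi_crit, the upper phi_stable.
#'
#' @param fit a `binsmooth` fitness model containing a smooth of
#'   `variable`.
#' @param variable name of the metabolic-index column (default "phi").
#' @param grid_size prediction-grid size (default 200).
#' @param averaging passed to [predict_curve()].
#' @param ... passed to [fit_segmented()].
#' @return object of class `threshold_pair`: list with `crit`, `stable`,
#'   `ci_crit`, `ci_stable`, `r_squared`, `relative_se`, `percent_gap`,
#'   `segmented`, `curve`.
#' @export
estimate_thresholds <- function(fit, variable = "phi", grid_size = 200,
                                averaging = "means", ...) {
  curve <- predict_curve(fit, variable, grid_size = grid_size,
                         averaging = averaging)
  sf <- fit_segmented(curve$value, curve$log_odds, 2, ...)
  structure(list(crit = sf$breakpoints[1], stable = sf$breakpoints[2],
                 ci_crit = sf$ci_bp1, ci_stable = sf$ci_bp2,
                 r_squared = sf$r_squared, relative_se = sf$relative_se,
                 percent_gap = percent_between(sf$breakpoints[1],
                                               sf$breakpoints[2]),
                 segmented = sf, curve = curve),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "Thresholds: crit = %.3f [%.3f, %.3f], stable = %.3f [%.3f, %.3f]\n",
    x$crit, x$ci_crit[1], x$ci_crit[2], x$stable, x$ci_stable[1],
    x$ci_stable[2]))
  cat(sprintf("  stable is %.0f%% above crit; segmented R2 = %.4f, relative SE = %.4f\n",
              x$percent_gap, x$r_squared, x$relative_se))
  invisible(x)
}
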
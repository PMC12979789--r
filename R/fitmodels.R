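#' Build a penalized spline basis
#'
#' Constructs a spline evaluation matrix and its curvature (integrated
#' squared second derivative) penalty. For `kind = "cubic"` the basis is a
#' B-spline basis of degree `min(3, k - 1)` with interior knots at
#' quantiles of `x` (so `k = 3` spans exactly the quadratics and any
#' `k >= 4` is a cubic spline space); the penalty is computed by
#' trapezoidal quadrature of the second-derivative Gram matrix and is
#' exactly zero on coefficient vectors representing linear functions.
#' For `kind = "cyclic"` a cyclic cubic spline basis (mgcv) is returned.
#'
#' @param x covariate values (non-degenerate).
#' @param k basis dimension (>= 3; at most the number of unique x).
#' @param kind "cubic" (default) or "cyclic".
#' @return list with `X` (n x k evaluation matrix), `S` (k x k penalty),
#'   `knots`, `degree`, `kind`.
#' @export
build_spline_basis <- function(x, k, kind = c("cubic", "cyclic")) {
  kind <- match.arg(kind)
  if (k < 3) stop("k must be >= 3")
  ux <- unique(x)
  if (length(ux) < k)
    stop("fewer unique x values (", length(ux), ") than basis dimension ",
         k)
  if (kind == "cyclic") {
    sm <- mgcv::smoothCon(mgcv::s(x, bs = "cc", k = k),
                          data = data.frame(x = x), absorb.cons = FALSE)[[1]]
    return(list(X = sm$X, S = sm$S[[1]], knots = sm$xp, degree = 3,
                kind = kind))
  }
  degree <- min(3L, k - 1L)
  ord <- degree + 1L
  n_int <- k - ord
  rng <- range(x)
  interior <- if (n_int > 0)
    stats::quantile(x, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
  else numeric(0)
  knots <- c(rep(rng[1], ord), interior, rep(rng[2], ord))
  X <- splines::splineDesign(knots, x, ord = ord)
  tt <- seq(rng[1], rng[2], length.out = 1001)
  D2 <- splines::splineDesign(knots, tt, ord = ord, derivs = 2)
  w <- rep(diff(tt)[1], length(tt)); w[c(1, length(tt))] <- w[1] / 2
  S <- crossprod(D2 * sqrt(w))
  list(X = X, S = (S + t(S)) / 2, knots = knots, degree = degree,
       kind = kind)
}

#' Specify a binomial smooth model
#'
#' Lightweight specification consumed by [fit_binomial_smooth()].
#'
#' @param outcome name of the binary (0/1) outcome column.
#' @param smooths named list: one element per smooth term, each a list
#'   with optional `k` (default 7) and `bs` ("cr" cubic regression
#'   spline, default, or "cc" cyclic). Names are covariate columns.
#' @param parametric character vector of linear-term columns.
#' @param interactions list of length-2 character vectors; each pair
#'   (a, b) adds the product of the two centered covariates as a single
#'   parametric term (the "parametric interaction" between two smooths).
#' @param random character vector of grouping columns to receive random
#'   intercepts (penalized group dummies).
#' @return object of class `smooth_model_spec`.
#' @export
smooth_model_spec <- function(outcome, smooths = list(),
                              parametric = character(),
                              interactions = list(),
                              random = character()) {
  if (is.character(smooths)) {
    smooths <- stats::setNames(rep(list(list()), length(smooths)), smooths)
  }
  smooths <- lapply(smooths, function(s) {
    s$k <- if (is.null(s$k)) 7L else as.integer(s$k)
    s$bs <- if (is.null(s$bs)) "cr" else s$bs
    if (s$k < 3) stop("each smooth needs k >= 3")
    s
  })
  structure(list(outcome = outcome, smooths = smooths,
                 parametric = parametric, interactions = interactions,
                 random = random),
            class = "smooth_model_spec")
}

.interaction_name <- function(pair) paste0(pair[1], "_x_", pair[2])

#' Fit a binomial smooth model with random intercepts
#'
#' Penalized binomial-logit regression: cubic regression spline smooths
#' (penalty selection by REML), parametric terms including centered
#' product interactions, and random intercepts as ridge-penalized group
#' dummies (`s(., bs = "re")`, equivalent to Gaussian random effects).
#' BIC is computed at the effective degrees of freedom (trace of the
#' influence matrix).
#'
#' @param data data.frame holding every column named in `spec`.
#' @param spec a [smooth_model_spec()].
#' @param method penalty-selection criterion, default "REML".
#' @param sp optional fixed smoothing-parameter vector (mgcv order);
#'   `NULL` (default) selects penalties by `method`.
#' @return object of class `binsmooth`: list with `model` (the mgcv fit),
#'   `spec`, `bic`, `edf`, `r2_dev`, `n`, `centers` (interaction centering
#'   constants), `data`.
#' @export
fit_binomial_smooth <- function(data, spec, method = "REML", sp = NULL) {
  y <- data[[spec$outcome]]
  if (is.null(y)) stop("outcome column '", spec$outcome, "' not found")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2)
    stop("outcome is constant: complete separation; the model is not ",
         "estimable (consider increasing the penalty or pooling data)")
  centers <- list()
  for (pair in spec$interactions) {
    cn <- .interaction_name(pair)
    mu <- c(mean(data[[pair[1]]]), mean(data[[pair[2]]]))
    centers[[cn]] <- mu
    data[[cn]] <- (data[[pair[1]]] - mu[1]) * (data[[pair[2]]] - mu[2])
  }
  for (g in spec$random) data[[g]] <- factor(data[[g]])
  terms <- c(
    vapply(names(spec$smooths), function(v)
      sprintf("s(%s, bs = \"%s\", k = %d)", v, spec$smooths[[v]]$bs,
              spec$smooths[[v]]$k), character(1)),
    spec$parametric,
    vapply(spec$interactions, .interaction_name, character(1)),
    vapply(spec$random, function(g) sprintf("s(%s, bs = \"re\")", g),
           character(1)))
  f <- stats::reformulate(terms, response = spec$outcome)
  m <- mgcv::gam(f, family = stats::binomial(), data = data,
                 method = method, sp = sp)
  if (!m$converged)
    stop("penalized IRLS did not converge; outer iteration info: ",
         paste(utils::capture.output(m$outer.info), collapse = " "))
  mu <- stats::fitted(m)
  if (all(mu < 1e-8 | mu > 1 - 1e-8))
    stop("fitted probabilities pinned at 0/1: separation; ",
         "increase the penalty or simplify the model")
  structure(list(model = m, spec = spec, bic = stats::BIC(m),
                 edf = sum(m$edf), r2_dev = 1 - m$deviance / m$null.deviance,
                 n = length(y), centers = centers, data = data),
            class = "binsmooth")
}

#' @export
print.binsmooth <- function(x, ...) {
  cat(sprintf(
    "Binomial smooth model: n = %d, edf = %.1f, BIC = %.1f, deviance R2 = %.3f\n",
    x$n, x$edf, x$bic, x$r2_dev))
  invisible(x)
}

## probability clipping bounds used before logit transforms
.p_eps <- 1e-6

#' Prediction curve over one covariate
#'
#' Predicted probability and log-odds of the outcome over an evenly
#' spaced grid spanning the observed range of `variable`, with other
#' covariates fixed at their training means (`averaging = "means"`) or
#' marginalized over their empirical distribution
#' (`averaging = "marginal"`), and random intercepts set to zero. 95%
#' intervals come from the coefficient covariance on the link scale and
#' are mapped through the inverse link; probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` before any logit transform.
#'
#' @param fit a `binsmooth` fit.
#' @param variable covariate to vary (must carry a smooth or parametric
#'   term).
#' @param grid_size number of grid points, default 200.
#' @param averaging "means" (default) or "marginal".
#' @param range optional length-2 grid range; defaults to the observed
#'   range. Requests beyond the observed range are refused unless
#'   `force = TRUE`.
#' @param force allow extrapolation beyond the observed range.
#' @return a `prediction_curve` data.frame: `value`, `log_odds`,
#'   `log_odds_lo`, `log_odds_hi`, `prob`, `prob_lo`, `prob_hi`, with
#'   attributes `variable` and `averaging`.
#' @export
predict_curve <- function(fit, variable, grid_size = 200,
                          averaging = c("means", "marginal"),
                          range = NULL, force = FALSE) {
  averaging <- match.arg(averaging)
  d <- fit$data
  if (!variable %in% names(d)) stop("variable '", variable, "' not found")
  obs_rng <- base::range(d[[variable]])
  if (is.null(range)) range <- obs_rng
  if (!force && (range[1] < obs_rng[1] - 1e-12 ||
                 range[2] > obs_rng[2] + 1e-12))
    stop("requested grid extrapolates beyond the observed range of '",
         variable, "'; use force = TRUE to override")
  grid <- seq(range[1], range[2], length.out = grid_size)
  num_cols <- names(d)[vapply(d, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c(fit$spec$outcome, variable,
                                  vapply(fit$spec$interactions,
                                         .interaction_name, character(1))))
  re_terms <- sprintf("s(%s)", fit$spec$random)
  build_nd <- function(base_row) {
    nd <- base_row[rep(1, grid_size), , drop = FALSE]
    nd[[variable]] <- grid
    for (pair in fit$spec$interactions) {
      cn <- .interaction_name(pair)
      mu <- fit$centers[[cn]]
      nd[[cn]] <- (nd[[pair[1]]] - mu[1]) * (nd[[pair[2]]] - mu[2])
    }
    nd
  }
  if (averaging == "means") {
    base_row <- d[1, , drop = FALSE]
    for (v in num_cols) base_row[[v]] <- mean(d[[v]])
    nd <- build_nd(base_row)
    p <- mgcv::predict.gam(fit$model, newdata = nd, se.fit = TRUE,
                           type = "link", exclude = re_terms)
    eta <- as.numeric(p$fit); se <- as.numeric(p$se.fit)
  } else {
    ## marginalize: average link predictions over the training rows
    eta_mat <- se_mat <- matrix(0, grid_size, 0)
    idx <- seq_len(nrow(d))
    if (nrow(d) > 500) idx <- sample(idx, 500) # cap the averaging cost
    etas <- vapply(idx, function(i) {
      nd <- build_nd(d[i, , drop = FALSE])
      as.numeric(mgcv::predict.gam(fit$model, newdata = nd, type = "link",
                                   exclude = re_terms))
    }, numeric(grid_size))
    eta <- rowMeans(etas)
    ## approximate SE at the mean covariate point
    base_row <- d[1, , drop = FALSE]
    for (v in num_cols) base_row[[v]] <- mean(d[[v]])
    p <- mgcv::predict.gam(fit$model, newdata = build_nd(base_row),
                           se.fit = TRUE, type = "link",
                           exclude = re_terms)
    se <- as.numeric(p$se.fit)
  }
  clip <- function(p) pmin(pmax(p, .p_eps), 1 - .p_eps)
  prob <- clip(stats::plogis(eta))
  out <- data.frame(value = grid,
                    log_odds = stats::qlogis(prob),
                    log_odds_lo = eta - 1.96 * se,
                    log_odds_hi = eta + 1.96 * se,
                    prob = prob,
                    prob_lo = clip(stats::plogis(eta - 1.96 * se)),
                    prob_hi = clip(stats::plogis(eta + 1.96 * se)))
  structure(out, variable = variable, averaging = averaging,
            class = c("prediction_curve", "data.frame"))
}

#' Concurvity of the smooth terms
#'
#' For each smooth, the extent (0-1) to which its fitted effect can be
#' approximated by the other model terms (the "estimate" flavor: R-squared
#' of the smooth's basis projected on the span of everything else).
#' Values at or above 0.7 indicate the covariates should not share a
#' model.
#'
#' @param fit a `binsmooth` fit with at least two smooth terms.
#' @return named numeric vector, one value in \[0, 1\] per smooth.
#' @export
concurvity_estimate <- function(fit) {
  n_sm <- length(fit$spec$smooths) + length(fit$spec$random)
  if (n_sm < 2) stop("need >= 2 smooth terms for concurvity")
  cc <- mgcv::concurvity(fit$model, full = TRUE)
  est <- cc["estimate", , drop = TRUE]
  keep <- grep("^s\\(", names(est), value = TRUE)
  keep <- keep[!keep %in% sprintf("s(%s)", fit$spec$random)]
  pmin(pmax(est[keep], 0), 1)
}

#' Compare two fitted models by BIC
#'
#' @param model_a,model_b `binsmooth` fits of the same outcome vector.
#' @param labels length-2 labels for reporting.
#' @return list with `bic`, `delta_bic` (a minus b), and `preferred`.
#' @export
compare_bic <- function(model_a, model_b, labels = c("A", "B")) {
  ya <- model_a$data[[model_a$spec$outcome]]
  yb <- model_b$data[[model_b$spec$outcome]]
  if (length(ya) != length(yb) || !all(ya == yb))
    stop("models were not fitted to the same outcome vector")
  bic <- stats::setNames(c(model_a$bic, model_b$bic), labels)
  list(bic = bic, delta_bic = unname(bic[1] - bic[2]),
       preferred = labels[which.min(bic)])
}
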
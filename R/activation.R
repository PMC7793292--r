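# Hill-equation dose-response fitting: EC50 and Hill coefficient with
# analytic standard errors, parameterized in log10(EC50) for positivity and
# conditioning, evaluated through the logistic form for overflow safety.

#' Hill dose-response model
#'
#' y = y0 + (ymax - y0) * c^n / (ec50^n + c^n), evaluated in the log domain
#' as a logistic in n * (log c - log ec50), so large n * log(c) cannot
#' overflow. Monotone increasing in c for n > 0; y(ec50) = (y0 + ymax)/2.
#'
#' @param c concentration(s), > 0 (any unit, consistently with `ec50`).
#' @param ec50 half-maximal concentration, > 0.
#' @param hill_n Hill coefficient.
#' @param y0,ymax baseline and plateau responses.
#' @return response(s), same length as `c`.
#' @export
hill_model <- function(c, ec50, hill_n, y0 = 0, ymax = 1) {
  if (any(c <= 0)) stop("concentrations must be > 0")
  if (ec50 <= 0) stop("ec50 must be > 0")
  y0 + (ymax - y0) * stats::plogis(hill_n * (log(c) - log(ec50)))
}

#' Fit the Hill model to dose-response data
#'
#' Nonlinear least squares on (log10 EC50, n, y0, ymax), default-initialized
#' from the data (midpoint of the response range, n = 1, observed min/max).
#' Standard errors come from the residual-variance-scaled inverse curvature
#' of the sum of squares at the optimum. Non-convergence is flagged, not
#' raised.
#'
#' @param data a `dose_response` data.frame (concentration_nM, response,
#'   optionally replicate) with >= 4 distinct concentrations.
#' @param init optional named list overriding initial values (ec50, hill_n,
#'   y0, ymax).
#' @param fix_y0,fix_ymax optionally fix baseline/plateau at given values.
#' @return a `hill_fit`: list(ec50, hill_n, y0, ymax, se_ec50, se_hill,
#'   converged, rss, n_obs).
#' @export
fit_hill <- function(data, init = NULL, fix_y0 = NULL, fix_ymax = NULL) {
  conc <- data$concentration_nM
  y <- data$response
  if (length(unique(conc)) < 4)
    stop("insufficient data: need >= 4 distinct concentrations")
  if (any(conc <= 0)) stop("concentrations must be > 0")

  ymid <- (min(y) + max(y)) / 2
  i0 <- list(
    lec50 = log10(conc[which.min(abs(tapply_means(conc, y) - ymid))]),
    hill_n = 1,
    y0 = if (is.null(fix_y0)) min(y) else fix_y0,
    ymax = if (is.null(fix_ymax)) max(y) else fix_ymax)
  if (!is.null(init$ec50)) i0$lec50 <- log10(init$ec50)
  for (nm in c("hill_n", "y0", "ymax"))
    if (!is.null(init[[nm]])) i0[[nm]] <- init[[nm]]

  free <- c(TRUE, TRUE, is.null(fix_y0), is.null(fix_ymax))
  full <- c(i0$lec50, i0$hill_n, i0$y0, i0$ymax)
  obj <- function(p) {
    th <- full; th[free] <- p
    mu <- th[3] + (th[4] - th[3]) *
      stats::plogis(th[2] * log(10) * (log10(conc) - th[1]))
    sum((y - mu)^2)
  }
  opt <- stats::optim(full[free], obj, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-14))
  th <- full; th[free] <- opt$par
  n_obs <- length(y); p_free <- sum(free)
  s2 <- opt$value / max(1, n_obs - p_free)
  # cov(theta) ~ 2 s^2 H^-1 for H the hessian of the SSR
  se <- rep(NA_real_, 4)
  covm <- try(2 * s2 * solve(opt$hessian), silent = TRUE)
  if (!inherits(covm, "try-error") && all(diag(covm) >= 0))
    se[free] <- sqrt(diag(covm))
  ec50 <- 10^th[1]
  structure(list(
    ec50 = ec50, hill_n = th[2], y0 = th[3], ymax = th[4],
    se_ec50 = ec50 * log(10) * se[1],   # delta method from log10 scale
    se_hill = se[2],
    converged = opt$convergence == 0,
    rss = opt$value, n_obs = n_obs), class = "hill_fit")
}

# per-concentration mean responses, aligned with unique concentrations
tapply_means <- function(conc, y) {
  m <- tapply(y, conc, mean)
  as.numeric(m)[match(conc, sort(unique(conc)))]
}

#' Compare Hill fits across constructs
#'
#' Tabulates EC50, Hill coefficient and their standard errors, the EC50
#' ratio of the first (reference) fit to each, an easier-to-activate flag
#' (EC50 below the reference), and a reduced-cooperativity flag
#' (Hill coefficient < 1).
#'
#' @param fits list of `hill_fit` objects (>= 2); the first is the reference.
#' @param labels character labels, one per fit.
#' @return a data.frame, one row per fit.
#' @export
compare_activation <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 2)
  labels <- labels %||% paste0("fit", seq_along(fits))
  ref <- fits[[1]]$ec50
  out <- data.frame(
    label = labels,
    ec50_nM = vapply(fits, `[[`, numeric(1), "ec50"),
    se_ec50 = vapply(fits, `[[`, numeric(1), "se_ec50"),
    hill_n = vapply(fits, `[[`, numeric(1), "hill_n"),
    se_hill = vapply(fits, `[[`, numeric(1), "se_hill"),
    stringsAsFactors = FALSE)
  out$ec50_ratio_ref <- ref / out$ec50_nM
  out$easier_to_activate <- out$ec50_nM < ref
  out$reduced_cooperativity <- out$hill_n < 1
  out
}
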
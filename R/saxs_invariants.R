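# Small-angle scattering quantities from coordinate models and 1D profiles:
# Debye model intensities, P(r), radii of gyration by two routes, the Porod
# invariant with its molecular-weight rule, the Kratky transform, and the
# chi-square agreement between a model and an experimental profile.

#' Construct a 1D scattering profile
#'
#' @param q momentum transfer grid (1/Angstrom), strictly ascending, >= 0.
#' @param intensity I(q), arbitrary units.
#' @param sigma optional per-point uncertainty, > 0 where given.
#' @return a `scattering_profile` data.frame (q, intensity[, sigma]).
#' @export
scattering_profile <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity), all(diff(q) > 0), all(q >= 0))
  out <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(sigma > 0))
    out$sigma <- sigma
  }
  class(out) <- c("scattering_profile", "data.frame")
  out
}

#' Read a 3-column SAXS profile (q, I, sigma)
#'
#' Whitespace- or comma-separated text; lines starting with '#' are comments.
#'
#' @param path file path.
#' @return a `scattering_profile`.
#' @export
read_scattering_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  m <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  if (all(is.na(m[, 3]))) scattering_profile(m[, 1], m[, 2])
  else scattering_profile(m[, 1], m[, 2], m[, 3])
}

#' Debye scattering profile of a coordinate model
#'
#' I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij), with the i = j and q -> 0
#' limits equal to 1, so I(0) = (sum f)^2. Computed through the weighted
#' pair-distance histogram, giving O(n^2 + n_q * n_bins) cost; uniform
#' scattering factors f = 1 by default.
#'
#' @param model a `structure_model`.
#' @param q_grid ascending momentum-transfer grid (1/Angstrom), >= 0.
#' @param weights optional per-atom scattering factors.
#' @param bin_width pair-distance histogram bin width (Angstrom).
#' @return a `scattering_profile`.
#' @export
debye_profile <- function(model, q_grid, weights = NULL, bin_width = 0.1) {
  xyz <- coords(model)
  n <- nrow(xyz)
  if (n < 2) stop("empty structure: Debye sum needs >= 2 scatterers")
  stopifnot(all(diff(q_grid) > 0), all(q_grid >= 0))
  f <- weights %||% rep(1, n)
  stopifnot(length(f) == n)
  pd <- pair_distance_histogram(xyz, f, bin_width)
  self_term <- sum(f^2)
  I <- vapply(q_grid, function(q) {
    if (q == 0) return(self_term + 2 * sum(pd$w))
    x <- q * pd$r
    self_term + 2 * sum(pd$w * ifelse(x < 1e-8, 1, sin(x) / x))
  }, numeric(1))
  scattering_profile(q_grid, I)
}

# Weighted histogram of all pairwise distances (i < j): bin centers r and
# summed weights w = sum f_i f_j per bin.
pair_distance_histogram <- function(xyz, f, bin_width) {
  n <- nrow(xyz)
  d <- stats::dist(xyz)
  if (all(f == f[1])) {
    wpair <- rep(f[1]^2, length(d))
  } else {
    fi <- rep(f[-n], times = (n - 1):1)
    fj <- f[unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))]
    wpair <- fi * fj
  }
  bin <- pmax(1L, ceiling(as.numeric(d) / bin_width))
  w <- tapply(wpair, bin, sum)
  r <- (as.integer(names(w)) - 0.5) * bin_width
  list(r = r, w = as.numeric(w), dmax = max(d))
}

#' Pair distance distribution P(r) of a coordinate model
#'
#' Weighted histogram of all pairwise distances, normalized to unit area.
#'
#' @param model a `structure_model` with >= 2 atoms.
#' @param bin_width histogram bin width (Angstrom).
#' @param weights optional per-atom scattering factors.
#' @return a `pair_distance_distribution`: list(r = bin centers, pr = density,
#'   dmax = largest pair distance, bin_width).
#' @export
pair_distance_distribution <- function(model, bin_width = 0.5,
                                       weights = NULL) {
  xyz <- coords(model)
  if (nrow(xyz) < 2) stop("insufficient atoms: P(r) needs >= 2")
  stopifnot(bin_width > 0)
  f <- weights %||% rep(1, nrow(xyz))
  pd <- pair_distance_histogram(xyz, f, bin_width)
  bins <- as.integer(round(pd$r / bin_width + 0.5))
  r <- (seq_len(max(bins)) - 0.5) * bin_width
  pr <- numeric(length(r))
  pr[bins] <- pd$w
  pr <- pr / (sum(pr) * bin_width)
  structure(list(r = r, pr = pr, dmax = pd$dmax, bin_width = bin_width,
                 self_fraction = sum(f^2) / sum(f)^2),
            class = "pair_distance_distribution")
}

#' Radius of gyration from P(r)
#'
#' Rg^2 = integral(r^2 P(r) dr) / (2 integral(P(r) dr)); invariant to any
#' positive rescaling of P(r). For a discrete point model the full density
#' autocorrelation carries a self-pair term at r = 0 that the distinct-pair
#' histogram omits; when the distribution records its `self_fraction`
#' (sum f_i^2 / (sum f)^2, as set by [pair_distance_distribution]) the
#' formula is corrected by 1 - self_fraction, which is what makes the
#' two-point body give exactly Rg = d/2. The correction is O(1/n) and
#' negligible for many-atom models.
#'
#' @param pr a `pair_distance_distribution`.
#' @return Rg in Angstrom.
#' @export
rg_from_pr <- function(pr) {
  tot <- sum(pr$pr) * pr$bin_width
  if (tot <= 0) stop("zero total mass in P(r)")
  s <- pr$self_fraction %||% 0
  sqrt((1 - s) * sum(pr$r^2 * pr$pr) * pr$bin_width / (2 * tot))
}

#' Guinier fit of the low-q region
#'
#' Weighted linear fit of ln I versus q^2 over the largest low-q window
#' satisfying qmax * Rg <= `qrg_limit`, found by iterating fit -> trim until
#' the window is self-consistent. Returns Rg = sqrt(-3 slope) and
#' I0 = exp(intercept).
#'
#' @param profile a `scattering_profile`, positive over the fitted region.
#' @param qrg_limit Guinier validity limit (default 1.3, standard practice).
#' @param min_points minimum window size (default 5).
#' @return a `guinier_result`: list(rg, i0, q_range_used, n_points,
#'   fit_residual).
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5L) {
  ok <- profile$intensity > 0 & profile$q > 0
  q <- profile$q[ok]; I <- profile$intensity[ok]
  s <- if (!is.null(profile$sigma)) profile$sigma[ok] else NULL
  if (length(q) < min_points) stop("too few positive points for Guinier fit")
  # seed the iteration from a small low-q window; the full range would start
  # far outside the Guinier regime and can cycle
  upper <- max(min_points, min(10L, length(q)))
  seen <- integer(0)
  for (it in seq_len(20)) {
    qq <- q[1:upper]^2
    y <- log(I[1:upper])
    w <- if (is.null(s)) rep(1, upper) else (I[1:upper] / s[1:upper])^2
    fit <- stats::lm.wfit(cbind(1, qq), y, w)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0)
      stop("invalid Guinier region: non-negative slope (Rg imaginary)")
    rg <- sqrt(-3 * slope)
    new_upper <- min(length(q), max(min_points, sum(q * rg <= qrg_limit)))
    if (new_upper == upper || new_upper %in% seen) {
      res <- sqrt(mean(fit$residuals^2))
      return(structure(list(rg = unname(rg),
                            i0 = unname(exp(fit$coefficients[1])),
                            q_range_used = c(q[1], q[upper]),
                            n_points = upper, fit_residual = res),
                       class = "guinier_result"))
    }
    seen <- c(seen, upper)
    upper <- new_upper
  }
  stop("Guinier window iteration did not converge in 20 rounds")
}

#' Porod volume and molecular-weight estimate
#'
#' Porod invariant Q = integral(q^2 I(q) dq), by trapezoid over the data
#' with an analytic K/q^4 tail extension beyond qmax (the tail otherwise
#' biases the volume low); Vp = 2 pi^2 I0 / Q. The molecular weight is then
#' estimated by the empirical rule MW(kDa) = Vp / 1.7 / 1000, reported
#' rounded to integer kDa. A plateau check on q^4 I(q) over the last part of
#' the range sets `plateau_ok`; a missing plateau flags (not hides) the
#' result.
#'
#' @param profile a `scattering_profile` extending to the Porod regime.
#' @param i0 forward intensity (e.g. from [guinier_fit]), > 0.
#' @param tail_fraction fraction of the high-q range used for the q^4
#'   plateau estimate (default 0.2).
#' @return a `porod_result`: list(porod_volume, mw_estimate (kDa, exact),
#'   mw_kda (integer reporting value), plateau_ok, q_extrapolation).
#' @export
porod_volume_mw <- function(profile, i0, tail_fraction = 0.2) {
  stopifnot(i0 > 0)
  q <- profile$q; I <- profile$intensity
  if (q[1] > 0) {  # extend to q = 0 with the Guinier limit I -> i0
    q <- c(0, q); I <- c(i0, I)
  }
  Qdata <- trapz(q, q^2 * I)
  ntail <- max(3L, ceiling(tail_fraction * length(q)))
  tail_idx <- seq(length(q) - ntail + 1, length(q))
  k4 <- (q^4 * I)[tail_idx]
  plateau_ok <- stats::sd(k4) / mean(k4) < 0.2
  K <- mean(k4)
  qmax <- q[length(q)]
  Qtail <- K / qmax                       # integral of K/q^2 from qmax to Inf
  Q <- Qdata + Qtail
  vp <- 2 * pi^2 * i0 / Q
  structure(list(porod_volume = vp, mw_estimate = vp / 1.7 / 1000,
                 mw_kda = as.integer(round(vp / 1.7 / 1000)),
                 plateau_ok = plateau_ok,
                 q_extrapolation = sprintf(
                   "K/q^4 tail beyond qmax=%.4g (K=%.4g)", qmax, K)),
            class = "porod_result")
}

#' Molecular weight from a Porod volume
#'
#' The empirical rule MW(kDa) = Vp(A^3) / 1.7 / 1000, rounded to integer
#' kDa for reporting.
#'
#' @param porod_volume Porod volume in cubic Angstrom, > 0.
#' @return integer kDa.
#' @export
porod_mw_from_volume <- function(porod_volume) {
  stopifnot(porod_volume > 0)
  as.integer(round(porod_volume / 1.7 / 1000))
}

#' Kratky transform q^2 I(q)
#'
#' Also reports a compactness flag: TRUE when the curve has an interior
#' maximum and returns below `peak_fraction` of that peak at high q (the
#' bell shape of compact globular particles).
#'
#' @param profile a `scattering_profile`.
#' @param peak_fraction high-q return threshold (default 0.2).
#' @return a `kratky_result`: list(q, kratky = q^2 I, compact, peak_q).
#' @export
kratky_transform <- function(profile, peak_fraction = 0.2) {
  k <- profile$q^2 * profile$intensity
  imax <- which.max(k)
  interior <- imax > 1 && imax < length(k)
  returns <- length(k) > imax &&
    utils::tail(k, 1) < peak_fraction * max(k)
  structure(list(q = profile$q, kratky = k,
                 compact = interior && returns,
                 peak_q = profile$q[imax]),
            class = "kratky_result")
}

#' Reduced chi-square between a model and an experimental profile
#'
#' The model is linearly interpolated onto the experimental q grid and a
#' scalar scale factor c is fitted by closed-form weighted least squares;
#' chi^2 = sum[((I_exp - c I_model)/sigma)^2] / (N - 1).
#'
#' @param model_profile a `scattering_profile` (model intensities).
#' @param exp_profile a `scattering_profile` carrying `sigma`.
#' @return a `chi2_result`: list(chi2, scale, n_points).
#' @export
profile_chi2 <- function(model_profile, exp_profile) {
  if (is.null(exp_profile$sigma)) stop("experimental profile needs sigma")
  qe <- exp_profile$q
  keep <- qe >= min(model_profile$q) & qe <= max(model_profile$q)
  if (!any(keep)) stop("no overlapping q support between model and data")
  qe <- qe[keep]
  Ie <- exp_profile$intensity[keep]
  se <- exp_profile$sigma[keep]
  Im <- stats::approx(model_profile$q, model_profile$intensity, qe)$y
  cc <- sum(Ie * Im / se^2) / sum(Im^2 / se^2)
  chi2 <- sum(((Ie - cc * Im) / se)^2) / (length(qe) - 1)
  structure(list(chi2 = chi2, scale = cc, n_points = length(qe)),
            class = "chi2_result")
}
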
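# Inter-domain polar displacement vectors in a body-fixed frame, the
# mean-normalized protomer asymmetry index, and helix hinge-angle
# decomposition by principal axes.

#' Per-frame polar coordinates of an inter-domain anchor vector
#'
#' Every frame is first superposed onto the reference frame (frame 1) using
#' the `body_frame_sel` atoms, which removes global rigid-body motion and
#' fixes the body frame (axes inherited from the reference coordinates).
#' The vector anchorB - anchorA is then converted to spherical polar form:
#' d = |v|, theta = acos(z/d) in [0, 180] degrees from the body z axis,
#' phi = atan2(y, x) in (-180, 180] degrees from the body x axis. A vector
#' along +z has undefined azimuth; phi is reported as 0 by convention.
#'
#' @param traj an `ensemble_trajectory`.
#' @param anchorA_sel,anchorB_sel selections resolving to exactly one atom.
#' @param body_frame_sel selection of >= 3 non-collinear atoms defining the
#'   body-fixed frame.
#' @return a `polar_vector_series` data.frame (frame, d_A, theta_deg,
#'   phi_deg) with the frame definition attached as an attribute.
#' @export
interdomain_vector_series <- function(traj, anchorA_sel, anchorB_sel,
                                      body_frame_sel) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  ia <- select_atoms(traj, anchorA_sel, require_one = TRUE)
  ib <- select_atoms(traj, anchorB_sel, require_one = TRUE)
  bi <- select_atoms(traj, body_frame_sel)
  if (length(bi) < 3) stop("degenerate body frame: needs >= 3 atoms")
  nf <- n_frames(traj)
  ref <- traj$frames[1, bi, ]
  d <- theta <- phi <- numeric(nf)
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(traj$frames[f, bi, ], ref)
    ab <- traj$frames[f, c(ia, ib), ]
    ab <- sweep(ab %*% t(fit$rotation), 2, fit$translation, `+`)
    v <- ab[2, ] - ab[1, ]
    d[f] <- sqrt(sum(v^2))
    if (d[f] == 0) stop("anchors coincide at frame ", f)
    theta[f] <- acos(pmin(1, pmax(-1, v[3] / d[f]))) * 180 / pi
    phi[f] <- if (abs(v[1]) < 1e-12 && abs(v[2]) < 1e-12) 0
      else atan2(v[2], v[1]) * 180 / pi
  }
  out <- data.frame(frame = seq_len(nf), d_A = d, theta_deg = theta,
                    phi_deg = phi)
  attr(out, "frame_definition") <-
    paste0("superposed onto frame 1 via ", format_selection(body_frame_sel),
           "; axes inherited from reference coordinates")
  class(out) <- c("polar_vector_series", "data.frame")
  out
}

#' Mean-normalized asymmetry index between two polar vector series
#'
#' For each component X in {theta, phi, d}, both series are divided by their
#' own mean and the average per-frame absolute difference is reported as a
#' percentage: DeltaX = 100 * mean_f |X1_f/mean(X1) - X2_f/mean(X2)|.
#' Mean-normalization cancels any common scale, so proportional series give
#' Delta = 0 exactly. Azimuth series are unwrapped (+-360 jumps removed)
#' before normalization, since branch cuts would otherwise corrupt the mean.
#'
#' @param series1,series2 `polar_vector_series` of equal length (matching
#'   frames of the two protomers).
#' @return an `asymmetry_result`: list(delta_theta, delta_phi, delta_d,
#'   n_frames), all percentages >= 0.
#' @export
asymmetry_index <- function(series1, series2) {
  if (nrow(series1) != nrow(series2))
    stop("series length mismatch: cannot pair frames")
  one <- function(x1, x2, label) {
    m1 <- mean(x1); m2 <- mean(x2)
    if (abs(m1) < 1e-12 || abs(m2) < 1e-12)
      stop("zero mean in component ", label, ": normalization undefined")
    100 * mean(abs(x1 / m1 - x2 / m2))
  }
  structure(list(
    delta_theta = one(series1$theta_deg, series2$theta_deg, "theta"),
    delta_phi = one(unwrap_degrees(series1$phi_deg),
                    unwrap_degrees(series2$phi_deg), "phi"),
    delta_d = one(series1$d_A, series2$d_A, "d"),
    n_frames = nrow(series1)), class = "asymmetry_result")
}

# First principal axis of a coordinate set, oriented along increasing
# sequence (first -> last atom).
principal_axis <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  ax <- svd(c0)$v[, 1]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
  ax
}

#' Hinge angles between consecutive helix segments
#'
#' Each segment's axis is the first principal axis of its selected atoms,
#' oriented N-to-C along the sequence; the hinge angle between consecutive
#' segments is the arccos of the unit-axis dot product. Collinear segments
#' give 0 degrees. Typical use: the long contiguous B/C/N helix of a PKA
#' regulatory subunit, split at its two hinge points.
#'
#' @param model a `structure_model`.
#' @param segB,segC,segN inclusive residue ranges c(lo, hi) of the three
#'   segments, non-overlapping and each resolving >= 3 atoms.
#' @param atom_name atom name defining the axis trace (default "CA").
#' @param chain optional chain restriction.
#' @return a `hinge_angles`: list(angle_BC, angle_CN, segment_ranges,
#'   axis_method), angles in [0, 180] degrees.
#' @export
hinge_angles <- function(model, segB, segC, segN, atom_name = "CA",
                         chain = NULL) {
  segs <- list(B = segB, C = segC, N = segN)
  for (i in 1:2)
    if (segs[[i]][2] >= segs[[i + 1]][1])
      stop("segment ranges overlap or are out of order")
  axes <- lapply(names(segs), function(s) {
    idx <- select_atoms(model, atom_selection(
      chain = chain, resid_range = segs[[s]], names = atom_name))
    if (length(idx) < 3)
      stop("insufficient atoms: segment ", s, " resolves ", length(idx),
           " '", atom_name, "' atoms (need >= 3)")
    principal_axis(coords(model)[idx, , drop = FALSE])
  })
  ang <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
  structure(list(angle_BC = ang(axes[[1]], axes[[2]]),
                 angle_CN = ang(axes[[2]], axes[[3]]),
                 segment_ranges = segs,
                 axis_method = "principal axis, N->C oriented"),
            class = "hinge_angles")
}
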
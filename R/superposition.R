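# Least-squares rigid-body superposition (Kabsch, via SVD with reflection
# correction) and per-residue RMSF profiles computed against the iterated
# mean structure.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimizing the (weighted)
#' RMSD between `R %*% mobile + t` and `reference`. Reflections are excluded
#' by the standard determinant correction, so `rotation` is always a proper
#' rotation (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not collinear.
#' @param weights optional non-negative per-point weights.
#' @return a `superposition_result`: list(rotation 3x3, translation length-3,
#'   rmsd). Apply as `sweep(mobile %*% t(rotation), 2, translation, "+")`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3) stop("degenerate geometry: need >= 3 points")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate geometry: points are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- cr - as.vector(R %*% cm)
  fitted <- sweep(A %*% t(R), 2, cr, `+`)
  moved <- sweep(mobile %*% t(R), 2, trans, `+`)
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "superposition_result")
}

# Align every frame of `frames` (nf x na x 3) onto `ref_xyz` using the
# `align_idx` atoms; returns the transformed array.
align_frames <- function(frames, align_idx, ref_xyz) {
  nf <- dim(frames)[1]
  out <- frames
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(frames[f, align_idx, ], ref_xyz)
    out[f, , ] <- sweep(frames[f, , ] %*% t(fit$rotation), 2,
                        fit$translation, `+`)
  }
  out
}

#' Per-residue RMSF profile of an aligned ensemble
#'
#' Frames are superposed on the mean structure (two rounds: align to frame 1,
#' average, re-align the originals to that average) using the `align_sel`
#' atoms; RMSF_i = sqrt(mean over frames of the squared deviation from the
#' mean position), then averaged over each residue's `target_sel` atoms.
#'
#' @param traj an `ensemble_trajectory` with >= 2 frames.
#' @param align_sel `atom_selection` defining the alignment reference (e.g.
#'   the stable core of one protomer).
#' @param target_sel `atom_selection` of atoms to profile.
#' @return a `flexibility_profile` data.frame (chain, resid, rmsf_A), with
#'   the selections attached as attributes.
#' @export
compute_rmsf <- function(traj, align_sel, target_sel = atom_selection()) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  if (n_frames(traj) < 2) stop("insufficient frames: RMSF needs >= 2")
  ai <- select_atoms(traj, align_sel)
  ti <- select_atoms(traj, target_sel)
  if (length(ai) == 0) stop("no atoms match align_sel: ",
                            format_selection(align_sel))
  if (length(ti) == 0) stop("no atoms match target_sel: ",
                            format_selection(target_sel))
  if (length(ai) < 3) stop("align_sel must resolve >= 3 atoms")

  aligned <- align_frames(traj$frames, ai, traj$frames[1, ai, ])
  mean_xyz <- apply(aligned, c(2, 3), mean)
  aligned <- align_frames(traj$frames, ai, mean_xyz[ai, ])
  mean_xyz <- apply(aligned, c(2, 3), mean)

  dev2 <- (aligned - rep(mean_xyz, each = dim(aligned)[1]))^2
  rmsf_atom <- sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))

  topo <- traj$topology[ti, , drop = FALSE]
  key <- paste(topo$chain, topo$resid)
  agg <- tapply(rmsf_atom[ti], key, mean)
  ord <- match(unique(key), names(agg))
  first <- !duplicated(key)
  prof <- data.frame(chain = topo$chain[first], resid = topo$resid[first],
                     rmsf_A = as.numeric(agg[ord]),
                     stringsAsFactors = FALSE)
  attr(prof, "align_selection") <- align_sel
  attr(prof, "target_selection") <- target_sel
  class(prof) <- c("flexibility_profile", "data.frame")
  prof
}

#' Mean RMSF over a residue window of a profile
#'
#' Convenience summary used when contrasting protomer mobile domains.
#'
#' @param profile a `flexibility_profile`.
#' @param chain chain to summarize.
#' @param resid_range inclusive residue range.
#' @export
mean_rmsf <- function(profile, chain = NULL, resid_range = NULL) {
  keep <- rep(TRUE, nrow(profile))
  if (!is.null(chain)) keep <- keep & profile$chain %in% chain
  if (!is.null(resid_range))
    keep <- keep & profile$resid >= resid_range[1] &
      profile$resid <= resid_range[2]
  mean(profile$rmsf_A[keep])
}
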
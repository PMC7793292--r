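# Seeded generators for every input class the analyses consume: asymmetric
# two-protomer coordinate ensembles, uniform bead spheres with closed-form
# scattering, and noisy Hill-model activation curves.
#
# The protomer template is deliberately coarse (one pseudo-atom per residue
# plus the two pocket landmark atoms): the analyses under test are purely
# geometric and need no chemistry. Its architecture mirrors a regulatory
# subunit: a stable core (CNB-A analogue, residues 201-265) ending at a
# pivot residue (265), and a mobile domain (CNB-B analogue, residues
# 266-360) that swings about the pivot as a rigid body.

#' Build a coarse two-domain protomer template
#'
#' One pseudo-CA per residue along a gently curved backbone; residues
#' 201-265 form the rigid core, 266-360 the mobile domain attached at the
#' resid-265 pivot. Residue 351 carries an extra CG atom and residue 360 an
#' extra CB atom: the pocket-opening landmark pair. Anchor roles (the
#' inter-domain vector end points) default to the resid-230 and resid-359 CA.
#'
#' @param core_resids,mobile_resids inclusive residue ranges.
#' @param pivot_resid pivot residue (must lie in the core range).
#' @return a `protomer_template`: list(atoms, is_mobile, pivot_idx,
#'   hinge_axis, anchorA, anchorB, pocket_pair) where anchor/pocket entries
#'   are topology row indices.
#' @export
protomer_template <- function(core_resids = c(201L, 265L),
                              mobile_resids = c(266L, 360L),
                              pivot_resid = 265L) {
  stopifnot(pivot_resid >= core_resids[1], pivot_resid <= core_resids[2],
            mobile_resids[1] == core_resids[2] + 1L)
  resid <- seq(core_resids[1], mobile_resids[2])
  n <- length(resid)
  # curved pseudo-backbone: 3.8 A per residue with a slow bend so segments
  # are never collinear (principal axes well defined)
  t <- seq_len(n)
  xyz <- cbind(12 * sin(t / 18), 12 * (1 - cos(t / 18)), 3.0 * t)
  atoms <- data.frame(name = "CA", resname = "GLY", chain = "A",
                      resid = resid, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = "C", stringsAsFactors = FALSE)
  # pocket landmark atoms: CG on 351, CB on 360, offset from their CA so the
  # closed-state pair separation is ~5.9 A before any latent-state resetting
  ca351 <- xyz[match(351L, resid), ]
  ca360 <- xyz[match(360L, resid), ]
  extra <- data.frame(name = c("CG", "CB"), resname = c("LEU", "ALA"),
                      chain = "A", resid = c(351L, 360L),
                      x = c(ca351[1] + 1.5, ca360[1] - 1.2),
                      y = c(ca351[2] + 1.0, ca360[2] - 0.8),
                      z = c(ca351[3], ca360[3]),
                      element = "C", stringsAsFactors = FALSE)
  atoms <- rbind(atoms, extra)
  is_mobile <- atoms$resid >= mobile_resids[1]
  pivot_idx <- which(atoms$resid == pivot_resid & atoms$name == "CA")
  structure(list(
    atoms = atoms, is_mobile = is_mobile, pivot_idx = pivot_idx,
    hinge_axis = c(1, 0, 0),
    anchorA = which(atoms$resid == 230L & atoms$name == "CA"),
    anchorB = which(atoms$resid == 359L & atoms$name == "CA"),
    pocket_pair = c(which(atoms$resid == 351L & atoms$name == "CG"),
                    which(atoms$resid == 360L & atoms$name == "CB"))),
    class = "protomer_template")
}

#' Parameters of the two-protomer ensemble generator
#'
#' @param n_frames number of frames (>= 2).
#' @param hinge_sigma_p1,hinge_sigma_p2 SD (degrees) of the per-frame hinge
#'   angle of the mobile domain in protomer 1 / 2.
#' @param core_jitter_sigma isotropic Gaussian positional noise SD (Angstrom)
#'   added to every core-atom coordinate.
#' @param pocket_open_fraction_p1,pocket_open_fraction_p2 per-frame
#'   probability of the open pocket state in protomer 1 / 2.
#' @param pocket_open_A,pocket_closed_A target landmark separations of the
#'   open / closed pocket states (defaults 6.9 / 4.9 Angstrom).
#' @param pocket_spread_A Gaussian spread of the target separation.
#' @param seed RNG seed (mandatory for reproducible pipelines).
#' @return an `ensemble_params` list.
#' @export
ensemble_params <- function(n_frames = 200L,
                            hinge_sigma_p1 = 2, hinge_sigma_p2 = 20,
                            core_jitter_sigma = 0.1,
                            pocket_open_fraction_p1 = 0.3,
                            pocket_open_fraction_p2 = 0.3,
                            pocket_open_A = 6.9, pocket_closed_A = 4.9,
                            pocket_spread_A = 0.3,
                            seed = 1L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (hinge_sigma_p1 < 0 || hinge_sigma_p2 < 0 || core_jitter_sigma < 0 ||
      pocket_spread_A < 0)
    stop("sigmas must be >= 0")
  fr <- c(pocket_open_fraction_p1, pocket_open_fraction_p2)
  if (any(fr < 0 | fr > 1)) stop("pocket open fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "ensemble_params")
}

#' Generate a C2-symmetric two-protomer ensemble with tunable asymmetry
#'
#' Two copies of the template are placed C2-symmetrically about the z axis
#' (chains A and B). Per frame, each protomer's mobile domain is rotated
#' about its pivot by an angle drawn from N(0, hinge_sigma); core atoms get
#' isotropic Gaussian jitter; the pocket landmark pair is reset to an
#' open/closed target separation drawn from the per-protomer latent state.
#' Bit-reproducible under a fixed seed.
#'
#' @param template a `protomer_template`.
#' @param params an `ensemble_params`.
#' @return list(trajectory = `ensemble_trajectory`,
#'   truth = `synthetic_truth` holding the generator parameters and all
#'   per-frame latent draws).
#' @export
make_two_protomer_ensemble <- function(template = protomer_template(),
                                       params = ensemble_params()) {
  stopifnot(inherits(template, "protomer_template"),
            inherits(params, "ensemble_params"))
  nf <- params$n_frames
  na1 <- nrow(template$atoms)
  sig <- c(params$hinge_sigma_p1, params$hinge_sigma_p2)
  opf <- c(params$pocket_open_fraction_p1, params$pocket_open_fraction_p2)

  lat <- with_seed(params$seed, {
    list(hinge = cbind(stats::rnorm(nf, 0, sig[1]),
                       stats::rnorm(nf, 0, sig[2])),
         open  = cbind(stats::runif(nf) < opf[1], stats::runif(nf) < opf[2]),
         dnoise = matrix(stats::rnorm(2 * nf, 0, params$pocket_spread_A),
                         nf, 2),
         jitter = array(stats::rnorm(nf * 2 * na1 * 3, 0,
                                     params$core_jitter_sigma),
                        c(nf, 2 * na1, 3)))
  })
  target_d <- ifelse(lat$open, params$pocket_open_A, params$pocket_closed_A) +
    lat$dnoise

  X0 <- as.matrix(template$atoms[, c("x", "y", "z")])
  pivot <- X0[template$pivot_idx, ]
  place <- list(diag(3), rotation_about_axis(c(0, 0, 1), 180))
  offset <- c(30, 0, 0)                      # protomer displacement off the C2 axis
  mob <- template$is_mobile
  core <- !mob

  frames <- array(NA_real_, c(nf, 2 * na1, 3))
  for (f in seq_len(nf)) {
    for (p in 1:2) {
      X <- X0
      R <- rotation_about_axis(template$hinge_axis, lat$hinge[f, p])
      X[mob, ] <- sweep(sweep(X[mob, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, `+`)
      # reset the landmark pair separation to the latent target
      i1 <- template$pocket_pair[1]; i2 <- template$pocket_pair[2]
      u <- X[i2, ] - X[i1, ]
      u <- u / sqrt(sum(u^2))
      X[i2, ] <- X[i1, ] + u * target_d[f, p]
      cols <- (p - 1) * na1 + seq_len(na1)
      Xg <- sweep(X, 2, offset, `+`) %*% t(place[[p]])
      Xg[core, ] <- Xg[core, ] + lat$jitter[f, cols[core], ]
      frames[f, cols, ] <- Xg
    }
  }
  topo <- rbind(template$atoms, template$atoms)
  topo$chain <- rep(c("A", "B"), each = na1)
  topo <- structure_model(topo)$atoms   # fill serial/occupancy/... defaults
  traj <- structure(list(topology = topo, frames = frames),
                    class = "ensemble_trajectory")
  truth <- structure(list(params = params, hinge_angles = lat$hinge,
                          pocket_open = lat$open,
                          pocket_distance = target_d),
                     class = "synthetic_truth")
  list(trajectory = traj, truth = truth)
}

#' Uniform bead model of a solid sphere
#'
#' Beads uniformly distributed in a ball of the given radius (rejection
#' sampling), all with identical scattering weight; the standard closed-form
#' oracle body for scattering invariants (Rg = sqrt(3/5) R, volume
#' 4/3 pi R^3, known form factor).
#'
#' @param radius sphere radius (Angstrom), > 0.
#' @param n_beads number of beads (>= 100 for tolerable uniformity).
#' @param seed RNG seed.
#' @return a `structure_model` of HETATM pseudo-atoms.
#' @export
make_sphere_bead_model <- function(radius, n_beads = 5000L, seed = 1L) {
  if (radius <= 0) stop("radius must be > 0")
  if (n_beads < 100) stop("n_beads must be >= 100 to approximate uniformity")
  pts <- with_seed(seed, {
    out <- matrix(NA_real_, n_beads, 3)
    got <- 0L
    while (got < n_beads) {
      cand <- matrix(stats::runif(3 * (n_beads - got) * 2, -radius, radius),
                     ncol = 3)
      keep <- rowSums(cand^2) <= radius^2
      cand <- cand[keep, , drop = FALSE]
      take <- min(nrow(cand), n_beads - got)
      if (take > 0) out[got + seq_len(take), ] <- cand[seq_len(take), ]
      got <- got + take
    }
    out
  })
  structure_model(data.frame(
    name = "BD", resname = "BEA", chain = "X", resid = seq_len(n_beads),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], element = "C", hetatm = TRUE,
    stringsAsFactors = FALSE))
}

#' Generate noisy Hill-model dose-response data
#'
#' Replicate responses y = y0 + (ymax - y0) c^n / (ec50^n + c^n) + noise,
#' with iid Gaussian noise of SD `noise_sigma`.
#'
#' @param ec50 half-maximal concentration (nM), > 0.
#' @param hill_n Hill coefficient.
#' @param y0,ymax baseline and plateau responses.
#' @param concentrations concentrations (nM), all > 0; default 12 log-spaced
#'   points from 1 nM to 100 uM.
#' @param noise_sigma Gaussian noise SD (response units).
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @return list(data = `dose_response` data.frame (concentration_nM,
#'   replicate, response), truth = `synthetic_truth`).
#' @export
make_dose_response <- function(ec50, hill_n, y0 = 0, ymax = 1,
                               concentrations = 10^seq(0, 5, length.out = 12),
                               noise_sigma = 0.02, n_replicates = 2L,
                               seed = 1L) {
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  conc <- sort(concentrations)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration_nM = conc)[, 2:1]
  mu <- hill_model(grid$concentration_nM, ec50, hill_n, y0, ymax)
  eps <- with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sigma))
  d <- data.frame(concentration_nM = grid$concentration_nM,
                  replicate = grid$replicate,
                  response = mu + eps)
  class(d) <- c("dose_response", "data.frame")
  truth <- structure(list(ec50 = ec50, hill_n = hill_n, y0 = y0, ymax = ymax,
                          noise_sigma = noise_sigma, seed = seed),
                     class = "synthetic_truth")
  list(data = d, truth = truth)
}
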
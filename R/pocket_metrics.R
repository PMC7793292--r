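# Pocket-opening distance series and populations, and probe-based
# Shrake-Rupley solvent-accessible surface area of a residue set.

# van der Waals radii (Angstrom), element-keyed
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Per-frame distance between two single atoms
#'
#' Plain Euclidean distance per frame; no superposition is applied, since
#' intramolecular distances are invariant to global motion.
#'
#' @param x a `structure_model` or `ensemble_trajectory`.
#' @param sel1,sel2 selections each resolving to exactly one atom.
#' @return a `distance_series` data.frame (frame, distance_A).
#' @export
atom_pair_distance_series <- function(x, sel1, sel2) {
  i1 <- select_atoms(x, sel1, require_one = TRUE)
  i2 <- select_atoms(x, sel2, require_one = TRUE)
  if (inherits(x, "ensemble_trajectory")) {
    dv <- x$frames[, i1, , drop = FALSE] - x$frames[, i2, , drop = FALSE]
    d <- sqrt(dv[, 1, 1]^2 + dv[, 1, 2]^2 + dv[, 1, 3]^2)
  } else {
    v <- coords(x)[i1, ] - coords(x)[i2, ]
    d <- sqrt(sum(v^2))
  }
  out <- data.frame(frame = seq_along(d), distance_A = d)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Normalized distance population (histogram density)
#'
#' Histogram of a distance series over [min, max] padded by one bin on each
#' side; the returned density integrates to 1.
#'
#' @param series a `distance_series` with >= 2 frames.
#' @param bin_width bin width in Angstrom (default 0.1).
#' @return a `distance_population` data.frame (bin_center_A, density) with
#'   the bin width attached as an attribute.
#' @export
distance_population <- function(series, bin_width = 0.1) {
  v <- series$distance_A
  if (length(v) < 2) stop("insufficient data: need >= 2 frames")
  stopifnot(bin_width > 0)
  lo <- floor(min(v) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- hist(v, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_center_A = h$mids, density = h$density)
  attr(out, "bin_width_A") <- bin_width
  class(out) <- c("distance_population", "data.frame")
  out
}

#' Probability mass of a population near a landmark distance
#'
#' @param pop a `distance_population`.
#' @param center landmark distance (Angstrom).
#' @param halfwidth window half-width (Angstrom).
#' @export
population_mass <- function(pop, center, halfwidth) {
  bw <- attr(pop, "bin_width_A")
  keep <- abs(pop$bin_center_A - center) <= halfwidth
  sum(pop$density[keep]) * bw
}

# Shrake-Rupley accessible area of atoms `pocket_idx` in one coordinate set.
sasa_one_frame <- function(xyz, radii, pocket_idx, probe, pts) {
  total <- 0
  rexp <- radii + probe
  for (i in pocket_idx) {
    ri <- rexp[i]
    # only neighbours whose expanded spheres can intersect this one occlude
    dv <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(dv^2)
    nb <- which(d2 < (ri + rexp)^2 & d2 > 0)
    surf <- sweep(pts * ri, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])
      acc[acc] <- rowSums(dj^2) >= rexp[j]^2
    }
    total <- total + mean(acc) * 4 * pi * ri^2
  }
  total
}

#' Probe-based solvent-accessible surface area of a pocket
#'
#' Shrake-Rupley algorithm: `n_sphere_points` quasi-uniform points (a
#' deterministic golden-spiral lattice) are placed on each pocket atom's
#' expanded sphere of radius r_atom + probe; a point is accessible if it
#' lies outside every other atom's expanded sphere (all atoms in the model
#' occlude, not only pocket atoms). The pocket area is the accessible
#' fraction times 4 pi (r_atom + probe)^2 summed over pocket atoms. The
#' probe mimics the ligand whose access is being scored; for a cAMP-sized
#' probe use ~2.8 Angstrom.
#'
#' @param x a `structure_model` or `ensemble_trajectory`.
#' @param pocket_sel `atom_selection` of pocket atoms to score.
#' @param probe_radius probe radius in Angstrom, > 0.
#' @param n_sphere_points test points per atom (default 960).
#' @param radii optional named vector of per-element radii overriding the
#'   built-in van der Waals table (C 1.70, N 1.55, O 1.52, S 1.80).
#' @return a `sasa_result`: list(area_A2 per frame, probe_radius,
#'   pocket_indices, n_sphere_points).
#' @export
pocket_sasa <- function(x, pocket_sel = atom_selection(), probe_radius = 2.8,
                        n_sphere_points = 960L, radii = NULL) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12)
  tab <- .vdw_radii
  if (!is.null(radii)) tab[names(radii)] <- radii
  topo <- if (inherits(x, "ensemble_trajectory")) x$topology else x$atoms
  el <- topo$element
  el[el == "" | is.na(el)] <- substr(topo$name[el == "" | is.na(el)], 1, 1)
  r <- unname(tab[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("no radius for element(s): ", paste(bad, collapse = ", "),
         " (supply `radii` overrides)")
  }
  pocket_idx <- select_atoms(x, pocket_sel)
  if (length(pocket_idx) == 0)
    stop("no atoms match pocket selection: ", format_selection(pocket_sel))
  pts <- golden_spiral_points(n_sphere_points)
  areas <- if (inherits(x, "ensemble_trajectory")) {
    vapply(seq_len(n_frames(x)), function(f)
      sasa_one_frame(x$frames[f, , ], r, pocket_idx, probe_radius, pts),
      numeric(1))
  } else {
    sasa_one_frame(coords(x), r, pocket_idx, probe_radius, pts)
  }
  structure(list(area_A2 = areas, probe_radius = probe_radius,
                 pocket_indices = pocket_idx,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_result")
}
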
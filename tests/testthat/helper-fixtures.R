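# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# Write a small PDB file from a vector of raw lines; returns the path.
write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# A 10-residue single-chain CA trace as raw PDB lines.
ten_residue_lines <- function() {
  sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          1:10, 1:10, 3.8 * (1:10), rep(0, 10), rep(0, 10))
}

# Ideal alpha-helix CA trace: rise 1.5 A/residue, twist 100 deg/residue,
# radius 2.3 A, axis along `axis` starting at `origin`.
ideal_helix <- function(n_res, axis = c(0, 0, 1), origin = c(0, 0, 0),
                        phase = 0) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  i <- seq_len(n_res) - 1
  ang <- phase + i * 100 * pi / 180
  t(sapply(seq_along(i), function(k)
    origin + 1.5 * i[k] * axis + 2.3 * cos(ang[k]) * u +
      2.3 * sin(ang[k]) * v))
}

# structure_model from a bare coordinate matrix (one CA per residue).
model_from_xyz <- function(xyz, resid = seq_len(nrow(xyz)), chain = "A",
                           name = "CA", element = "C") {
  structure_model(data.frame(
    name = name, resname = "GLY", chain = chain, resid = resid,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = element,
    stringsAsFactors = FALSE))
}

# Independent Kabsch oracle: best-fit RMSD by brute-force search over unit
# quaternions (coarse grid + local refinement via optim on quaternion
# parameters). Slow; use on tiny point sets only.
brute_force_rmsd <- function(mobile, reference) {
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf
  set.seed(99)
  for (i in 1:200) {
    q0 <- rnorm(4)
    o <- optim(q0, obj, method = "BFGS", control = list(maxit = 200))
    if (o$value < best) best <- o$value
  }
  best
}

# Independent two-sphere SASA oracle by exact spherical-cap geometry:
# accessible area of sphere 1 (radius R1, center at origin) occluded by
# sphere 2 (radius R2, center at distance d).
two_sphere_cap_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  # height of the cap of sphere 1 inside sphere 2
  x <- (d^2 + R1^2 - R2^2) / (2 * d)   # plane of intersection
  h <- R1 - x
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Analytic solid-sphere form factor, normalized to 1 at q = 0.
sphere_form_factor <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# Default synthetic ensemble pair used across tests (cached per session).
asym_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_two_protomer_ensemble(
        protomer_template(),
        ensemble_params(n_frames = 200, hinge_sigma_p1 = 2,
                        hinge_sigma_p2 = 20, core_jitter_sigma = 0.1,
                        seed = 42))
    cache
  }
})

sel_core <- function(ch) atom_selection(chain = ch, resid_range = c(201, 265))
sel_mobile <- function(ch) atom_selection(chain = ch, resid_range = c(266, 360))
sel_atom <- function(ch, resid, name)
  atom_selection(chain = ch, resids = resid, names = name)

vector_series_for <- function(traj, ch)
  interdomain_vector_series(traj, sel_atom(ch, 230, "CA"),
                            sel_atom(ch, 359, "CA"), sel_core(ch))
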
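test_that("pair distance series matches direct geometry", {
  traj <- asym_ensemble()$trajectory
  same <- atom_pair_distance_series(traj, sel_atom("A", 230, "CA"),
                                    sel_atom("A", 230, "CA"))
  expect_equal(same$distance_A, rep(0, n_frames(traj)))
  ser <- atom_pair_distance_series(traj, sel_atom("A", 351, "CG"),
                                   sel_atom("A", 360, "CB"))
  i1 <- select_atoms(traj, sel_atom("A", 351, "CG"))
  i2 <- select_atoms(traj, sel_atom("A", 360, "CB"))
  direct <- sqrt(rowSums((traj$frames[, i1, ] - traj$frames[, i2, ])^2))
  expect_equal(ser$distance_A, direct)
  expect_error(atom_pair_distance_series(traj, atom_selection(names = "CA"),
                                         sel_atom("A", 360, "CB")),
               "expected exactly 1")
})

test_that("landmark separations in the synthetic reference fragments read 6.9/4.9", {
  # synthetic stand-ins for the open (holoenzyme) and closed (cAMP-bound)
  # pocket states; see inst/extdata/README.txt
  holo <- read_structure(system.file("extdata", "synthetic_holo_cnbb.pdb",
                                     package = "protasym"))[[1]]
  camp <- read_structure(system.file("extdata", "synthetic_camp_cnbb.pdb",
                                     package = "protasym"))[[1]]
  d_open <- atom_pair_distance_series(
    holo, sel_atom("A", 360, "CB"), sel_atom("A", 351, "CG"))$distance_A
  d_closed <- atom_pair_distance_series(
    camp, sel_atom("A", 360, "CB"), sel_atom("A", 351, "CG"))$distance_A
  expect_equal(round(d_open, 1), 6.9)
  expect_equal(round(d_closed, 1), 4.9)
})

test_that("distance populations are normalized and recover latent state mass", {
  const <- structure(data.frame(frame = 1:10, distance_A = rep(5, 10)),
                     class = c("distance_series", "data.frame"))
  pop <- distance_population(const)
  bw <- attr(pop, "bin_width_A")
  expect_equal(sum(pop$density) * bw, 1, tolerance = 1e-6)
  expect_equal(sum(pop$density > 0), 1)
  expect_true(any(abs(pop$bin_center_A[pop$density > 0] - 5) <= bw))

  gen <- make_two_protomer_ensemble(
    protomer_template(),
    ensemble_params(n_frames = 2000, pocket_open_fraction_p1 = 0.3,
                    core_jitter_sigma = 0, seed = 9))
  ser <- atom_pair_distance_series(gen$trajectory, sel_atom("A", 351, "CG"),
                                   sel_atom("A", 360, "CB"))
  pop <- distance_population(ser)
  expect_equal(sum(pop$density) * 0.1, 1, tolerance = 1e-6)
  mass_open <- population_mass(pop, 6.9, 0.6)
  expect_equal(mass_open, 0.30, tolerance = 0.03 / 0.30)
  # cross-check against the generator's latent states
  expect_equal(mean(gen$truth$pocket_open[, 1]), 0.30, tolerance = 0.1)

  expect_error(distance_population(const[1, , drop = FALSE]),
               "insufficient data")
})

test_that("binning a mixed series equals the frame-weighted population mixture", {
  s1 <- structure(data.frame(frame = 1:60,
                             distance_A = seq(4, 6, length.out = 60)),
                  class = c("distance_series", "data.frame"))
  s2 <- structure(data.frame(frame = 1:40,
                             distance_A = seq(5, 8, length.out = 40)),
                  class = c("distance_series", "data.frame"))
  mixed <- structure(data.frame(frame = 1:100,
                                distance_A = c(s1$distance_A, s2$distance_A)),
                     class = c("distance_series", "data.frame"))
  pm <- distance_population(mixed)
  mass_in <- function(pop, lo, hi) {
    bw <- attr(pop, "bin_width_A")
    sum(pop$density[pop$bin_center_A >= lo & pop$bin_center_A < hi]) * bw
  }
  p1 <- distance_population(s1); p2 <- distance_population(s2)
  for (win in list(c(4, 5), c(5, 6), c(6, 8.5))) {
    expect_equal(mass_in(pm, win[1], win[2]),
                 0.6 * mass_in(p1, win[1], win[2]) +
                   0.4 * mass_in(p2, win[1], win[2]),
                 tolerance = 1e-9)
  }
})

test_that("isolated-atom SASA matches the closed form and occlusion zeroes it", {
  m <- model_from_xyz(matrix(c(0, 0, 0), 1, 3), name = "S", element = "S")
  res <- pocket_sasa(m, atom_selection(), probe_radius = 1.4,
                     n_sphere_points = 960)
  expect_equal(res$area_A2, 4 * pi * (1.8 + 1.4)^2,
               tolerance = 0.01)

  # atom enclosed by a tight shell of occluders -> zero accessible area
  shell <- golden_spiral_points(60) * 2.0
  xyz <- rbind(c(0, 0, 0), shell)
  m <- model_from_xyz(xyz, resid = 1:61)
  res <- pocket_sasa(m, atom_selection(resids = 1), probe_radius = 1.4)
  expect_equal(res$area_A2, 0)
})

test_that("two-sphere SASA matches the analytic spherical-cap oracle", {
  probe <- 1.4
  r <- 1.7                               # carbon
  R <- r + probe
  for (sep in c(3.0, 4.5, 5.5)) {
    m <- model_from_xyz(rbind(c(0, 0, 0), c(sep, 0, 0)), resid = 1:2)
    got <- pocket_sasa(m, atom_selection(resids = 1), probe_radius = probe,
                       n_sphere_points = 3840)$area_A2
    expect_equal(got, two_sphere_cap_area(R, R, sep),
                 tolerance = 0.02)
  }
})

test_that("SASA invariants: rigid motion, monotone occlusion, convergence", {
  set.seed(8)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  m <- model_from_xyz(xyz, resid = 1:10)
  sel <- atom_selection(resids = 1:4)
  a0 <- pocket_sasa(m, sel)$area_A2

  Rm <- protasym:::rotation_about_axis(c(1, 2, 3), 55)
  # invariance holds up to the finite sphere-point lattice (~0.1% here)
  m2 <- model_from_xyz(sweep(xyz %*% t(Rm), 2, c(4, 5, 6), `+`), resid = 1:10)
  expect_equal(pocket_sasa(m2, sel)$area_A2, a0, tolerance = 0.005)

  # adding occluders can only decrease pocket area
  m3 <- model_from_xyz(rbind(xyz, xyz + 1.0), resid = 1:20)
  expect_lte(pocket_sasa(m3, sel)$area_A2, a0 + 1e-9)

  a_fine <- pocket_sasa(m, sel, n_sphere_points = 3840)$area_A2
  expect_lt(abs(a_fine - a0) / a_fine, 0.005)

  expect_error(pocket_sasa(model_from_xyz(xyz, element = "Xx"), sel),
               "no radius")
})

test_that("open-prone ensembles expose more pocket surface", {
  area_for <- function(open_frac) {
    gen <- make_two_protomer_ensemble(
      protomer_template(),
      ensemble_params(n_frames = 25, pocket_open_fraction_p1 = open_frac,
                      core_jitter_sigma = 0, seed = 21))
    res <- pocket_sasa(gen$trajectory,
                       atom_selection(chain = "A", resids = c(351, 360)),
                       probe_radius = 2.8, n_sphere_points = 480)
    mean(res$area_A2)
  }
  expect_gt(area_for(0.8), area_for(0.2))
})
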
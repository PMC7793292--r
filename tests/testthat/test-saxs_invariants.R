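# Closed-form bodies (two-point scatterers, uniform spheres) provide exact
# oracles for every scattering quantity.

q_small <- seq(0.005, 0.8, length.out = 160)

test_that("Debye profile matches the two-scatterer closed form", {
  d <- 5
  m <- model_from_xyz(rbind(c(0, 0, 0), c(d, 0, 0)), resid = 1:2)
  prof <- debye_profile(m, c(0, 0.1, 0.5, 1.0), bin_width = 1e-4)
  expected <- function(q) if (q == 0) 4 else 2 + 2 * sin(q * d) / (q * d)
  expect_equal(prof$intensity, vapply(c(0, 0.1, 0.5, 1.0), expected,
                                      numeric(1)), tolerance = 1e-4)
  expect_error(debye_profile(model_from_xyz(matrix(0, 1, 3)), q_small),
               "empty structure")
})

test_that("Debye I(0) equals (sum f)^2 including non-uniform weights", {
  set.seed(3)
  m <- model_from_xyz(matrix(rnorm(60, sd = 8), 20, 3), resid = 1:20)
  f <- runif(20, 0.5, 2)
  prof <- debye_profile(m, c(0, 0.01), weights = f, bin_width = 0.01)
  expect_equal(prof$intensity[1], sum(f)^2, tolerance = 1e-9)
})

test_that("histogram-accelerated Debye matches the direct double sum", {
  set.seed(12)
  xyz <- matrix(rnorm(600, sd = 10), 200, 3)
  m <- model_from_xyz(xyz, resid = 1:200)
  qg <- c(0.02, 0.1, 0.3)
  prof <- debye_profile(m, qg, bin_width = 0.02)
  direct <- vapply(qg, function(q) {
    D <- as.matrix(dist(xyz))
    x <- q * D
    s <- ifelse(x < 1e-12, 1, sin(x) / x)
    sum(s)
  }, numeric(1))
  expect_equal(prof$intensity, direct, tolerance = 1e-3)
})

test_that("Debye profile of a bead sphere matches the solid-sphere form factor", {
  sp <- make_sphere_bead_model(10, 5000, seed = 3)
  q <- seq(0.02, 0.4, by = 0.02)          # qR <= 4
  prof <- debye_profile(sp, q, bin_width = 0.05)
  got <- prof$intensity / 5000^2
  expect_equal(got, sphere_form_factor(q, 10), tolerance = 0.02)
})

test_that("P(r) is a unit-area density with correct dmax and peaks", {
  m <- model_from_xyz(rbind(c(0, 0, 0), c(5, 0, 0)), resid = 1:2)
  pr <- pair_distance_distribution(m, bin_width = 0.5)
  expect_equal(pr$dmax, 5)
  expect_equal(sum(pr$pr) * pr$bin_width, 1, tolerance = 1e-9)
  expect_equal(sum(pr$pr > 0), 1)
  expect_true(abs(pr$r[pr$pr > 0] - 5) <= 0.5)

  sp <- make_sphere_bead_model(10, 3000, seed = 5)
  pr <- pair_distance_distribution(sp, bin_width = 0.25)
  expect_lte(pr$dmax, 20)
  expect_equal(sum(pr$pr) * 0.25, 1, tolerance = 1e-9)
  # uniform-ball pair-distance density peaks near ~1.05 R
  peak_r <- pr$r[which.max(pr$pr)]
  expect_lt(abs(peak_r - 10.5), 1.0)
  expect_error(pair_distance_distribution(model_from_xyz(matrix(0, 1, 3))),
               "insufficient atoms")
})

test_that("Rg from P(r): two-point body, sphere, and scale invariance", {
  d <- 8
  m <- model_from_xyz(rbind(c(0, 0, 0), c(d, 0, 0)), resid = 1:2)
  pr <- pair_distance_distribution(m, bin_width = 1e-3)
  expect_equal(rg_from_pr(pr), d / 2, tolerance = 1e-3)

  sp <- make_sphere_bead_model(10, 5000, seed = 3)
  pr <- pair_distance_distribution(sp, bin_width = 0.25)
  expect_equal(rg_from_pr(pr), sqrt(3 / 5) * 10, tolerance = 0.02)

  pr_scaled <- pr; pr_scaled$pr <- 17.3 * pr$pr
  expect_equal(rg_from_pr(pr_scaled), rg_from_pr(pr), tolerance = 1e-12)
})

test_that("Guinier fit recovers exact synthetic parameters", {
  q <- seq(0.002, 0.1, by = 0.002)
  prof <- scattering_profile(q, 7 * exp(-q^2 * 25^2 / 3))
  fit <- guinier_fit(prof)
  expect_equal(fit$rg, 25, tolerance = 1e-6)
  expect_equal(fit$i0, 7, tolerance = 1e-6)
  expect_lte(fit$q_range_used[2] * fit$rg, 1.3 + 1e-6)
})

test_that("Guinier Rg of the bead sphere is within 2% of sqrt(3/5) R", {
  sp <- make_sphere_bead_model(10, 5000, seed = 3)
  prof <- debye_profile(sp, q_small)
  fit <- guinier_fit(prof)
  expect_equal(fit$rg, sqrt(3 / 5) * 10, tolerance = 0.02)
  # dual-route internal consistency
  rg_pr <- rg_from_pr(pair_distance_distribution(sp, 0.25))
  expect_equal(fit$rg, rg_pr, tolerance = 0.03)
})

test_that("Guinier estimates are unbiased and tight under 1% noise", {
  q <- seq(0.002, 0.15, by = 0.002)
  true_rg <- 20
  clean <- 10 * exp(-q^2 * true_rg^2 / 3)
  rgs <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- clean * (1 + rnorm(length(q), 0, 0.01))
    guinier_fit(scattering_profile(q, noisy, sigma = clean * 0.01))$rg
  }, numeric(1))
  expect_lt(abs(mean(rgs) - true_rg) / true_rg, 0.01)
  expect_lt(sd(rgs) / true_rg, 0.02)
})

test_that("Porod MW rule reproduces the printed worked values", {
  expect_identical(porod_mw_from_volume(290000), 171L)
  expect_identical(porod_mw_from_volume(347000), 204L)
  # porod_volume_mw applies the same rule to its own volume
  sp <- make_sphere_bead_model(10, 5000, seed = 3)
  prof <- debye_profile(sp, q_small)
  fit <- guinier_fit(prof)
  po <- porod_volume_mw(prof, fit$i0)
  expect_equal(po$mw_estimate, po$porod_volume / 1.7 / 1000)
  expect_identical(po$mw_kda, porod_mw_from_volume(po$porod_volume))
})

test_that("Porod volume of the bead sphere is within 5% of 4/3 pi R^3", {
  sp <- make_sphere_bead_model(10, 5000, seed = 3)
  prof <- debye_profile(sp, q_small)
  fit <- guinier_fit(prof)
  po <- porod_volume_mw(prof, fit$i0)
  expect_equal(po$porod_volume, 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("Kratky transform: sphere bell shape, 1/q^2 plateau, zeros", {
  sp <- make_sphere_bead_model(10, 2000, seed = 4)
  prof <- debye_profile(sp, q_small)
  kr <- kratky_transform(prof)
  expect_true(kr$compact)
  expect_gt(kr$peak_q, q_small[1])

  q <- seq(0.05, 0.5, by = 0.01)
  kr <- kratky_transform(scattering_profile(q, 3.5 / q^2))
  expect_equal(kr$kratky, rep(3.5, length(q)), tolerance = 1e-12)
  expect_false(kr$compact)

  kr <- kratky_transform(scattering_profile(q, rep(0, length(q))))
  expect_equal(kr$kratky, rep(0, length(q)))
})

test_that("profile chi-square: zero for identity, ~1 at matched noise, sigma scaling", {
  q <- seq(0.01, 0.3, by = 0.005)
  Im <- 100 * exp(-q^2 * 30)
  self <- profile_chi2(scattering_profile(q, Im),
                       scattering_profile(q, Im, sigma = rep(1, length(q))))
  expect_equal(self$chi2, 0, tolerance = 1e-12)
  expect_equal(self$scale, 1, tolerance = 1e-12)

  chis <- vapply(1:50, function(s) {
    set.seed(s)
    Ie <- 2.5 * Im + rnorm(length(q))
    profile_chi2(scattering_profile(q, Im),
                 scattering_profile(q, Ie, sigma = rep(1, length(q))))$chi2
  }, numeric(1))
  sem <- sd(chis) / sqrt(50)
  expect_lt(abs(mean(chis) - 1), 3 * sem)
  set.seed(1)
  Ie <- 2.5 * Im + rnorm(length(q))
  fit <- profile_chi2(scattering_profile(q, Im),
                      scattering_profile(q, Ie, sigma = rep(1, length(q))))
  expect_equal(fit$scale, 2.5, tolerance = 0.01)

  # noise-free mismatch: doubling sigma divides chi2 by 4
  Ie2 <- Im * 1.02 + 0.5
  c1 <- profile_chi2(scattering_profile(q, Im),
                     scattering_profile(q, Ie2, sigma = rep(1, length(q))))
  c2 <- profile_chi2(scattering_profile(q, Im),
                     scattering_profile(q, Ie2, sigma = rep(2, length(q))))
  expect_equal(c1$chi2 / c2$chi2, 4, tolerance = 1e-9)

  expect_error(profile_chi2(scattering_profile(c(1, 2), c(1, 1)),
                            scattering_profile(c(5, 6), c(1, 1),
                                               sigma = c(1, 1))),
               "overlapping")
})

test_that("SAXS quantities are invariant under rigid-body motion", {
  sp <- make_sphere_bead_model(8, 800, seed = 6)
  xyz <- coords(sp)
  Rm <- protasym:::rotation_about_axis(c(3, 1, 2), 71)
  sp2 <- model_from_xyz(sweep(xyz %*% t(Rm), 2, c(100, -50, 3), `+`),
                        resid = seq_len(nrow(xyz)))
  q <- seq(0.01, 0.5, length.out = 60)
  expect_equal(debye_profile(sp2, q)$intensity,
               debye_profile(sp, q)$intensity, tolerance = 1e-6)
  expect_equal(pair_distance_distribution(sp2, 0.25)$dmax,
               pair_distance_distribution(sp, 0.25)$dmax, tolerance = 1e-9)
})

test_that("3-column profile files round-trip through the reader", {
  q <- seq(0.01, 0.2, by = 0.01)
  I <- 5 * exp(-q^2 * 100)
  f <- tempfile(fileext = ".dat")
  writeLines(c("# q I sigma", sprintf("%.6f %.6e %.3e", q, I, I * 0.02)), f)
  prof <- read_scattering_profile(f)
  expect_equal(prof$q, q)
  expect_equal(prof$intensity, I, tolerance = 1e-5)
  expect_equal(prof$sigma, I * 0.02, tolerance = 1e-3)
})
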
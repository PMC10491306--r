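# Density profiles, FWHM thickness and protein-proximal thinning.

test_that("proximal selection keeps whole lipids within the cutoff", {
  prot <- matrix(c(5, 5, 5), 1, 3)
  sys <- make_flat_system(head_z = c(5.2, 5.2, 4.8), tail_z = c(5, 5, 5),
                          head_xy = rbind(c(5.5, 5), c(9, 9), c(5.3, 5)),
                          protein_xyz = prot)
  beads <- proximal_lipid_beads(sys$frame, sys$topology, cutoff_nm = 1.0)
  near_res <- unique(sys$topology$atoms$resid[beads])
  expect_setequal(near_res, c(1L, 3L))
  # headgroup beads are excluded from the hydrophobic set
  expect_false(any(sys$topology$atoms$name[beads] == "NC3"))
  expect_length(proximal_lipid_beads(sys$frame, sys$topology, cutoff_nm = 0),
                0L)
})

test_that("empty protein group demands an explicit bulk request", {
  sys <- make_flat_system(head_z = c(7, 3), tail_z = c(5, 5))
  expect_error(proximal_lipid_beads(sys$frame, sys$topology), "bulk")
})

test_that("proximal selection agrees with an exhaustive pairwise-distance oracle", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 36L, duration_ns = 2,
                         n_replicas = 1L, flip_rate = 0,
                         protein = synthetic_protein(), seed = 21)
  sim <- simulate_bilayer(spec)
  topo <- sim$topology
  fr <- get_frame(sim$trajectories[[1]], 1L)
  got <- sort(proximal_lipid_beads(fr, topo, cutoff_nm = 1.0))
  # O(N^2) oracle with explicit xy minimum image
  box <- fr$box
  lip <- topo$groups$lipids
  prot <- topo$groups$protein
  near <- logical(0)
  for (r in unique(topo$atoms$resid[lip])) {
    ridx <- lip[topo$atoms$resid[lip] == r]
    dmin <- Inf
    for (i in ridx) for (j in prot) {
      d <- fr$coords[i, ] - fr$coords[j, ]
      d[1] <- d[1] - box[1] * round(d[1] / box[1])
      d[2] <- d[2] - box[2] * round(d[2] / box[2])
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    if (dmin <= 1.0) near <- c(near, r)
  }
  hb <- hydrophobic_beads(topo)
  expected <- sort(hb[topo$atoms$resid[hb] %in% near])
  expect_identical(got, expected)
})

test_that("density profiles are normalised to beads per frame", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 16L, duration_ns = 50,
                         frame_interval_ns = 5, n_replicas = 1L,
                         flip_rate = 0, seed = 22)
  sim <- simulate_bilayer(spec)
  sel <- select_lipids(sim$topology)
  prof <- density_profile(sim$trajectories[[1]], sim$topology, sel,
                          equilibration_ns = 0)
  expect_equal(sum(prof$density) * attr(prof, "bin_nm"),
               attr(prof, "mean_beads_per_frame"))
  # 10 hydrophobic beads per lipid (12 minus NC3 and PO4)
  expect_equal(attr(prof, "mean_beads_per_frame"), 32 * 10)
})

test_that("a uniform slab of beads gives a flat profile of height N per width", {
  n <- 80L
  z <- 5 + seq(-2 + 4 / (2 * n), 2 - 4 / (2 * n), length.out = n)
  sys <- make_flat_system(head_z = rep(c(7.5, 2.5), n / 2), tail_z = z,
                          head_xy = cbind(rep(seq_len(10), 8), rep(1:8, each = 10)))
  prof <- density_profile(sys$trajectory, sys$topology, sys$selection,
                          equilibration_ns = 0, stride_ns = 1)
  inside <- abs(prof$z_nm) < 1.9
  # 2 tail beads per lipid, uniform over 4 nm
  expect_true(all(abs(prof$density[inside] - 2 * n / 4) < 1e-9))
  expect_true(all(prof$density[abs(prof$z_nm) > 2.1] == 0))
})

test_that("FWHM of simple analytic profiles is exact", {
  z <- seq(-3.05, 3.05, by = 0.1)  # bin centres straddle the edges at +-1.5
  rect <- data.frame(z_nm = z, density = as.numeric(abs(z) < 1.5))
  expect_equal(thickness_from_profile(rect), 3.0, tolerance = 1e-9)
  z <- seq(-3, 3, by = 0.1)
  tri <- data.frame(z_nm = z, density = pmax(0, 1 - abs(z) / 2))
  expect_equal(thickness_from_profile(tri), 2.0, tolerance = 1e-9)
  # Gaussian-edged slab: closed-form FWHM = 2a + 2*s*sqrt(2 ln 2)
  zf <- seq(-5, 5, by = 0.001)
  a <- 1.3; s <- 0.25
  d <- ifelse(abs(zf) <= a, 1, exp(-(abs(zf) - a)^2 / (2 * s^2)))
  expect_equal(thickness_from_profile(data.frame(z_nm = zf, density = d)),
               2 * a + 2 * s * sqrt(2 * log(2)), tolerance = 1e-3)
})

test_that("multimodal profiles raise an ambiguity error with the crossing count", {
  z <- seq(-3, 3, by = 0.1)
  two <- data.frame(z_nm = z,
                    density = exp(-(z - 1.5)^2 / 0.02) +
                      exp(-(z + 1.5)^2 / 0.02))
  expect_error(thickness_from_profile(two), "4 half-maximum crossings")
})

test_that("thickness is invariant under z translation and reflection", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 25L, duration_ns = 100,
                         frame_interval_ns = 5, n_replicas = 1L,
                         flip_rate = 0, seed = 23)
  sim <- simulate_bilayer(spec)
  sel <- select_lipids(sim$topology)
  tr <- sim$trajectories[[1]]
  t0 <- thickness_from_profile(
    density_profile(tr, sim$topology, sel, equilibration_ns = 0))
  shifted <- tr; shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 0.8
  t1 <- thickness_from_profile(
    density_profile(shifted, sim$topology, sel, equilibration_ns = 0))
  mirrored <- tr; mirrored$coords[, 3, ] <- 10 - mirrored$coords[, 3, ]
  t2 <- thickness_from_profile(
    density_profile(mirrored, sim$topology, sel, equilibration_ns = 0))
  expect_equal(t1, t0, tolerance = 1e-12)
  expect_equal(t2, t0, tolerance = 1e-12)
})

test_that("identical local and bulk profiles give zero thinning", {
  prof <- data.frame(z_nm = seq(-3, 3, 0.1),
                     density = as.numeric(abs(seq(-3, 3, 0.1)) <= 1.45))
  expect_equal(thickness_from_profile(prof) - thickness_from_profile(prof), 0)
})

test_that("an imposed 0.3 nm proximal thinning is recovered within 0.05 nm", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 256L, duration_ns = 800,
                         frame_interval_ns = 5, n_replicas = 1L,
                         flip_rate = 0, protein = synthetic_protein(),
                         local_thinning_nm = 0.3, seed = 24)
  sim <- simulate_bilayer(spec)
  sel <- select_lipids(sim$topology)
  th <- thinning_analysis(sim$trajectories[[1]], sim$topology, sel,
                          equilibration_ns = 100)
  expect_equal(th$thinning_nm, 0.3, tolerance = 0.05 / 0.3)
  expect_gt(th$local_nm, 0)
  expect_gt(th$bulk_nm, 0)
})

test_that("rate-thinning correlation report matches cor() and stays small for independent systems", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r <- rate_thinning_correlation(x, y)
  expect_equal(r$r, cor(x, y))
  expect_equal(r$n, 5L)
  # independently imposed rates and thinnings across measured systems
  set.seed(25)
  rates <- numeric(12); thins <- numeric(12)
  for (i in 1:12) {
    lam <- runif(1, 0, 5); delta <- runif(1, 0, 0.4)
    sim <- simulate_bilayer(
      synthetic_spec(n_lipids_per_leaflet = 36L, duration_ns = 1200,
                     n_replicas = 1L, flip_rate = lam,
                     protein = synthetic_protein(),
                     local_thinning_nm = delta, seed = 1000 + i),
      mode = "angles")
    s <- rate_from_sim(sim, equilibration_ns = 200, bin_width_ns = 100)
    rates[i] <- s$summary$mean
    thins[i] <- delta
  }
  r2 <- rate_thinning_correlation(rates, thins)
  expect_true(abs(r2$r) < 0.8)
})
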
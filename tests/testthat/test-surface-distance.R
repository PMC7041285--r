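test_that("surface sampling is area-uniform, linear in density and deterministic", {
  # unit square as two triangles, density 100 -> about 100 points on it
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0.2))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 5), c(2, 3, 5), c(3, 4, 5),
             c(4, 1, 5))
  m <- meniscus_mesh(v, f, "square", "medial", "right",
                     root_anterior = c(1, 0.5, 0), root_posterior = c(0, 0.5, 0))
  p <- sample_surface(m, density = 100, seed = 7)
  sq <- p[p[, 3] == 0, , drop = FALSE]
  area_sq <- 1
  expect_gt(nrow(sq), area_sq * 100 - 15)
  expect_lt(nrow(sq), area_sq * 100 + 15)
  expect_true(all(sq[, 1] >= 0 & sq[, 1] <= 1 & sq[, 2] >= 0 & sq[, 2] <= 1))

  p2 <- sample_surface(m, density = 200, seed = 7)
  expect_gt(nrow(p2) / nrow(p), 2 * 0.9)
  expect_lt(nrow(p2) / nrow(p), 2 * 1.1)

  expect_identical(sample_surface(m, 100, seed = 7),
                   sample_surface(m, 100, seed = 7))
})

test_that("ICP recovers an applied rigid transform on an exact copy", {
  m <- small_meniscus(shape_seed = 13, perturb_amplitude = 0.8)
  rot <- rot_z(25)
  tra <- c(5, -3, 2)
  mt <- menisize:::transform_mesh(m, rot, tra)
  tf <- icp_register(m, mt, density = 2)
  expect_true(tf$converged)
  # recovered transform composed with the inverse of the applied one
  comp <- t(rot) %*% tf$rotation
  ang <- acos(pmin(1, (sum(diag(comp)) - 1) / 2))
  expect_lt(ang, 1e-3)
  expect_lt(max(abs(tf$translation - tra)), 1e-3)

  # source = target: identity transform, zero RMS
  tf0 <- icp_register(m, m, density = 2)
  expect_lt(acos(pmin(1, (sum(diag(tf0$rotation)) - 1) / 2)), 1e-6)
  expect_lt(max(abs(tf0$translation)), 1e-6)
  expect_lt(tf0$rms, 1e-9)
})

test_that("ICP improves on centroid-only alignment", {
  a <- small_meniscus(shape_seed = 1, patient_id = "pa")
  b <- small_meniscus(31, 44, 8.5, shape_seed = 2, patient_id = "pb")
  tf <- suppressWarnings(icp_register(a, b, density = 2))
  # centroid-only RMS: mean squared closest distance after matching centroids
  pa <- sample_surface(a, 2)
  pb <- sample_surface(b, 2)
  shift <- colMeans(pb) - colMeans(pa)
  pa_c <- sweep(pa, 2L, -shift)
  d <- menisize:::cpp_point_surface_distance(pa_c, b$vertices, b$faces - 1L)
  expect_lte(tf$rms, sqrt(mean(d^2)) + 1e-9)
})

test_that("identical meshes are at (near) zero distance, also after perturbation", {
  m <- small_meniscus(shape_seed = 21)
  d <- surface_distance(m, m, density = 2)
  expect_lt(d$mesd, 1e-3)
  expect_lt(d$masd, 1e-3)

  set.seed(99)
  for (i in 1:3) {
    mt <- menisize:::transform_mesh(m, random_rotation(), rnorm(3, 0, 20))
    dt <- surface_distance(m, mt, density = 2)
    expect_lt(dt$mesd, 1e-3)
  }
})

test_that("concentric spheres reproduce the analytic gap", {
  s10 <- icosphere_mesh(10, subdiv = 4, patient_id = "s10")
  s11 <- icosphere_mesh(11, subdiv = 4, patient_id = "s11")
  d <- surface_distance(s10, s11, density = 2, register = FALSE)
  expect_equal(d$mesd, 1.0, tolerance = 0.02)
  expect_equal(d$masd, 1.0, tolerance = 0.02)
})

test_that("tree-accelerated distances match the brute-force oracle exactly", {
  for (i in 1:4) {
    a <- generate_base_mesh(28 + i, 42 + i, 8 + i / 2, "medial",
                            shape_seed = i, perturb_amplitude = 0.8,
                            patient_id = "oa", n_arc = 10L, n_profile = 6L)
    b <- generate_base_mesh(30, 45, 9, "medial", shape_seed = i + 50,
                            perturb_amplitude = 0.8, patient_id = "ob",
                            n_arc = 10L, n_profile = 6L)
    got <- surface_distance(a, b, density = 0.08, register = FALSE)
    want <- oracle_surface_distance(a, b, density = 0.08)
    expect_equal(unname(got$directed_means["ab"]), want$mean_ab,
                 tolerance = 1e-9)
    expect_equal(unname(got$directed_means["ba"]), want$mean_ba,
                 tolerance = 1e-9)
    expect_equal(got$mesd, want$mesd, tolerance = 1e-9)
    expect_equal(got$masd, want$masd, tolerance = 1e-9)
  }
})

test_that("MeSD/MaSD are symmetric, ordered, and rigid-motion invariant", {
  set.seed(31)
  meshes <- lapply(1:5, function(i)
    small_meniscus(28 + 2 * runif(1), 43 + 3 * runif(1), 8 + runif(1),
                   shape_seed = i, patient_id = paste0("p", i)))
  for (i in 1:4) {
    a <- meshes[[i]]
    b <- meshes[[i + 1]]
    d1 <- surface_distance(a, b, density = 2)
    d2 <- surface_distance(b, a, density = 2)
    expect_lt(abs(d1$mesd - d2$mesd), 1e-6)
    expect_lt(abs(d1$masd - d2$masd), 1e-6)
    expect_lte(d1$mesd, d1$masd)
    expect_equal(d1$mesd, max(d1$directed_means))
    expect_equal(d1$masd, max(d1$directed_maxima))

    mt <- menisize:::transform_mesh(a, random_rotation(), rnorm(3, 0, 15))
    d3 <- surface_distance(mt, b, density = 2)
    expect_lt(abs(d3$mesd - d1$mesd), 0.02)
    expect_lt(abs(d3$masd - d1$masd), 0.02)
  }
})

test_that("distance grows monotonically with uniform scaling", {
  m <- small_meniscus(shape_seed = 17)
  scaled <- function(s) {
    m2 <- m
    m2$patient_id <- paste0("scaled", s)
    m2$vertices <- m$vertices * (1 + s)
    m2$root_anterior <- m$root_anterior * (1 + s)
    m2$root_posterior <- m$root_posterior * (1 + s)
    m2
  }
  d <- vapply(c(0.02, 0.05, 0.10), function(s)
    surface_distance(m, scaled(s), density = 2)$mesd, numeric(1L))
  expect_true(all(diff(d) > 0))
  expect_gt(d[1], 0)
})

test_that("the good-fit flag combines the MeSD and MaSD criteria", {
  expect_true(good_fit(0.8, 2.0))
  expect_false(good_fit(1.2, 2.0))   # MeSD too high
  expect_false(good_fit(0.8, 2.5))   # MaSD more than 3x MeSD
})
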
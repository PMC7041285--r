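test_that("generated meshes hit the requested dimensions and are deterministic", {
  m <- generate_base_mesh(30, 45, 9, "medial", shape_seed = 1,
                          perturb_amplitude = 0)
  d <- measure_dimensions(m)
  expect_equal(d$width, 30, tolerance = 0.02)
  expect_equal(d$length, 45, tolerance = 0.02)
  expect_equal(d$height, 9, tolerance = 0.02)

  m2 <- generate_base_mesh(30, 45, 9, "medial", shape_seed = 1,
                           perturb_amplitude = 0)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$faces, m2$faces)

  # perturbation changes the shape but not the enclosing box
  mp <- generate_base_mesh(30, 45, 9, "medial", shape_seed = 1,
                           perturb_amplitude = 1.5)
  dp <- measure_dimensions(mp)
  expect_equal(dp$width, 30, tolerance = 0.02 * 30)
  expect_gt(surface_distance(m, mp, density = 1)$mesd, 0)

  expect_error(generate_base_mesh(0, 45, 9, "medial"), "3, 100")
  expect_error(generate_base_mesh(30, 450, 9, "medial"), "3, 100")
})

test_that("virtual patients are near-mirror bilateral pairs", {
  params <- population_params(asym_amplitude = 0, n_arc = 36L,
                              n_profile = 14L)
  set.seed(11)
  pat <- generate_patient(params, "PT1")
  for (side in c("medial", "lateral")) {
    right <- pat$meshes$right[[side]]
    left <- pat$meshes$left[[side]]
    expect_identical(left$laterality, "left")
    d <- surface_distance(mirror_to_right(left), right, density = 2)
    expect_lt(d$mesd, 0.05)
  }

  # with nonzero asymmetry the partners differ but stay close
  params2 <- population_params(asym_amplitude = 0.4, n_arc = 36L,
                               n_profile = 14L)
  set.seed(12)
  pat2 <- generate_patient(params2, "PT2")
  d2 <- surface_distance(mirror_to_right(pat2$meshes$left$medial),
                         pat2$meshes$right$medial, density = 2)
  expect_gt(d2$mesd, 0.005)
  expect_lt(d2$mesd, 1.5)
})

test_that("noise-free radiographs invert the Pollard relations", {
  params <- population_params(rx_width_sd = 0, rx_length_sd = 0,
                              n_arc = 36L, n_profile = 14L)
  set.seed(21)
  pat <- generate_patient(params, "PT3")
  for (side in c("medial", "lateral")) {
    rx <- pat$radiographs
    row <- rx[rx$knee == "right" & rx$side == side, ]
    derived <- pollard_derive(list(plateau_width = row$plateau_width,
                                   plateau_length = row$plateau_length), side)
    truth <- measure_dimensions(pat$meshes$right[[side]])
    expect_equal(derived$width, truth$width, tolerance = 1e-6)
    expect_equal(derived$length, truth$length, tolerance = 1e-6)
  }
})

test_that("bank composition follows the bilateral/unilateral design", {
  params <- population_params(n_arc = 16L, n_profile = 8L, seed = 5)
  bank <- generate_bank(params, n_bilateral = 3, n_unilateral = 2)
  for (side in c("medial", "lateral")) {
    expect_length(bank_ids(bank, side), 2 * 3 + 2)
    expect_length(bank_ids(bank, side, validation_only = TRUE), 2 * 3)
  }
  # all entries mirrored to right
  lats <- vapply(bank$entries, function(e) e$mesh$laterality, character(1L))
  expect_true(all(lats == "right"))
  # precomputed dims3d are recomputable from the mesh
  for (id in bank_ids(bank, "medial")) {
    e <- bank$entries[[id]]
    d <- measure_dimensions(e$mesh)
    expect_equal(d$width, e$dims3d$width, tolerance = 1e-12)
  }

  bank1 <- generate_bank(params, n_bilateral = 1, n_unilateral = 0)
  expect_length(bank_ids(bank1, "medial"), 2)
  expect_length(bank_ids(bank1, "medial", validation_only = TRUE), 2)
})

test_that("bank generation is reproducible from its seed", {
  params <- population_params(n_arc = 16L, n_profile = 8L, seed = 99)
  b1 <- generate_bank(params, n_bilateral = 2, n_unilateral = 1)
  b2 <- generate_bank(params, n_bilateral = 2, n_unilateral = 1)
  expect_identical(b1$index, b2$index)
  expect_identical(b1$radiographs, b2$radiographs)
  expect_identical(b1$entries[[1]]$mesh$vertices, b2$entries[[1]]$mesh$vertices)
})

test_that("generated dimensions recover the configured population", {
  params <- population_params(n_arc = 24L, n_profile = 10L, seed = 31)
  bank <- generate_bank(params, n_bilateral = 10, n_unilateral = 20)
  idx <- bank$index[bank$index$side == "medial", ]
  n <- nrow(idx)
  se_w <- params$medial$width[2] / sqrt(n)
  expect_lt(abs(mean(idx$width) - params$medial$width[1]),
            3 * se_w + 0.02 * params$medial$width[1])
  se_h <- params$medial$height[2] / sqrt(n)
  expect_lt(abs(mean(idx$height) - params$medial$height[1]),
            3 * se_h + 0.02 * params$medial$height[1])
})

test_that("the contralateral partner is the bank's best shape match", {
  # with small asymmetry the mirrored partner should be the closest MeSD
  # match for nearly every validation meniscus
  params <- population_params(asym_amplitude = 0.3, n_arc = 36L,
                              n_profile = 14L, seed = 13)
  bank <- generate_bank(params, n_bilateral = 6, n_unilateral = 2)
  hits <- 0L
  vids <- bank_ids(bank, "medial", validation_only = TRUE)
  for (vid in vids) {
    e <- bank$entries[[vid]]
    sel <- select_by_mesd(e$mesh, bank, "medial", density = 1,
                          exclude_patient = NULL)
    ranking <- sel$ranking[sel$ranking$id != vid, ]
    partner <- bank$index$id[bank$index$side == "medial" &
                               bank$index$patient_id == e$patient_id &
                               bank$index$id != vid]
    if (ranking$id[1] == partner) hits <- hits + 1L
  }
  expect_gte(hits / length(vids), 0.9)
})
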
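test_that("constructor enforces mesh invariants with distinct errors", {
  m <- tetra_mesh()
  expect_s3_class(m, "meniscus_mesh")

  bad_idx <- m$faces
  bad_idx[1, 1] <- 99L
  expect_error(meniscus_mesh(m$vertices, bad_idx, root_anterior = m$root_anterior,
                             root_posterior = m$root_posterior),
               "face index out of range")

  v_dup <- rbind(m$vertices, m$vertices[1, ])
  f_dg <- rbind(m$faces, c(1L, 1L, 5L))
  expect_error(meniscus_mesh(v_dup, f_dg, root_anterior = m$root_anterior,
                             root_posterior = m$root_posterior),
               "degenerate")

  # two disjoint tetrahedra -> not a single connected component
  v2 <- rbind(m$vertices, m$vertices + 100)
  f2 <- rbind(m$faces, m$faces + 4L)
  expect_error(meniscus_mesh(v2, f2, root_anterior = m$root_anterior,
                             root_posterior = m$root_posterior),
               "connected")

  expect_error(meniscus_mesh(m$vertices, m$faces,
                             root_anterior = m$root_anterior + c(0, 0, 10),
                             root_posterior = m$root_posterior),
               "landmark")
})

test_that("mesh I/O round-trips across PLY, STL and OBJ", {
  m <- small_meniscus(shape_seed = 3)
  dir <- withr::local_tempdir()
  for (fmt in list(list(file = "m.ply", binary = FALSE),
                    list(file = "mb.ply", binary = TRUE),
                    list(file = "m.stl", binary = FALSE),
                    list(file = "m.obj", binary = FALSE))) {
    path <- file.path(dir, fmt$file)
    save_mesh(m, path, binary = fmt$binary)
    m2 <- load_mesh(path, patient_id = m$patient_id, side = m$side,
                    laterality = m$laterality,
                    root_anterior = m$root_anterior,
                    root_posterior = m$root_posterior)
    expect_equal(nrow(m2$faces), nrow(m$faces), info = fmt$file)
    # STL de-duplication may renumber vertices; compare sorted coordinates
    expect_lt(max(abs(sort(m2$vertices) - sort(m$vertices))), 1e-4)
  }
})

test_that("a tetrahedron survives PLY and STL with identical geometry", {
  m <- tetra_mesh()
  dir <- withr::local_tempdir()
  save_mesh(m, file.path(dir, "t.ply"))
  save_mesh(m, file.path(dir, "t.stl"))
  p <- load_mesh(file.path(dir, "t.ply"), root_anterior = m$root_anterior,
                 root_posterior = m$root_posterior)
  s <- load_mesh(file.path(dir, "t.stl"), root_anterior = m$root_anterior,
                 root_posterior = m$root_posterior)
  expect_equal(nrow(p$vertices), 4L)
  expect_equal(nrow(p$faces), 4L)
  # STL stores triangles independently; de-duplication must recover 4 vertices
  expect_equal(nrow(s$vertices), 4L)
  expect_equal(sort(s$vertices), sort(p$vertices), tolerance = 1e-5)
})

test_that("unreadable paths and unsupported formats are reported", {
  expect_error(load_mesh("no/such/file.ply", root_anterior = 1:3,
                         root_posterior = 4:6), "does not exist")
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", tmp)
  expect_error(load_mesh(tmp, root_anterior = 1:3, root_posterior = 4:6),
               "unsupported")
  m <- tetra_mesh()
  expect_error(save_mesh(m, "no/such/dir/x.ply"), "does not exist")
})

test_that("mirroring is an involution and an isometry", {
  m <- small_meniscus(shape_seed = 5, perturb_amplitude = 1.2)
  left <- menisize:::reflect_mesh(m, laterality = "left")
  expect_identical(left$laterality, "left")
  back <- mirror_to_right(left)
  expect_identical(back$laterality, "right")
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(back$faces, m$faces)
  expect_equal(back$root_anterior, m$root_anterior)

  # right mesh passes through unchanged
  expect_identical(mirror_to_right(m), m)

  # pairwise distances preserved under the reflection
  idx <- seq(1, nrow(m$vertices), by = 37)
  d0 <- dist(m$vertices[idx, ])
  d1 <- dist(left$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # area and enclosed volume invariant (winding flip preserves orientation)
  av0 <- mesh_area_volume(m)
  av1 <- mesh_area_volume(left)
  expect_equal(unname(av1["area"]), unname(av0["area"]), tolerance = 1e-12)
  expect_equal(unname(av1["volume"]), unname(av0["volume"]), tolerance = 1e-12)
})

test_that("mirroring leaves the oriented-box dimensions unchanged", {
  m <- small_meniscus(shape_seed = 8, perturb_amplitude = 1.0)
  left <- menisize:::reflect_mesh(m, laterality = "left")
  d0 <- measure_dimensions(m)
  d1 <- measure_dimensions(left)
  expect_equal(d1$width, d0$width, tolerance = 1e-9)
  expect_equal(d1$length, d0$length, tolerance = 1e-9)
  expect_equal(d1$height, d0$height, tolerance = 1e-9)
})
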
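# minimal hand-built bank for selector tests (no meshes needed for the
# dimension-based selector beyond the index)
dims_bank <- function(tab) {
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    list(id = tab$id[i], mesh = NULL,
         dims3d = meniscus_dimensions(tab$width[i], tab$length[i],
                                      tab$height[i]),
         dims2d = meniscus_dimensions(tab$width[i], tab$length[i]),
         patient_id = tab$patient_id[i], side = tab$side[i],
         source_laterality = "right", validation = FALSE)
  })
  names(entries) <- tab$id
  tab$width2d <- tab$width
  tab$length2d <- tab$length
  tab$validation <- FALSE
  structure(list(entries = entries, index = tab, radiographs = NULL,
                 params = NULL), class = "allograft_bank")
}

test_that("the Pollard derivation applies the published factors", {
  rx <- radiograph_measure(30, 50)
  med <- pollard_derive(rx, "medial")
  expect_equal(med$width, 30)
  expect_equal(med$length, 40)   # 0.8 x 50
  lat <- pollard_derive(rx, "lateral")
  expect_equal(lat$width, 30)
  expect_equal(lat$length, 35)   # 0.7 x 50
  expect_error(radiograph_measure(0, 50), "positive")
  expect_error(pollard_derive(list(plateau_width = -1, plateau_length = 50),
                              "medial"), "positive")
})

test_that("dimension selection minimises the error sum of squares", {
  tab <- data.frame(id = c("A", "B", "C"),
                    patient_id = c("p1", "p2", "p3"),
                    side = "medial",
                    width = c(31, 28, 33), length = c(46, 44, 43),
                    height = c(9, 9, 9), stringsAsFactors = FALSE)
  bank <- dims_bank(tab)
  sel <- select_by_dims(meniscus_dimensions(30, 45), bank, "medial")
  expect_identical(sel$selected_id, "A")
  expect_equal(sel$score, 2)                       # (30-31)^2 + (45-46)^2
  expect_equal(sel$ranking$score, c(2, 5, 13))

  # exact-dimension candidate wins with score zero
  sel0 <- select_by_dims(meniscus_dimensions(28, 44), bank, "medial")
  expect_identical(sel0$selected_id, "B")
  expect_equal(sel0$score, 0)

  # exclusion removes the patient's menisci
  sel_ex <- select_by_dims(meniscus_dimensions(30, 45), bank, "medial",
                           exclude_patient = "p1")
  expect_identical(sel_ex$selected_id, "B")
  expect_false("A" %in% sel_ex$ranking$id)
  expect_error(select_by_dims(meniscus_dimensions(30, 45),
                              dims_bank(tab[1, ]), "medial",
                              exclude_patient = "p1"), "empty")
})

test_that("dimension selection equals brute-force argmin on random banks", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    tab <- data.frame(id = sprintf("c%02d", seq_len(n)),
                      patient_id = sprintf("q%02d", seq_len(n)),
                      side = "medial",
                      width = round(rnorm(n, 31.6, 3.3), 2),
                      length = round(rnorm(n, 46.8, 3.7), 2),
                      height = round(rnorm(n, 9.3, 1.4), 2),
                      stringsAsFactors = FALSE)
    tab$width <- pmax(tab$width, 5)
    tab$length <- pmax(tab$length, 5)
    tab$height <- pmax(tab$height, 3)
    bank <- dims_bank(tab)
    target <- meniscus_dimensions(rnorm(1, 31.6, 3.3), rnorm(1, 46.8, 3.7))
    sel <- select_by_dims(target, bank, "medial")
    brute <- (target$width - tab$width)^2 + (target$length - tab$length)^2
    expect_identical(sel$selected_id, tab$id[which.min(brute)])
    expect_equal(sel$score, min(brute))
  }
})

test_that("ties are broken deterministically by candidate id", {
  tab <- data.frame(id = c("Z", "A"), patient_id = c("p1", "p2"),
                    side = "medial", width = c(30, 30), length = c(45, 45),
                    height = c(9, 9), stringsAsFactors = FALSE)
  sel <- select_by_dims(meniscus_dimensions(30, 45), dims_bank(tab), "medial")
  expect_identical(sel$selected_id, "A")
})

test_that("MeSD selection finds an exact copy and matches brute force", {
  params <- population_params(n_arc = 20L, n_profile = 9L, seed = 17)
  bank <- generate_bank(params, n_bilateral = 2, n_unilateral = 3)
  ids <- bank_ids(bank, "medial")
  template <- bank$entries[[ids[3]]]$mesh

  sel <- select_by_mesd(template, bank, "medial", density = 1)
  expect_identical(sel$selected_id, ids[3])      # the copy itself
  expect_lt(sel$score, 1e-3)

  # brute force over the same pool
  scores <- vapply(ids, function(id)
    surface_distance(template, bank$entries[[id]]$mesh, density = 1)$mesd,
    numeric(1L))
  expect_identical(sel$selected_id, names(which.min(scores)))

  # leave-one-out never offers the tested patient's menisci
  pat <- bank$entries[[ids[1]]]$patient_id
  sel_ex <- select_by_mesd(template, bank, "medial", exclude_patient = pat,
                           density = 1)
  expect_false(any(bank$index$patient_id[match(sel_ex$ranking$id,
                                               bank$index$id)] == pat))
})

test_that("templates carry exactly what each sizing method needs", {
  params <- population_params(asym_amplitude = 0, rx_width_sd = 0,
                              rx_length_sd = 0, n_arc = 24L, n_profile = 10L)
  set.seed(3)
  pat <- generate_patient(params, "PT9")

  t3 <- build_template("mri3d", pat, "medial", "right")
  expect_s3_class(t3$template_mesh, "meniscus_mesh")
  expect_null(t3$target_dims)
  # zero asymmetry: template is the mirror of an identical shape
  d <- surface_distance(t3$template_mesh, pat$meshes$right$medial, density = 2)
  expect_lt(d$mesd, 0.05)

  t2 <- build_template("mri2d", pat, "medial", "right")
  truth <- measure_dimensions(pat$meshes$right$medial)
  expect_equal(t2$target_dims$width, truth$width, tolerance = 0.05)
  expect_equal(t2$target_dims$length, truth$length, tolerance = 0.05)

  tr <- build_template("rx2d", pat, "medial", "right")
  expect_equal(tr$target_dims$width, truth$width, tolerance = 1e-6)
  expect_equal(tr$target_dims$length, truth$length, tolerance = 1e-6)

  # missing inputs are reported
  pat_uni <- generate_patient(params, "PT10", bilateral = FALSE)
  expect_error(build_template("mri3d", pat_uni, "medial", "right"),
               "contralateral")
})
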
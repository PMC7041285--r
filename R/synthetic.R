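# Parametric generator of synthetic meniscus meshes, virtual patients and
# allograft banks.
#
# The shape family is a crescent: an elliptical centerline arc swept with a
# triangular wedge cross-section (flat tibial base, vertical peripheral wall,
# tapering inner rim), modulated by a smooth low-order random radial/height
# field. The generator rescales each mesh so its oriented-bounding-box
# dimensions match the requested width/length/height, which decouples the
# three printed dimensions from residual 3D shape variation -- the degeneracy
# the 3D sizing method exploits (same width/length, different shape).

#' Population parameters for the synthetic meniscus bank
#'
#' Defaults reproduce the published population statistics of 140 healthy
#' menisci per side: medial width/length/height 31.6 +/- 3.3, 46.8 +/- 3.7,
#' 9.3 +/- 1.4 mm; lateral 31.7 +/- 3.7, 35.3 +/- 2.8, 9.9 +/- 1.4 mm; a weak
#' width-length correlation (R^2 about 0.31) and the Pollard radiographic
#' prediction errors of 2.9 mm (width) and 3.8 mm (length).
#'
#' @param medial,lateral per-side lists with `width`, `length`, `height`
#'   (each `c(mean, sd)` in mm) and `wl_cor` (width-length Pearson r).
#' @param perturb_amplitude RMS amplitude (mm) of the smooth random shape
#'   perturbation distinguishing menisci of identical dimensions.
#' @param asym_amplitude RMS amplitude (mm) of the additional perturbation
#'   between the two sides of one patient (contralateral asymmetry).
#' @param rx_width_sd,rx_length_sd standard deviation (mm) of the
#'   radiograph-derived width/length around the true dimensions.
#' @param noise2d_sd standard deviation (mm) of 2D-MRI measurement noise
#'   applied to bank `dims2d`; 0 disables it.
#' @param n_arc,n_profile tessellation counts (arc stations x cross-section
#'   points); defaults give about 2,000 vertices per mesh.
#' @param seed RNG seed for bank generation.
#' @return An object of class `population_params`.
#' @export
population_params <- function(
    medial = list(width = c(31.6, 3.3), length = c(46.8, 3.7),
                  height = c(9.3, 1.4), wl_cor = sqrt(0.310)),
    lateral = list(width = c(31.7, 3.7), length = c(35.3, 2.8),
                   height = c(9.9, 1.4), wl_cor = sqrt(0.304)),
    perturb_amplitude = 0.8, asym_amplitude = 0.3,
    rx_width_sd = 2.9, rx_length_sd = 3.8, noise2d_sd = 0,
    n_arc = 72L, n_profile = 26L, seed = 1L) {
  p <- list(medial = medial, lateral = lateral,
            perturb_amplitude = perturb_amplitude,
            asym_amplitude = asym_amplitude,
            rx_width_sd = rx_width_sd, rx_length_sd = rx_length_sd,
            noise2d_sd = noise2d_sd,
            n_arc = as.integer(n_arc), n_profile = as.integer(n_profile),
            seed = as.integer(seed))
  for (s in c("medial", "lateral")) {
    for (f in c("width", "length", "height")) {
      v <- p[[s]][[f]]
      if (length(v) != 2L || v[1] <= 0 || v[2] < 0)
        stopf("%s %s must be c(mean > 0, sd >= 0)", s, f)
    }
    if (abs(p[[s]]$wl_cor) >= 1) stopf("|width-length correlation| must be < 1")
  }
  if (perturb_amplitude < 0 || asym_amplitude < 0 ||
      rx_width_sd < 0 || rx_length_sd < 0 || noise2d_sd < 0)
    stopf("amplitudes and noise SDs must be non-negative")
  structure(p, class = "population_params")
}

#' Radiographic tibia plateau measurement
#'
#' @param plateau_width AP-view tibia plateau width (mm).
#' @param plateau_length lateral-view tibia plateau length (mm).
#' @return An object of class `radiograph_measure`.
#' @export
radiograph_measure <- function(plateau_width, plateau_length) {
  if (plateau_width <= 0 || plateau_length <= 0)
    stopf("plateau measurements must be positive")
  structure(list(plateau_width = plateau_width,
                 plateau_length = plateau_length),
            class = "radiograph_measure")
}

# smooth low-order random field on the arc parameter: Fourier modes 2..4,
# coefficients N(0, 1), normalised to unit RMS
smooth_field <- function(phi, coefs) {
  modes <- 2:4
  f <- 0
  for (i in seq_along(modes)) {
    f <- f + coefs[2 * i - 1] * cos(modes[i] * phi) +
      coefs[2 * i] * sin(modes[i] * phi)
  }
  f / sqrt(length(modes))
}

#' Generate one synthetic meniscus mesh
#'
#' Builds a C-shaped wedge: an elliptical centerline arc (span 300 degrees
#' medial, 330 degrees lateral) swept with a triangular cross-section of
#' peripheral height `height` tapering toward the inner rim, plus a smooth
#' low-order random radial/height perturbation of RMS amplitude
#' `perturb_amplitude`. Anterior and posterior roots sit at the arc endpoint
#' apices. After perturbation the mesh is rescaled so its oriented-bounding-
#' box dimensions match the requested width/length/height (within 2%).
#'
#' @param width,length,height requested bounding-box dimensions (mm), each in
#'   (3, 100).
#' @param side `"medial"` or `"lateral"` (controls the arc span).
#' @param shape_seed integer seed of the per-meniscus perturbation field.
#' @param perturb_amplitude RMS perturbation amplitude (mm).
#' @param patient_id,laterality metadata for the resulting mesh.
#' @param asym_seed,asym_amplitude optional second perturbation field (used to
#'   create near-mirror contralateral partners); when `asym_amplitude > 0`
#'   the mesh is NOT rescaled after this extra field is applied, so its
#'   dimensions differ from the request by about the asymmetry amplitude.
#' @param n_arc,n_profile tessellation counts.
#' @return A [meniscus_mesh()] (laterality `"right"` geometry; use
#'   `reflect = TRUE` inside [generate_patient()] for left sides).
#' @export
generate_base_mesh <- function(width, length, height,
                               side = c("medial", "lateral"),
                               shape_seed = 1L, perturb_amplitude = 0.8,
                               patient_id = "synthetic", laterality = "right",
                               asym_seed = NULL, asym_amplitude = 0,
                               n_arc = 72L, n_profile = 26L) {
  side <- match.arg(side)
  for (d in c(width, length, height))
    if (!is.finite(d) || d < 3 || d > 100)
      stopf("dimensions must lie in [3, 100] mm (got %.2f)", d)
  span <- if (side == "medial") 300 else 330
  s2 <- span / 2 * pi / 180
  wc <- 0.30 * width                      # radial body width of the wedge
  a <- max((length - wc) / 2, 1)
  b <- max((width - wc) / (1 - cos(s2)), 1)

  n_st <- n_arc + 1L
  th <- seq(-s2, s2, length.out = n_st)
  phi <- (th + s2) / (2 * s2) * 2 * pi

  coefs <- with_seed(shape_seed, rnorm(12L))
  dr <- perturb_amplitude * smooth_field(phi, coefs[1:6])
  dz <- perturb_amplitude * smooth_field(phi, coefs[7:12])

  # cross-section profile: closed triangle loop in local (r, z)
  hw <- wc / 2
  corners <- rbind(c(-hw, 0), c(hw, 0), c(hw, height))
  seg <- rbind(corners[2, ] - corners[1, ],
               corners[3, ] - corners[2, ],
               corners[1, ] - corners[3, ])
  slen <- sqrt(rowSums(seg^2))
  per <- sum(slen)
  tpos <- (seq_len(n_profile) - 1L) / n_profile * per
  cum <- c(0, cumsum(slen))
  prof <- t(vapply(tpos, function(tt) {
    e <- findInterval(tt, cum, rightmost.closed = TRUE)
    u <- (tt - cum[e]) / slen[e]
    corners[e, ] + u * seg[e, ]
  }, numeric(2L)))

  centre <- cbind(a * sin(th), -b * cos(th))
  nrm <- cbind(sin(th) / a, -cos(th) / b)
  nrm <- nrm / sqrt(rowSums(nrm^2))

  ji <- rep(seq_len(n_st), each = n_profile)
  ki <- rep(seq_len(n_profile), times = n_st)
  roff <- prof[ki, 1] + dr[ji]
  V <- cbind(centre[ji, 1] + roff * nrm[ji, 1],
             centre[ji, 2] + roff * nrm[ji, 2],
             prof[ki, 2] * (1 + dz[ji] / height))

  # tube faces
  j <- rep(seq_len(n_arc), each = n_profile)
  k <- rep(seq_len(n_profile), times = n_arc)
  k2 <- k %% n_profile + 1L
  v1 <- (j - 1L) * n_profile + k
  v2 <- (j - 1L) * n_profile + k2
  v3 <- j * n_profile + k2
  v4 <- j * n_profile + k
  F_tube <- rbind(cbind(v1, v2, v3), cbind(v1, v3, v4))

  # end caps with apex vertices at the ring centroids = root landmarks
  nv <- n_st * n_profile
  ring1 <- seq_len(n_profile)
  ringN <- (n_st - 1L) * n_profile + seq_len(n_profile)
  apex_post <- colMeans(V[ring1, , drop = FALSE])   # theta = -span/2, x < 0
  apex_ant <- colMeans(V[ringN, , drop = FALSE])    # theta = +span/2, x > 0
  V <- rbind(V, apex_post, apex_ant)
  ia <- nv + 1L
  ib <- nv + 2L
  kk <- seq_len(n_profile)
  kk2 <- kk %% n_profile + 1L
  F_cap1 <- cbind(rep(ia, n_profile), ring1[kk2], ring1[kk])
  F_cap2 <- cbind(rep(ib, n_profile), ringN[kk], ringN[kk2])
  F <- rbind(F_tube, F_cap1, F_cap2)

  # enforce outward orientation globally
  av <- cpp_area_volume(V, F - 1L)
  if (av[2] < 0) F <- F[, c(1L, 3L, 2L)]

  mesh <- meniscus_mesh(V, F, patient_id, side, "right",
                        root_anterior = apex_ant, root_posterior = apex_post,
                        validate = FALSE)

  # iterative anisotropic rescale so OBB dims hit the request
  target <- c(length, width, height)
  for (it in 1:8) {
    d <- measure_dimensions(mesh)
    cur <- c(d$length, d$width, d$height)
    f <- target / cur
    if (all(abs(f - 1) < 0.002)) break
    S <- c(f[1], f[2], f[3])
    mesh$vertices <- sweep(mesh$vertices, 2L, S, "*")
    mesh$root_anterior <- mesh$root_anterior * S
    mesh$root_posterior <- mesh$root_posterior * S
  }

  if (!is.null(asym_seed) && asym_amplitude > 0) {
    # re-apply the asymmetry field after rescaling so partner dims genuinely
    # differ by about the asymmetry amplitude
    ac <- with_seed(asym_seed, rnorm(12L))
    dra <- asym_amplitude * smooth_field(phi, ac[1:6])
    dza <- asym_amplitude * smooth_field(phi, ac[7:12])
    idx <- seq_len(nv)
    mesh$vertices[idx, 1] <- mesh$vertices[idx, 1] + dra[ji] * nrm[ji, 1]
    mesh$vertices[idx, 2] <- mesh$vertices[idx, 2] + dra[ji] * nrm[ji, 2]
    mesh$vertices[idx, 3] <- mesh$vertices[idx, 3] +
      dza[ji] * prof[ki, 2] / height
    mesh$vertices[ia, ] <- colMeans(mesh$vertices[ring1, , drop = FALSE])
    mesh$vertices[ib, ] <- colMeans(mesh$vertices[ringN, , drop = FALSE])
    mesh$root_posterior <- mesh$vertices[ia, ]
    mesh$root_anterior <- mesh$vertices[ib, ]
  }
  validate_mesh(mesh)
  mesh
}

# truncated bivariate-normal draw of (width, length) plus independent height
draw_dims <- function(sidepar) {
  repeat {
    z <- rnorm(2L)
    rho <- sidepar$wl_cor
    w <- sidepar$width[1] + sidepar$width[2] * z[1]
    l <- sidepar$length[1] +
      sidepar$length[2] * (rho * z[1] + sqrt(1 - rho^2) * z[2])
    h <- rnorm(1L, sidepar$height[1], sidepar$height[2])
    if (all(c(w, l, h) > 3) && all(c(w, l, h) < 100))
      return(c(width = w, length = l, height = h))
  }
}

#' Generate a virtual patient
#'
#' Draws per-side dimensions from the configured population (width and length
#' bivariate normal with the configured correlation, height independent),
#' builds the right-knee meshes, creates the left knee as a mirror image plus
#' an independent smooth perturbation of the contralateral-asymmetry
#' amplitude, and back-computes radiographic tibia plateau measurements by
#' inverting the Pollard relations from each knee's true dimensions plus
#' Gaussian noise of the configured radiograph SDs.
#'
#' Consumes the caller's RNG stream: seed before calling (or use
#' [generate_bank()], which seeds once from `params$seed`).
#'
#' @param params a [population_params()].
#' @param patient_id patient identifier.
#' @param bilateral generate both knees (`TRUE`) or the right knee only.
#' @return An object of class `virtual_patient`: `meshes[[laterality]][[side]]`
#'   ([meniscus_mesh()] objects in anatomical laterality) and `radiographs`
#'   (data frame with one row per knee x side).
#' @export
generate_patient <- function(params, patient_id, bilateral = TRUE) {
  stopifnot(inherits(params, "population_params"))
  meshes <- list(right = list(), left = list())
  rx <- list()
  for (side in c("medial", "lateral")) {
    dims <- draw_dims(params[[side]])
    shape_seed <- sample.int(.Machine$integer.max, 1L)
    right <- generate_base_mesh(
      dims["width"], dims["length"], dims["height"], side,
      shape_seed = shape_seed,
      perturb_amplitude = params$perturb_amplitude,
      patient_id = patient_id, laterality = "right",
      n_arc = params$n_arc, n_profile = params$n_profile)
    meshes$right[[side]] <- right
    knees <- "right"
    if (bilateral) {
      asym_seed <- sample.int(.Machine$integer.max, 1L)
      left_geo <- generate_base_mesh(
        dims["width"], dims["length"], dims["height"], side,
        shape_seed = shape_seed,
        perturb_amplitude = params$perturb_amplitude,
        patient_id = patient_id, laterality = "right",
        asym_seed = asym_seed, asym_amplitude = params$asym_amplitude,
        n_arc = params$n_arc, n_profile = params$n_profile)
      meshes$left[[side]] <- reflect_mesh(left_geo, laterality = "left")
      knees <- c("right", "left")
    }
    for (knee in knees) {
      m <- meshes[[knee]][[side]]
      d <- measure_dimensions(m)
      fac <- if (side == "medial") 0.8 else 0.7
      pw <- d$width + rnorm(1L, 0, params$rx_width_sd)
      pl <- (d$length + rnorm(1L, 0, params$rx_length_sd)) / fac
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = patient_id, knee = knee, side = side,
        plateau_width = max(pw, 1e-3), plateau_length = max(pl, 1e-3),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(patient_id = patient_id,
                 meshes = meshes,
                 radiographs = do.call(rbind, rx)),
            class = "virtual_patient")
}

#' Generate a synthetic allograft bank with a validation group
#'
#' Generates `n_bilateral` virtual patients with both knees and
#' `n_unilateral` with one knee. All menisci are mirrored to right-sided
#' models and pooled into the bank: `2 * n_bilateral + n_unilateral` entries
#' per side, the bilateral patients' menisci flagged as the validation group.
#'
#' @param params a [population_params()]; `params$seed` seeds the generation.
#' @param n_bilateral number of bilateral (validation) patients.
#' @param n_unilateral number of unilateral (bank-only) patients.
#' @return An object of class `allograft_bank`: `entries` (named list; each
#'   entry holds `mesh` mirrored to right, precomputed `dims3d` and `dims2d`,
#'   and provenance), `index` (data frame), `radiographs` (data frame) and
#'   `params`.
#' @export
generate_bank <- function(params = population_params(), n_bilateral = 50L,
                          n_unilateral = 40L) {
  stopifnot(n_bilateral >= 1L, n_unilateral >= 0L)
  with_seed(params$seed, {
    entries <- list()
    index <- list()
    rx <- list()
    n <- n_bilateral + n_unilateral
    ids <- sprintf("P%03d", seq_len(n))
    for (i in seq_len(n)) {
      bilateral <- i <= n_bilateral
      pat <- generate_patient(params, ids[i], bilateral = bilateral)
      rx[[i]] <- pat$radiographs
      for (knee in names(pat$meshes)) {
        for (side in names(pat$meshes[[knee]])) {
          mesh <- mirror_to_right(pat$meshes[[knee]][[side]])
          id <- paste(ids[i], side, substr(knee, 1L, 1L), sep = ".")
          dims3d <- measure_dimensions(mesh)
          dims2d <- if (params$noise2d_sd > 0) {
            measure_dimensions_2d(mesh, noise_sd = params$noise2d_sd,
                                  seed = sample.int(.Machine$integer.max, 1L))
          } else measure_dimensions_2d(mesh)
          entries[[id]] <- list(id = id, mesh = mesh, dims3d = dims3d,
                                dims2d = dims2d, patient_id = ids[i],
                                side = side, source_laterality = knee,
                                validation = bilateral)
          index[[length(index) + 1L]] <- data.frame(
            id = id, patient_id = ids[i], side = side,
            source_laterality = knee, validation = bilateral,
            width = dims3d$width, length = dims3d$length,
            height = dims3d$height,
            width2d = dims2d$width, length2d = dims2d$length,
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(entries = entries,
                   index = do.call(rbind, index),
                   radiographs = do.call(rbind, rx),
                   params = params),
              class = "allograft_bank")
  })
}

#' @export
print.allograft_bank <- function(x, ...) {
  tab <- table(x$index$side)
  nval <- table(x$index$side[x$index$validation])
  cat(sprintf("<allograft_bank> %d entries (%s), validation group: %s\n",
              nrow(x$index),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              paste(sprintf("%s %d", names(nval), nval), collapse = ", ")))
  invisible(x)
}

#' Bank entry identifiers for one side
#'
#' @param bank an [generate_bank()] result.
#' @param side `"medial"` or `"lateral"`.
#' @param validation_only restrict to the validation group.
#' @return Character vector of entry ids.
#' @export
bank_ids <- function(bank, side, validation_only = FALSE) {
  keep <- bank$index$side == side
  if (validation_only) keep <- keep & bank$index$validation
  bank$index$id[keep]
}
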
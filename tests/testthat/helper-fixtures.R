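# Test fixtures built in code: canonical box/tetrahedron meshes, icospheres,
# rigid motions, and a coarse meniscus for cheap pairwise work.

# axis-aligned rectangular box [0,dx] x [0,dy] x [0,dz] with root landmarks
# on the centres of the two x-extreme faces
box_mesh <- function(dx = 45, dy = 30, dz = 9, patient_id = "box",
                     side = "medial") {
  v <- as.matrix(expand.grid(x = c(0, dx), y = c(0, dy), z = c(0, dz)))
  colnames(v) <- NULL
  # corner order: (0,0,0)(dx,0,0)(0,dy,0)(dx,dy,0)(0,0,dz)(dx,0,dz)(0,dy,dz)(dx,dy,dz)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # bottom (z = 0)
    c(5, 6, 7), c(6, 8, 7),      # top
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = dy
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = dx
  meniscus_mesh(v, f, patient_id, side, "right",
                root_anterior = c(dx, dy / 2, dz / 2),
                root_posterior = c(0, dy / 2, dz / 2))
}

tetra_mesh <- function(scale = 10) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.4, 1)) * scale
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  meniscus_mesh(v, f, "tetra", "medial", "right",
                root_anterior = v[2, ], root_posterior = v[1, ])
}

# geodesic sphere by icosahedron subdivision
icosphere_mesh <- function(radius = 10, subdiv = 4, patient_id = "sphere") {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (is.null(id)) {
        v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
        id <- nrow(v)
        edge_id[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 0L, 3L)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  meniscus_mesh(v, f, patient_id, "medial", "right",
                root_anterior = v[which.max(v[, 1]), ],
                root_posterior = v[which.min(v[, 1]), ])
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# coarse-tessellation meniscus for cheap pairwise computations
small_meniscus <- function(width = 30, length = 45, height = 9,
                           side = "medial", shape_seed = 1,
                           perturb_amplitude = 0.8, patient_id = "small") {
  generate_base_mesh(width, length, height, side, shape_seed = shape_seed,
                     perturb_amplitude = perturb_amplitude,
                     patient_id = patient_id, n_arc = 20L, n_profile = 9L)
}

# cheap deterministic stand-in for surface_distance() used in dry runs where
# only the combinatorics are under test
dims_surrogate_distance <- function(a, b) {
  da <- measure_dimensions(a)
  db <- measure_dimensions(b)
  mesd <- sqrt((da$width - db$width)^2 + (da$length - db$length)^2 +
                 (da$height - db$height)^2) / 5
  list(mesd = mesd, masd = 3 * mesd + 0.5)
}
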
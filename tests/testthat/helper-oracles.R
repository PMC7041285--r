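# Independent oracles, kept deliberately separate from the package's
# algorithms: closest point on a triangle by constrained quadratic
# minimisation (not the region-classification routine the package uses), and
# brute-force all-points-against-all-triangles surface distances.

oracle_closest_point_triangle <- function(p, a, b, c) {
  e1 <- b - a
  e2 <- c - a
  d <- a - p
  # minimise |a + u e1 + v e2 - p|^2
  g <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- -c(sum(e1 * d), sum(e2 * d))
  uv <- tryCatch(solve(g, rhs), error = function(e) c(NA_real_, NA_real_))
  inside <- !anyNA(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1
  if (inside) return(a + uv[1] * e1 + uv[2] * e2)
  # otherwise the minimum lies on one of the three edges
  edge_point <- function(p0, p1) {
    e <- p1 - p0
    t <- sum((p - p0) * e) / sum(e * e)
    t <- min(max(t, 0), 1)
    p0 + t * e
  }
  cands <- rbind(edge_point(a, b), edge_point(b, c), edge_point(c, a))
  cands[which.min(rowSums(sweep(cands, 2, p)^2)), ]
}

oracle_point_mesh_distance <- function(p, mesh) {
  dmin <- Inf
  for (r in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[r, ], , drop = FALSE]
    q <- oracle_closest_point_triangle(p, tri[1, ], tri[2, ], tri[3, ])
    dmin <- min(dmin, sqrt(sum((p - q)^2)))
  }
  dmin
}

# directed + symmetric surface distances in the given pose (no registration),
# brute force over every sample point x every triangle
oracle_surface_distance <- function(a, b, density) {
  pa <- sample_surface(a, density)
  pb <- sample_surface(b, density)
  d_ab <- apply(pa, 1L, oracle_point_mesh_distance, mesh = b)
  d_ba <- apply(pb, 1L, oracle_point_mesh_distance, mesh = a)
  list(mean_ab = mean(d_ab), mean_ba = mean(d_ba),
       max_ab = max(d_ab), max_ba = max(d_ba),
       mesd = max(mean(d_ab), mean(d_ba)),
       masd = max(max(d_ab), max(d_ba)))
}
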
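# internal helpers

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# content + identity derived key; used for handle caching and for the
# canonical pair ordering, so pairwise results are order-independent
mesh_key <- function(mesh) {
  id <- paste(mesh$patient_id %||% "", mesh$side %||% "",
              mesh$laterality %||% "", sep = ".")
  cpp_hash_mesh(mesh$vertices, id)
}

# sampling seed derived from identity + topology only (never coordinates):
# per-face barycentric draws then commute exactly with rigid motions, which
# makes the surface-distance pipeline rigid-motion equivariant
sample_seed <- function(mesh) {
  cpp_hash_string(paste(mesh$patient_id %||% "", mesh$side %||% "",
                        nrow(mesh$vertices), nrow(mesh$faces), sep = "."))
}

# pose-invariant ordering key for a mesh pair: which mesh drives the ICP must
# not depend on the incidental pose, or rigid-motion invariance of the
# distances would be lost when the direction flips
pair_order_key <- function(mesh) {
  av <- cpp_area_volume(mesh$vertices, mesh$faces - 1L)
  c(sample_seed(mesh), round(av[1], 6), round(av[2], 6))
}

key_less <- function(ka, kb) {
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  FALSE
}

# per-session cache of C++ mesh handles, keyed by content hash + density
.handle_cache <- new.env(parent = emptyenv())

mesh_handle <- function(mesh, density, icp_max_points = 400L,
                        min_points = 50L) {
  key <- sprintf("%.0f_%g_%d", mesh_key(mesh), density, icp_max_points)
  h <- .handle_cache[[key]]
  if (is.null(h)) {
    h <- cpp_build_handle(mesh$vertices, mesh$faces - 1L, density,
                          sample_seed(mesh), as.integer(icp_max_points),
                          as.integer(min_points))
    .handle_cache[[key]] <- h
  }
  h
}

clear_handle_cache <- function() {
  rm(list = ls(.handle_cache), envir = .handle_cache)
  invisible(NULL)
}
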
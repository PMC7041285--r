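# On-disk bank layout: one mesh file per entry plus a metadata CSV (one row
# per mesh with patient/side/laterality, mesh path and root landmarks) and an
# optional radiograph CSV.

#' Write an allograft bank to a directory
#'
#' Writes each entry's mesh as PLY together with `metadata.csv` (columns
#' `id, patient_id, side, laterality, validation, mesh_path,
#' root_anterior_x/y/z, root_posterior_x/y/z`) and `radiographs.csv`.
#'
#' @param bank an [generate_bank()] result.
#' @param dir output directory (created if missing).
#' @param binary write binary little-endian PLY instead of ascii.
#' @return `dir`, invisibly.
#' @export
write_bank <- function(bank, dir, binary = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meshdir <- file.path(dir, "meshes")
  dir.create(meshdir, showWarnings = FALSE)
  rows <- lapply(bank$index$id, function(id) {
    e <- bank$entries[[id]]
    rel <- file.path("meshes", paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".ply"))
    save_mesh(e$mesh, file.path(dir, rel), binary = binary)
    data.frame(id = id, patient_id = e$patient_id, side = e$side,
               laterality = e$mesh$laterality,
               source_laterality = e$source_laterality,
               validation = e$validation, mesh_path = rel,
               root_anterior_x = e$mesh$root_anterior[1],
               root_anterior_y = e$mesh$root_anterior[2],
               root_anterior_z = e$mesh$root_anterior[3],
               root_posterior_x = e$mesh$root_posterior[1],
               root_posterior_y = e$mesh$root_posterior[2],
               root_posterior_z = e$mesh$root_posterior[3],
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "metadata.csv"),
            row.names = FALSE)
  if (!is.null(bank$radiographs))
    write.csv(bank$radiographs, file.path(dir, "radiographs.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read an allograft bank from a directory
#'
#' Reconstructs the bank written by [write_bank()]: loads every mesh, then
#' recomputes `dims3d` and `dims2d` with the oriented-bounding-box
#' measurements (so the precomputed dimensions always match the meshes).
#'
#' @param dir directory containing `metadata.csv`.
#' @return An `allograft_bank`.
#' @export
read_bank <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stopf("no metadata.csv in %s", dir)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  entries <- list()
  index <- list()
  for (i in seq_len(nrow(meta))) {
    r <- meta[i, ]
    mesh <- load_mesh(file.path(dir, r$mesh_path),
                      patient_id = r$patient_id, side = r$side,
                      laterality = r$laterality,
                      root_anterior = c(r$root_anterior_x, r$root_anterior_y,
                                        r$root_anterior_z),
                      root_posterior = c(r$root_posterior_x,
                                         r$root_posterior_y,
                                         r$root_posterior_z))
    dims3d <- measure_dimensions(mesh)
    dims2d <- measure_dimensions_2d(mesh)
    entries[[r$id]] <- list(id = r$id, mesh = mesh, dims3d = dims3d,
                            dims2d = dims2d, patient_id = r$patient_id,
                            side = r$side,
                            source_laterality = r$source_laterality,
                            validation = isTRUE(r$validation))
    index[[i]] <- data.frame(
      id = r$id, patient_id = r$patient_id, side = r$side,
      source_laterality = r$source_laterality,
      validation = isTRUE(r$validation),
      width = dims3d$width, length = dims3d$length, height = dims3d$height,
      width2d = dims2d$width, length2d = dims2d$length,
      stringsAsFactors = FALSE)
  }
  rx_path <- file.path(dir, "radiographs.csv")
  rx <- if (file.exists(rx_path)) read.csv(rx_path, stringsAsFactors = FALSE)
        else NULL
  structure(list(entries = entries, index = do.call(rbind, index),
                 radiographs = rx, params = NULL),
            class = "allograft_bank")
}
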
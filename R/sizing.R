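# The three allograft-sizing/selection rules: 3D-MRI (closest MeSD to the
# mirrored contralateral template), 2D-MRI (closest width/length error sum of
# squares to the contralateral 2D measurement), and 2D-RX (Pollard-derived
# width/length from the ipsilateral tibia plateau, then error sum of squares).

#' Pollard radiographic derivation of meniscal width and length
#'
#' Meniscal width is taken equal to the tibia plateau width for both sides;
#' meniscal length is 80% (medial) or 70% (lateral) of the tibia plateau
#' length.
#'
#' @param radiograph a [radiograph_measure()] (or list with `plateau_width`
#'   and `plateau_length`, mm).
#' @param side `"medial"` or `"lateral"`.
#' @return A [meniscus_dimensions()] with `height = NA`.
#' @export
pollard_derive <- function(radiograph, side = c("medial", "lateral")) {
  side <- match.arg(side)
  pw <- radiograph$plateau_width
  pl <- radiograph$plateau_length
  if (!is.finite(pw) || !is.finite(pl) || pw <= 0 || pl <= 0)
    stopf("plateau measurements must be positive")
  meniscus_dimensions(width = pw,
                      length = pl * if (side == "medial") 0.8 else 0.7)
}

# candidate table for one side with the tested patient's menisci removed
candidate_table <- function(bank, side, exclude_patient = NULL) {
  idx <- bank$index[bank$index$side == side, , drop = FALSE]
  if (!is.null(exclude_patient))
    idx <- idx[idx$patient_id != exclude_patient, , drop = FALSE]
  if (nrow(idx) == 0L) stopf("allograft pool is empty after exclusion")
  idx[order(idx$id), , drop = FALSE]
}

#' Select an allograft by closest width/length (error sum of squares)
#'
#' Score per candidate: `(target width - candidate width)^2 +
#' (target length - candidate length)^2` (mm^2), width and length equally
#' weighted. By default 2D templates are scored against the bank's 3D
#' measured width and length; set `use_2d_bank = TRUE` to score against the
#' bank's 2D measurements instead. Ties are broken by smaller candidate id.
#'
#' @param target a [meniscus_dimensions()] (height ignored).
#' @param bank an [generate_bank()] result (or compatible `allograft_bank`).
#' @param side `"medial"` or `"lateral"`.
#' @param exclude_patient patient id whose menisci are removed from the pool.
#' @param use_2d_bank score against the bank's `dims2d` instead of `dims3d`.
#' @param method label recorded in the result.
#' @return A `selection_result`: `method`, `selected_id`, `score` (mm^2) and
#'   the full `ranking` data frame sorted ascending.
#' @export
select_by_dims <- function(target, bank, side, exclude_patient = NULL,
                           use_2d_bank = FALSE, method = "dims") {
  idx <- candidate_table(bank, side, exclude_patient)
  w <- if (use_2d_bank) idx$width2d else idx$width
  l <- if (use_2d_bank) idx$length2d else idx$length
  score <- (target$width - w)^2 + (target$length - l)^2
  ord <- order(score, idx$id)
  ranking <- data.frame(id = idx$id[ord], score = score[ord],
                        stringsAsFactors = FALSE)
  structure(list(method = method, selected_id = ranking$id[1],
                 score = ranking$score[1], ranking = ranking),
            class = "selection_result")
}

#' Select an allograft by closest mean surface distance
#'
#' Scores every pool candidate by the MeSD between the template mesh and the
#' candidate mesh after ICP superimposition and returns the argmin. Ties
#' (scores within 1e-9 mm) are broken by smaller candidate id.
#'
#' @param template_mesh the 3D template ([meniscus_mesh()], typically the
#'   mirrored contralateral meniscus).
#' @param bank,side,exclude_patient see [select_by_dims()].
#' @param density sampling density for [surface_distance()].
#' @param distance_fn optional replacement distance, a
#'   `function(mesh_a, mesh_b)` returning a list with `mesd` and `masd`
#'   (used for dry runs and testing).
#' @param method label recorded in the result.
#' @return A `selection_result` with scores in mm (MeSD).
#' @export
select_by_mesd <- function(template_mesh, bank, side, exclude_patient = NULL,
                           density = 4, distance_fn = NULL, method = "mesd") {
  idx <- candidate_table(bank, side, exclude_patient)
  if (is.null(distance_fn))
    distance_fn <- function(a, b) surface_distance(a, b, density = density)
  score <- vapply(idx$id, function(id)
    distance_fn(template_mesh, bank$entries[[id]]$mesh)$mesd, numeric(1L))
  ord <- order(round(score / 1e-9) * 1e-9, idx$id)
  ranking <- data.frame(id = idx$id[ord], score = unname(score[ord]),
                        stringsAsFactors = FALSE)
  structure(list(method = method, selected_id = ranking$id[1],
                 score = ranking$score[1], ranking = ranking),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method %s: selected %s (score %.4g, %d candidates)\n",
              x$method, x$selected_id, x$score, nrow(x$ranking)))
  invisible(x)
}

#' Build the sizing template for one missing meniscus
#'
#' For a meniscus assumed missing at (`laterality`, `side`) of a virtual
#' patient: the 3D-MRI template is the mirrored contralateral mesh; the
#' 2D-MRI template is the 2D width/length measurement of that mirrored
#' contralateral mesh; the 2D-RX template is the Pollard derivation from the
#' ipsilateral radiograph.
#'
#' @param method `"mri3d"`, `"mri2d"` or `"rx2d"`.
#' @param patient a [generate_patient()] result.
#' @param side `"medial"` or `"lateral"`.
#' @param laterality knee of the missing meniscus.
#' @return A `sizing_template`: `method` plus `template_mesh` (mri3d) or
#'   `target_dims` (mri2d, rx2d).
#' @export
build_template <- function(method = c("mri3d", "mri2d", "rx2d"), patient,
                           side = c("medial", "lateral"),
                           laterality = c("right", "left")) {
  method <- match.arg(method)
  side <- match.arg(side)
  laterality <- match.arg(laterality)
  out <- list(method = method)
  if (method %in% c("mri3d", "mri2d")) {
    contra <- setdiff(c("right", "left"), laterality)
    cmesh <- patient$meshes[[contra]][[side]]
    if (is.null(cmesh))
      stopf("patient %s lacks a contralateral %s meniscus (%s knee)",
            patient$patient_id, side, contra)
    tm <- mirror_to_right(cmesh)
    if (method == "mri3d") out$template_mesh <- tm
    else out$target_dims <- measure_dimensions_2d(tm)
  } else {
    rx <- patient$radiographs
    row <- rx[rx$knee == laterality & rx$side == side, , drop = FALSE]
    if (nrow(row) == 0L)
      stopf("patient %s lacks an ipsilateral radiograph (%s knee)",
            patient$patient_id, laterality)
    out$target_dims <- pollard_derive(
      list(plateau_width = row$plateau_width[1],
           plateau_length = row$plateau_length[1]), side)
  }
  structure(out, class = "sizing_template")
}
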
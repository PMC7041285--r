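# Leave-one-out sizing validation: every validation meniscus is treated as
# missing, allografts are selected by the gold standard (best possible MeSD)
# and by the three sizing methods, and each selected meniscus is compared
# back to the original. All pairwise surface distances are cached by
# unordered pair, which is the dominant cost of the simulation.

# memoised pairwise distance between two bank entries
make_pair_cache <- function(bank, density, distance_fn = NULL) {
  cache <- new.env(parent = emptyenv())
  if (is.null(distance_fn))
    distance_fn <- function(a, b) surface_distance(a, b, density = density)
  list(
    get = function(id_a, id_b) {
      key <- paste(sort(c(id_a, id_b)), collapse = "|")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- distance_fn(bank$entries[[id_a]]$mesh, bank$entries[[id_b]]$mesh)
        cache[[key]] <- list(mesd = v$mesd, masd = v$masd)
      }
      v
    },
    size = function() length(ls(cache)))
}

outlier_wlh <- function(width_diff, length_diff, height_diff) {
  width_diff > 5 | length_diff > 5 | height_diff > 4
}

#' Run the leave-one-out allograft-selection validation
#'
#' For every validation meniscus (an entry of a bilateral patient): (1) both
#' same-side menisci of that patient are excluded from the pool; (2) the gold
#' standard selects by MeSD with the original mesh itself as the template
#' (best possible allograft); (3) each requested sizing method selects with
#' its own template (mri3d: mirrored contralateral mesh; mri2d: contralateral
#' 2D width/length; rx2d: Pollard derivation from the ipsilateral
#' radiograph); (4) every selected meniscus is compared with the original by
#' surface distance and absolute dimension differences, and outliers are
#' flagged (width or length difference > 5 mm, height difference > 4 mm, or
#' MaSD > 5 mm).
#'
#' @param bank an [generate_bank()] result.
#' @param sides sides to validate.
#' @param methods sizing methods to run besides the always-computed gold
#'   standard (`"best"`).
#' @param density sampling density for surface distances (points per mm^2).
#' @param use_2d_bank score 2D templates against the bank's 2D measurements
#'   instead of the 3D measured width/length.
#' @param distance_fn optional replacement for [surface_distance()] (dry
#'   runs); see [select_by_mesd()].
#' @return A `validation_result` list: `comparisons` (one row per validation
#'   meniscus x method), `summary` (see [summarize_validation()]), `outliers`
#'   (per-method counts) and `counts` (design bookkeeping: bank size, pool
#'   size per case, gold-standard MeSD evaluations per side).
#' @export
run_validation <- function(bank, sides = c("medial", "lateral"),
                           methods = c("mri3d", "mri2d", "rx2d"),
                           density = 4, use_2d_bank = FALSE,
                           distance_fn = NULL) {
  stopifnot(inherits(bank, "allograft_bank"))
  pair <- make_pair_cache(bank, density, distance_fn)
  rows <- list()
  counts <- list()
  for (side in sides) {
    val_ids <- bank_ids(bank, side, validation_only = TRUE)
    n_bank <- length(bank_ids(bank, side))
    n_gold_eval <- 0L
    pool_sizes <- integer(0)
    for (vid in val_ids) {
      orig <- bank$entries[[vid]]
      pool <- candidate_table(bank, side, exclude_patient = orig$patient_id)
      pool_sizes <- c(pool_sizes, nrow(pool))
      n_gold_eval <- n_gold_eval + nrow(pool)

      score_pool <- function(template_id) {
        vapply(pool$id, function(cid) pair$get(template_id, cid)$mesd,
               numeric(1L))
      }
      pick <- function(score, ids) {
        ord <- order(round(score / 1e-9) * 1e-9, ids)
        ids[ord][1]
      }

      selections <- list()
      gold_scores <- score_pool(vid)
      selections$best <- pick(gold_scores, pool$id)

      for (m in methods) {
        if (m == "mri3d") {
          partner <- bank$index$id[bank$index$side == side &
                                     bank$index$patient_id == orig$patient_id &
                                     bank$index$id != vid]
          if (length(partner) != 1L)
            stopf("validation meniscus %s lacks a contralateral partner", vid)
          selections$mri3d <- pick(score_pool(partner), pool$id)
        } else if (m == "mri2d") {
          partner <- bank$index$id[bank$index$side == side &
                                     bank$index$patient_id == orig$patient_id &
                                     bank$index$id != vid]
          if (length(partner) != 1L)
            stopf("validation meniscus %s lacks a contralateral partner", vid)
          sel <- select_by_dims(bank$entries[[partner]]$dims2d, bank, side,
                                exclude_patient = orig$patient_id,
                                use_2d_bank = use_2d_bank, method = "mri2d")
          selections$mri2d <- sel$selected_id
        } else if (m == "rx2d") {
          rx <- bank$radiographs
          row <- rx[rx$patient_id == orig$patient_id &
                      rx$knee == orig$source_laterality &
                      rx$side == side, , drop = FALSE]
          if (nrow(row) == 0L)
            stopf("validation meniscus %s lacks an ipsilateral radiograph", vid)
          target <- pollard_derive(
            list(plateau_width = row$plateau_width[1],
                 plateau_length = row$plateau_length[1]), side)
          sel <- select_by_dims(target, bank, side,
                                exclude_patient = orig$patient_id,
                                use_2d_bank = use_2d_bank, method = "rx2d")
          selections$rx2d <- sel$selected_id
        } else stopf("unknown sizing method '%s'", m)
      }

      for (m in names(selections)) {
        sid <- selections[[m]]
        d <- pair$get(vid, sid)
        sd3 <- bank$entries[[sid]]$dims3d
        od3 <- orig$dims3d
        wd <- abs(sd3$width - od3$width)
        ld <- abs(sd3$length - od3$length)
        hd <- abs(sd3$height - od3$height)
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, original_id = vid, method = m, selected_id = sid,
          mesd = d$mesd, masd = d$masd,
          width_diff = wd, length_diff = ld, height_diff = hd,
          outlier_wlh = outlier_wlh(wd, ld, hd),
          outlier_masd = d$masd > 5,
          stringsAsFactors = FALSE)
      }
    }
    counts[[side]] <- list(n_bank = n_bank, n_validation = length(val_ids),
                           pool_size = unique(pool_sizes),
                           n_gold_evaluations = n_gold_eval)
  }
  comparisons <- do.call(rbind, rows)
  structure(list(comparisons = comparisons,
                 summary = summarize_validation(comparisons),
                 outliers = count_outliers(comparisons),
                 counts = counts),
            class = "validation_result")
}

#' Summary table of a validation run
#'
#' Mean, min, max and SD of each similarity metric per side and method,
#' mirroring the structure of the published result tables, plus
#' Bonferroni-adjusted pairwise p-values between methods per metric.
#'
#' @param comparisons the `comparisons` data frame of [run_validation()].
#' @return A list with `stats` (data frame side x method x metric) and
#'   `p_values` (data frame of pairwise comparisons).
#' @export
summarize_validation <- function(comparisons) {
  metrics <- c("mesd", "masd", "width_diff", "length_diff", "height_diff")
  methods <- unique(comparisons$method)
  stats_rows <- list()
  p_rows <- list()
  for (side in unique(comparisons$side)) {
    cs <- comparisons[comparisons$side == side, , drop = FALSE]
    for (metric in metrics) {
      for (m in methods) {
        x <- cs[[metric]][cs$method == m]
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          side = side, method = m, metric = metric,
          mean = mean(x), min = min(x), max = max(x), sd = sd(x),
          stringsAsFactors = FALSE)
      }
      pairs <- utils::combn(methods, 2L)
      n_comp <- ncol(pairs)
      for (i in seq_len(n_comp)) {
        x <- cs[[metric]][cs$method == pairs[1L, i]]
        y <- cs[[metric]][cs$method == pairs[2L, i]]
        p <- tryCatch(
          t_test_independent(x, y, n_comparisons = n_comp)$p_adjusted,
          error = function(e) NA_real_)
        p_rows[[length(p_rows) + 1L]] <- data.frame(
          side = side, metric = metric,
          method_a = pairs[1L, i], method_b = pairs[2L, i], p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(stats = do.call(rbind, stats_rows),
       p_values = do.call(rbind, p_rows))
}

#' Count outliers per method and side
#'
#' Outliers are selected allografts differing from the original meniscus by
#' more than 5 mm in width, more than 5 mm in length, or more than 4 mm in
#' height (W/L/H outlier), or with a maximum surface distance above 5 mm
#' (MaSD outlier). All inequalities are strict.
#'
#' @param comparisons the `comparisons` data frame of [run_validation()].
#' @return Data frame with per side x method counts `n_cases`, `wlh`, `masd`.
#' @export
count_outliers <- function(comparisons) {
  out <- aggregate(cbind(wlh = outlier_wlh, masd = outlier_masd) ~
                     side + method, data = comparisons, FUN = sum)
  n <- aggregate(outlier_wlh ~ side + method, data = comparisons, FUN = length)
  names(n)[3] <- "n_cases"
  merge(n, out, by = c("side", "method"))
}

#' Diversity statistics of an allograft bank
#'
#' All ordered-pair surface distances per side (n x (n-1) values), their
#' summaries, and the width-length and MeSD-MaSD squared correlations.
#'
#' @param bank an [generate_bank()] result.
#' @param sides sides to analyse.
#' @param density sampling density for surface distances.
#' @param distance_fn optional replacement distance (dry runs).
#' @return A list per side with `n_pairs`, `mesd`/`masd` summaries (mean, sd,
#'   min, max), `r2_width_length`, `r2_mesd_masd`; plus `total_pairs` over
#'   the analysed sides.
#' @export
diversity_stats <- function(bank, sides = c("medial", "lateral"), density = 4,
                            distance_fn = NULL) {
  pair <- make_pair_cache(bank, density, distance_fn)
  out <- list()
  total <- 0L
  for (side in sides) {
    ids <- bank_ids(bank, side)
    n <- length(ids)
    if (n < 2L) stopf("need at least 2 bank entries per side")
    mesd <- masd <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- pair$get(ids[i], ids[j])
        mesd <- c(mesd, d$mesd)
        masd <- c(masd, d$masd)
      }
    }
    # ordered pairs: each unordered pair contributes twice
    mesd2 <- rep(mesd, 2L)
    masd2 <- rep(masd, 2L)
    idx <- bank$index[bank$index$side == side, , drop = FALSE]
    out[[side]] <- list(
      n = n, n_pairs = n * (n - 1L),
      mesd = c(mean = mean(mesd2), sd = sd(mesd2),
               min = min(mesd2), max = max(mesd2)),
      masd = c(mean = mean(masd2), sd = sd(masd2),
               min = min(masd2), max = max(masd2)),
      r2_width_length = if (n >= 3L) pearson_r2(idx$width, idx$length)
                        else NA_real_,
      r2_mesd_masd = if (length(mesd) >= 3L && sd(mesd) > 0)
                       pearson_r2(mesd, masd) else NA_real_)
    total <- total + n * (n - 1L)
  }
  out$total_pairs <- total
  out
}
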
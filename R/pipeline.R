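# End-to-end experiment: ground-truth cohort -> backside removal ->
# reconstruction (group-averaged / plaque-specific / oracle rNCt) ->
# geometry scores -> FE stress on ground-truth and reconstructed geometries
# -> peak-cap-stress comparison.

#' Pipeline configuration
#'
#' @param pop a [population_spec()] for synthetic input, or NULL when
#'   `contours` is given.
#' @param contours path to a contour CSV/GeoJSON (alternative input source).
#' @param n_sections cap on cohort size.
#' @param methods reconstruction methods to run.
#' @param stress_methods subset of `methods` for which FE stress is computed
#'   (ground truth is always solved); NULL = all.
#' @param gee_source "refit" (fit on this cohort's ground truth; group
#'   averages leave-one-plaque-out) or "packaged" (published constants).
#' @param recon_params [reconstruction_params()].
#' @param materials [material_table()].
#' @param mesh [mesh_options()].
#' @param prestress run backward-incremental prestress before loading.
#' @param p_sys_mmHg,p0_mmHg systolic and imaging pressure, mmHg.
#' @param run_stress set FALSE for a geometry-only run.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed integer seed for the synthetic cohort.
#' @return list of class `run_config`.
#' @export
run_config <- function(pop = population_spec(), contours = NULL,
                       n_sections = NULL,
                       methods = c("group_average", "plaque_specific"),
                       stress_methods = NULL, gee_source = c("refit", "packaged"),
                       recon_params = reconstruction_params(),
                       materials = material_table(), mesh = mesh_options(),
                       prestress = TRUE, p_sys_mmHg = 140, p0_mmHg = 100,
                       run_stress = TRUE, out_dir = NULL, seed = 1L) {
  gee_source <- match.arg(gee_source)
  if (!is.null(contours) && !file.exists(contours))
    stop("contour file not found: ", contours)
  if (is.null(stress_methods)) stress_methods <- methods
  structure(as.list(environment()), class = "run_config")
}

# ground-truth rNCt table (one row per NC) for GEE refits / oracle lookup
gt_feature_rows <- function(features) {
  ft <- features_table(features)
  ft$plaque_key <- paste(ft$section_id, ft$nc_index, sep = ":")
  ft
}

refit_gee_pair <- function(ft) {
  mid <- data.frame(rnct = ft$rNCt_mid, nc_angle = ft$nc_angle_deg * pi / 180,
                    imt = ft$IMT_mid * 1000, capt = ft$capT_mid * 1000,
                    artery_id = ft$artery_id)
  side <- data.frame(rnct = ft$rNCt_side, nc_angle = ft$nc_angle_deg * pi / 180,
                     imt = ft$IMT_side * 1000, capt = ft$capT_side * 1000,
                     artery_id = ft$artery_id)
  list(mid = fit_gee(mid, "midcap"), side = fit_gee(side, "sidecap"))
}

#' Run the full reconstruction-and-stress experiment
#'
#' @param config a [run_config()].
#' @return list(records = per-(section, NC) comparison data.frame,
#'   summary = [summarize_records()] output, failures = data.frame,
#'   features, cohort, gee = fitted/packaged coefficient pair).
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  if (!is.null(config$contours)) {
    sections <- if (grepl("\\.json$|\\.geojson$", config$contours))
      read_contours_geojson(config$contours) else read_contours_csv(config$contours)
    if (!is.null(config$n_sections))
      sections <- sections[seq_len(min(length(sections), config$n_sections))]
  } else {
    pop <- config$pop; pop$seed <- config$seed
    sections <- sample_population(pop, n_sections = config$n_sections)$sections
  }
  features <- lapply(sections, characterize)
  ft <- gt_feature_rows(features)
  gee <- switch(config$gee_source,
                packaged = list(mid = published_coefficients("midcap"),
                                side = published_coefficients("sidecap")),
                refit = refit_gee_pair(ft))
  all_mid <- stats::setNames(ft$rNCt_mid, ft$plaque_key)
  all_side <- stats::setNames(ft$rNCt_side, ft$plaque_key)
  records <- list(); failures <- list()
  for (si in seq_along(sections)) {
    cs <- sections[[si]]
    rec_polys <- list()   # method -> list of per-NC polygons
    for (k in seq_along(cs$ncs)) {
      key <- paste(cs$section_id, k, sep = ":")
      row <- tryCatch({
        front <- nc_front_side(cs, cs$ncs[[k]])
        ga <- if (config$gee_source == "packaged")
          list(rnct_mid = 0.40, rnct_side = 0.35)
        else  # leave-one-plaque-out cohort medians
          list(rnct_mid = median(all_mid[names(all_mid) != key]),
               rnct_side = median(all_side[names(all_side) != key]))
        out <- data.frame(section_id = cs$section_id, artery_id = cs$artery_id,
                          nc_index = k, seed = config$seed,
                          stringsAsFactors = FALSE)
        for (m in config$methods) {
          rr <- switch(m,
            group_average = reconstruct(cs, front, "group_average",
                                        averages = ga, params = config$recon_params),
            plaque_specific = reconstruct(cs, front, "plaque_specific",
                                          coeffs = gee, params = config$recon_params),
            oracle = reconstruct(cs, front, "oracle",
                                 rnct = c(all_side[key], all_mid[key], all_side[key]),
                                 params = config$recon_params))
          rec_polys[[m]] <- c(rec_polys[[m]], list(rr$nc_polygon$xy))
          sc <- similarity_index(cs$ncs[[k]], rr$nc_polygon)
          out[[paste0("si_", m)]] <- sc$si
          out[[paste0("da_", m)]] <- sc$delta_a_pct
          out[[paste0("clipped_", m)]] <- rr$clipped_to_media
        }
        out
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(
          section_id = cs$section_id, nc_index = k, stage = "reconstruction",
          message = conditionMessage(e))
        NULL
      })
      if (!is.null(row)) records[[key]] <- row
    }
    if (config$run_stress && length(rec_polys) > 0) {
      res <- tryCatch({
        run_mesh <- config$mesh
        gt_run <- compute_pcs(cs, p_sys_mmHg = config$p_sys_mmHg,
                              prestress = config$prestress,
                              p0_mmHg = config$p0_mmHg,
                              materials = config$materials, mesh = run_mesh)
        per_m <- lapply(config$stress_methods, function(m) {
          if (length(rec_polys[[m]]) != length(cs$ncs)) return(NULL)
          compute_pcs(cs, ncs = rec_polys[[m]],
                      p_sys_mmHg = config$p_sys_mmHg,
                      prestress = config$prestress, p0_mmHg = config$p0_mmHg,
                      materials = config$materials, mesh = run_mesh)
        })
        names(per_m) <- config$stress_methods
        for (k in seq_along(cs$ncs)) {
          key <- paste(cs$section_id, k, sep = ":")
          if (is.null(records[[key]])) next
          pgt <- gt_run$pcs[[k]]
          records[[key]]$pcs_gt <- pgt$pcs
          records[[key]]$pcs_gt_region <- pgt$region
          for (m in config$stress_methods) {
            if (is.null(per_m[[m]])) next
            pm <- per_m[[m]]$pcs[[k]]
            records[[key]][[paste0("pcs_", m)]] <- pm$pcs
            records[[key]][[paste0("pcs_diff_pct_", m)]] <-
              abs(pm$pcs - pgt$pcs) / pgt$pcs * 100
            front_k <- nc_front_side(cs, cs$ncs[[k]])
            sh <- tryCatch(classify_pcs_shift(pgt$location, pm$location, cs,
                                              front_k),
                           error = function(e) list(distance = NA_real_,
                                                    category = NA_character_))
            records[[key]][[paste0("pcs_dist_", m)]] <- sh$distance
            records[[key]][[paste0("pcs_shift_", m)]] <- sh$category
          }
        }
        TRUE
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(
          section_id = cs$section_id, nc_index = NA_integer_,
          stage = "stress", message = conditionMessage(e))
        FALSE
      })
    }
  }
  rec_df <- if (length(records)) rbind_fill(records) else NULL
  fail_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(section_id = character(0), nc_index = integer(0),
               stage = character(0), message = character(0))
  summ <- if (!is.null(rec_df) && nrow(rec_df) >= 3L)
    summarize_records(rec_df, methods = config$methods,
                      stress_methods = if (config$run_stress) config$stress_methods
                                       else character(0))
  else NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ft, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    if (!is.null(rec_df))
      write.csv(rec_df, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
    write.csv(fail_df, file.path(config$out_dir, "failures.csv"), row.names = FALSE)
    if (!is.null(summ))
      jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    if (config$gee_source == "refit") {
      write_coefficients_json(gee$mid, file.path(config$out_dir, "coeffs_midcap.json"))
      write_coefficients_json(gee$side, file.path(config$out_dir, "coeffs_sidecap.json"))
    }
  }
  list(records = rec_df, summary = summ, failures = fail_df,
       features = features, gee = gee)
}

# rbind a list of one-row data.frames whose column sets may differ
# (e.g. stress columns missing for sections whose FE stage failed)
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  }))
}

med_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Summarize a comparison-record table
#'
#' Medians and IQRs of SI, area difference and PCS differences per method,
#' linear regression of reconstructed vs ground-truth PCS, shift-category
#' counts, and stratification by ground-truth PCS below/above 300 kPa (a
#' 300 kPa value falls in the high group).
#'
#' @param records data.frame from [run_pipeline()].
#' @param methods reconstruction methods present.
#' @param stress_methods methods with PCS columns.
#' @return nested list (JSON-ready).
#' @export
summarize_records <- function(records,
                              methods = c("group_average", "plaque_specific"),
                              stress_methods = methods) {
  if (nrow(records) < 3L) stop("need at least 3 records")
  out <- list(n_records = nrow(records))
  for (m in methods) {
    out[[m]] <- list(si = med_iqr(records[[paste0("si_", m)]]),
                     delta_a_pct = med_iqr(records[[paste0("da_", m)]]))
  }
  if ("pcs_gt" %in% names(records)) {
    out$pcs_gt <- med_iqr(records$pcs_gt)
    hi <- records$pcs_gt >= 300
    for (m in stress_methods) {
      pc <- records[[paste0("pcs_", m)]]
      dd <- records[[paste0("pcs_diff_pct_", m)]]
      if (is.null(pc)) next
      ok <- is.finite(pc) & is.finite(records$pcs_gt)
      fit <- if (sum(ok) >= 3L && stats::sd(records$pcs_gt[ok]) > 0) {
        lmf <- lm(pc[ok] ~ records$pcs_gt[ok])
        list(slope = unname(coef(lmf)[2]), intercept = unname(coef(lmf)[1]),
             r_squared = if (stats::sd(pc[ok]) == 0 && stats::sd(records$pcs_gt[ok]) == 0) 1
                         else summary(lmf)$r.squared)
      } else NULL
      shifts <- records[[paste0("pcs_shift_", m)]]
      out[[paste0("pcs_", m)]] <- list(
        pcs = med_iqr(pc), diff_pct = med_iqr(dd),
        diff_pct_low = med_iqr(dd[!hi]), diff_pct_high = med_iqr(dd[hi]),
        regression = fit,
        shift_counts = if (!is.null(shifts)) as.list(table(shifts)) else NULL)
    }
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `pop` and `mesh`
#' sub-blocks mirror [population_spec()] and [mesh_options()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("pop", "mesh", "recon_params"))]
  if (!is.null(y$pop)) args$pop <- do.call(population_spec, y$pop)
  if (!is.null(y$mesh)) args$mesh <- do.call(mesh_options, y$mesh)
  if (!is.null(y$recon_params))
    args$recon_params <- do.call(reconstruction_params, y$recon_params)
  do.call(run_config, args)
}
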
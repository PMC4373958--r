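#' Experiment configuration
#'
#' Describes the full replicated virtual study: five target sizes with
#' size-matched prescriptions, a number of measurement replicates per plan,
#' the measurement error model, and the gamma criteria pairs.
#'
#' @param target_diameters_mm target diameters (default 10, 30, 50, 70, 90).
#' @param prescriptions_cgy prescriptions aligned by index with the diameters
#'   (default 200, 400, 600, 800, 1000).
#' @param replicates measurements per plan (default 3).
#' @param em measurement [error_model()] (default: field-size response on,
#'   0.5% reading noise).
#' @param criteria list of [gamma_criteria()] pairs (default 3%/3mm and
#'   2%/2mm).
#' @param seed master seed; every random draw in [run_experiment()] derives
#'   from it.
#' @param spacing_mm dose-grid spacing (default 1; 2 is the fast profile).
#' @param bin_width_cgy DVH bin width.
#' @param floor_frac reconstruction exclusion floor.
#' @param model beam model parameters.
#' @param peripheral_spec peripheral rim geometry (see [roi_set()]).
#' @return an object of class `qa_config`.
#' @export
experiment_config <- function(target_diameters_mm = c(10, 30, 50, 70, 90),
                              prescriptions_cgy = c(200, 400, 600, 800, 1000),
                              replicates = 3L,
                              em = error_model(noise_sd = 0.005),
                              criteria = list(gamma_criteria(3, 3),
                                              gamma_criteria(2, 2)),
                              seed = 1L,
                              spacing_mm = 1,
                              bin_width_cgy = 1,
                              floor_frac = 0.01,
                              model = beam_model(),
                              peripheral_spec = list(outer_diameter_mm = 210,
                                                     thickness_mm = 10,
                                                     length_mm = 50)) {
  if (length(target_diameters_mm) != length(prescriptions_cgy)) {
    stop("diameters and prescriptions must be aligned by index",
         call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(target_diameters_mm = target_diameters_mm,
                 prescriptions_cgy = prescriptions_cgy,
                 replicates = as.integer(replicates), em = em,
                 criteria = criteria, seed = as.integer(seed),
                 spacing_mm = spacing_mm, bin_width_cgy = bin_width_cgy,
                 floor_frac = floor_frac, model = model,
                 peripheral_spec = peripheral_spec),
            class = "qa_config")
}

crit_id <- function(criteria) {
  paste0(criteria$dose_tol_pct, "_", criteria$dta_mm)
}

#' Build the plans of an experiment configuration
#'
#' One five-field plan per target size on a shared grid. Exposed separately so
#' plans can be reused across experiment variants (they do not depend on the
#' error model).
#'
#' @param config a `qa_config`.
#' @return list of `qa_plan`.
#' @export
build_experiment_plans <- function(config) {
  grid <- make_grid(spacing_mm = config$spacing_mm)
  lapply(seq_along(config$target_diameters_mm), function(i) {
    rois <- roi_set(grid, config$target_diameters_mm[i],
                    peripheral_spec = config$peripheral_spec)
    compose_plan(config$target_diameters_mm[i], config$prescriptions_cgy[i],
                 grid, model = config$model, rois = rois)
  })
}

# aggregate mean/sd of a raw column by size; sd absent (NA) with 1 replicate
agg_by_size <- function(raw, column) {
  sizes <- sort(unique(raw$diameter_mm))
  data.frame(
    size_cm = sizes / 10,
    mean = vapply(sizes, function(s) mean(raw[[column]][raw$diameter_mm == s]),
                  numeric(1)),
    sd = vapply(sizes, function(s) {
      v <- raw[[column]][raw$diameter_mm == s]
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, numeric(1)))
}

anova_by_size <- function(raw, column) {
  sizes <- sort(unique(raw$diameter_mm))
  groups <- lapply(sizes, function(s) raw[[column]][raw$diameter_mm == s])
  if (any(vapply(groups, length, integer(1)) < 2)) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  anova_oneway(groups)
}

safe_pearson <- function(x, y) {
  tryCatch(pearson_correlation(x, y),
           error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                    n = length(x)))
}

#' Run the full replicated virtual QA experiment
#'
#' For each target size: build ROIs and the plan, sample the planned diode
#' reference, then per replicate simulate a measurement, evaluate the 2D diode
#' gamma, reconstruct the perturbed 3D dose, evaluate the 3D gamma per ROI,
#' and collect DVH metrics and dose deviations. Results are aggregated into
#' machine-readable analogs of the study's report tables. Fully deterministic
#' given `config$seed`.
#'
#' Seeding: target size `i` uses error-model seed `config$seed + 1000 * (i -
#' 1)`; replicate `r` of a size adds `r` (diode noise) and `500000 + r` (the
#' ion-chamber analog's reading noise).
#'
#' @param config a `qa_config`.
#' @param plans optional precomputed [build_experiment_plans()] output.
#' @param verbose print progress.
#' @return an object of class `qa_report`: `raw` (one row per size x
#'   replicate), `table2` ... `table7` with their test summaries, and the
#'   config.
#' @export
run_experiment <- function(config, plans = NULL, verbose = FALSE) {
  if (is.null(plans)) plans <- build_experiment_plans(config)
  geometry <- build_geometry()
  cids <- vapply(config$criteria, crit_id, character(1))
  rois_names <- c("target", "adjacent", "peripheral")
  rows <- list()
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    rx <- plan$prescription
    if (verbose) message("target ", plan$target_diameter, " mm")
    planned_reading <- sample_dose_at_diodes(plan, geometry)
    em_i <- config$em
    em_i$seed <- config$seed + 1000L * (i - 1L)
    delivered <- delivered_dose(plan, em_i)
    iso_planned <- isocenter_dose(plan$total_dose)
    iso_delivered <- isocenter_dose(delivered)
    planned_metrics <- lapply(rois_names, function(rn) {
      dvh_metrics(plan$total_dose, plan$rois[[rn]], rx, config$bin_width_cgy)
    })
    names(planned_metrics) <- rois_names
    for (r in seq_len(config$replicates)) {
      meas <- simulate_measurement(planned_reading, plan, em_i, replicate = r)
      iso_measured <- if (em_i$noise_sd > 0) {
        iso_delivered * (1 + with_seed(em_i$seed + 500000L + r,
                                       stats::rnorm(1, sd = em_i$noise_sd)))
      } else iso_delivered
      perturbed <- reconstruct_dose(plan, meas, planned_reading,
                                    config$floor_frac)
      iso_predicted <- predicted_isocenter(perturbed)
      row <- list(diameter_mm = plan$target_diameter, size_cm =
                    plan$target_diameter / 10, prescription_cgy = rx,
                  replicate = r,
                  iso_planned_cgy = iso_planned,
                  iso_planned_pct_rx = 100 * iso_planned / rx,
                  iso_measured_cgy = iso_measured,
                  iso_predicted_cgy = iso_predicted,
                  dev_measured_pct = dose_deviation_pct(iso_measured,
                                                        iso_planned),
                  dev_predicted_pct = dose_deviation_pct(iso_predicted,
                                                         iso_planned))
      for (ci in seq_along(config$criteria)) {
        crit <- config$criteria[[ci]]
        g2 <- gamma_map_diode(meas, plan$total_dose, geometry, crit)
        row[[paste0("pass2d_", cids[ci])]] <- g2$passing_rate
        for (rn in rois_names) {
          g3 <- gamma_map_grid(perturbed, plan$total_dose, crit,
                               roi = plan$rois[[rn]])
          row[[paste0("pass3d_", rn, "_", cids[ci])]] <- g3$passing_rate
        }
      }
      for (rn in rois_names) {
        pm <- planned_metrics[[rn]]
        qm <- dvh_metrics(perturbed, plan$rois[[rn]], rx,
                          config$bin_width_cgy)
        row[[paste0("planned_", rn, "_mean_pct")]] <- pm$mean_pct
        row[[paste0("planned_", rn, "_d50_pct")]] <- pm$d50_pct
        row[[paste0("predicted_", rn, "_mean_pct")]] <- qm$mean_pct
        row[[paste0("predicted_", rn, "_d50_pct")]] <- qm$d50_pct
        row[[paste0("dev_", rn, "_mean_pct")]] <-
          dose_deviation_pct(qm$mean_cgy, pm$mean_cgy)
        row[[paste0("dev_", rn, "_d50_pct")]] <-
          dose_deviation_pct(qm$d50_cgy, pm$d50_cgy)
        if (rn == "target") {
          row[["planned_target_d95_pct"]] <- pm$d95_pct
          row[["predicted_target_d95_pct"]] <- qm$d95_pct
          row[["dev_target_d95_pct"]] <-
            dose_deviation_pct(qm$d95_cgy, pm$d95_cgy)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  raw <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  report_tables(raw, config, cids)
}

# assemble the table analogs from the raw per-replicate results
report_tables <- function(raw, config, cids) {
  rois_names <- c("target", "adjacent", "peripheral")
  with_sd <- config$replicates > 1

  tab <- function(column, extra) {
    a <- agg_by_size(raw, column)
    cbind(extra[rep(1, nrow(a)), , drop = FALSE], a, row.names = NULL)
  }
  # Table 2 analog: isocenter dose deviations by size
  table2 <- rbind(tab("dev_measured_pct",
                      data.frame(quantity = "measured_over_planned")),
                  tab("dev_predicted_pct",
                      data.frame(quantity = "predicted_over_planned")))
  table2_tests <- if (with_sd) {
    do.call(rbind, lapply(c(measured_over_planned = "dev_measured_pct",
                            predicted_over_planned = "dev_predicted_pct"),
                          function(cl) {
                            a <- anova_by_size(raw, cl)
                            data.frame(F = a$statistic, p = a$p_value)
                          }))
  } else NULL

  # Table 3 analog: 2D diode passing rates by size and criteria
  table3 <- do.call(rbind, lapply(seq_along(cids), function(ci) {
    tab(paste0("pass2d_", cids[ci]), data.frame(criteria = cids[ci]))
  }))
  table3_tests <- if (with_sd) {
    do.call(rbind, lapply(cids, function(cid) {
      a <- anova_by_size(raw, paste0("pass2d_", cid))
      data.frame(criteria = cid, F = a$statistic, p = a$p_value)
    }))
  } else NULL

  # Table 4 analog: 3D ROI passing rates
  table4 <- do.call(rbind, lapply(seq_along(cids), function(ci) {
    do.call(rbind, lapply(rois_names, function(rn) {
      tab(paste0("pass3d_", rn, "_", cids[ci]),
          data.frame(criteria = cids[ci], roi = rn))
    }))
  }))
  table4_tests <- if (with_sd) {
    do.call(rbind, lapply(cids, function(cid) {
      do.call(rbind, lapply(rois_names, function(rn) {
        a <- anova_by_size(raw, paste0("pass3d_", rn, "_", cid))
        data.frame(criteria = cid, roi = rn, F = a$statistic, p = a$p_value)
      }))
    }))
  } else NULL

  # Table 5 analog: planned vs predicted DVH metrics (% of prescription),
  # pooled over all plans; independent t-test planned vs predicted
  metric_set <- function(rn) if (rn == "target") c("mean", "d95", "d50")
    else c("mean", "d50")
  table5 <- do.call(rbind, lapply(rois_names, function(rn) {
    do.call(rbind, lapply(metric_set(rn), function(mt) {
      pl <- raw[[paste0("planned_", rn, "_", mt, "_pct")]]
      pr <- raw[[paste0("predicted_", rn, "_", mt, "_pct")]]
      tt <- if (length(pl) >= 2) {
        tryCatch(t_test_independent(pl, pr),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))
      } else list(statistic = NA_real_, p_value = NA_real_)
      data.frame(roi = rn, metric = mt,
                 planned_mean = mean(pl), planned_sd = stats::sd(pl),
                 predicted_mean = mean(pr), predicted_sd = stats::sd(pr),
                 t = tt$statistic, p = tt$p_value)
    }))
  }))

  # Table 6 analog: DVH-metric deviations by size
  table6 <- do.call(rbind, lapply(rois_names, function(rn) {
    do.call(rbind, lapply(metric_set(rn), function(mt) {
      tab(paste0("dev_", rn, "_", mt, "_pct"),
          data.frame(roi = rn, metric = mt))
    }))
  }))
  table6_tests <- if (with_sd) {
    do.call(rbind, lapply(rois_names, function(rn) {
      do.call(rbind, lapply(metric_set(rn), function(mt) {
        a <- anova_by_size(raw, paste0("dev_", rn, "_", mt, "_pct"))
        data.frame(roi = rn, metric = mt, F = a$statistic, p = a$p_value)
      }))
    }))
  } else NULL

  # Table 7 analog: correlation of DVH deviations with the ROI's 3D passing
  # rate, over all size x replicate pairs
  table7 <- do.call(rbind, lapply(cids, function(cid) {
    do.call(rbind, lapply(rois_names, function(rn) {
      do.call(rbind, lapply(metric_set(rn), function(mt) {
        ct <- safe_pearson(raw[[paste0("dev_", rn, "_", mt, "_pct")]],
                           raw[[paste0("pass3d_", rn, "_", cid)]])
        data.frame(criteria = cid, roi = rn, metric = mt,
                   r = ct$statistic, p = ct$p_value, n = nrow(raw))
      }))
    }))
  }))

  structure(list(raw = raw, table2 = table2, table2_tests = table2_tests,
                 table3 = table3, table3_tests = table3_tests,
                 table4 = table4, table4_tests = table4_tests,
                 table5 = table5, table6 = table6,
                 table6_tests = table6_tests, table7 = table7,
                 config = config),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %d target sizes x %d replicates (spacing %g mm)\n",
              length(x$config$target_diameters_mm), x$config$replicates,
              x$config$spacing_mm))
  cat("tables: table2 (isocenter deviations), table3 (2D rates), ",
      "table4 (3D rates),\n        table5 (DVH metrics), table6 ",
      "(DVH deviations), table7 (correlations)\n", sep = "")
  invisible(x)
}
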
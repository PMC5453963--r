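#' Default run configuration
#'
#' A complete configuration for a synthetic end-to-end run. The default is
#' a small demonstration: one poor-regime year (2013) and one good-regime
#' year (2015), both sexes, a handful of birds per stratum, 200
#' randomizations. A full-study configuration is
#' `run_config(strata = berlenga_strata(), scale = 1, n_perm = 1000)`.
#'
#' @param strata data.frame of stratum parameters (rows of
#'   [berlenga_strata()] or custom rows with the same fields).
#' @param scale multiplier applied to per-stratum trip/bird counts (trips
#'   are capped below by 2 x birds, birds by 2).
#' @param seed base seed for every random stage.
#' @param n_perm randomizations of the overlap test.
#' @param levels UD contour levels (percent).
#' @param cell KDE/environment grid cell (degrees).
#' @param buffer_km colony buffer for regional environmental summaries.
#' @param fpt_r_max,fpt_r_by,fpt_sample_step FPT radius grid (km) and
#'   along-path evaluation spacing.
#' @param gen a [generator_config()] (its seed is overridden by `seed`).
#' @param env_n_days layers per simulated environmental stack.
#' @return a named list (class `fs_runconfig`).
#' @export
run_config <- function(strata = NULL, scale = 0.3, seed = 42, n_perm = 200,
                       levels = c(50, 95, 99), cell = 0.05, buffer_km = 200,
                       fpt_r_max = 50, fpt_r_by = 1, fpt_sample_step = 1,
                       gen = generator_config(), env_n_days = 3,
                       isotopes = TRUE, condition = TRUE, habitat = TRUE) {
  if (is.null(strata)) {
    all <- berlenga_strata()
    strata <- all[all$year %in% c(2013, 2015), ]
  }
  gen$seed <- seed
  structure(list(
    strata = strata, scale = scale, seed = seed, n_perm = n_perm,
    levels = levels, cell = cell, buffer_km = buffer_km,
    fpt_r_max = fpt_r_max, fpt_r_by = fpt_r_by,
    fpt_sample_step = fpt_sample_step, gen = gen, env_n_days = env_n_days,
    isotopes = isotopes, condition = condition, habitat = habitat
  ), class = "fs_runconfig")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `gen:` holds
#' [generator_config()] fields and `strata:` a list of stratum records.
#'
#' @param path YAML file.
#' @return an `fs_runconfig`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$gen %||% list()
  if (!is.null(gen_args$colony)) gen_args$colony <- unlist(gen_args$colony)
  gen <- do.call(generator_config, gen_args)
  strata <- if (is.null(y$strata)) NULL else
    do.call(rbind, lapply(y$strata, function(s) as.data.frame(s)))
  args <- y[setdiff(names(y), c("gen", "strata"))]
  do.call(run_config, c(list(strata = strata, gen = gen), args))
}

#' Stratum summary table (mean +/- SD)
#'
#' Per group x year mean, SD and count of every numeric metric column,
#' mirroring the study's headline summary-table layout. Single-observation
#' strata get SD 0 and a degenerate flag; empty strata yield NA rows.
#'
#' @param df data.frame with `group`, `year` and numeric metric columns.
#' @param metrics metric column names (default: all numeric columns except
#'   `year`).
#' @return long data.frame: group, year, metric, n, mean, sd, degenerate.
#' @export
summarize_strata <- function(df, metrics = NULL) {
  if (is.null(metrics))
    metrics <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "year")
  strata <- unique(df[, c("group", "year")])
  out <- NULL
  for (k in seq_len(nrow(strata))) {
    rows <- df$group == strata$group[k] & df$year == strata$year[k]
    for (m in metrics) {
      v <- df[[m]][rows]
      v <- v[is.finite(v)]
      out <- rbind(out, data.frame(
        group = strata$group[k], year = strata$year[k], metric = m,
        n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_,
        degenerate = length(v) < 2))
    }
  }
  rownames(out) <- NULL
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Executes trajectory simulation and processing, FPT/ARS detection,
#' kernel-UD overlap with the bird-level randomization test, environmental
#' extraction, isotopic niche metrics, body condition, and the AICc-ranked
#' habitat models, writing every output surface (stratum summaries, overlap
#' table, model rankings, per-trip metrics, ARS zones) plus a run manifest
#' to `outdir`. Reruns with the same configuration are byte-identical.
#'
#' @param config an `fs_runconfig` from [run_config()] or
#'   [load_run_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = run_config(), outdir, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    res <- list(config = config)
    st <- config$strata
    colony <- config$gen$colony
    n_birds <- pmax(round(st$n_birds * config$scale), pmin(st$n_birds, 3))
    n_trips <- pmax(round(st$n_trips * config$scale), pmin(st$n_trips, 4),
                    n_birds)

    stage <- "simulate"
    say("simulating ", sum(n_trips), " trips over ", nrow(st), " strata")
    trips <- list()
    for (k in seq_len(nrow(st)))
      trips <- c(trips, simulate_stratum_trips(st[k, ], config$gen,
                                               n_trips[k], n_birds[k]))

    stage <- "trajectory+fpt"
    r_grid <- seq(config$fpt_r_by, config$fpt_r_max, by = config$fpt_r_by)
    metrics <- NULL; zones_all <- NULL; spectra <- NULL; ars_pts <- NULL
    hab_rows <- NULL
    for (tr in trips) {
      tr <- compute_speeds(project_trip(tr))
      mov <- filter_resting(tr)
      if (is.null(mov)) next
      path <- interpolate_path(mov, step = 0.1)
      prof <- suppressWarnings(
        fpt_spectrum(path, r_grid, config$fpt_sample_step))
      r_star <- suppressWarnings(detect_ars_scale(prof))
      spectra <- rbind(spectra, data.frame(
        trip_id = trip_attr(tr, "trip_id"), radius_km = prof$r,
        var_log_fpt = prof$var_log_fpt))
      if (!is.na(r_star)) {
        lab <- label_ars(path, r_star)
        full <- map_ars_to_trip(mov, path, lab$mask)
        if (nrow(lab$zones)) {
          z <- lab$zones
          z$trip_id <- trip_attr(tr, "trip_id")
          z$bird_id <- trip_attr(tr, "bird_id")
          z$group <- trip_attr(tr, "group")
          z$year <- trip_attr(tr, "year")
          zones_all <- rbind(zones_all, z)
        }
        # ARS locations (interpolated, at the FPT sampling spacing)
        sel <- prof$eval_idx[lab$mask[prof$eval_idx]]
        if (length(sel)) {
          fpt_sel <- prof$fpt[lab$mask[prof$eval_idx],
                              which.min(abs(prof$r - r_star)), drop = TRUE]
          ars_pts <- rbind(ars_pts, data.frame(
            bird_id = trip_attr(tr, "bird_id"),
            trip_id = trip_attr(tr, "trip_id"),
            group = trip_attr(tr, "group"), year = trip_attr(tr, "year"),
            lon = path$lon[sel], lat = path$lat[sel],
            x = path$x[sel], y = path$y[sel],
            fpt_h = fpt_sel))
        }
      } else {
        full <- map_ars_to_trip(mov, path, rep(FALSE, nrow(path)))
      }
      metrics <- rbind(metrics, suppressWarnings(trip_metrics(full)))
    }
    res$trip_metrics <- metrics
    res$ars_zones <- zones_all
    res$ars_points <- ars_pts
    utils::write.csv(metrics, file.path(outdir, "trip_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(spectra, file.path(outdir, "fpt_spectra.csv"),
                     row.names = FALSE)
    if (!is.null(zones_all))
      utils::write.csv(zones_all, file.path(outdir, "ars_zones.csv"),
                       row.names = FALSE)

    stage <- "kernel_overlap"
    overlaps <- NULL
    h_ref <- NULL
    for (yr in sort(unique(st$year))) {
      pts <- ars_pts[ars_pts$year == yr, ]
      if (is.null(pts) || length(unique(pts$group)) < 2) next
      enough <- all(tapply(pts$bird_id, pts$group,
                           function(b) length(unique(b))) >= 2)
      if (!enough) next
      if (is.null(h_ref)) {
        h_ref <- as.numeric(lscv_bandwidth(pts$x, pts$y))
        say(sprintf("reference LSCV bandwidth: %.1f km", h_ref))
      }
      ov <- randomization_test(pts, h = h_ref, center = colony,
                               levels = config$levels,
                               n_perm = config$n_perm,
                               seed = config$seed + yr)
      ov$year <- yr
      overlaps <- rbind(overlaps, ov)
    }
    res$overlap <- overlaps
    res$h_ref <- h_ref
    if (!is.null(overlaps))
      utils::write.csv(
        overlaps[, c("year", "level", "observed", "randomized", "n_perm", "p")],
        file.path(outdir, "overlap.csv"), row.names = FALSE)

    stage <- "environment"
    pad <- 0.6
    lon_rng <- range(c(ars_pts$lon, colony[1])) + c(-pad, pad)
    lat_rng <- range(c(ars_pts$lat, colony[2])) + c(-pad, pad)
    years <- sort(unique(st$year))
    regime_of <- stats::setNames(st$regime, paste(st$year))[paste(years)]
    sst_by_year <- list(); chl_by_year <- list()
    for (i in seq_along(years)) {
      poor <- regime_of[i] == "poor"
      env <- simulate_env_rasters(
        colony, lon_rng, lat_rng, resolution = config$cell,
        seed = config$seed + 1000 + years[i], n_days = config$env_n_days,
        sst_base = if (poor) 20.5 else 17.0,
        chl_base = if (poor) 0.8 else 2.0)
      sst_by_year[[paste(years[i])]] <- composite_mean(env$SST)
      chl_by_year[[paste(years[i])]] <- composite_mean(env$CHL)
      if (i == 1) bat <- env$BAT
    }
    sst_baseline <- composite_mean(sst_by_year)
    dcol <- distance_to_colony(list(lon = bat$lon, lat = bat$lat), colony)
    env_summary <- NULL
    for (yr in names(sst_by_year)) {
      env_summary <- rbind(env_summary, data.frame(
        year = as.integer(yr),
        sst_200km = buffer_mean(sst_by_year[[yr]], colony, config$buffer_km),
        chl_200km = buffer_mean(chl_by_year[[yr]], colony, config$buffer_km),
        asst_200km = buffer_mean(sst_anomaly(sst_by_year[[yr]], sst_baseline),
                                 colony, config$buffer_km)))
    }
    res$env_summary <- env_summary
    utils::write.csv(env_summary, file.path(outdir, "env_summary.csv"),
                     row.names = FALSE)
    # covariates at ARS locations
    if (!is.null(ars_pts)) {
      hab_rows <- ars_pts
      for (yr in unique(hab_rows$year)) {
        sel <- hab_rows$year == yr
        sst <- sst_by_year[[paste(yr)]]
        chl <- chl_by_year[[paste(yr)]]
        hab_rows$SST[sel] <- extract_at_points(sst, hab_rows$lon[sel],
                                               hab_rows$lat[sel])
        hab_rows$CHL[sel] <- extract_at_points(chl, hab_rows$lon[sel],
                                               hab_rows$lat[sel])
        hab_rows$ASST[sel] <- extract_at_points(
          sst_anomaly(sst, sst_baseline), hab_rows$lon[sel], hab_rows$lat[sel])
        hab_rows$SSTG[sel] <- extract_at_points(gradient_pc(sst),
                                                hab_rows$lon[sel],
                                                hab_rows$lat[sel])
        hab_rows$CHLG[sel] <- extract_at_points(gradient_pc(chl),
                                                hab_rows$lon[sel],
                                                hab_rows$lat[sel])
      }
      hab_rows$BAT <- extract_at_points(bat, hab_rows$lon, hab_rows$lat)
      hab_rows$BATG <- extract_at_points(gradient_pc(bat), hab_rows$lon,
                                         hab_rows$lat)
      hab_rows$DCOL <- extract_at_points(dcol, hab_rows$lon, hab_rows$lat)
      hab_rows$log_fpt <- log(hab_rows$fpt_h)
      utils::write.csv(hab_rows, file.path(outdir, "habitat_table.csv"),
                       row.names = FALSE)
      res$habitat_table <- hab_rows
    }

    stage <- "isotopes"
    iso <- NULL
    if (isTRUE(config$isotopes)) {
      for (k in seq_len(nrow(st)))
        iso <- rbind(iso, simulate_isotopes(
          st[k, ], n = max(n_birds[k], 5),
          seed = split_seed(config$seed, st$group[k], st$year[k], 999)))
      res$isotopes <- iso
      niche <- isotope_niche_summary(iso, n_draws = 4000,
                                     seed = config$seed)
      # posterior probability the female niche is larger, per year
      probs <- NULL
      for (yr in unique(st$year)) {
        f <- iso[iso$group == "female" & iso$year == yr, ]
        m <- iso[iso$group == "male" & iso$year == yr, ]
        if (nrow(f) >= 3 && nrow(m) >= 3) {
          bf <- sea_bayes(f$d13C, f$d15N, 4000, seed = config$seed + 1)
          bm <- sea_bayes(m$d13C, m$d15N, 4000, seed = config$seed + 2)
          probs <- rbind(probs, data.frame(
            year = yr,
            p_female_larger = niche_size_probability(bm$draws, bf$draws)))
        }
      }
      res$isotope_niche <- niche
      res$niche_probs <- probs
      utils::write.csv(niche, file.path(outdir, "isotope_niche.csv"),
                       row.names = FALSE)
    } else {
      warning("isotope stage disabled; skipping")
    }

    stage <- "body_condition"
    if (isTRUE(config$condition)) {
      morpho <- NULL
      for (k in seq_len(nrow(st)))
        morpho <- rbind(morpho, simulate_morphometrics(
          st[k, ], n_birds = max(n_birds[k], 3),
          seed = split_seed(config$seed, st$group[k], st$year[k], 998)))
      morpho$pc1 <- body_size_pc1(morpho)
      morpho$bci <- bci(morpho$mass_capture, morpho$pc1)
      morpho$mass_gain_per_day <- mass_gain_per_day(
        morpho$mass_capture, morpho$mass_recapture, morpho$trip_duration_days)
      res$condition <- morpho
      utils::write.csv(morpho, file.path(outdir, "condition.csv"),
                       row.names = FALSE)
    }

    stage <- "habitat_model"
    if (isTRUE(config$habitat) && !is.null(hab_rows)) {
      rankings <- list()
      for (sex in unique(hab_rows$group)) {
        d <- hab_rows[hab_rows$group == sex, ]
        d <- d[stats::complete.cases(
          d[, c("log_fpt", "BAT", "BATG", "SST", "SSTG", "ASST",
                "CHL", "CHLG", "DCOL")]), ]
        if (nrow(d) < 50 || length(unique(d$bird_id)) < 2) next
        keep <- collinearity_screen(
          d, "log_fpt", c("BAT", "BATG", "SST", "SSTG", "ASST",
                          "CHL", "CHLG", "DCOL"))
        candidates <- c(
          list(keep),
          lapply(keep, function(v) v),
          list(character(0)))
        fits <- lapply(candidates, function(cv)
          fit_additive_model(d, cv, spatial = FALSE))
        rk <- rank_models(fits)
        rankings[[sex]] <- rk
        utils::write.csv(rk, file.path(
          outdir, sprintf("habitat_ranking_%s.csv", sex)), row.names = FALSE)
      }
      res$habitat_rankings <- rankings
    }

    stage <- "summaries"
    tab <- metrics
    tab$lt <- as.numeric(tab$class == "LT")
    summary_tab <- summarize_strata(
      tab, c("duration_days", "max_colony_distance_km",
             "time_flying_per_day_h", "pct_time_in_ars", "lt"))
    if (!is.null(iso))
      summary_tab <- rbind(summary_tab,
                           summarize_strata(iso, c("d13C", "d15N")))
    if (!is.null(res$condition))
      summary_tab <- rbind(summary_tab, summarize_strata(
        res$condition, c("bci", "mass_gain_per_day")))
    res$stratum_summary <- summary_tab
    utils::write.csv(summary_tab, file.path(outdir, "stratum_summary.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    cfg_file <- file.path(outdir, "run_config.yaml")
    yaml::write_yaml(config_to_list(config), cfg_file)
    manifest <- list(
      package = "forageseg",
      version = as.character(utils::packageVersion("forageseg")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      outputs = sort(setdiff(list.files(outdir), "manifest.json")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("pipeline complete: ", outdir)
    invisible(res)
  }, error = on_fail)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$gen <- unclass(out$gen)
  out$gen$colony <- as.list(out$gen$colony)
  out$strata <- lapply(seq_len(nrow(config$strata)), function(i)
    as.list(config$strata[i, ]))
  out
}
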
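piv_defaults <- function() {
  list(initial_window = 48, refine_window = 24, overlap = 0.5, n_passes = 2,
       subpixel = "gaussian2d", snr_min = 1.2, validation_eps = 0.1,
       validation_thresh = 2.0, stride = 1)
}

feature_defaults <- function() {
  list(n_chunks = 8, strain_mode = "vorticity", fold = TRUE, standardize = FALSE)
}

metric_defaults <- function() {
  list(closure_times_h = c(0, 6, 12, 24), n_bins = 41, segment_window = 24)
}

reject_unknown <- function(keys, known, where) {
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, known)
      cand <- if (min(d) <= 3) known[which.min(d)] else {
        fuzzy <- agrep(k, known, max.distance = 0.25, value = TRUE)
        if (length(fuzzy)) fuzzy[1] else NULL
      }
      if (!is.null(cand)) sprintf(" (did you mean '%s'?)", cand) else ""
    }, character(1))
    stop("unknown ", where, " key(s): ",
         paste0("'", unknown, "'", hints, collapse = ", "))
  }
}

fill_defaults <- function(x, defaults, where) {
  x <- x %||% list()
  reject_unknown(names(x), names(defaults), where)
  utils::modifyList(defaults, x)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an R list, fills in all defaults
#' (windows 48/24, overlap 0.5, 8 chunks, ...), checks units and rejects
#' unknown keys with a spelling suggestion. Every movie entry needs a
#' `label` and either a `path` (TIFF on disk) or a `preset` (synthetic
#' phenotype); `calibration` with positive `um_per_px` and `min_per_frame`
#' is mandatory.
#'
#' @param config file path or list.
#' @return an object of class `run_config` with all defaults applied.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  known_top <- c("movies", "calibration", "geometry", "piv", "simulate",
                 "features", "metrics", "clustering", "output_dir", "seed")
  reject_unknown(names(config), known_top, "config")

  cal <- config$calibration
  if (is.null(cal) || is.null(cal$um_per_px) || is.null(cal$min_per_frame))
    stop("calibration with um_per_px and min_per_frame is required")
  reject_unknown(names(cal), c("um_per_px", "min_per_frame"), "calibration")
  if (cal$um_per_px <= 0 || cal$min_per_frame <= 0)
    stop("calibration values must be > 0")

  movies <- config$movies
  if (is.data.frame(movies)) movies <- split(movies, seq_len(nrow(movies)))
  if (is.null(movies) || length(movies) == 0) stop("config lists no movies")
  movies <- lapply(seq_along(movies), function(i) {
    m <- as.list(movies[[i]])
    m <- m[!vapply(m, function(v) is.null(v) || (length(v) == 1 && is.na(v)), TRUE)]
    reject_unknown(names(m), c("path", "preset", "label", "seed"),
                   sprintf("movie %d", i))
    if (is.null(m$label)) stop("movie ", i, " has no label")
    if (is.null(m$path) == is.null(m$preset))
      stop("movie ", i, " needs exactly one of 'path' or 'preset'")
    m
  })

  piv <- fill_defaults(config$piv, piv_defaults(), "piv")
  cfg_piv <- do.call(piv_config, piv)   # validates windows/overlap/etc.

  feats <- fill_defaults(config$features, feature_defaults(), "features")
  if (!feats$strain_mode %in% c("strain", "vorticity"))
    stop("features$strain_mode must be 'strain' or 'vorticity'")
  mets <- fill_defaults(config$metrics, metric_defaults(), "metrics")
  clus <- fill_defaults(config$clustering, list(n_permutations = 999), "clustering")
  sim <- fill_defaults(config$simulate, list(n_frames = 30), "simulate")

  geometry <- if (is.null(config$geometry)) {
    wound_geometry()
  } else if (inherits(config$geometry, "wound_geometry")) {
    config$geometry
  } else {
    g <- config$geometry
    reject_unknown(names(g), c("frame_shape", "wound_center_col", "wound_halfwidth"),
                   "geometry")
    do.call(wound_geometry, g)
  }

  structure(list(movies = movies, calibration = cal, geometry = geometry,
                 piv = cfg_piv, simulate = sim, features = feats,
                 metrics = mets, clustering = clus,
                 output_dir = config$output_dir %||% "sheetflow-out",
                 seed = as.integer(config$seed %||% 1L)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(
    rapply(unclass(cfg), unclass, how = "replace"), auto_unbox = TRUE, digits = NA,
    force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

export_heatmap <- function(values, path, diverging = TRUE, main = "") {
  pal <- if (diverging) {
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  } else {
    grDevices::colorRampPalette(c("#F7F7F7", "#B2182B"))(255)
  }
  z <- t(values[rev(seq_len(nrow(values))), , drop = FALSE])
  lim <- if (diverging) c(-1, 1) * max(abs(z), na.rm = TRUE) else range(z, na.rm = TRUE)
  if (!all(is.finite(lim)) || diff(lim) == 0) lim <- c(-1, 1)
  grDevices::png(path, width = 640, height = 480)
  graphics::image(z, col = pal, zlim = lim, axes = FALSE, main = main)
  grDevices::dev.off()
  invisible(path)
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Run the full migration-analysis pipeline
#'
#' Executes simulate/load -> PIV -> metrics -> kymographs -> chunk features
#' -> PCA -> group separation for every movie in the configuration, writing
#' each intermediate artifact (tidy CSVs, PNG heatmaps, a JSON report) to
#' the output directory. A single global seed fans out to per-movie
#' sub-seeds, so reruns with an identical configuration reproduce identical
#' numeric outputs.
#'
#' @param config a [validate_config()] result, file path, or list.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("sheetflow %s run\n", utils::packageVersion("sheetflow")),
      file = log_path)
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"),
                       file.path(out, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  cal <- cfg$calibration
  feats_v <- feats_s <- list()
  labels <- character(0)
  movie_reports <- list()

  for (i in seq_along(cfg$movies)) {
    m <- cfg$movies[[i]]
    id <- sprintf("%02d_%s", i, m$label)
    mdir <- file.path(out, "movies", id)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    t0 <- proc.time()[3]

    stage <- "input"
    res <- tryCatch({
      if (!is.null(m$preset)) {
        seed_i <- m$seed %||% sub_seed(cfg$seed, i)
        gm <- generate_movie(phenotype_preset(m$preset), cfg$geometry,
                             n_frames = cfg$simulate$n_frames,
                             um_per_px = cal$um_per_px,
                             min_per_frame = cal$min_per_frame,
                             seed = seed_i,
                             grid_window = cfg$piv$refine_window,
                             grid_overlap = cfg$piv$overlap)
        seq <- gm$sequence
      } else {
        seq <- read_movie(m$path, cal$um_per_px, cal$min_per_frame)
      }
      wcc <- cfg$geometry$wound_center_col

      stage <- "piv"
      series <- run_piv(seq, cfg$piv)
      write_velocity_series(series, file.path(mdir, "velocity_fields.csv"))

      stage <- "metrics"
      smap <- summation_map(series, wcc)
      write_matrix_csv(smap$values, file.path(mdir, "summation_map.csv"))
      export_heatmap(smap$values, file.path(mdir, "summation_map.png"),
                     main = paste("summation map:", m$label))
      dd <- displacement_distribution(series, wcc, cfg$metrics$n_bins)
      utils::write.csv(data.frame(frame = seq_along(dd$per_frame_mean_speed),
                                  mean_speed_um_min = dd$per_frame_mean_speed),
                       file.path(mdir, "mean_speed.csv"), row.names = FALSE)
      write_matrix_csv(dd$summed, file.path(mdir, "summed_displacement.csv"))
      cc <- tryCatch({
        n <- dim(seq$frames)[3]
        want <- unique(pmin(n, pmax(1, round(
          cfg$metrics$closure_times_h * 60 / seq$min_per_frame) + 1)))
        closure_curve(seq, cfg$geometry, frames = want,
                      window = cfg$metrics$segment_window)
      }, error = function(e) {
        logf("movie %s: closure curve skipped (%s)", id, conditionMessage(e))
        NULL
      })
      if (!is.null(cc))
        utils::write.csv(as.data.frame(cc), file.path(mdir, "closure_curve.csv"),
                         row.names = FALSE)

      stage <- "kymographs"
      kv <- velocity_kymograph(series, wcc, fold = cfg$features$fold)
      ks <- strain_kymograph(series, mode = cfg$features$strain_mode,
                             fold = cfg$features$fold)
      write_matrix_csv(kv$values, file.path(mdir, "kymo_velocity.csv"))
      write_matrix_csv(ks$values, file.path(mdir, "kymo_strain.csv"))
      export_heatmap(kv$values, file.path(mdir, "kymo_velocity.png"),
                     main = paste("velocity kymograph:", m$label))
      export_heatmap(ks$values, file.path(mdir, "kymo_strain.png"),
                     diverging = FALSE, main = paste("strain kymograph:", m$label))

      stage <- "features"
      fv <- chunk_features(kv, cfg$features$n_chunks)
      fs <- chunk_features(ks, cfg$features$n_chunks)
      list(fv = fv, fs = fs,
           summary = list(
             id = id, label = m$label,
             median_summed_displacement_um = stats::median(dd$summed, na.rm = TRUE),
             mean_speed_um_min = mean(dd$per_frame_mean_speed, na.rm = TRUE),
             closure = if (is.null(cc)) NULL else
               as.list(stats::setNames(cc$closure_pct, paste0("t", cc$time_h, "h")))))
    }, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s' for movie %s: %s",
                   stage, id, conditionMessage(e)), call. = FALSE)
    })

    feats_v[[i]] <- res$fv
    feats_s[[i]] <- res$fs
    labels[i] <- m$label
    movie_reports[[i]] <- res$summary
    logf("movie %s done in %.1f s", id, proc.time()[3] - t0)
  }

  Xv <- do.call(rbind, lapply(feats_v, `[[`, "values"))
  Xs <- do.call(rbind, lapply(feats_s, `[[`, "values"))
  ids <- vapply(movie_reports, `[[`, character(1), "id")
  utils::write.csv(data.frame(movie = ids, label = labels, Xv),
                   file.path(out, "features_velocity.csv"), row.names = FALSE)
  utils::write.csv(data.frame(movie = ids, label = labels, Xs),
                   file.path(out, "features_strain.csv"), row.names = FALSE)

  cohort <- NULL
  if (length(cfg$movies) >= 3 && length(unique(labels)) >= 2) {
    ncomp <- min(2, nrow(Xv) - 1, ncol(Xv))
    emb_v <- pca_embed(Xv, ncomp, cfg$features$standardize, labels)
    emb_s <- pca_embed(Xs, ncomp, cfg$features$standardize, labels)
    for (nm in c("velocity", "strain")) {
      emb <- if (nm == "velocity") emb_v else emb_s
      utils::write.csv(data.frame(movie = ids, label = labels, emb$scores),
                       file.path(out, sprintf("embedding_%s.csv", nm)),
                       row.names = FALSE)
    }
    tab <- table(labels)
    sep <- NULL
    if (length(tab) >= 2 && all(tab >= 2)) {
      sep <- list(
        velocity = unclass(cluster_separation(emb_v, labels,
                                              cfg$clustering$n_permutations,
                                              seed = sub_seed(cfg$seed, 9001L))),
        strain = unclass(cluster_separation(emb_s, labels,
                                            cfg$clustering$n_permutations,
                                            seed = sub_seed(cfg$seed, 9002L))))
    }
    cohort <- list(
      explained_variance_velocity = emb_v$explained_variance_ratio,
      explained_variance_strain = emb_s$explained_variance_ratio,
      separation = sep)
  }

  report <- structure(list(movies = movie_reports, cohort = cohort,
                           labels = labels,
                           version = as.character(utils::packageVersion("sheetflow")),
                           config_hash = config_hash(cfg),
                           seed = cfg$seed, output_dir = out),
                      class = "run_report")
  jsonlite::write_json(rapply(unclass(report), unclass, how = "replace"),
                       file.path(out, "report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d movies (%s), outputs in %s\n",
              length(x$movies), paste(unique(x$labels), collapse = ", "),
              x$output_dir))
  if (!is.null(x$cohort$separation)) {
    cat(sprintf("  velocity separation: silhouette %.3f, p = %.4g\n",
                x$cohort$separation$velocity$statistic,
                x$cohort$separation$velocity$p_value))
    cat(sprintf("  strain separation:   silhouette %.3f, p = %.4g\n",
                x$cohort$separation$strain$statistic,
                x$cohort$separation$strain$p_value))
  }
  invisible(x)
}
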
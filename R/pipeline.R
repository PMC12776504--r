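#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Every
#' default reproduces the study constants: 500 Hz sampling, 1-50 Hz
#' broadband filter, 4-second epochs and 29 epochs per subject, the five
#' canonical bands, 5% beamformer regularization, and the classifier grids
#' of [classifier_config()].
#'
#' @param seed master seed for the whole run
#' @param n_per_group subjects per group
#' @param conditions cohort conditions to simulate
#' @param duration_s,fs,n_sensors,snr_db generator settings
#' @param filter_low,filter_high,filter_order broadband filter settings
#' @param epoch_seconds,epoch_count,epoch_selection epoching settings
#' @param bands band table as in [default_bands()]
#' @param beamformer_regularization diagonal-loading fraction
#' @param mvar_order `"auto"` or fixed integer
#' @param mvar_candidates candidate orders under `"auto"`
#' @param omst_stop_patience OMST stopping patience
#' @param alpha_connectivity declaration threshold for connectivity contrasts
#' @param run_stats,run_classification stage switches
#' @param classify_bands band names fed to the classifier
#' @param classify a `classifier_config`
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(seed = 42, n_per_group = 22,
                            conditions = c("HC", "stroke_pre", "stroke_post"),
                            duration_s = 180, fs = 500, n_sensors = 64,
                            snr_db = 10,
                            filter_low = 1, filter_high = 50, filter_order = 4,
                            epoch_seconds = 4, epoch_count = 29,
                            epoch_selection = "first",
                            bands = default_bands(),
                            beamformer_regularization = 0.05,
                            mvar_order = "auto", mvar_candidates = 2:10,
                            omst_stop_patience = 3,
                            alpha_connectivity = 0.01,
                            run_stats = TRUE, run_classification = TRUE,
                            classify_bands = "alpha",
                            classify = classifier_config()) {
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              conditions = conditions, duration_s = duration_s, fs = fs,
              n_sensors = n_sensors, snr_db = snr_db,
              filter_low = filter_low, filter_high = filter_high,
              filter_order = filter_order, epoch_seconds = epoch_seconds,
              epoch_count = epoch_count, epoch_selection = epoch_selection,
              bands = bands,
              beamformer_regularization = beamformer_regularization,
              mvar_order = mvar_order, mvar_candidates = mvar_candidates,
              omst_stop_patience = omst_stop_patience,
              alpha_connectivity = alpha_connectivity,
              run_stats = run_stats, run_classification = run_classification,
              classify_bands = classify_bands, classify = classify)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$duration_s > 0, cfg$n_per_group >= 1,
            cfg$filter_low > 0, cfg$filter_low < cfg$filter_high,
            cfg$filter_high < cfg$fs / 2,
            cfg$epoch_seconds > 0, cfg$epoch_count >= 1,
            cfg$beamformer_regularization >= 0)
  bad <- setdiff(cfg$conditions, c("HC", "stroke_pre", "stroke_post"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  bad_band <- setdiff(cfg$classify_bands, cfg$bands$name)
  if (length(bad_band)) stop("unknown band name(s): ",
                             paste(bad_band, collapse = ", "))
  if (cfg$duration_s < cfg$epoch_seconds * cfg$epoch_count)
    stop("duration_s too short for ", cfg$epoch_count, " epochs of ",
         cfg$epoch_seconds, " s")
  invisible(TRUE)
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trips the configuration losslessly through a human-readable file.
#'
#' @param config a `pipeline_config`
#' @param path YAML file path
#' @return `save_config`: invisibly, `path`; `load_config`: the validated
#'   `pipeline_config`
#' @export
save_config <- function(config, path) {
  plain <- unclass(config)
  plain$bands <- as.list(plain$bands)
  plain$classify <- unclass(plain$classify)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$bands <- as.data.frame(plain$bands)
  plain$classify <- structure(plain$classify, class = "classifier_config")
  plain$mvar_candidates <- as.integer(plain$mvar_candidates)
  validate_config(plain)
  class(plain) <- "pipeline_config"
  plain
}

stage_digest <- function(x) sprintf("%.10e", sum(abs(unlist(x))))

#' Preprocess and localize one recording into analysis-ready epochs
#'
#' Broadband filter, common-average reference, sensor covariance, LCMV
#' filters, virtual-channel extraction, epoching and hemisphere flipping —
#' the per-subject front half of the pipeline.
#'
#' @param recording an `eeg_recording`
#' @param leadfield the `leadfield` used for beamforming
#' @param config a `pipeline_config`
#' @return a `source_epochs` in canonical layout (affected hemisphere left)
#' @export
preprocess_subject <- function(recording, leadfield, config = pipeline_config()) {
  rec <- bandpass_filter(recording, config$filter_low, config$filter_high,
                         order = config$filter_order)
  rec <- common_average_reference(rec)
  C <- sensor_covariance(rec)
  # the re-referenced data lives in the average-referenced sensor space, so
  # the lead field must be projected the same way before filter computation
  leadfield$gain <- sweep(leadfield$gain, 2, colMeans(leadfield$gain))
  flt <- lcmv_filters(leadfield, C, config$beamformer_regularization)
  vc <- extract_virtual_channels(flt, rec)
  ep <- segment_epochs(vc, fs = rec$fs, epoch_seconds = config$epoch_seconds,
                       n_epochs = config$epoch_count,
                       selection = config$epoch_selection,
                       seed = config$seed,
                       meta = list(subject_id = rec$subject_id,
                                   group = rec$group, session = rec$session,
                                   lesion_side = rec$lesion_side))
  flip_hemispheres(ep, rec$lesion_side)
}

#' Run the end-to-end cohort analysis
#'
#' Simulates the cohort, preprocesses and localizes every recording,
#' estimates band-averaged PDC connectivity, binarizes with OMST, computes
#' graph metrics and laterality indices, runs the planned group statistics
#' on regional out-strength, and classifies the configured comparisons from
#' flattened connectivity features. All stages are deterministic given the
#' configuration.
#'
#' @param config a `pipeline_config`
#' @return a `cohort_result_set`: list with `connectivity` (per subject-session,
#'   per band), `metrics` (tidy data.frame: subject, session, group, band,
#'   region, metric, value), `laterality` (tidy per-subject LI),
#'   `li_tests`, `stats` (regional out-strength contrasts), `classification`,
#'   `clinical` (summary + mixed ANOVA on the packaged scores table),
#'   `manifest`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  t_start <- Sys.time()
  cohort <- generate_cohort(config$n_per_group, config$conditions,
                            seed = config$seed, duration_s = config$duration_s,
                            fs = config$fs, n_sensors = config$n_sensors,
                            snr_db = config$snr_db)
  keys <- names(cohort$recordings)
  conn <- vector("list", length(keys)); names(conn) <- keys
  masks <- vector("list", length(keys)); names(masks) <- keys
  metrics <- list(); lat <- list()
  for (key in keys) {
    rec <- cohort$recordings[[key]]
    ep <- preprocess_subject(rec, cohort$leadfield, config)
    conn[[key]] <- subject_connectivity(
      ep, bands = config$bands, order = config$mvar_order,
      order_candidates = config$mvar_candidates)
    masks[[key]] <- lapply(conn[[key]], omst_binarize,
                           stop_patience = config$omst_stop_patience)
    for (band in names(conn[[key]])) {
      cm <- conn[[key]][[band]]; bn <- masks[[key]][[band]]
      s_out <- node_strength(cm, "out", mask = bn)
      deg <- node_degree(bn)
      leff <- local_efficiency(cm, mask = bn)
      metrics[[length(metrics) + 1]] <- data.frame(
        subject_id = rec$subject_id, session = rec$session, group = rec$group,
        band = band, region = names(s_out),
        strength_out = unname(s_out), degree = unname(deg),
        local_efficiency = unname(leff), row.names = NULL)
      li <- laterality_index(cm, mask = bn, atlas = cohort$atlas)
      lat[[length(lat) + 1]] <- data.frame(
        subject_id = rec$subject_id, session = rec$session, group = rec$group,
        band = band, base_region = names(li), li = unname(li),
        row.names = NULL)
    }
  }
  metrics <- do.call(rbind, metrics)
  lat <- do.call(rbind, lat)

  li_tests <- NULL; stats_tab <- NULL; classification <- NULL
  if (config$run_stats) {
    li_tests <- run_li_tests(lat)
    stats_tab <- run_strength_contrasts(metrics, config$alpha_connectivity)
  }
  if (config$run_classification) {
    classification <- run_classification(conn, config)
  }
  clinical <- list(summary = fma_summary(load_fma_table()),
                   anova = mixed_anova(load_fma_table()))
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("pdcnet")),
                   started = format(t_start), finished = format(Sys.time()),
                   digests = list(connectivity = stage_digest(
                     lapply(conn, function(cc) lapply(cc, `[[`, "weights"))),
                     metrics = stage_digest(metrics[sapply(metrics, is.numeric)]),
                     laterality = stage_digest(lat$li[!is.na(lat$li)])))
  res <- list(connectivity = conn, masks = masks, metrics = metrics,
              laterality = lat, li_tests = li_tests, stats = stats_tab,
              classification = classification, clinical = clinical,
              truth = cohort$truth, manifest = manifest)
  class(res) <- "cohort_result_set"
  res
}

run_li_tests <- function(lat) {
  out <- list()
  combos <- unique(lat[, c("group", "session", "band")])
  for (r in seq_len(nrow(combos))) {
    sub <- lat[lat$group == combos$group[r] & lat$session == combos$session[r] &
                 lat$band == combos$band[r], ]
    for (base in unique(sub$base_region)) {
      vals <- sub$li[sub$base_region == base]
      if (sum(!is.na(vals)) < 3) next
      tst <- li_group_test(vals)
      out[[length(out) + 1]] <- data.frame(
        group = combos$group[r], session = combos$session[r],
        band = combos$band[r], base_region = base,
        mean_li = tst$mean, p_value = tst$p_value,
        significant = tst$significant, test_used = tst$test_used,
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

run_strength_contrasts <- function(metrics, alpha) {
  out <- list()
  for (band in unique(metrics$band)) {
    mb <- metrics[metrics$band == band, ]
    hc <- mb[mb$group == "HC", ]
    pre <- mb[mb$session == "pre", ]
    post <- mb[mb$session == "post", ]
    for (region in unique(mb$region)) {
      v_hc <- hc$strength_out[hc$region == region][order(hc$subject_id[hc$region == region])]
      v_pre <- pre$strength_out[pre$region == region][order(pre$subject_id[pre$region == region])]
      v_post <- post$strength_out[post$region == region][order(post$subject_id[post$region == region])]
      add <- function(comparison, res) {
        out[[length(out) + 1]] <<- data.frame(
          band = band, region = region, comparison = comparison,
          statistic = res$statistic, p_value = res$p_value,
          effect_size_d = res$effect_size_d, test_used = res$test_used,
          significant = res$significant, row.names = NULL)
      }
      if (length(v_hc) >= 3 && length(v_pre) >= 3)
        add("HC_vs_pre", compare_unpaired(v_hc, v_pre, alpha))
      if (length(v_hc) >= 3 && length(v_post) >= 3)
        add("HC_vs_post", compare_unpaired(v_hc, v_post, alpha))
      if (length(v_pre) >= 3 && length(v_pre) == length(v_post))
        add("post_vs_pre", compare_paired(v_pre, v_post, alpha))
    }
  }
  do.call(rbind, out)
}

run_classification <- function(conn, config) {
  meta <- lapply(conn, function(cc) cc[[1]]$meta)
  group <- vapply(meta, function(m) m$group %||% "HC", character(1))
  session <- vapply(meta, function(m) m$session %||% "single", character(1))
  sid <- vapply(meta, function(m) m$subject_id %||% "s", character(1))
  comparisons <- list(
    HC_vs_pre = list(a = group == "HC", b = group == "stroke" & session == "pre"),
    HC_vs_post = list(a = group == "HC", b = group == "stroke" & session == "post"),
    pre_vs_post = list(a = group == "stroke" & session == "pre",
                       b = group == "stroke" & session == "post"))
  out <- list()
  for (band in config$classify_bands) {
    for (cmp in names(comparisons)) {
      sel_a <- comparisons[[cmp]]$a; sel_b <- comparisons[[cmp]]$b
      if (sum(sel_a) < 2 || sum(sel_b) < 2) next
      idx <- which(sel_a | sel_b)
      mats <- lapply(conn[idx], `[[`, band)
      labels <- ifelse(sel_a[idx], strsplit(cmp, "_vs_")[[1]][1],
                       strsplit(cmp, "_vs_")[[1]][2])
      ft <- vectorize(mats, labels, subject_ids = sid[idx])
      cfg <- config$classify
      cfg$seed <- config$seed
      out[[paste(band, cmp, sep = ".")]] <-
        loocv_evaluate(ft, config = cfg)
    }
  }
  out
}

#' @export
print.cohort_result_set <- function(x, ...) {
  cat("cohort_result_set: ", length(x$connectivity), " subject-sessions, ",
      length(unique(x$metrics$band)), " bands\n", sep = "")
  if (!is.null(x$classification))
    for (nm in names(x$classification)) {
      cat("  ", nm, ": ", sep = ""); print(x$classification[[nm]])
    }
  invisible(x)
}
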
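# End-to-end orchestration: preprocess -> IF field -> GF-IF -> pooled
# k-means microstates -> metrics -> dynamics validation -> group statistics.

#' Default pipeline configuration
#'
#' One flat key-value list mirroring every tunable of the pipeline; a YAML
#' config file with any subset of these keys overrides the defaults.
#'
#' @return Named list of parameters.
#' @export
pipeline_config <- function() {
  list(
    band_low = 4,            # Hz, band-pass lower edge
    band_high = 13,          # Hz, band-pass upper edge
    filter_order = 4,        # Butterworth prototype order (zero-phase)
    trim_s = 5,              # s trimmed from each epoch end
    if_median_window = 0.1,  # s, phase-slip median filter
    gfif_median_window = 0.025,  # s, GF-IF ripple median filter
    field = "if",            # "if" or "ia" (amplitude variant)
    k = 4,                   # number of microstates
    seed = 17,               # master seed (k-means, surrogates)
    restarts = 50,           # k-means++ restarts
    dynamics = TRUE,         # run PSD / MSE / surrogate suite
    psd_window_s = 5,        # Welch window
    mse_max_scale = 20,      # MSE scales
    mse_m = 2, mse_r = 0.2,  # SampEn parameters
    n_surrogates = 10,       # IAAFT surrogates per recording
    iaaft_iterations = 100,  # IAAFT iterations
    q = 0.05                 # FDR level
  )
}

#' Read a YAML pipeline config, merged over the defaults
#'
#' @param path YAML file with any subset of [pipeline_config()] keys.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, user)
}

#' Preprocess one recording and derive its IF field and GF-IF series
#'
#' Applies the full single-recording chain: band-pass filter, edge trim,
#' Hilbert phase, instantaneous frequency with slip-suppressing median,
#' deviation field, GF-IF with extrema detection.
#'
#' @param rec An `if_recording` (raw).
#' @param cfg Configuration list from [pipeline_config()].
#' @return List with `iff` (an `if_field`), `gfif` (a `gfif_series`),
#'   `subject_id`, `group`, `mmse`, and `mean_if` (grand-mean IF, Hz).
#' @export
process_recording <- function(rec, cfg = pipeline_config()) {
  filt <- bandpass_filter(rec, low = cfg$band_low, high = cfg$band_high,
                          order = cfg$filter_order)
  filt <- trim_edges(filt, seconds = cfg$trim_s)
  ph <- instantaneous_phase(filt)
  iff <- instantaneous_frequency(ph, median_window = cfg$if_median_window)
  iff <- deviation_field(iff, field = cfg$field)
  g <- gfif_series(iff, smooth_window = cfg$gfif_median_window)
  list(iff = iff, gfif = g, subject_id = rec$subject_id, group = rec$group,
       mmse = rec$mmse, mean_if = mean(iff$iff))
}

canonical_state_order <- function(labels) {
  pref <- c("frontal", "occipital", "left", "right")
  order(match(labels, pref, nomatch = length(pref) + 1L), seq_along(labels))
}

#' Analyze a cohort of recordings held in memory
#'
#' The workhorse behind [run_full_analysis()]: processes every recording,
#' pools peak topographies over all subjects of both groups, fits one
#' k-means state model, segments every recording against it, and computes
#' per-subject metrics, group test tables (with the fixed FDR family
#' sizes), GF-IF dynamics validation, and MMSE correlations.
#'
#' @param recordings List of `if_recording` objects.
#' @param cfg Configuration list.
#' @param progress Emit per-stage messages (default FALSE).
#' @return List of class `if_analysis` with `model`, `processed`,
#'   `sequences`, `metrics`, `subject_table`, `tests`, `dynamics`,
#'   `mmse_tests`, `config`.
#' @export
analyze_cohort <- function(recordings, cfg = pipeline_config(),
                           progress = FALSE) {
  if (length(recordings) == 0L) stop("empty cohort", call. = FALSE)
  say <- function(...) if (progress) message(...)

  say("stage 1/5: preprocessing + IF fields (", length(recordings),
      " recordings)")
  processed <- lapply(recordings, function(r) {
    tryCatch(process_recording(r, cfg),
             error = function(e) stop("stage preprocess/instafreq failed for subject '",
                                      r$subject_id, "': ", conditionMessage(e),
                                      call. = FALSE))
  })

  say("stage 2/5: pooled k-means (k = ", cfg$k, ")")
  peaks <- collect_peak_vectors(processed)
  mont <- processed[[1]]$iff$montage
  model <- fit_state_model(peaks, k = cfg$k, seed = cfg$seed,
                           restarts = cfg$restarts, mont = mont)

  say("stage 3/5: segmentation + microstate metrics")
  sequences <- lapply(processed, function(p) {
    assign_segments(p$iff, p$gfif, model)
  })
  metrics <- lapply(sequences, microstate_metrics)

  ord <- canonical_state_order(model$labels)
  lab <- model$labels[ord]
  subject_table <- do.call(rbind, lapply(seq_along(processed), function(i) {
    m <- metrics[[i]]
    row <- data.frame(subject_id = processed[[i]]$subject_id,
                      group = processed[[i]]$group,
                      mmse = processed[[i]]$mmse,
                      mean_if = processed[[i]]$mean_if,
                      mean_gfif = mean(processed[[i]]$gfif$gfif),
                      emergence_all = m$emergence_all,
                      n_segments = m$n_segments)
    em <- m$emergence[ord]; oc <- m$occurrence_rate[ord]
    tr <- m$transition[ord, ord]
    names(em) <- paste0("emergence_", lab)
    names(oc) <- paste0("occurrence_", lab)
    trv <- as.vector(t(tr))
    names(trv) <- paste0("trans_", rep(lab, each = length(lab)), "_to_",
                         rep(lab, length(lab)))
    cbind(row, as.data.frame(as.list(c(em, oc, trv)), check.names = FALSE))
  }))

  dynamics <- NULL
  if (isTRUE(cfg$dynamics)) {
    say("stage 4/5: GF-IF dynamics (PSD / MSE / IAAFT surrogates)")
    dynamics <- lapply(seq_along(processed), function(i) {
      g <- processed[[i]]$gfif
      psd <- welch_psd(g$gfif, rate = g$rate, window_s = cfg$psd_window_s)
      surr <- surrogate_comparison(g$gfif, n_surr = cfg$n_surrogates,
                                   iterations = cfg$iaaft_iterations,
                                   max_scale = cfg$mse_max_scale,
                                   m = cfg$mse_m, r = cfg$mse_r,
                                   base_seed = cfg$seed + 1000L * i)
      list(subject_id = processed[[i]]$subject_id,
           group = processed[[i]]$group, psd = psd,
           mse = surr$original_mse, surrogates = surr)
    })
  }

  say("stage 5/5: group statistics")
  groups <- vapply(processed, `[[`, character(1), "group")
  tests <- NULL
  mmse_tests <- NULL
  if (any(groups == "HC") && any(groups == "AD")) {
    tests <- cohort_group_tests(subject_table, dynamics, cfg)
  }
  is_ad <- subject_table$group == "AD" & is.finite(subject_table$mmse)
  if (sum(is_ad) >= 3L) {
    mmse_tests <- cohort_mmse_tests(subject_table[is_ad, , drop = FALSE], cfg)
  }

  structure(list(model = model, processed = processed, sequences = sequences,
                 metrics = metrics, subject_table = subject_table,
                 tests = tests, dynamics = dynamics, mmse_tests = mmse_tests,
                 config = cfg),
            class = "if_analysis")
}

# Group-comparison tables with the fixed family sizes: emergence k+1,
# occurrence k, transitions k*k, MSE scales, PSD bins.
cohort_group_tests <- function(tab, dynamics, cfg) {
  hc <- tab[tab$group == "HC", , drop = FALSE]
  ad <- tab[tab$group == "AD", , drop = FALSE]
  pick <- function(df, pat) as.matrix(df[, grep(pat, names(df)), drop = FALSE])
  out <- list(
    emergence = group_test_table(
      pick(hc, "^emergence"), pick(ad, "^emergence"),
      family_size = cfg$k + 1L, q = cfg$q),
    occurrence = group_test_table(
      pick(hc, "^occurrence_"), pick(ad, "^occurrence_"),
      family_size = cfg$k, q = cfg$q),
    transitions = group_test_table(
      pick(hc, "^trans_"), pick(ad, "^trans_"),
      family_size = cfg$k^2, q = cfg$q)
  )
  if (!is.null(dynamics)) {
    grp <- vapply(dynamics, `[[`, character(1), "group")
    psd_m <- t(vapply(dynamics, function(d) d$psd$power,
                      numeric(length(dynamics[[1]]$psd$power))))
    colnames(psd_m) <- sprintf("psd_%.3fHz", dynamics[[1]]$psd$freqs)
    mse_m <- t(vapply(dynamics, function(d) d$mse$sampen,
                      numeric(cfg$mse_max_scale)))
    colnames(mse_m) <- paste0("mse_scale", seq_len(cfg$mse_max_scale))
    out$psd <- group_test_table(psd_m[grp == "HC", , drop = FALSE],
                                psd_m[grp == "AD", , drop = FALSE],
                                family_size = ncol(psd_m), q = cfg$q)
    out$mse <- group_test_table(mse_m[grp == "HC", , drop = FALSE],
                                mse_m[grp == "AD", , drop = FALSE],
                                family_size = cfg$mse_max_scale, q = cfg$q)
    # paired original-vs-surrogate SampEn per group, per scale
    out$surrogate <- lapply(c(HC = "HC", AD = "AD"), function(g) {
      dg <- dynamics[grp == g]
      if (length(dg) < 2L) return(NULL)
      orig <- t(vapply(dg, function(d) d$mse$sampen,
                       numeric(cfg$mse_max_scale)))
      surr <- t(vapply(dg, function(d) d$surrogates$surrogate_mse_mean,
                       numeric(cfg$mse_max_scale)))
      res <- lapply(seq_len(cfg$mse_max_scale), function(j) {
        tryCatch(paired_ttest(orig[, j], surr[, j]),
                 error = function(e) list(t = NA_real_, p = NA_real_))
      })
      p <- vapply(res, `[[`, numeric(1), "p")
      data.frame(name = paste0("scale", seq_len(cfg$mse_max_scale)),
                 t = vapply(res, `[[`, numeric(1), "t"), p = p,
                 significant = bh_fdr(p, q = cfg$q,
                                      family_size = cfg$mse_max_scale))
    })
  }
  out
}

cohort_mmse_tests <- function(ad_tab, cfg) {
  fam <- function(pat) {
    cols <- grep(pat, names(ad_tab), value = TRUE)
    res <- lapply(cols, function(cn) {
      tryCatch(mmse_correlation(ad_tab[[cn]], ad_tab$mmse),
               error = function(e) list(r = NA_real_, p = NA_real_))
    })
    p <- vapply(res, `[[`, numeric(1), "p")
    data.frame(name = cols, r = vapply(res, `[[`, numeric(1), "r"), p = p,
               significant = bh_fdr(p, q = cfg$q, family_size = length(cols)))
  }
  list(emergence = fam("^emergence"), occurrence = fam("^occurrence_"),
       transitions = fam("^trans_"))
}

#' Run the full analysis from a cohort manifest
#'
#' Reads every recording named in the manifest, runs [analyze_cohort()],
#' and (optionally) writes all result tables plus a run manifest with
#' seeds, parameters and package version sufficient to reproduce the run
#' bit-identically.
#'
#' @param manifest Path to a cohort manifest (see [read_cohort()]).
#' @param config Path to a YAML config, or `NULL` for defaults.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param rate Sampling rate for csv/npy recordings.
#' @param progress Emit stage messages (default TRUE).
#' @return The `if_analysis` bundle, invisibly when writing.
#' @export
run_full_analysis <- function(manifest, config = NULL, out_dir = NULL,
                              rate = 200, progress = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else
    if (is.list(config)) utils::modifyList(pipeline_config(), config) else
      pipeline_config()
  cohort <- read_cohort(manifest)
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    tryCatch(
      read_recording(cohort$path[i], rate = rate,
                     subject_id = cohort$subject_id[i],
                     group = cohort$group[i], mmse = cohort$mmse[i]),
      error = function(e) stop("stage io failed for subject '",
                               cohort$subject_id[i], "': ",
                               conditionMessage(e), call. = FALSE))
  })
  res <- analyze_cohort(recs, cfg, progress = progress)
  if (!is.null(out_dir)) {
    write_analysis(res, out_dir)
    return(invisible(res))
  }
  res
}

#' Write an analysis bundle to a directory
#'
#' @param res An `if_analysis` from [analyze_cohort()].
#' @param out_dir Output directory (created if needed).
#' @export
write_analysis <- function(res, out_dir) {
  stopifnot(inherits(res, "if_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(res$subject_table, file.path(out_dir, "subject_metrics.tsv"))
  model <- res$model
  jsonlite::write_json(
    list(centroids = model$centroids, labels = model$labels, k = model$k,
         seed = model$seed, inertia = model$inertia),
    file.path(out_dir, "state_model.json"), digits = NA, auto_unbox = TRUE)
  for (nm in names(res$tests)) {
    obj <- res$tests[[nm]]
    if (is.data.frame(obj)) {
      write_results(obj, file.path(out_dir, paste0("tests_", nm, ".tsv")))
    } else if (is.list(obj)) {
      for (g in names(obj)) {
        if (!is.null(obj[[g]])) {
          write_results(obj[[g]],
                        file.path(out_dir, paste0("tests_", nm, "_", g, ".tsv")))
        }
      }
    }
  }
  for (nm in names(res$mmse_tests)) {
    write_results(res$mmse_tests[[nm]],
                  file.path(out_dir, paste0("mmse_", nm, ".tsv")))
  }
  run_manifest <- list(
    package = "ifstate",
    version = as.character(utils::packageVersion("ifstate")),
    config = res$config,
    n_subjects = nrow(res$subject_table),
    state_labels = res$model$labels,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
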
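# Session-bundle disk format, invariant validation, and the pipeline
# orchestrator tying all analysis stages together.

#' Write a session bundle (and optional ground truth) to a directory
#'
#' Plain-text tabular format: `trials.csv`, `licks.csv`, `spikes.csv`
#' (area, unit_id, time_s), per-area `lfp_<area>.bin` (float32,
#' little-endian, channel-major) with `lfp_<area>.json` metadata, and
#' `meta.json`. Ground truth (synthetic sessions only) goes to
#' `ground_truth.json`.
#'
#' @param bundle a `session_bundle`
#' @param path output directory (created if missing)
#' @param truth optional `ground_truth`
#' @return `path`, invisibly
#' @export
write_session_bundle <- function(bundle, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time_s = bundle$licks),
                   file.path(path, "licks.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(names(bundle$spikes), function(a) {
    do.call(rbind, lapply(seq_along(bundle$spikes[[a]]), function(u) {
      t <- bundle$spikes[[a]][[u]]
      if (length(t) == 0L) return(NULL)
      data.frame(area = a, unit_id = u, time_s = t)
    }))
  }))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  for (a in names(bundle$lfp)) {
    lf <- bundle$lfp[[a]]
    con <- file(file.path(path, sprintf("lfp_%s.bin", tolower(a))), "wb")
    writeBin(as.numeric(t(lf$data)), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(list(fs_hz = lf$fs_hz, n_channels = nrow(lf$data),
                              uv_per_unit = 1),
                         file.path(path, sprintf("lfp_%s.json", tolower(a))),
                         auto_unbox = TRUE)
  }
  jsonlite::write_json(bundle$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$assemblies <- lapply(tr$assemblies, function(a)
      a[c("area", "members", "weights", "ripple_coupling", "bias")])
    jsonlite::write_json(tr, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' @param path directory written by [write_session_bundle()]
#' @return a `session_bundle`
#' @export
read_session_bundle <- function(path) {
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  licks <- utils::read.csv(file.path(path, "licks.csv"))$time_s
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  spikes <- lapply(meta$areas, function(a) {
    sa <- sp[sp$area == a, , drop = FALSE]
    n_u <- if (nrow(sa)) max(sa$unit_id) else 0L
    lapply(seq_len(n_u), function(u) sort(sa$time_s[sa$unit_id == u]))
  })
  names(spikes) <- meta$areas
  lfp <- NULL
  for (a in meta$areas) {
    jf <- file.path(path, sprintf("lfp_%s.json", tolower(a)))
    bf <- file.path(path, sprintf("lfp_%s.bin", tolower(a)))
    if (file.exists(jf) && file.exists(bf)) {
      info <- jsonlite::read_json(jf, simplifyVector = TRUE)
      con <- file(bf, "rb")
      raw <- readBin(con, numeric(), n = file.size(bf) / 4L, size = 4L,
                     endian = "little")
      close(con)
      lfp[[a]] <- list(data = matrix(raw, nrow = info$n_channels,
                                     byrow = TRUE) * info$uv_per_unit,
                       fs_hz = info$fs_hz)
    }
  }
  structure(list(spikes = spikes, lfp = lfp, trials = trials,
                 licks = licks, meta = meta), class = "session_bundle")
}

#' Validate session-bundle invariants
#'
#' Checks that spike, lick and event times lie within the session, that
#' LFP sample counts are consistent with the sampling rate and duration,
#' and that every CS+ trial is rewarded at onset + 3 s. Violations are
#' reported, not thrown.
#'
#' @param bundle a `session_bundle` or a path readable by
#'   [read_session_bundle()]
#' @return data.frame with columns `check`, `detail` (zero rows when the
#'   bundle is well formed)
#' @export
validate_bundle <- function(bundle) {
  if (is.character(bundle)) bundle <- read_session_bundle(bundle)
  v <- list()
  bad <- function(check, detail)
    v[[length(v) + 1L]] <<- data.frame(check = check, detail = detail)
  dur <- bundle$meta$duration_s
  for (a in names(bundle$spikes)) {
    rng <- range(unlist(bundle$spikes[[a]]), na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > dur))
      bad("spike_times", sprintf("%s spikes outside [0, %.1f]", a, dur))
  }
  if (length(bundle$licks) && (min(bundle$licks) < 0 || max(bundle$licks) > dur))
    bad("lick_times", "licks outside session bounds")
  if (nrow(bundle$trials)) {
    if (min(bundle$trials$onset_s) < 0 || max(bundle$trials$onset_s) > dur)
      bad("trial_onsets", "trial onsets outside session bounds")
    if (is.unsorted(bundle$trials$onset_s))
      bad("trial_onsets", "trial onsets not increasing")
    plus <- bundle$trials$cs_type == "plus"
    rw <- bundle$trials$reward_time_s[plus]
    if (any(is.na(rw)) || any(abs(rw - bundle$trials$onset_s[plus] - 3) > 1e-6))
      bad("reward_times", "CS+ trials must be rewarded at onset + 3 s")
  }
  for (a in names(bundle$lfp)) {
    lf <- bundle$lfp[[a]]
    expect <- round(dur * lf$fs_hz)
    if (abs(ncol(lf$data) - expect) > lf$fs_hz * 0.01)
      bad("lfp_length", sprintf("%s LFP has %d samples, expected ~%d",
                                a, ncol(lf$data), expect))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(check = character(0), detail = character(0))
}

#' Run the analysis pipeline on one session
#'
#' Executes the requested stages in dependency order (behavior -> cells ->
#' population / rrr / ripples -> coherence / assemblies) and returns a run
#' report with per-stage outputs. Fails fast with a stage-attributed error
#' when a stage's dependency was not requested or its required data is
#' missing. With `out_dir`, per-stage tables are written as CSV/JSON.
#'
#' @param bundle a `session_bundle` or bundle directory path
#' @param stages character vector of stages to run (default: all
#'   applicable)
#' @param out_dir optional output directory
#' @param seed RNG seed governing all stochastic steps (subsampling,
#'   cross-validation folds, ICA restarts, permutations)
#' @param folds decoding CV folds
#' @param rrr_subsamples RRR subsample replicates
#' @param coherence_perm permutations for the coherence test (0 skips)
#' @return object of class `run_report`: list with `results`, `stages`,
#'   `params`, `warnings`
#' @export
run_pipeline <- function(bundle,
                         stages = c("behavior", "cells", "population",
                                    "rrr", "ripples", "coherence",
                                    "assemblies"),
                         out_dir = NULL, seed = 1L, folds = 20L,
                         rrr_subsamples = 10L, coherence_perm = 0L) {
  if (is.character(bundle)) bundle <- read_session_bundle(bundle)
  order_all <- c("behavior", "cells", "population", "rrr", "ripples",
                 "coherence", "assemblies")
  stages <- intersect(order_all, stages)
  deps <- list(cells = "behavior", population = "cells",
               coherence = "ripples", assemblies = "ripples")
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage '", miss[1], "'")
  }
  set.seed(seed)
  res <- list()
  warns <- character(0)
  has_lfp <- !is.null(bundle$lfp) && length(bundle$lfp) > 0L
  dur <- bundle$meta$duration_s

  if ("behavior" %in% stages) {
    res$behavior <- classify_bundle_learning(bundle)
    res$first_licks <- first_anticipatory_lick(bundle)
  }
  if ("cells" %in% stages)
    res$cells <- classify_response_windows(bundle, res$first_licks)
  if ("population" %in% stages) {
    res$population <- lapply(names(bundle$spikes), function(a) {
      pv <- population_vectors(bundle, res$cells, area = a)
      dist <- distance_trace(pv$plus, pv$minus, pv$time)
      dec <- decode_trial_identity(bundle, res$cells, area = a,
                                   folds = folds)
      list(area = a, vectors = pv, distance = dist, decoding = dec,
           pca = pca_trajectory(pv))
    })
    names(res$population) <- names(bundle$spikes)
  }
  if ("rrr" %in% stages) {
    if (length(bundle$spikes) < 2L) {
      warns <- c(warns, "rrr: single-area bundle, within-area only")
    }
    res$rrr <- crossarea_analysis(bundle, n_subsamples = rrr_subsamples)
  }
  if ("ripples" %in% stages) {
    if (!has_lfp || is.null(bundle$lfp$CA1))
      stop("stage 'ripples' requires CA1 LFP in the bundle")
    rb <- ripple_band_channel(bundle$lfp$CA1$data, bundle$lfp$CA1$fs_hz)
    ev <- detect_ripples(rb$trace, bundle$lfp$CA1$fs_hz, bundle$licks,
                         bundle$trials)
    res$ripples <- list(events = ev, channel = rb$channel,
                        rates = ripple_rate_dynamics(ev, bundle$trials, dur))
    res$ripple_filtered_channel <- rb$trace
  }
  if ("coherence" %in% stages) {
    if (is.null(bundle$lfp$PFC))
      stop("stage 'coherence' requires PFC LFP in the bundle")
    x <- bundle$lfp$CA1$data[res$ripples$channel, ]
    y <- bundle$lfp$PFC$data[1L, ]
    fs <- bundle$lfp$CA1$fs_hz
    seg_tr <- period_segments(bundle$trials, "trace")
    seg_bl <- period_segments(bundle$trials, "baseline")
    res$coherence <- list(
      trace = multitaper_coherence(x, y, fs, seg_tr),
      baseline = multitaper_coherence(x, y, fs, seg_bl))
    if (coherence_perm > 0L)
      res$coherence$test <- per_frequency_permutation_test(
        x, y, fs, seg_tr, seg_bl, n_perm = coherence_perm)
  }
  if ("assemblies" %in% stages) {
    res$assemblies <- list()
    for (a in names(bundle$spikes)) {
      model <- detect_assemblies(bundle$spikes[[a]], bundle$trials)
      entry <- list(area = a, model = model)
      if (model$n_assemblies > 0L) {
        act <- assembly_activation(model, bundle$spikes[[a]], 0, dur)
        entry$reactivation <- swr_triggered_reactivation(
          act, res$ripples$events, bundle$trials)
        entry$stimulus <- stimulus_triggered_activation(act, bundle$trials)
        entry$modulation <- modulation_scores(entry$stimulus)
      }
      res$assemblies[[a]] <- entry
    }
    pr_ca1 <- res$assemblies$CA1$reactivation$per_ripple
    pr_pfc <- res$assemblies$PFC$reactivation$per_ripple
    if (!is.null(pr_ca1) && !is.null(pr_pfc) && nrow(pr_ca1) >= 10L &&
        ncol(pr_ca1) > 0L && ncol(pr_pfc) > 0L)
      res$quadrant <- quadrant_coactivation(pr_ca1, pr_pfc)
  }

  report <- structure(list(results = res, stages = stages,
                           params = list(seed = seed, folds = folds,
                                         rrr_subsamples = rrr_subsamples,
                                         coherence_perm = coherence_perm),
                           warnings = warns),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# Persist the main tabular outputs of a pipeline run.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  if (!is.null(res$behavior))
    jsonlite::write_json(res$behavior[c("learned", "p_value", "mean_plus",
                                        "mean_minus")],
                         file.path(out_dir, "lick_analysis.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$cells))
    utils::write.csv(res$cells, file.path(out_dir, "cell_classification.csv"),
                     row.names = FALSE)
  if (!is.null(res$population)) {
    dec <- lapply(res$population, function(p)
      list(area = p$area, accuracy = p$decoding$accuracy,
           n_units = p$decoding$n_units))
    jsonlite::write_json(unname(dec), file.path(out_dir, "decoding.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$rrr))
    utils::write.csv(res$rrr, file.path(out_dir, "rrr_results.csv"),
                     row.names = FALSE)
  if (!is.null(res$ripples))
    utils::write.csv(as.data.frame(res$ripples$events),
                     file.path(out_dir, "ripples.csv"), row.names = FALSE)
  if (!is.null(res$coherence)) {
    co <- data.frame(freq = res$coherence$trace$freq,
                     coherence_trace = res$coherence$trace$coherence,
                     coherence_baseline = res$coherence$baseline$coherence)
    utils::write.csv(co, file.path(out_dir, "coherence.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$assemblies)) {
    pats <- do.call(rbind, lapply(res$assemblies, function(e) {
      if (e$model$n_assemblies == 0L) return(NULL)
      do.call(rbind, lapply(seq_len(e$model$n_assemblies), function(j)
        data.frame(area = e$area, assembly_id = j,
                   unit_id = seq_len(nrow(e$model$patterns)),
                   weight = e$model$patterns[, j])))
    }))
    if (!is.null(pats))
      utils::write.csv(pats, file.path(out_dir, "patterns.csv"),
                       row.names = FALSE)
  }
  jsonlite::write_json(report$params, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(x$stages, collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
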
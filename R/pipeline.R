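#' Pipeline configuration
#'
#' Collects every constant of the end-to-end synthetic run: the simulation
#' settings (a [sim_config()]), the lab constants (chamber volume 0.54 l,
#' oxygen solubility 0.4755 mg O2 l^-1 kPa^-1), the QC and filtering
#' thresholds (per-cycle r-squared 0.90, SMR percentile 10, buffer radius
#' 0.5 m, burst interval 30 s, activity-probability threshold 0.75, 7-day
#' exclusion and 12-day analysis window) and the cohort-exclusion counts.
#' Round-trips unchanged through YAML serialization.
#'
#' @param seed master seed, propagated to every stage.
#' @param sim named list of overrides for [sim_config()].
#' @param n_predated,n_failed fish excluded as predated / as transmitter
#'   failures before analysis.
#' @param r2_threshold,smr_percentile,mmr_mode respirometry settings.
#' @param buffer_radius,p_threshold,exclude_days,window_days,day_anchor
#'   trajectory settings.
#' @param hmm_restarts,hmm_fix_noise HMM settings; when `hmm_fix_noise` is
#'   `TRUE` the positional-noise SD is held at the simulation's known value.
#' @param lmm_starts optimizer starts per mixed-model fit.
#' @param measures activity measures to model.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = list(),
                            n_predated = 3L, n_failed = 4L,
                            r2_threshold = 0.90, smr_percentile = 10,
                            mmr_mode = "first3",
                            buffer_radius = 0.5, p_threshold = 0.75,
                            exclude_days = 7, window_days = 12,
                            day_anchor = "midnight",
                            hmm_restarts = 3L, hmm_fix_noise = FALSE,
                            lmm_starts = 2L,
                            measures = c("a_day", "u_max", "u_inst",
                                         "ar_day")) {
  sim_args <- utils::modifyList(list(seed = as.integer(seed)), sim)
  cfg <- list(
    seed = as.integer(seed),
    sim = sim_args,
    n_predated = as.integer(n_predated), n_failed = as.integer(n_failed),
    r2_threshold = r2_threshold, smr_percentile = smr_percentile,
    mmr_mode = mmr_mode,
    buffer_radius = buffer_radius, p_threshold = p_threshold,
    exclude_days = exclude_days, window_days = window_days,
    day_anchor = day_anchor,
    hmm_restarts = as.integer(hmm_restarts), hmm_fix_noise = hmm_fix_noise,
    lmm_starts = as.integer(lmm_starts),
    measures = measures
  )
  stopifnot(r2_threshold >= 0, r2_threshold <= 1,
            smr_percentile > 0, smr_percentile <= 100,
            buffer_radius > 0, p_threshold >= 0, p_threshold <= 1,
            exclude_days >= 0, window_days > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$sim$lake_boundary)) {
    x$sim$lake_boundary <- lapply(seq_len(nrow(x$sim$lake_boundary)),
                                  function(i) as.numeric(x$sim$lake_boundary[i, ]))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$sim$lake_boundary)) {
    x$sim$lake_boundary <- do.call(rbind, x$sim$lake_boundary)
  }
  do.call(pipeline_config, x)
}

#' Run the full synthetic lab-to-field pipeline
#'
#' Executes the stages in dependency order: simulate a cohort with known
#' phenotypes; mark the configured numbers of predated and
#' transmitter-failure fish (cohort accounting mirrors the field study:
#' tagged - predated - failures = analysed); simulate and analyse a
#' respirometry trace per fish (slopes, uptake, the ten metabolic traits);
#' compute fineness ratio, mass-corrected residuals and the PCA scores;
#' simulate telemetry tracks for the analysed fish, fit the two-state
#' activity HMM per fish and derive the four activity metrics; and fit the
#' heteroscedastic random-intercept model-selection grid for each activity
#' measure. All tabular outputs are written as CSV under `out_dir` together
#' with a machine-readable run manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param stages character subset of
#'   `c("respirometry", "phenotype", "telemetry", "lmm")` to run after the
#'   cohort stage (defaults to all; later stages require earlier ones).
#' @return list of class `pipeline_result`: `cohort`, `accounting`,
#'   `traits`, `phenotypes` (corrected), `activity` (per fish-day),
#'   `u_inst` (per observation), `hmm` (per-fish fit summaries),
#'   `selection` (per measure), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("respirometry", "phenotype",
                                    "telemetry", "lmm")) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- do.call(sim_config, config$sim)
  res <- list()

  cohort <- generate_cohort(sim)
  n <- nrow(cohort)
  if (config$n_predated + config$n_failed >= n) {
    stop("exclusions leave no fish to analyse", call. = FALSE)
  }
  excl <- with_seed(sub_seed(config$seed, 900L), {
    sample(n, config$n_predated + config$n_failed)
  })
  cohort$fate <- "analysed"
  cohort$fate[excl[seq_len(config$n_predated)]] <- "predated"
  cohort$fate[excl[config$n_predated + seq_len(config$n_failed)]] <- "transmitter_failure"
  accounting <- data.frame(
    stage = c("tagged", "predated", "transmitter_failure", "analysed"),
    n = c(n, config$n_predated, config$n_failed,
          sum(cohort$fate == "analysed"))
  )
  res$cohort <- cohort
  res$accounting <- accounting

  if ("respirometry" %in% stages) {
    traits <- do.call(rbind, lapply(seq_len(n), function(i) {
      tr <- simulate_respirometry_trace(cohort[i, ], sim)
      trace_traits(tr, r2_threshold = config$r2_threshold,
                   smr_percentile = config$smr_percentile,
                   mmr_mode = config$mmr_mode)
    }))
    res$traits <- traits
  }

  analysed <- cohort[cohort$fate == "analysed", , drop = FALSE]

  if ("phenotype" %in% stages) {
    res$phenotypes <- correct_traits(
      res$traits[res$traits$fish_id %in% analysed$fish_id, , drop = FALSE],
      analysed
    )
  }

  if ("telemetry" %in% stages) {
    act <- list(); ui <- list(); hmm_rows <- list()
    for (i in seq_len(nrow(analysed))) {
      fx <- simulate_track(analysed[i, ], sim)
      st <- track_steps(fx, sim$burst_interval)
      fit <- fit_activity_hmm(
        st$steps, st$seg_start,
        n_restarts = config$hmm_restarts,
        seed = sub_seed(config$seed, 7000L + i),
        sigma_noise_fixed = if (config$hmm_fix_noise) sim$position_noise_sd else NULL
      )
      pa <- p_active_per_fix(nrow(fx), fit, st)
      am <- activity_metrics(
        fx, pa, release_time = sim$release_time,
        burst_interval = sim$burst_interval,
        buffer_radius = config$buffer_radius,
        p_threshold = config$p_threshold,
        exclude_days = config$exclude_days,
        window_days = config$window_days,
        day_anchor = config$day_anchor
      )
      act[[i]] <- am$daily
      ui[[i]] <- am$u_inst
      hmm_rows[[i]] <- data.frame(
        fish_id = analysed$fish_id[i], loglik = fit$loglik,
        converged = fit$converged, n_iter = fit$n_iter,
        sigma_noise = fit$spec$sigma_noise,
        mean_active_step = fit$spec$gamma_shape * fit$spec$gamma_scale,
        p_become_active = fit$spec$trans[1, 2],
        p_become_inactive = fit$spec$trans[2, 1],
        frac_active = mean(classify_active(fit$p_active,
                                           config$p_threshold)),
        stringsAsFactors = FALSE
      )
    }
    res$activity <- do.call(rbind, act)
    res$u_inst <- do.call(rbind, ui)
    res$hmm <- do.call(rbind, hmm_rows)
  }

  if ("lmm" %in% stages) {
    covars <- data.frame(
      fish_id = res$phenotypes$fish_id,
      FL = res$phenotypes$fork_length,
      FR = res$phenotypes$fineness_ratio,
      SMR = res$phenotypes$smr_resid,
      MMR = res$phenotypes$mmr_resid,
      AMS = res$phenotypes$ams_resid,
      MET1 = res$phenotypes$MET1,
      MET2 = res$phenotypes$MET2,
      MET3 = res$phenotypes$MET3,
      stringsAsFactors = FALSE
    )
    res$selection <- lapply(setNames(config$measures, config$measures),
                            function(m) {
      obs <- if (m == "u_inst") {
        data.frame(fish_id = res$u_inst$fish_id, y0 = res$u_inst$u_inst)
      } else {
        data.frame(fish_id = res$activity$fish_id, y0 = res$activity[[m]])
      }
      obs <- obs[is.finite(obs$y0), , drop = FALSE]
      d <- merge(obs, covars, by = "fish_id")
      d$y <- transform_response(d$y0, m)
      d$fish <- d$fish_id
      tryCatch(
        model_select(d, n_starts = config$lmm_starts,
                     seed = sub_seed(config$seed, 31L)),
        error = function(e) {
          warning(sprintf("model selection failed for %s: %s", m,
                          conditionMessage(e)))
          NULL
        }
      )
    })
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("fieldscope")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = object_hash(unclass(config)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  class(res) <- "pipeline_result"

  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) if (!is.null(d)) write.csv(d, file.path(out_dir, f),
                                                 row.names = FALSE)
  w(res$cohort, "cohort.csv")
  w(res$accounting, "cohort_accounting.csv")
  w(res$traits, "metabolic_traits.csv")
  if (!is.null(res$phenotypes)) {
    w(res$phenotypes, "phenotypes_corrected.csv")
    pca <- attr(res$phenotypes, "pca")
    if (!is.null(pca)) {
      ld <- as.data.frame(pca$loadings[, 1:3, drop = FALSE])
      ld$trait <- rownames(pca$loadings)
      w(ld[c("trait", "MET1", "MET2", "MET3")], "pca_loadings.csv")
    }
  }
  w(res$activity, "activity_daily.csv")
  w(res$u_inst, "u_inst.csv")
  w(res$hmm, "hmm_fits.csv")
  if (!is.null(res$selection)) {
    sel <- do.call(rbind, lapply(names(res$selection), function(m) {
      s <- res$selection[[m]]
      if (is.null(s)) return(NULL)
      cbind(measure = m, s$table)
    }))
    w(sel, "model_selection.csv")
    summ <- do.call(rbind, lapply(names(res$selection), function(m) {
      s <- res$selection[[m]]
      if (is.null(s) || is.null(s$best_fit)) return(NULL)
      f <- s$best_fit
      data.frame(measure = m, best_model = s$best,
                 sigma_a = f$sigma_a,
                 sigma_j_median = median(f$sigma_j),
                 sigma_j_min = min(f$sigma_j), sigma_j_max = max(f$sigma_j),
                 icc_median = s$icc$median, icc_min = s$icc$min,
                 icc_max = s$icc$max, stringsAsFactors = FALSE)
    }))
    w(summ, "model_summaries.csv")
  }
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  writeLines(yaml::as.yaml(res$manifest), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$accounting)
  if (!is.null(x$traits)) {
    cat(sprintf("traits: %d fish; mean SMR %.1f, MMR %.1f, AMS %.1f mg O2/kg/h\n",
                nrow(x$traits), mean(x$traits$smr),
                mean(x$traits$mmr, na.rm = TRUE),
                mean(x$traits$ams, na.rm = TRUE)))
  }
  if (!is.null(x$activity)) {
    cat(sprintf("activity: %d fish-days\n", nrow(x$activity)))
  }
  if (!is.null(x$selection)) {
    for (m in names(x$selection)) {
      s <- x$selection[[m]]
      if (!is.null(s)) cat(sprintf("  %s: best %s (median ICC %.3f)\n",
                                   m, s$best, s$icc$median))
    }
  }
  invisible(x)
}
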
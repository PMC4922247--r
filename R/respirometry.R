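#' Construct a respirometry trace object
#'
#' Container for one fish's intermittent-flow respirometry recording: a
#' time-stamped oxygen partial-pressure series with flush/measure phase
#' structure plus the physical constants needed to convert O2 decline slopes
#' into mass-specific oxygen uptake.
#'
#' @param fish_id fish identifier.
#' @param samples `data.frame` with columns `time_h` (hours since the chase
#'   protocol ended, strictly increasing), `o2_kpa`, and optionally `phase`
#'   (`"flush"`/`"measure"`). Traces without phase labels are segmented by
#'   flush detection in [segment_cycles()].
#' @param chamber_volume respirometer volume in litres.
#' @param body_mass fish body mass in kilograms.
#' @param beta oxygen solubility in mg O2 l^-1 kPa^-1 (default 0.4755).
#' @param blank_slope background (microbial) respiration slope in kPa h^-1,
#'   subtracted from every measured decline before conversion.
#' @return an object of class `respirometry_trace`.
#' @export
respirometry_trace <- function(fish_id, samples, chamber_volume, body_mass,
                               beta = 0.4755, blank_slope = 0) {
  stopifnot(is.data.frame(samples), all(c("time_h", "o2_kpa") %in% names(samples)))
  if (is.unsorted(samples$time_h, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (chamber_volume - body_mass <= 0) {
    stop("chamber_volume must exceed the volume displaced by the fish",
         call. = FALSE)
  }
  structure(
    list(fish_id = fish_id, samples = samples,
         chamber_volume = chamber_volume, body_mass = body_mass,
         beta = beta, blank_slope = blank_slope),
    class = "respirometry_trace"
  )
}

#' @export
print.respirometry_trace <- function(x, ...) {
  cat(sprintf("<respirometry_trace> fish %s: %d samples over %.1f h, V = %.3g l, M = %.3g kg\n",
              x$fish_id, nrow(x$samples), diff(range(x$samples$time_h)),
              x$chamber_volume, x$body_mass))
  invisible(x)
}

#' Read a respirometry trace from CSV
#'
#' Accepts both dialects: with a `phase` column, or raw `time_s`/`o2_kpa`
#' only (phases then detected from the signal in [segment_cycles()]).
#' Time may be given as `time_s` (seconds) or `time_h` (hours).
#'
#' @param path CSV file path.
#' @param fish_id identifier to attach.
#' @param chamber_volume,body_mass,beta,blank_slope physical constants, as in
#'   [respirometry_trace()]; `body_mass` in kg.
#' @return a `respirometry_trace`.
#' @export
read_trace_csv <- function(path, fish_id, chamber_volume, body_mass,
                           beta = 0.4755, blank_slope = 0) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(d)) {
    if (!"time_s" %in% names(d)) stop("need a time_s or time_h column", call. = FALSE)
    d$time_h <- d$time_s / 3600
  }
  keep <- c("time_h", "o2_kpa", if ("phase" %in% names(d)) "phase")
  respirometry_trace(fish_id, d[keep], chamber_volume, body_mass, beta, blank_slope)
}

#' Segment a trace into measurement cycles and fit per-cycle slopes
#'
#' Splits the trace into closed-chamber measure phases (from the `phase`
#' labels when present, otherwise by detecting flush periods as sustained O2
#' rises), clips a leading transient from each phase, and fits an ordinary
#' least-squares line of O2 on time within each phase. The decline rate is
#' returned positive-valued.
#'
#' @param trace a [respirometry_trace()].
#' @param clip_s seconds discarded at the start of every measure phase to
#'   skip mixing transients (default 30).
#' @param detect_window width (samples) of the moving-average slope filter
#'   used for flush detection in the unlabelled dialect.
#' @return a `data.frame` of cycles: `start`, `end`, `t_mid` (hours),
#'   `slope_k` (kPa h^-1, decline positive), `r_squared`, `n`.
#' @export
segment_cycles <- function(trace, clip_s = 30, detect_window = 5) {
  stopifnot(inherits(trace, "respirometry_trace"))
  s <- trace$samples
  if (!"phase" %in% names(s)) s$phase <- detect_phases(s, detect_window)
  if (!any(s$phase == "measure")) stop("trace contains no measure phase", call. = FALSE)
  runs <- rle(s$phase)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- list()
  for (k in which(runs$values == "measure")) {
    idx <- starts[k]:ends[k]
    tt <- s$time_h[idx]; oo <- s$o2_kpa[idx]
    keep <- tt >= tt[1] + clip_s / 3600 - 1e-12
    tt <- tt[keep]; oo <- oo[keep]
    if (length(tt) < 3) {
      warning("measure phase with fewer than 3 samples after clipping; skipped")
      next
    }
    fit <- stats::lm.fit(cbind(1, tt), oo)
    slope <- -fit$coefficients[2]
    sst <- sum((oo - mean(oo))^2)
    sse <- sum(fit$residuals^2)
    r2 <- if (sst <= .Machine$double.eps * length(oo)) 0 else max(0, 1 - sse / sst)
    out[[length(out) + 1L]] <- data.frame(
      start = tt[1], end = tt[length(tt)], t_mid = mean(range(tt)),
      slope_k = unname(slope), r_squared = r2, n = length(tt)
    )
  }
  if (!length(out)) stop("no usable measurement cycles in trace", call. = FALSE)
  cycles <- do.call(rbind, out)
  rownames(cycles) <- NULL
  cycles
}

# Label flush phases as sustained O2 rises (moving-average of first
# differences > 0), everything else as measure.
detect_phases <- function(s, window = 5) {
  d <- c(0, diff(s$o2_kpa))
  ma <- as.numeric(stats::filter(d, rep(1 / window, window), sides = 2))
  ma[is.na(ma)] <- 0
  ifelse(ma > 0, "flush", "measure")
}

#' Convert a decline slope to mass-specific oxygen uptake
#'
#' Applies MO2 = K V beta / M, where K is the background-corrected linear
#' decline rate (kPa h^-1), V the respirometer volume corrected for the
#' volume of the fish (litres, assuming fish density 1 g ml^-1), beta the
#' oxygen solubility and M the body mass (kg). A blank slope exceeding the
#' measured slope clamps the corrected rate at zero with a warning.
#'
#' @param slope_k per-cycle decline rate(s), kPa h^-1 (positive = decline).
#' @param trace a [respirometry_trace()] carrying V, M, beta and the blank.
#' @return oxygen uptake in mg O2 kg^-1 h^-1 (vectorized over `slope_k`).
#' @export
compute_mo2 <- function(slope_k, trace) {
  stopifnot(inherits(trace, "respirometry_trace"))
  v_eff <- trace$chamber_volume - trace$body_mass  # kg -> litres at density 1
  if (v_eff <= 0) stop("effective volume is non-positive", call. = FALSE)
  k_corr <- slope_k - trace$blank_slope
  if (any(k_corr < 0)) {
    warning("background slope exceeds measured slope; clamping at zero uptake")
    k_corr <- pmax(k_corr, 0)
  }
  k_corr * v_eff * trace$beta / trace$body_mass
}

#' Extract the ten metabolic traits from measurement cycles
#'
#' Applies the trait definitions of the lab protocol to a per-cycle oxygen
#' uptake series spanning ~22 h after an exhaustive chase:
#' standard metabolic rate (SMR) is the mean of the cycles at or below the
#' 10th percentile of all retained uptake values; maximal metabolic rate
#' (MMR) is the highest of the first three post-chase measurements (or the
#' highest three-cycle rolling mean with `mmr_mode = "sliding3"`); aerobic
#' scope is their difference; recovery rate is the OLS slope of uptake on
#' time over the first five measurements; mean and SD of uptake are taken
#' over the final 19 h; routine uptake and the spontaneous minimum, maximum
#' and spontaneous scope over the final 4 h. Cycles failing the r-squared
#' filter are dropped, not re-fit.
#'
#' @param cycles `data.frame` from [segment_cycles()] with an `mo2` column
#'   (see [compute_mo2()]); columns used: `t_mid`, `end`, `r_squared`, `mo2`.
#' @param r2_threshold minimum per-cycle coefficient of determination
#'   (default 0.90).
#' @param smr_percentile percentile (0-100) defining the SMR set (default 10).
#' @param mmr_mode `"first3"` (default) or `"sliding3"`.
#' @param avg_window,routine_window trailing window lengths in hours
#'   (defaults 19 and 4), anchored at the last cycle.
#' @param mmr_within_h MMR requires >= 3 retained cycles starting within this
#'   many hours of the chase (default 1); otherwise MMR is returned missing.
#' @return one-row `data.frame` of class `metabolic_traits`: `smr`, `mmr`,
#'   `ams`, `recovery_rate`, `avg_mo2`, `metabolic_variability`,
#'   `routine_mo2`, `spont_min`, `spont_max`, `spont_ams`, plus QC columns
#'   `n_cycles`, `n_rejected`.
#' @export
extract_traits <- function(cycles, r2_threshold = 0.90, smr_percentile = 10,
                           mmr_mode = c("first3", "sliding3"),
                           avg_window = 19, routine_window = 4,
                           mmr_within_h = 1) {
  mmr_mode <- match.arg(mmr_mode)
  stopifnot(is.data.frame(cycles), "mo2" %in% names(cycles))
  cycles <- cycles[order(cycles$t_mid), , drop = FALSE]
  keep <- cycles$r_squared >= r2_threshold
  n_rejected <- sum(!keep)
  cc <- cycles[keep, , drop = FALSE]
  if (nrow(cc) == 0L) stop("no cycles pass the r-squared filter", call. = FALSE)
  mo2 <- cc$mo2
  tt <- cc$t_mid
  t_end <- max(cc$end)

  thr <- quantile(mo2, smr_percentile / 100, names = FALSE, type = 7)
  smr <- mean(mo2[mo2 <= thr])

  mmr <- if (mmr_mode == "first3") {
    if (nrow(cc) >= 3 && tt[3] <= min(tt) + mmr_within_h) max(mo2[1:3]) else NA_real_
  } else {
    if (nrow(cc) >= 3) {
      roll <- vapply(seq_len(nrow(cc) - 2), function(i) mean(mo2[i:(i + 2)]), 0)
      max(roll)
    } else NA_real_
  }
  ams <- mmr - smr

  recovery <- if (nrow(cc) >= 5) {
    unname(coef(lm(mo2[1:5] ~ tt[1:5]))[2])
  } else NA_real_

  in_avg <- tt >= t_end - avg_window
  avg_mo2 <- mean(mo2[in_avg])
  variability <- sd(mo2[in_avg])

  in_rt <- tt >= t_end - routine_window
  routine <- mean(mo2[in_rt])
  sp_min <- min(mo2[in_rt])
  sp_max <- max(mo2[in_rt])

  out <- data.frame(
    smr = smr, mmr = mmr, ams = ams,
    recovery_rate = recovery,
    avg_mo2 = avg_mo2, metabolic_variability = variability,
    routine_mo2 = routine, spont_min = sp_min, spont_max = sp_max,
    spont_ams = sp_max - sp_min,
    n_cycles = nrow(cc), n_rejected = n_rejected
  )
  class(out) <- c("metabolic_traits", "data.frame")
  out
}

#' Aerobic metabolic scope
#'
#' The difference between maximal and standard metabolic rate.
#'
#' @param mmr,smr metabolic rates in mg O2 kg^-1 h^-1.
#' @return `mmr - smr`.
#' @export
aerobic_scope <- function(mmr, smr) {
  if (any(mmr < smr, na.rm = TRUE)) {
    warning("mmr < smr: negative aerobic scope")
  }
  mmr - smr
}

#' Full trace-to-traits extraction for one fish
#'
#' Convenience wrapper: [segment_cycles()] then [compute_mo2()] then
#' [extract_traits()].
#'
#' @param trace a [respirometry_trace()].
#' @param ... passed on to [segment_cycles()] and [extract_traits()]
#'   (matched by name).
#' @return the `metabolic_traits` row, with the per-cycle table attached as
#'   attribute `"cycles"`.
#' @export
trace_traits <- function(trace, ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% c("clip_s", "detect_window")]
  ext_args <- dots[names(dots) %in% c("r2_threshold", "smr_percentile",
                                      "mmr_mode", "avg_window",
                                      "routine_window", "mmr_within_h")]
  cycles <- do.call(segment_cycles, c(list(trace), seg_args))
  cycles$mo2 <- compute_mo2(cycles$slope_k, trace)
  traits <- do.call(extract_traits, c(list(cycles), ext_args))
  traits$fish_id <- trace$fish_id
  attr(traits, "cycles") <- cycles
  traits
}
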
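# Biolayer interferometry: 1:1 Langmuir forward model, global fitting
# grouped by sensor, and binding classification.

#' Default BLI phase schedule
#'
#' Baseline 60 s, association 30 s, dissociation 100 s — the step lengths
#' of a standard Octet kinetics cycle for fast-dissociating interactions.
#'
#' @param baseline,association,dissociation Phase durations in seconds.
#' @param hz Sampling rate in points per second (default 5).
#' @return List with phase windows (`c(start, end)` in seconds) and `hz`.
#' @export
bli_schedule <- function(baseline = 60, association = 30,
                         dissociation = 100, hz = 5) {
  t0 <- 0
  list(baseline = c(t0, t0 + baseline),
       association = c(t0 + baseline, t0 + baseline + association),
       dissociation = c(t0 + baseline + association,
                        t0 + baseline + association + dissociation),
       hz = hz)
}

# Noise-free 1:1 signal at times `t` for one analyte concentration.
# Association: R(t) = Req (1 - exp(-(kon C + koff) t')), Req = Rmax C/(C+KD);
# dissociation: first-order decay from the association end point.
bli_signal <- function(t, conc, kon, koff, Rmax, schedule) {
  KD <- koff / kon
  Req <- Rmax * conc / (conc + KD)
  kobs <- kon * conc + koff
  a0 <- schedule$association[1]; a1 <- schedule$association[2]
  r_end <- Req * (1 - exp(-kobs * (a1 - a0)))
  out <- numeric(length(t))
  assoc <- t >= a0 & t < a1
  diss <- t >= a1
  out[assoc] <- Req * (1 - exp(-kobs * (t[assoc] - a0)))
  out[diss] <- r_end * exp(-koff * (t[diss] - a1))
  out
}

#' Simulate 1:1 binding sensorgrams
#'
#' Forward model of the 1:1 Langmuir scheme used for global fitting:
#' association `R(t) = Req (1 - exp(-(kon C + koff) t))` with
#' `Req = Rmax C / (C + KD)`, `KD = koff / kon`; first-order dissociation.
#' Gaussian noise of standard deviation `noise_sd` is added to every point.
#'
#' @param kon Association rate constant (1/M/s).
#' @param koff Dissociation rate constant (1/s).
#' @param Rmax Maximal response (nm), shared across the sensor.
#' @param concentrations Analyte concentrations in M (non-empty, positive).
#' @param schedule Phase schedule from [bli_schedule()].
#' @param noise_sd Gaussian noise SD in nm.
#' @param seed Integer seed.
#' @param sensor_id Sensor label.
#' @return A `SensorgramSet`: list of data.frames (`time_s`, `signal_nm`,
#'   `phase`, `conc_M`, `sensor_id`) plus the generating parameters.
#' @export
simulate_sensorgrams <- function(kon, koff, Rmax, concentrations,
                                 schedule = bli_schedule(), noise_sd = 0,
                                 seed = 1L, sensor_id = "S1") {
  stopifnot(kon > 0, koff > 0, Rmax > 0, noise_sd >= 0)
  if (length(concentrations) == 0) stop("empty concentration list")
  stopifnot(all(concentrations > 0))
  local_rng(seed)
  t <- seq(schedule$baseline[1], schedule$dissociation[2],
           by = 1 / schedule$hz)
  phase <- ifelse(t < schedule$association[1], "baseline",
                  ifelse(t < schedule$dissociation[1], "association",
                         "dissociation"))
  traces <- lapply(concentrations, function(conc) {
    sig <- bli_signal(t, conc, kon, koff, Rmax, schedule) +
      stats::rnorm(length(t), 0, noise_sd)
    data.frame(time_s = t, signal_nm = sig, phase = phase,
               conc_M = conc, sensor_id = sensor_id,
               stringsAsFactors = FALSE)
  })
  structure(list(traces = traces, schedule = schedule, noise_sd = noise_sd,
                 sensor_id = sensor_id,
                 truth = c(kon = kon, koff = koff, KD = koff / kon,
                           Rmax = Rmax)),
            class = "SensorgramSet")
}

#' @export
print.SensorgramSet <- function(x, ...) {
  cat("SensorgramSet:", length(x$traces), "trace(s), sensor", x$sensor_id,
      "; concentrations (M):",
      paste(signif(vapply(x$traces, function(d) d$conc_M[1], numeric(1)), 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write sensorgrams as CSV
#'
#' Columns `time_s`, `signal_nm`, `phase`, `conc_M`, `sensor_id`.
#'
#' @param sensorgrams A `SensorgramSet`.
#' @param path Output CSV.
#' @return The path, invisibly.
#' @export
write_sensorgrams_csv <- function(sensorgrams, path) {
  utils::write.csv(do.call(rbind, sensorgrams$traces), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sensorgrams from CSV
#'
#' @param path CSV in the schema of [write_sensorgrams_csv()].
#' @return A `SensorgramSet` (schedule reconstructed from the phase
#'   annotations).
#' @export
read_sensorgrams_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "signal_nm", "phase", "conc_M", "sensor_id") %in%
                  names(df)))
  traces <- split(df, list(df$sensor_id, df$conc_M), drop = TRUE)
  traces <- lapply(traces, function(d) d[order(d$time_s), ])
  b <- range(df$time_s[df$phase == "baseline"])
  a <- range(df$time_s[df$phase == "association"])
  d2 <- range(df$time_s[df$phase == "dissociation"])
  hz <- 1 / stats::median(diff(sort(unique(df$time_s))))
  structure(list(traces = unname(traces),
                 schedule = list(baseline = c(b[1], a[1]),
                                 association = c(a[1], d2[1]),
                                 dissociation = c(d2[1], d2[2]), hz = hz),
                 noise_sd = NA_real_, sensor_id = df$sensor_id[1],
                 truth = NULL),
            class = "SensorgramSet")
}

# Baseline-subtract each trace: subtract the mean of its final baseline
# seconds.
baseline_subtract <- function(sensorgrams, window_s = 10) {
  a0 <- sensorgrams$schedule$association[1]
  sensorgrams$traces <- lapply(sensorgrams$traces, function(d) {
    base <- d$signal_nm[d$phase == "baseline" & d$time_s >= a0 - window_s]
    if (length(base) == 0) base <- d$signal_nm[d$phase == "baseline"]
    d$signal_nm <- d$signal_nm - mean(base)
    d
  })
  sensorgrams
}

#' Globally fit a 1:1 binding model to a sensor's traces
#'
#' Baseline-subtracts each trace, then fits `kon`, `koff` and a shared
#' `Rmax` across all analyte concentrations of the sensor by
#' Levenberg-Marquardt least squares on the association and dissociation
#' phases jointly (the model is continuous at the phase boundary).
#' Parameters are fitted in log space with a multi-start grid over
#' `kon` and `koff`; bounds `kon` in `[1e2, 1e8]` 1/M/s and `koff` in
#' `[1e-5, 10]` 1/s.
#'
#' @param sensorgrams A `SensorgramSet` (one sensor).
#' @param noise_floor_mult A fit is flagged unfittable when the peak
#'   baseline-subtracted association signal is below this multiple of the
#'   baseline noise SD (default 3).
#' @param bounds List with `kon` and `koff` ranges.
#' @return A `KineticsParams`: list with `kon`, `koff`, `KD = koff/kon`,
#'   `Rmax`, `ssr`, `unfittable`, and per-trace residual SDs. When
#'   unfittable, the rate constants are `NA`.
#' @export
fit_1to1 <- function(sensorgrams, noise_floor_mult = 3,
                     bounds = list(kon = c(1e2, 1e8), koff = c(1e-5, 10))) {
  stopifnot(inherits(sensorgrams, "SensorgramSet"))
  sg <- baseline_subtract(sensorgrams)
  sched <- sg$schedule
  base_sd <- stats::sd(unlist(lapply(sg$traces, function(d)
    d$signal_nm[d$phase == "baseline"])))
  # peak of the 1-s boxcar-smoothed association signal: smoothing keeps the
  # extreme-value statistics of pure noise below the 3-sigma floor while
  # leaving a real binding plateau untouched
  win <- max(1L, round(sched$hz))
  peak <- max(vapply(sg$traces, function(d) {
    a <- d$signal_nm[d$phase == "association"]
    if (length(a) == 0) return(-Inf)
    max(stats::filter(a, rep(1 / win, win), sides = 2), na.rm = TRUE)
  }, numeric(1)))
  if (!is.finite(peak) || (is.finite(base_sd) && base_sd > 0 &&
                           peak < noise_floor_mult * base_sd)) {
    return(structure(list(kon = NA_real_, koff = NA_real_, KD = NA_real_,
                          Rmax = NA_real_, ssr = NA_real_, unfittable = TRUE,
                          noise_sd = base_sd, peak_signal = peak,
                          sensor_id = sg$sensor_id),
                     class = "KineticsParams"))
  }
  fitdat <- lapply(sg$traces, function(d)
    d[d$phase %in% c("association", "dissociation"), ])
  concs <- vapply(fitdat, function(d) d$conc_M[1], numeric(1))
  obs <- unlist(lapply(fitdat, `[[`, "signal_nm"))
  resid_fn <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2]); Rmax <- exp(p[3])
    pred <- unlist(lapply(seq_along(fitdat), function(i)
      bli_signal(fitdat[[i]]$time_s, concs[i], kon, koff, Rmax, sched)))
    pred - obs
  }
  rmax0 <- max(peak, base_sd, 1e-3)
  starts <- expand.grid(
    kon = exp(seq(log(bounds$kon[1] * 10), log(bounds$kon[2] / 10),
                  length.out = 3)),
    koff = exp(seq(log(bounds$koff[1] * 10), log(bounds$koff[2] / 10),
                   length.out = 3)))
  lower <- log(c(bounds$kon[1], bounds$koff[1], rmax0 * 1e-3))
  upper <- log(c(bounds$kon[2], bounds$koff[2], rmax0 * 1e3))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- log(c(starts$kon[s], starts$koff[s], rmax0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("1:1 fit failed to converge from any start")
  kon <- exp(best$par[1]); koff <- exp(best$par[2]); Rmax <- exp(best$par[3])
  res_sd <- vapply(seq_along(fitdat), function(i) {
    pred <- bli_signal(fitdat[[i]]$time_s, concs[i], kon, koff, Rmax, sched)
    stats::sd(fitdat[[i]]$signal_nm - pred)
  }, numeric(1))
  structure(list(kon = kon, koff = koff, KD = koff / kon, Rmax = Rmax,
                 ssr = best$ssr, unfittable = FALSE, noise_sd = base_sd,
                 peak_signal = peak, per_trace_residual_sd = res_sd,
                 sensor_id = sg$sensor_id),
            class = "KineticsParams")
}

#' @export
print.KineticsParams <- function(x, ...) {
  if (isTRUE(x$unfittable)) {
    cat("KineticsParams: unfittable (peak", format(x$peak_signal, digits = 3),
        "nm below noise floor)\n")
  } else {
    cat(sprintf(
      "KineticsParams: kon = %.4g 1/M/s, koff = %.4g 1/s, KD = %.4g M, Rmax = %.4g nm\n",
      x$kon, x$koff, x$KD, x$Rmax))
  }
  invisible(x)
}

#' Classify binding relative to a wild-type reference
#'
#' `"none"` when the mutant traces are unfittable at the maximum analyte
#' concentration tested; `"diminished"` when the fitted KD exceeds the
#' reference KD by more than `fold_threshold`; `"wt_like"` otherwise.
#'
#' @param fit A `KineticsParams` for the mutant (possibly unfittable).
#' @param reference A valid `KineticsParams` for the wild type.
#' @param max_conc Maximum analyte concentration tested (M), reported on
#'   the call (default 100e-6, i.e. 100 uM).
#' @param fold_threshold KD fold-change separating wt-like from diminished
#'   (default 3).
#' @return A `BindingCall`: list with `category`, `fold_change`,
#'   `max_conc_tested`.
#' @export
classify_binding <- function(fit, reference, max_conc = 100e-6,
                             fold_threshold = 3) {
  stopifnot(inherits(fit, "KineticsParams"),
            inherits(reference, "KineticsParams"))
  if (isTRUE(reference$unfittable) || !is.finite(reference$KD))
    stop("reference fit is not valid")
  if (isTRUE(fit$unfittable)) {
    call <- list(category = "none", fold_change = NA_real_,
                 max_conc_tested = max_conc)
  } else {
    fc <- fit$KD / reference$KD
    call <- list(category = if (fc > fold_threshold) "diminished" else "wt_like",
                 fold_change = fc, max_conc_tested = max_conc)
  }
  structure(call, class = "BindingCall")
}

#' Write kinetics fits as TSV
#'
#' @param fits Named list of `KineticsParams` (one per sensor/analyte).
#' @param path Output file.
#' @param calls Optional named list of `BindingCall`s aligned with `fits`.
#' @return The path, invisibly.
#' @export
write_kinetics_tsv <- function(fits, path, calls = NULL) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(id = nm, kon = f$kon, koff = f$koff, KD = f$KD,
               Rmax = f$Rmax, ssr = f$ssr %||% NA_real_,
               unfittable = isTRUE(f$unfittable),
               category = if (!is.null(calls[[nm]])) calls[[nm]]$category
                          else NA_character_)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
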
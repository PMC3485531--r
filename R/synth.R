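#' Synthetic segmental time-volume curves
#'
#' The generator emulates semi-automated border-detection output: 16 smooth
#' per-segment volume traces over one cardiac cycle. Each segment follows
#'
#'   V(t) = v_min + amplitude * w((t - delay) mod 100) + noise,  clipped at 0,
#'
#' where `w` is a smooth unimodal waveform with w(0) = 1 at QRS onset and
#' minimum 0 at the reference end-systolic time, so the segment's
#' end-systole lands at `reference_es_time + delay`. `amplitude` (= V_max -
#' V_min) is the contractility surrogate: amplitude 0 gives a flat, akinetic
#' segment whose timing is meaningless, which is exactly the hypokinetic
#' phenotype the STV indices are designed to down-weight. Noise is additive
#' Gaussian, independent across samples and segments.
#'
#' @param v_min Minimal (end-systolic) segmental volume, ml > 0.
#' @param amplitude Volume excursion V_max - V_min, ml >= 0.
#' @param delay Shift of the segmental end-systole relative to the
#'   reference time, %RR (negative = early contraction). Applied as a
#'   circular shift of the waveform argument.
#' @param waveform `"raised_cosine"` (default) or `"asymmetric_systole"`
#'   (faster volume descent than rise, closer to physiological curves).
#' @param noise_sd Gaussian noise SD, ml >= 0.
#' @return `segment_params()` returns a list of validated per-segment
#'   parameters.
#' @export
segment_params <- function(v_min, amplitude, delay = 0,
                           waveform = c("raised_cosine", "asymmetric_systole"),
                           noise_sd = 0) {
  waveform <- match.arg(waveform)
  stopifnot(is.finite(v_min), v_min > 0,
            is.finite(amplitude), amplitude >= 0,
            is.finite(delay), is.finite(noise_sd), noise_sd >= 0)
  list(v_min = v_min, amplitude = amplitude, delay = delay,
       waveform = waveform, noise_sd = noise_sd)
}

# unimodal waveform on [0, 100]: 1 at t = 0 and t = 100, 0 at t_es
systolic_waveform <- function(t, t_es, waveform = "raised_cosine") {
  t <- t %% 100
  w <- numeric(length(t))
  dn <- t <= t_es
  s <- t[dn] / t_es
  if (waveform == "asymmetric_systole") s <- s^0.7  # faster early descent
  w[dn] <- 0.5 * (1 + cos(pi * s))
  s <- (t[!dn] - t_es) / (100 - t_es)
  w[!dn] <- 0.5 * (1 - cos(pi * s))
  w
}

#' @rdname segment_params
#' @param params For [make_segment_curve()], a `segment_params()` list; for
#'   [simulate_study()], a [study_params()] list.
#' @param grid Time grid in %RR (at least 8 points).
#' @param reference_es_time End-systolic time of an undelayed segment, %RR.
#' @param label Segment label.
#' @return `make_segment_curve()` returns a [tv_curve()]. Noise is drawn
#'   from the ambient RNG stream; seed at the study level.
#' @export
make_segment_curve <- function(params, grid, reference_es_time = 40,
                               label = "segment") {
  grid <- as.numeric(grid)
  if (length(grid) < 8L)
    stop("grid must have at least 8 points")
  v <- params$v_min + params$amplitude *
    systolic_waveform(grid - params$delay, reference_es_time, params$waveform)
  if (params$noise_sd > 0)
    v <- v + stats::rnorm(length(grid), 0, params$noise_sd)
  tv_curve(grid, pmax(v, 0), label = label)
}

#' Parameters for one synthetic echo study
#'
#' Vector arguments are recycled across the 16 segments. `v_min` and
#' `amplitude` defaults approximate a dilated, poorly contracting ventricle
#' (EDV near 190 ml, EF near 20%), with basal segments carrying larger
#' volumes than mid and apical ones as in the real LV — the property that
#' makes basal segments weigh more in STV.
#'
#' @param delays Per-segment end-systolic delays, %RR (length 16 or
#'   recycled).
#' @param v_min,amplitude,noise_sd Per-segment values, recycled to 16.
#' @param waveform Waveform shape for all segments.
#' @param reference_es_time Undelayed end-systolic time, %RR.
#' @param n_samples Generation grid size (uniform on [0, 100]).
#' @param study_id Study identifier.
#' @param seed Optional integer seed; if given, [simulate_study()] is fully
#'   deterministic.
#' @return A list of class `study_params`.
#' @export
study_params <- function(delays = 0,
                         v_min = 9.1 * segment_size_weights(),
                         amplitude = 2.8 * segment_size_weights(),
                         noise_sd = 0,
                         waveform = c("raised_cosine", "asymmetric_systole"),
                         reference_es_time = 40,
                         n_samples = 201L,
                         study_id = "synthetic",
                         seed = NULL) {
  waveform <- match.arg(waveform)
  rec <- function(x) rep_len(as.numeric(x), N_SEGMENTS)
  structure(list(delays = rec(delays), v_min = rec(v_min),
                 amplitude = rec(amplitude), noise_sd = rec(noise_sd),
                 waveform = waveform,
                 reference_es_time = reference_es_time,
                 n_samples = as.integer(n_samples),
                 study_id = study_id, seed = seed),
            class = "study_params")
}

#' Relative volume of each LV segment
#'
#' Size weights (mean 1 over the 16 segments): basal segments are the
#' largest, apical the smallest. Multiplying a per-segment base volume by
#' these weights preserves the study total.
#'
#' @return Numeric vector of length 16 in [lv_segments()] order.
#' @export
segment_size_weights <- function() {
  w <- c(rep(1.3, 6), rep(1.0, 6), rep(0.55, 4))
  w / mean(w)
}

#' Simulate one synthetic echo study
#'
#' Builds the 16 segmental curves of [study_params()] on a shared uniform
#' grid. With `noise_sd = 0` the curves are exact analytic waveforms and
#' each segment's end-systole sits at `reference_es_time + delay` to within
#' grid resolution, giving ground truth for parameter-recovery checks.
#'
#' @param params A [study_params()] list.
#' @return A [curve_set()]; the true delays are attached as attribute
#'   `"true_delays"`.
#' @export
#' @examples
#' st <- simulate_study(study_params(delays = c(rep(-20, 4), rep(0, 12))))
#' analyze_study(st)
simulate_study <- function(params = study_params()) {
  stopifnot(inherits(params, "study_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  grid <- uniform_grid(params$n_samples)
  segs <- lv_segments()
  vols <- vapply(seq_len(N_SEGMENTS), function(i) {
    sp <- segment_params(params$v_min[i], params$amplitude[i],
                         params$delays[i], params$waveform,
                         params$noise_sd[i])
    make_segment_curve(sp, grid, params$reference_es_time,
                       label = segs[i])$volumes
  }, numeric(params$n_samples))
  colnames(vols) <- segs
  out <- curve_set(grid, vols, study_id = params$study_id,
                   metadata = list(generator = "stvloss-synthetic"))
  attr(out, "true_delays") <- params$delays
  out
}

#' Parameters for a synthetic CRT cohort
#'
#' Defaults are calibrated to a typical CRT trial population of dilated
#' ventricles: 20 responders whose dyssynchrony lives in early-contracting,
#' well-contracting segments (high Pre-STV, high SDI), and 8 non-responders
#' whose delayed segments are hypokinetic (timing dispersion comparable,
#' but little displaced volume, hence low Pre-STV). Follow-up curves shrink
#' the responders' delays by the homogenization factor and impose a drawn
#' end-systolic-volume change; the drawn changes are truncated away from
#' the 10% response boundary so the stored ground-truth labels are
#' unambiguous.
#'
#' Per-group fields (suffix `_r` responders, `_n` non-responders):
#' `n_delayed_*` ranges, `delay_mean_*`/`delay_sd_*` magnitudes of the early
#' shift in %RR (bounded to keep segmental minima inside the cycle),
#' `frac_hypokinetic_*` the fraction of delayed segments rendered
#' hypokinetic, `esv_change_*` the follow-up ESV change distribution
#' (mean, sd, lower, upper; percent, negative = reduction).
#'
#' @param n_responders,n_non_responders Group sizes.
#' @param edv_mean_r,edv_sd_r,edv_mean_n,edv_sd_n Baseline EDV targets (ml),
#'   truncated below at `edv_min`.
#' @param edv_min Lower truncation for EDV draws (ml).
#' @param ef_mean,ef_sd Ejection-fraction distribution (%), truncated to
#'   [6, 35]; with EDV it sets each patient's total displaced volume.
#' @param n_delayed_r,n_delayed_n Integer ranges (length 2) for the number
#'   of delayed segments per patient.
#' @param delay_mean_r,delay_sd_r,delay_mean_n,delay_sd_n Early-shift
#'   magnitude distributions, %RR, truncated to `delay_range`.
#' @param delay_range Magnitude truncation bounds, %RR.
#' @param frac_hypokinetic_r,frac_hypokinetic_n Fraction of each patient's
#'   delayed segments made hypokinetic (amplitude scaled by
#'   `hypo_amp_factor`).
#' @param hypo_amp_factor Amplitude multiplier for hypokinetic segments.
#' @param delayed_amp_lnorm Numeric c(meanlog, sdlog) of a per-patient
#'   log-normal contractility multiplier applied to the delayed segments
#'   that keep their inward motion (capped at 3.5). Clinical STV values are
#'   strongly right-skewed (group SDs of the same order as the means); a
#'   multiplicative severity factor reproduces that skew, which symmetric
#'   per-segment draws cannot.
#' @param timing_jitter_sd Per-segment end-systolic jitter SD applied to all
#'   segments, %RR.
#' @param esv_change_r,esv_change_n Numeric c(mean, sd, lower, upper) for
#'   the follow-up ESV change in percent.
#' @param homogenization Factor in [0, 1]; follow-up responder delays are
#'   multiplied by (1 - homogenization).
#' @param noise_sd Curve noise SD, ml.
#' @param n_samples Generation grid size.
#' @param seed Optional root seed for the whole cohort.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_responders = 20L, n_non_responders = 8L,
                          edv_mean_r = 195, edv_sd_r = 45,
                          edv_mean_n = 176, edv_sd_n = 60,
                          edv_min = 90,
                          ef_mean = 19, ef_sd = 8,
                          n_delayed_r = c(3L, 6L), n_delayed_n = c(3L, 5L),
                          delay_mean_r = 30, delay_sd_r = 6,
                          delay_mean_n = 14, delay_sd_n = 6,
                          delay_range = c(6, 34),
                          frac_hypokinetic_r = 0.1,
                          frac_hypokinetic_n = 0.9,
                          hypo_amp_factor = 0.1,
                          delayed_amp_lnorm = c(0.3, 0.8),
                          timing_jitter_sd = 2,
                          esv_change_r = c(-29, 8, -55, -12),
                          esv_change_n = c(3, 5, -8, 15),
                          homogenization = 0.8,
                          noise_sd = 0.02,
                          n_samples = 201L,
                          seed = NULL) {
  p <- as.list(environment())
  stopifnot(p$n_responders >= 1L, p$n_non_responders >= 1L,
            homogenization >= 0, homogenization <= 1,
            hypo_amp_factor >= 0,
            delay_range[1] > 0, delay_range[2] <= 35)
  for (ec in list(esv_change_r, esv_change_n)) {
    stopifnot(length(ec) == 4L, ec[3] <= ec[4], ec[2] >= 0)
    feasible <- ec[2] == 0 ||  # point mass, clamped into the bounds
      stats::pnorm(ec[4], ec[1], ec[2]) -
        stats::pnorm(ec[3], ec[1], ec[2]) > 0
    if (!feasible)
      stop("infeasible ESV-change distribution: no mass between truncation bounds")
  }
  class(p) <- "cohort_params"
  p
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# one patient's baseline segment-level parameters
draw_patient_baseline <- function(p, responder) {
  g <- if (responder) "r" else "n"
  gp <- function(nm) p[[paste0(nm, "_", g)]]
  edv <- rtrunc_norm(1, gp("edv_mean"), gp("edv_sd"), p$edv_min)
  # EDV and EF drawn from the heart-failure cohort distributions; their
  # product sets the displaced volume, which is what STV weights by
  ef <- rtrunc_norm(1, p$ef_mean / 100, p$ef_sd / 100, 0.06, 0.35)
  w <- segment_size_weights()
  v_min <- (edv * (1 - ef) / N_SEGMENTS) * w *
    rtrunc_norm(N_SEGMENTS, 1, 0.06, 0.8, 1.2)
  amplitude <- (edv * ef / N_SEGMENTS) * w *
    rtrunc_norm(N_SEGMENTS, 1, 0.25, 0.3, 1.9)
  nd_rng <- gp("n_delayed")
  n_delayed <- sample(nd_rng[1]:nd_rng[2], 1L)
  delayed <- sample(N_SEGMENTS, n_delayed)
  delays <- stats::rnorm(N_SEGMENTS, 0, p$timing_jitter_sd)
  delays[delayed] <- -rtrunc_norm(n_delayed, gp("delay_mean"), gp("delay_sd"),
                                  p$delay_range[1], p$delay_range[2])
  n_hypo <- round(gp("frac_hypokinetic") * n_delayed)
  hypo <- delayed[seq_len(n_hypo)]
  amplitude[hypo] <- amplitude[hypo] * p$hypo_amp_factor
  # per-patient severity: delayed segments with preserved inward motion
  preserved <- setdiff(delayed, hypo)
  sev <- min(stats::rlnorm(1, p$delayed_amp_lnorm[1], p$delayed_amp_lnorm[2]),
             3)
  amplitude[preserved] <- amplitude[preserved] * sev
  # keep every segmental minimum inside the cycle
  delays <- pmin(pmax(delays, -35), 55)
  list(v_min = v_min, amplitude = amplitude, delays = delays,
       delayed = delayed, hypo = hypo)
}

#' Simulate a paired baseline/follow-up CRT cohort
#'
#' Draws each patient's baseline ventricle per [cohort_params()], then a
#' follow-up study: responders get their delays multiplied by
#' `(1 - homogenization)` (CRT homogenises contraction timing) and an ESV
#' reduction drawn from `esv_change_r`; non-responders keep their baseline
#' delay pattern (fresh jitter and noise) with an ESV change drawn from
#' `esv_change_n`. Follow-up curves are rescaled multiplicatively so the
#' analysed ESV matches the drawn change exactly, making the stored
#' ground-truth labels recoverable by [classify_response()].
#'
#' @param params A [cohort_params()] list.
#' @return Object of class `stv_cohort`: list with `patients` (each with
#'   `patient_id`, `baseline` and `followup` [curve_set()]s, ground-truth
#'   `true_responder`, `true_delta_esv_pct`, `true_delays`), `params`,
#'   `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_params(n_responders = 4, n_non_responders = 2,
#'                                      seed = 1))
#' ev <- evaluate_cohort(coh)
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  labels <- c(rep(TRUE, params$n_responders),
              rep(FALSE, params$n_non_responders))
  patients <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    responder <- labels[i]
    pid <- sprintf("pt%02d", i)
    b <- draw_patient_baseline(params, responder)
    base_sp <- study_params(delays = b$delays, v_min = b$v_min,
                            amplitude = b$amplitude,
                            noise_sd = params$noise_sd,
                            n_samples = params$n_samples,
                            study_id = paste0(pid, "_baseline"))
    baseline <- simulate_study(base_sp)

    ec <- if (responder) params$esv_change_r else params$esv_change_n
    delta <- rtrunc_norm(1, ec[1], ec[2], ec[3], ec[4])
    fu_delays <- if (responder) {
      b$delays * (1 - params$homogenization) +
        stats::rnorm(N_SEGMENTS, 0, params$timing_jitter_sd / 2)
    } else {
      jit <- stats::rnorm(N_SEGMENTS, 0, params$timing_jitter_sd)
      d <- b$delays
      d[-b$delayed] <- jit[-b$delayed]
      d
    }
    fu_delays <- pmin(pmax(fu_delays, -35), 55)
    fu_sp <- study_params(delays = fu_delays, v_min = b$v_min,
                          amplitude = b$amplitude,
                          noise_sd = params$noise_sd,
                          n_samples = params$n_samples,
                          study_id = paste0(pid, "_followup"))
    followup <- simulate_study(fu_sp)
    # impose the drawn ESV change exactly (volumes scale linearly)
    esv_base <- min(rowSums(baseline$volumes))
    esv_fu <- min(rowSums(followup$volumes))
    scale <- esv_base * (1 + delta / 100) / esv_fu
    followup$volumes <- followup$volumes * scale
    attr_fu <- attr(followup, "true_delays")
    followup <- curve_set(followup$times, followup$volumes,
                          study_id = followup$study_id,
                          metadata = followup$metadata)
    attr(followup, "true_delays") <- attr_fu
    patients[[i]] <- list(patient_id = pid, baseline = baseline,
                          followup = followup,
                          true_responder = responder,
                          true_delta_esv_pct = delta,
                          true_delays = b$delays,
                          hypokinetic = lv_segments()[b$hypo])
  }
  structure(list(patients = patients, params = params, seed = params$seed),
            class = "stv_cohort")
}

#' @export
print.stv_cohort <- function(x, ...) {
  nr <- sum(vapply(x$patients, `[[`, logical(1), "true_responder"))
  cat(sprintf("<stv_cohort> %d patients (%d responders, %d non-responders)%s\n",
              length(x$patients), nr, length(x$patients) - nr,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}
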
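#' Systolic dyssynchrony index (SDI)
#'
#' Standard deviation of the 16 segmental times from QRS onset to minimal
#' segmental volume, in %RR. The sample standard deviation (divisor N-1) is
#' the default; the population form (divisor N) is available because the
#' convention used by clinical analysis software is not published.
#'
#' @param es_times Numeric vector of segmental end-systolic times (%RR),
#'   length 16 unless `allow_partial = TRUE`.
#' @param divisor `"n_minus_1"` (sample SD, default) or `"n"`.
#' @param allow_partial Accept fewer than 16 segments (with a warning);
#'   otherwise fewer segments is an error.
#' @return SDI in %RR (0 when all times coincide).
#' @export
#' @examples
#' compute_sdi(c(rep(40, 15), 56))  # 4 %RR
compute_sdi <- function(es_times, divisor = c("n_minus_1", "n"),
                        allow_partial = FALSE) {
  divisor <- match.arg(divisor)
  es_times <- check_es_times(es_times, allow_partial)
  n <- length(es_times)
  dev2 <- sum((es_times - mean(es_times))^2)
  if (divisor == "n_minus_1") sqrt(dev2 / (n - 1L)) else sqrt(dev2 / n)
}

#' Latest-minus-earliest segmental delay (L-E)
#'
#' Time between the earliest and the latest segment to reach minimal
#' volume, in %RR.
#'
#' @inheritParams compute_sdi
#' @return L-E in %RR.
#' @export
compute_le <- function(es_times, allow_partial = FALSE) {
  es_times <- check_es_times(es_times, allow_partial)
  max(es_times) - min(es_times)
}

check_es_times <- function(es_times, allow_partial) {
  es_times <- as.numeric(es_times)
  if (anyNA(es_times) || any(!is.finite(es_times)))
    stop("segmental end-systolic times must be finite")
  if (any(es_times < 0 | es_times > 100))
    stop("segmental end-systolic times must lie in [0, 100] %RR")
  if (length(es_times) < 2L)
    stop("need at least 2 segmental times")
  if (length(es_times) != N_SEGMENTS) {
    if (!allow_partial)
      stop("expected 16 segmental times, got ", length(es_times),
           " (set allow_partial = TRUE to override)")
    warning("computing timing index over ", length(es_times),
            " of 16 segments")
  }
  es_times
}

#' Per-segment systolic time-volume loss area
#'
#' The STV area of one segment is the area under its time-volume curve,
#' measured above the segmental minimal volume, between segmental and
#' global end-systole (trapezoidal rule; units ml x %RR, printed as
#' "ml%"). A segment reaching its minimum before global end-systole is in
#' early relaxation at global end-systole, so its curve sits above its own
#' minimum over that interval; the enclosed area grows with both the timing
#' offset and the volume the segment moves, which is what distinguishes STV
#' from purely timing-based indices. Segments minimal before global
#' end-systole are classified `"pre"`, after it `"post"`, and exactly at it
#' `"synchronous"` (area zero). Tiny negative integrand values from
#' numerical noise are clamped to zero.
#'
#' @param curve A [tv_curve()] for one segment; both end-systolic times must
#'   lie on its grid (guaranteed after shared resampling).
#' @param t_seg_es Segmental end-systolic time (%RR).
#' @param v_seg_min Segmental minimal volume (ml).
#' @param t_glob_es Global end-systolic time (%RR).
#' @return List with `segment`, `classification` (`"pre"`, `"post"` or
#'   `"synchronous"`), `area` (ml x %RR), `es_time`, `es_volume`.
#' @export
#' @examples
#' crv <- tv_curve(c(0, 25, 50, 75, 100), c(10, 4, 6, 8, 10), "mid_anterior")
#' segment_stv(crv, t_seg_es = 25, v_seg_min = 4, t_glob_es = 50)
segment_stv <- function(curve, t_seg_es, v_seg_min, t_glob_es) {
  stopifnot(inherits(curve, "tv_curve"))
  classification <-
    if (t_seg_es < t_glob_es) "pre"
    else if (t_seg_es > t_glob_es) "post"
    else "synchronous"
  lo <- min(t_seg_es, t_glob_es)
  hi <- max(t_seg_es, t_glob_es)
  sel <- curve$times >= lo & curve$times <= hi
  tt <- curve$times[sel]
  integrand <- pmax(curve$volumes[sel] - v_seg_min, 0)
  area <- if (length(tt) < 2L) 0 else trapz(tt, integrand)
  list(segment = curve$label, classification = classification,
       area = area, es_time = t_seg_es, es_volume = v_seg_min)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Pre-, post- and total systolic time-volume loss of a study
#'
#' Computes the per-segment STV areas (see [segment_stv()]) and sums them by
#' class: Pre-STV over segments reaching minimal volume before global
#' end-systole, Post-STV over segments reaching it after, total STV as
#' their sum. Every segment falls in exactly one class; synchronous
#' segments contribute zero to either sum. No wrapping across the cycle
#' boundary is attempted: events around end-diastole are outside the model.
#'
#' @param curve_set A [curve_set()] on a shared grid (resample first; see
#'   [analyze_study()] for the full pipeline).
#' @return List with `pre_stv`, `post_stv`, `total_stv` (ml x %RR) and
#'   `entries`, a data.frame of the 16 per-segment results.
#' @export
compute_stv <- function(curve_set) {
  stopifnot(inherits(curve_set, "curve_set"))
  es <- end_systole_table(curve_set)
  t_glob <- attr(es, "global_es_time")
  entries <- lapply(seq_len(N_SEGMENTS), function(i)
    segment_stv(segment_curve(curve_set, es$segment[i]),
                t_seg_es = es$es_time[i], v_seg_min = es$es_volume[i],
                t_glob_es = t_glob))
  entries <- data.frame(
    segment = vapply(entries, `[[`, character(1), "segment"),
    classification = vapply(entries, `[[`, character(1), "classification"),
    area = vapply(entries, `[[`, numeric(1), "area"),
    es_time = vapply(entries, `[[`, numeric(1), "es_time"),
    es_volume = vapply(entries, `[[`, numeric(1), "es_volume"),
    stringsAsFactors = FALSE)
  pre <- sum(entries$area[entries$classification == "pre"])
  post <- sum(entries$area[entries$classification == "post"])
  list(pre_stv = pre, post_stv = post, total_stv = pre + post,
       entries = entries, es_table = es)
}

#' Global left-ventricular volumes and ejection fraction
#'
#' EDV and ESV are the maximum and minimum of the global (summed) curve;
#' EF = 100 x (EDV - ESV) / EDV.
#'
#' @param curve_set A [curve_set()].
#' @return List with `edv` (ml), `esv` (ml), `ef` (%).
#' @export
compute_global_function <- function(curve_set) {
  g <- global_curve(curve_set)
  edv <- max(g$volumes)
  esv <- min(g$volumes)
  if (edv <= 0)
    stop("degenerate study: end-diastolic volume is zero")
  list(edv = edv, esv = esv, ef = 100 * (edv - esv) / edv)
}

#' Full dyssynchrony analysis of one echo study
#'
#' The core analysis: resamples the 16 segmental curves onto a shared
#' uniform grid, locates global and segmental end-systole, and computes
#' global function (EDV, ESV, EF), the timing-only dyssynchrony indices
#' (SDI, L-E) and the volume-weighted ones (Pre-STV, Post-STV, total STV)
#' with the per-segment breakdown.
#'
#' SDI and L-E see only the segmental end-systolic times, so a severely
#' hypokinetic segment with a long delay moves them as much as a
#' well-contracting one; its STV contribution, by contrast, scales with the
#' volume it displaces and vanishes as the segment becomes akinetic. That
#' dissociation is the rationale for the STV family.
#'
#' @param curve_set A [curve_set()].
#' @param n_samples Shared analysis grid size (default 201, i.e. 0.5 %RR
#'   resolution). Set to `NULL` to analyse on the stored grid unchanged.
#' @param sdi_divisor Passed to [compute_sdi()].
#' @return Object of class `stv_report`: a list with fields `study_id`,
#'   `edv`, `esv`, `ef`, `sdi`, `le`, `pre_stv`, `post_stv`, `total_stv`,
#'   `entries` (per-segment data.frame), `es_table`, `n_samples`,
#'   `sdi_divisor`.
#' @seealso [print.stv_report()], [summary.stv_report()],
#'   [coef.stv_report()], [plot.stv_report()]
#' @export
#' @examples
#' set.seed(1)
#' st <- simulate_study(study_params(delays = c(-15, -12, rep(0, 14))))
#' analyze_study(st)
analyze_study <- function(curve_set, n_samples = 201L,
                          sdi_divisor = c("n_minus_1", "n")) {
  stopifnot(inherits(curve_set, "curve_set"))
  sdi_divisor <- match.arg(sdi_divisor)
  if (!is.null(n_samples)) {
    uniform_grid(n_samples, min_n = 8L)  # analysis grid floor
    curve_set <- resample_uniform(curve_set, n_samples)
  }
  fun <- compute_global_function(curve_set)
  stv <- compute_stv(curve_set)
  es_times <- stv$es_table$es_time
  out <- list(
    study_id = curve_set$study_id,
    edv = fun$edv, esv = fun$esv, ef = fun$ef,
    sdi = compute_sdi(es_times, divisor = sdi_divisor),
    le = compute_le(es_times),
    pre_stv = stv$pre_stv, post_stv = stv$post_stv,
    total_stv = stv$total_stv,
    entries = stv$entries, es_table = stv$es_table,
    n_samples = if (is.null(n_samples)) length(curve_set$times)
                else as.integer(n_samples),
    sdi_divisor = sdi_divisor,
    curve_set = curve_set)
  class(out) <- "stv_report"
  out
}

#' @export
print.stv_report <- function(x, digits = 2, ...) {
  cat(sprintf("LV dyssynchrony analysis: study '%s' (%d-point grid)\n",
              x$study_id, x$n_samples))
  cat(sprintf("  EDV %.*f ml  ESV %.*f ml  EF %.1f%%\n",
              digits, x$edv, digits, x$esv, x$ef))
  cat(sprintf("  SDI %.*f %%RR  L-E %.*f %%RR\n", digits, x$sdi, digits, x$le))
  cat(sprintf("  Pre-STV %.*f ml%%  Post-STV %.*f ml%%  total STV %.*f ml%%\n",
              digits, x$pre_stv, digits, x$post_stv, digits, x$total_stv))
  invisible(x)
}

#' @describeIn analyze_study Per-segment summary: prints the headline
#'   metrics and the classification/area of every segment.
#' @param object,x An `stv_report`.
#' @param ... Unused.
#' @export
summary.stv_report <- function(object, ...) {
  print(object)
  cat(sprintf("\nGlobal end-systole at %.2f %%RR; per-segment breakdown:\n",
              attr(object$es_table, "global_es_time")))
  e <- object$entries
  e$area <- round(e$area, 3)
  print(e, row.names = FALSE)
  invisible(object)
}

#' @describeIn analyze_study Named vector of the scalar metrics
#'   (edv, esv, ef, sdi, le, pre_stv, post_stv, total_stv).
#' @export
coef.stv_report <- function(object, ...) {
  with(object, c(edv = edv, esv = esv, ef = ef, sdi = sdi, le = le,
                 pre_stv = pre_stv, post_stv = post_stv,
                 total_stv = total_stv))
}

#' @describeIn analyze_study Plots the global and segmental time-volume
#'   curves with global end-systole marked.
#' @export
plot.stv_report <- function(x, ...) {
  cs <- x$curve_set
  g <- global_curve(cs)
  op <- graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(cs$times, cs$volumes, type = "l", lty = 1,
                    col = grDevices::grey(0.65),
                    xlab = "time (% RR-interval)", ylab = "volume (ml)",
                    main = sprintf("Study '%s': segmental and global/16 curves",
                                   x$study_id), ...)
  graphics::lines(g$times, g$volumes / N_SEGMENTS, lwd = 2)
  graphics::abline(v = attr(x$es_table, "global_es_time"), lty = 2)
  graphics::legend("topright", bty = "n", lwd = c(1, 2),
                   col = c(grDevices::grey(0.65), "black"),
                   legend = c("segments", "global / 16"))
  invisible(x)
}
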
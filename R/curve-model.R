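#' Segmental time-volume curve containers
#'
#' A `tv_curve` is one volume trace over a single cardiac cycle: time in
#' percent of the RR-interval (0 = QRS onset, 100 = the next QRS), volume in
#' ml. A `curve_set` holds the 16 segmental traces of one echo study on a
#' shared time grid; the global LV curve is the pointwise sum of the 16
#' segments and is always recomputed, never stored.
#'
#' @param times Numeric vector, strictly increasing, within [0, 100] %RR,
#'   length >= 3.
#' @param volumes Numeric vector of non-negative volumes (ml), same length
#'   as `times`. For [curve_set()], a length(times) x 16 numeric matrix with
#'   one column per segment in [lv_segments()] order (a named list of 16
#'   vectors is also accepted).
#' @param label Curve label: a segment name or `"global"`.
#' @param rr_interval_ms Optional positive RR-interval duration in ms
#'   (metadata only; all analysis runs on the %RR scale).
#' @param study_id Study identifier string.
#' @param metadata Optional named list of opaque study metadata (e.g. NYHA
#'   class, BNP); carried through, never computed on.
#' @return [tv_curve()] returns an object of class `tv_curve` (a list with
#'   `times`, `volumes`, `label`); [curve_set()] returns class `curve_set`
#'   (a list with `times`, `volumes` matrix, `rr_interval_ms`, `study_id`,
#'   `metadata`).
#' @seealso [global_curve()], [resample_uniform()], [analyze_study()]
#' @export
#' @examples
#' tv_curve(c(0, 50, 100), c(10, 4, 10), label = "mid_anterior")
tv_curve <- function(times, volumes, label = "global") {
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  if (length(times) < 3L)
    stop("a time-volume curve needs at least 3 samples, got ", length(times))
  if (length(volumes) != length(times))
    stop("times and volumes differ in length (", length(times), " vs ",
         length(volumes), ")")
  if (anyNA(times) || anyNA(volumes))
    stop("times/volumes must not contain NA")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (times[1L] < 0 || times[length(times)] > 100)
    stop("times must lie within [0, 100] %RR, got range [",
         times[1L], ", ", times[length(times)], "]")
  if (any(volumes < 0))
    stop("volumes must be non-negative")
  structure(list(times = times, volumes = volumes,
                 label = as.character(label)[1L]),
            class = "tv_curve")
}

#' @rdname tv_curve
#' @export
curve_set <- function(times, volumes, rr_interval_ms = NULL,
                      study_id = "study", metadata = list()) {
  times <- as.numeric(times)
  if (is.list(volumes) && !is.data.frame(volumes)) {
    nm <- names(volumes)
    if (is.null(nm) || anyNA(nm))
      stop("a list of segment traces must be named by segment")
    missing <- setdiff(lv_segments(), nm)
    if (length(missing))
      stop("missing segment(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(nm, lv_segments())
    if (length(extra))
      stop("unknown segment(s): ", paste(extra, collapse = ", "))
    volumes <- vapply(lv_segments(), function(s) as.numeric(volumes[[s]]),
                      numeric(length(times)))
  }
  volumes <- as.matrix(volumes)
  if (is.null(colnames(volumes)) && ncol(volumes) == N_SEGMENTS)
    colnames(volumes) <- lv_segments()
  if (!identical(sort(colnames(volumes)), sort(lv_segments())))
    stop("curve set must contain exactly the 16 canonical segments; see lv_segments()")
  volumes <- volumes[, lv_segments(), drop = FALSE]
  if (nrow(volumes) != length(times))
    stop("volume matrix has ", nrow(volumes), " rows but ", length(times),
         " time points")
  # per-segment validation via the curve constructor
  for (s in lv_segments()) tv_curve(times, volumes[, s], label = s)
  if (!is.null(rr_interval_ms)) {
    rr_interval_ms <- as.numeric(rr_interval_ms)[1L]
    if (!is.finite(rr_interval_ms) || rr_interval_ms <= 0)
      stop("rr_interval_ms must be a positive duration")
  }
  structure(list(times = times, volumes = volumes,
                 rr_interval_ms = rr_interval_ms,
                 study_id = as.character(study_id)[1L],
                 metadata = metadata),
            class = "curve_set")
}

#' @export
print.tv_curve <- function(x, ...) {
  cat(sprintf("<tv_curve '%s'>  %d samples on [%.1f, %.1f] %%RR, volume %.2f-%.2f ml\n",
              x$label, length(x$times), x$times[1L], x$times[length(x$times)],
              min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set '%s'>  16 segments x %d samples on [%.1f, %.1f] %%RR\n",
              x$study_id, length(x$times), x$times[1L],
              x$times[length(x$times)]))
  g <- global_curve(x)
  cat(sprintf("  global volume range %.1f-%.1f ml\n",
              min(g$volumes), max(g$volumes)))
  invisible(x)
}

#' Extract one segment's curve from a curve set
#'
#' @param curve_set A [curve_set()].
#' @param segment Segment name from [lv_segments()].
#' @return A [tv_curve()].
#' @export
segment_curve <- function(curve_set, segment) {
  stopifnot(inherits(curve_set, "curve_set"))
  segment <- match.arg(segment, lv_segments())
  tv_curve(curve_set$times, curve_set$volumes[, segment], label = segment)
}

#' Resample curves onto a uniform grid over one cardiac cycle
#'
#' Linear interpolation onto `n_samples` equidistant points spanning
#' [0, 100] %RR. Frame rate (hence time sampling) differs between
#' acquisitions; a common uniform grid makes end-systole detection and area
#' integration comparable across studies and guarantees that segmental and
#' global end-systolic times fall on shared grid points. Where the original
#' grid does not reach 0 or 100 the boundary volume is held constant
#' (clamped extrapolation) and a warning is raised.
#'
#' @param x A [tv_curve()] or [curve_set()].
#' @param n_samples Number of grid points (at least 3 for bare resampling;
#'   analysis via [analyze_study()] requires at least 8). Default 201
#'   (0.5 %RR resolution).
#' @return Object of the same class on the uniform grid.
#' @export
#' @examples
#' crv <- tv_curve(c(0, 50, 100), c(10, 4, 10))
#' resample_uniform(crv, 5)$volumes  # 10 7 4 7 10
resample_uniform <- function(x, n_samples = 201L) {
  UseMethod("resample_uniform")
}

uniform_grid <- function(n_samples, min_n = 8L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < min_n)
    stop("n_samples must be an integer >= ", min_n)
  seq(0, 100, length.out = n_samples)
}

#' @export
resample_uniform.tv_curve <- function(x, n_samples = 201L) {
  grid <- uniform_grid(n_samples, min_n = 3L)
  if (x$times[1L] > 0 || x$times[length(x$times)] < 100)
    warning(sprintf(
      "curve '%s' spans [%.2f, %.2f] %%RR; boundary volumes clamped onto [0, 100]",
      x$label, x$times[1L], x$times[length(x$times)]))
  v <- stats::approx(x$times, x$volumes, xout = grid, method = "linear",
                     rule = 2)$y
  tv_curve(grid, v, label = x$label)
}

#' @export
resample_uniform.curve_set <- function(x, n_samples = 201L) {
  grid <- uniform_grid(n_samples, min_n = 3L)
  if (x$times[1L] > 0 || x$times[length(x$times)] < 100)
    warning(sprintf(
      "study '%s' spans [%.2f, %.2f] %%RR; boundary volumes clamped onto [0, 100]",
      x$study_id, x$times[1L], x$times[length(x$times)]))
  v <- apply(x$volumes, 2L, function(col)
    stats::approx(x$times, col, xout = grid, method = "linear", rule = 2)$y)
  colnames(v) <- colnames(x$volumes)
  curve_set(grid, v, rr_interval_ms = x$rr_interval_ms,
            study_id = x$study_id, metadata = x$metadata)
}

#' Global left-ventricular time-volume curve
#'
#' The global LV volume at each time point is the sum of the 16 segmental
#' volumes. Global end-systole is the moment this sum is minimal, which in a
#' dyssynchronous ventricle is not the moment any individual segment is
#' minimal.
#'
#' @param curve_set A [curve_set()].
#' @return A [tv_curve()] labelled `"global"`.
#' @export
global_curve <- function(curve_set) {
  stopifnot(inherits(curve_set, "curve_set"))
  tv_curve(curve_set$times, rowSums(curve_set$volumes), label = "global")
}

#' Locate end-systole on a time-volume curve
#'
#' End-systole is the grid point of minimal volume. The minimum is taken on
#' the discrete grid without sub-sample refinement; analyse on a resampled
#' grid (default 201 points, 0.5 %RR) if finer resolution is needed. Exact
#' ties are broken towards the earliest time, a deterministic rule that
#' biases an exactly-tied segment towards the pre-systolic class.
#'
#' @param curve A [tv_curve()].
#' @return Named list with `time` (%RR) and `volume` (ml).
#' @export
#' @examples
#' find_end_systole(tv_curve(c(0, 25, 50, 75, 100), c(10, 4, 6, 8, 10)))
find_end_systole <- function(curve) {
  stopifnot(inherits(curve, "tv_curve"))
  i <- which.min(curve$volumes)  # which.min returns the first minimum
  list(time = curve$times[i], volume = curve$volumes[i])
}

#' Global and segmental end-systole table
#'
#' Tabulates, for one study, the global end-systolic time and volume (from
#' the summed global curve) and each segment's individual end-systolic time
#' and minimal volume. In a dyssynchronous ventricle the segmental times
#' scatter around the global one; their dispersion is what SDI and L-E
#' summarise and what the STV areas weight by displaced volume.
#'
#' @param curve_set A [curve_set()].
#' @return Object of class `es_table`: a data.frame with columns `segment`,
#'   `es_time` (%RR), `es_volume` (ml) and attributes `global_es_time`,
#'   `global_es_volume`.
#' @export
end_systole_table <- function(curve_set) {
  stopifnot(inherits(curve_set, "curve_set"))
  ges <- find_end_systole(global_curve(curve_set))
  seg <- lapply(lv_segments(), function(s)
    find_end_systole(segment_curve(curve_set, s)))
  out <- data.frame(
    segment = lv_segments(),
    es_time = vapply(seg, `[[`, numeric(1), "time"),
    es_volume = vapply(seg, `[[`, numeric(1), "volume"),
    stringsAsFactors = FALSE)
  attr(out, "global_es_time") <- ges$time
  attr(out, "global_es_volume") <- ges$volume
  class(out) <- c("es_table", "data.frame")
  out
}

#' @export
print.es_table <- function(x, ...) {
  cat(sprintf("Global end-systole: t = %.2f %%RR, V = %.2f ml\n",
              attr(x, "global_es_time"), attr(x, "global_es_volume")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
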
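# shared fixtures, built in code

# fully synchronous noiseless ventricle
synchronous_study <- function(n_samples = 201L) {
  simulate_study(study_params(delays = 0, noise_sd = 0,
                              n_samples = n_samples))
}

# random valid noiseless study with mixed early/late delays
random_study <- function(noise_sd = 0, waveform = "raised_cosine",
                         n_samples = 201L) {
  n_delayed <- sample(2:8, 1)
  delays <- numeric(16)
  delays[sample(16, n_delayed)] <- runif(n_delayed, -30, 30)
  simulate_study(study_params(
    delays = delays,
    v_min = 9.1 * segment_size_weights() * runif(16, 0.8, 1.2),
    amplitude = 2.8 * segment_size_weights() * runif(16, 0.5, 1.5),
    noise_sd = noise_sd, waveform = waveform, n_samples = n_samples))
}

# one early segment against 15 sharply synchronous ones; glob ES pinned at 40
single_early_study <- function(k = 1, delay = -25, base_amp = 1,
                               n_samples = 201L) {
  simulate_study(study_params(
    delays = c(delay, rep(0, 15)),
    v_min = 9,
    amplitude = c(k * base_amp, rep(8.4, 15)),
    noise_sd = 0, n_samples = n_samples))
}

# independent AUC oracle: exhaustive concordant-pair count, ties half
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# dense Riemann-sum oracle for a segment's STV area on the
# piecewise-linear interpolated curve
riemann_stv_area <- function(curve, t_seg_es, v_seg_min, t_glob_es,
                             n_sub = 1e4) {
  lo <- min(t_seg_es, t_glob_es)
  hi <- max(t_seg_es, t_glob_es)
  if (hi - lo == 0) return(0)
  h <- (hi - lo) / n_sub
  mids <- lo + (seq_len(n_sub) - 0.5) * h
  v <- stats::approx(curve$times, curve$volumes, xout = mids)$y
  sum(pmax(v - v_seg_min, 0)) * h
}
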
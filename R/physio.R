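# Cardiac and respiratory signal extraction from pilot-tone records.
#
# Physiologically plausible frequency bands: cardiac 0.5-3.0 Hz (30-180 bpm)
# and respiratory 0.05-0.7 Hz (3-42 breaths/min).
CARDIAC_BAND <- c(0.5, 3.0)
RESP_BAND <- c(0.05, 0.7)

# One-sided periodogram. Returns freq (Hz) and power.
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2 / n
  k <- seq_len(floor(n / 2))
  list(freq = (k - 1) * fs / n, power = p[k])
}

# Fraction of spectral power inside a band, and the in-band peak frequency.
band_stats <- function(x, fs, band) {
  pg <- periodogram(x, fs)
  inb <- pg$freq >= band[1] & pg$freq <= band[2]
  tot <- sum(pg$power[pg$freq > 0])
  if (tot == 0 || !any(inb)) return(list(fraction = 0, peak = NA_real_))
  list(fraction = sum(pg$power[inb]) / tot,
       peak = pg$freq[inb][which.max(pg$power[inb])])
}

# Zero-phase Butterworth filter with reflection padding against edge
# transients. type: "pass" needs w = c(lo, hi); "low" needs scalar w (Hz).
zero_phase_filter <- function(x, fs, w, type = c("pass", "low")) {
  type <- match.arg(type)
  nyq <- fs / 2
  w <- pmin(pmax(w / nyq, 1e-4), 0.99)
  flt <- if (type == "pass") signal::butter(2, w, type = "pass") else
    signal::butter(2, w, type = "low")
  npad <- min(length(x) - 1, ceiling(3 * fs))
  xp <- c(rev(x[seq_len(npad) + 1]), x, rev(x[length(x) - seq_len(npad)]))
  y <- signal::filtfilt(flt, xp)
  y[npad + seq_along(x)]
}

# Symmetric FastICA (tanh nonlinearity) on whitened data X (samples x comps).
# Deterministic given the seed. Returns the estimated sources (same shape).
fastica_sources <- function(X, seed = 1L, max_iter = 200, tol = 1e-6) {
  k <- ncol(X)
  n <- nrow(X)
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- X %*% t(W)          # n x k sources
    g <- tanh(WX)
    gp <- 1 - g^2
    W1 <- t(g) %*% X / n - diag(colMeans(gp), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  X %*% t(W)
}

#' Extract the cardiac signal from a pilot-tone record
#'
#' Principal component analysis (keeping at most 8 components) followed by
#' independent component analysis; the independent component with the
#' dominant spectral peak inside the cardiac band (0.5-3 Hz) is selected and
#' band-pass filtered around its peak frequency (+/- 0.3 Hz, zero phase).
#' The polarity is canonicalized so that the sharper extrema of the raw
#' component - the family used as triggers - are minima.
#'
#' @param pt pilot-tone record (list with `data` channels x time and `fs`),
#'   or a plain channel x time matrix.
#' @param fs sampling rate (Hz); taken from `pt$fs` when missing.
#' @param seed seed for the ICA initialization.
#' @return numeric cardiac series (unit variance) with attributes `fs` and
#'   `peak_hz`.
#' @export
extract_cardiac_signal <- function(pt, fs = NULL, seed = 1L) {
  data <- if (is.list(pt)) pt$data else pt
  fs <- fs %||% pt$fs
  if (nrow(data) < 2) stopf("need at least 2 pilot-tone channels")
  nt <- ncol(data)
  if (nt / fs < 10) stopf("pilot-tone record shorter than 10 s")

  pc <- prcomp(t(data), center = TRUE, scale. = FALSE)
  k <- min(8L, ncol(pc$x), qr(data)$rank)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  white <- scale(scores)  # unit-variance PCs: whitened input for ICA
  src <- fastica_sources(white, seed = seed)

  stats <- apply(src, 2, band_stats, fs = fs, band = CARDIAC_BAND)
  frac <- vapply(stats, `[[`, numeric(1), "fraction")
  best <- which.max(frac)
  if (frac[best] < 0.2) {
    stopf("no independent component with a dominant cardiac-band (%.1f-%.1f Hz) peak",
          CARDIAC_BAND[1], CARDIAC_BAND[2])
  }
  comp <- src[, best]
  peak <- stats[[best]]$peak

  # polarity: sharper extremum family (larger curvature magnitude) -> minima.
  # Decided on the component limited to the full cardiac band, where the
  # waveform asymmetry survives but out-of-band noise does not.
  cb <- zero_phase_filter(comp, fs, CARDIAC_BAND, "pass")
  d2 <- diff(cb, differences = 2)
  interior <- 2:(nt - 1)
  is_min <- cb[interior] < cb[interior - 1] & cb[interior] <= cb[interior + 1]
  is_max <- cb[interior] > cb[interior - 1] & cb[interior] >= cb[interior + 1]
  curv_min <- mean(abs(d2[is_min]), na.rm = TRUE)
  curv_max <- mean(abs(d2[is_max]), na.rm = TRUE)
  sign_fix <- if (isTRUE(curv_max > curv_min)) -1 else 1
  comp <- sign_fix * comp

  lo <- max(CARDIAC_BAND[1], peak - 0.3)
  hi <- min(CARDIAC_BAND[2], peak + 0.3)
  out <- zero_phase_filter(comp, fs, c(lo, hi), "pass")
  out <- out / sd(out)
  attr(out, "fs") <- fs
  attr(out, "peak_hz") <- peak
  out
}

#' Detect cardiac triggers
#'
#' Interior local minima of the cardiac signal with a refractory spacing of
#' at least half the dominant cardiac period; minima positions are refined
#' to sub-sample precision by parabolic interpolation.
#'
#' @param cardiac cardiac series (e.g. from [extract_cardiac_signal()]).
#' @param fs sampling rate (Hz); defaults to the series' `fs` attribute.
#' @param t0 time of the first sample (s) on the shared clock.
#' @return numeric vector of trigger times (s), strictly increasing; empty
#'   (with a warning) for a constant signal.
#' @export
detect_triggers <- function(cardiac, fs = NULL, t0 = 0) {
  fs <- fs %||% attr(cardiac, "fs")
  x <- as.numeric(cardiac)
  n <- length(x)
  if (n == 0) stopf("empty cardiac series")
  if (max(x) - min(x) <= 0) {
    warnf("constant cardiac signal: no triggers detected")
    return(numeric(0))
  }
  peak <- attr(cardiac, "peak_hz") %||% band_stats(x, fs, CARDIAC_BAND)$peak
  if (is.na(peak) || peak <= 0) peak <- 1
  refractory <- 0.5 / peak

  interior <- 2:(n - 1)
  cand <- interior[x[interior] < x[interior - 1] & x[interior] <= x[interior + 1]]
  if (length(cand) == 0) return(numeric(0))
  # greedy: deepest minima first, enforce refractory spacing
  cand <- cand[order(x[cand])]
  keep <- numeric(0)
  for (i in cand) {
    if (all(abs(i - keep) >= refractory * fs)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # parabolic sub-sample refinement
  a <- x[keep - 1]; b <- x[keep]; c <- x[keep + 1]
  denom <- a - 2 * b + c
  frac <- ifelse(abs(denom) > 1e-12, 0.5 * (a - c) / denom, 0)
  frac <- pmin(pmax(frac, -0.5), 0.5)
  t0 + (keep - 1 + frac) / fs
}

#' Extract the unitless respiratory curve
#'
#' Principal component with dominant power in the respiratory band
#' (0.05-0.7 Hz), adaptively low-pass filtered (cut-off at 2.5x the
#' component's spectral peak, capped at the band edge), then linearly
#' detrended per sequence: each side of the inter-sequence gap gets its own
#' fitted line, removing drift and the step offset between the two
#' acquisitions in one deterministic regression. The output polarity places
#' the longer plateau (end-expiration) at negative values and the curve is
#' scaled to unit maximum absolute amplitude.
#'
#' @param pt pilot-tone record or channel x time matrix.
#' @param fs sampling rate (Hz).
#' @param gap_time optional time (s) of the inter-sequence gap.
#' @return numeric curve r(t) in `[-1, 1]` with attributes `t` and `fs`.
#' @export
extract_respiratory_curve <- function(pt, fs = NULL, gap_time = NULL) {
  data <- if (is.list(pt)) pt$data else pt
  fs <- fs %||% pt$fs
  if (is.list(pt) && is.null(gap_time)) gap_time <- pt$gap_time
  nt <- ncol(data)
  t <- (seq_len(nt) - 1) / fs

  pc <- prcomp(t(data), center = TRUE, scale. = FALSE)
  k <- min(8L, ncol(pc$x))
  stats <- apply(pc$x[, seq_len(k), drop = FALSE], 2, band_stats,
                 fs = fs, band = RESP_BAND)
  frac <- vapply(stats, `[[`, numeric(1), "fraction")
  best <- which.max(frac)
  if (frac[best] < 0.2) {
    stopf("no principal component with dominant respiratory-band (%.2f-%.1f Hz) power",
          RESP_BAND[1], RESP_BAND[2])
  }
  comp <- pc$x[, best]
  peak <- stats[[best]]$peak
  cutoff <- min(2.5 * peak, RESP_BAND[2])
  r <- zero_phase_filter(comp, fs, cutoff, "low")

  # per-sequence linear detrend: each side of the gap gets its own fitted
  # line (slope and intercept), which removes both drift and the
  # inter-sequence step offset in one deterministic regression
  detrend <- function(idx) {
    if (length(idx) < 3) return(r[idx] - mean(r[idx]))
    fit <- lm(r[idx] ~ t[idx])
    r[idx] - fitted(fit)
  }
  if (!is.null(gap_time) && gap_time > t[1] && gap_time < t[nt]) {
    pre <- which(t <= gap_time)
    post <- which(t > gap_time)
    r[pre] <- detrend(pre)
    r[post] <- detrend(post)
  } else {
    r <- detrend(seq_len(nt))
  }

  # polarity: end-expiratory plateau (longer dwell) at negative values
  if (median(r) > 0) r <- -r
  r <- r / max(abs(r))
  attr(r, "t") <- t
  attr(r, "fs") <- fs
  r
}

# Resample a respiratory curve (with its `t` attribute) at arbitrary times.
resp_at_times <- function(r, times) {
  approx(attr(r, "t"), as.numeric(r), xout = times, rule = 2)$y
}

#' Assign readouts to cardiac phases
#'
#' Linear intra-beat phase: for a timestamp in the trigger interval
#' `[T_k, T_{k+1})` the phase index is `floor((t - T_k) / (T_{k+1} - T_k) *
#' P)` clipped to `P - 1`. Timestamps before the first or after the last
#' trigger are flagged as discarded (`NA`).
#'
#' @param t numeric timestamps (s).
#' @param triggers strictly increasing trigger times (>= 2).
#' @param n_phases number of cardiac phases P (default 20).
#' @return integer vector of phase indices in `0..P-1`, `NA` where
#'   discarded.
#' @export
assign_cardiac_phase <- function(t, triggers, n_phases = 20L) {
  if (length(triggers) < 2) stopf("need at least 2 triggers")
  if (any(diff(triggers) <= 0)) stopf("triggers must be strictly increasing")
  P <- as.integer(n_phases)
  if (P < 1) stopf("n_phases must be >= 1")
  idx <- findInterval(t, triggers)
  ok <- idx >= 1 & idx < length(triggers) & t >= triggers[1]
  phase <- rep(NA_integer_, length(t))
  i <- idx[ok]
  frac <- (t[ok] - triggers[i]) / (triggers[i + 1] - triggers[i])
  phase[ok] <- pmin(as.integer(floor(frac * P)), P - 1L)
  phase
}

#' Build a physiological record for a session
#'
#' Runs cardiac and respiratory extraction once on the pilot-tone record
#' shared by the two back-to-back acquisitions, so the derived triggers and
#' respiratory curve live on a single clock common to both readout
#' schedules.
#'
#' @param pt shared pilot-tone record.
#' @param gap_time inter-sequence gap time (s).
#' @param seed ICA seed.
#' @return list of class `physio_record` with `cardiac_signal`,
#'   `trigger_times`, `resp_curve`, `fs`.
#' @export
make_physio_record <- function(pt, gap_time = NULL, seed = 1L) {
  cardiac <- extract_cardiac_signal(pt, seed = seed)
  triggers <- detect_triggers(cardiac)
  resp <- extract_respiratory_curve(pt, gap_time = gap_time)
  structure(list(cardiac_signal = cardiac, trigger_times = triggers,
                 resp_curve = resp, fs = pt$fs, gap_time = gap_time),
            class = "physio_record")
}
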
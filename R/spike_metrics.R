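#' Ensemble firing rate
#'
#' Total spike count divided by total observed time, i.e. the time- and
#' ensemble-averaged rate of the summed spike train
#' \eqn{y(t) = \sum_i \delta(t - t_i)}.
#'
#' @param trains a [spike_train()] or a list of them.
#' @return Firing rate in spikes/ms.
#' @export
firing_rate <- function(trains) {
  trains <- as_train_list(trains)
  total_t <- sum(vapply(trains, function(tr) tr$duration, 1))
  if (total_t <= 0) stop("zero total observation time")
  sum(vapply(trains, function(tr) length(tr$times), 1L)) / total_t
}

as_train_list <- function(trains) {
  if (inherits(trains, "spike_train")) return(list(trains))
  stopifnot("expected spike_train objects" =
              all(vapply(trains, inherits, TRUE, "spike_train")))
  trains
}

pooled_spike_times <- function(trains) {
  unlist(lapply(as_train_list(trains), function(tr) tr$times),
         use.names = FALSE)
}

#' Empirical phase density of spikes relative to a sinusoid
#'
#' Maps each spike time to the phase \eqn{\psi_i = t_i \bmod T} of the
#' driving sinusoid (period \eqn{T = 1/\varphi}, phase expressed in time
#' units) and histograms the phases, normalized to a probability density on
#' `[0, T)` -- the cycle histogram.
#'
#' @param trains spike train(s).
#' @param phi sinusoid frequency (cycles/ms), > 0.
#' @param n_bins number of equal-width bins (default 50).
#' @return Object of class `"phase_histogram"` with `bin_edges`, `density`,
#'   `counts`, `n_spikes`, `phi`. With zero spikes the histogram is returned
#'   empty with `empty = TRUE`.
#' @export
empirical_phase_density <- function(trains, phi, n_bins = 50) {
  stopifnot("phi must be > 0" = phi > 0, n_bins >= 1)
  T_per <- 1 / phi
  psi <- pooled_spike_times(trains) %% T_per
  edges <- seq(0, T_per, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(psi, edges), n_bins), nbins = n_bins)
  n <- length(psi)
  structure(list(bin_edges = edges,
                 density = if (n > 0) counts / (n * diff(edges)) else
                   rep(0, n_bins),
                 counts = counts, n_spikes = n, phi = phi, empty = n == 0),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("phase histogram: %d spikes, %d bins on [0, %g) ms%s\n",
              x$n_spikes, length(x$counts), 1 / x$phi,
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Vector strength (phase locking)
#'
#' Resultant length of the spike phases on the unit circle,
#' \deqn{r = \left|\left(\int_0^T p(\psi)\cos(2\pi\varphi\psi)d\psi,\;
#'   \int_0^T p(\psi)\sin(2\pi\varphi\psi)d\psi\right)\right| \in [0, 1].}
#' For spike trains the sum of unit vectors over the raw phases is used
#' (free of binning bias); for a [empirical_phase_density()] histogram or a
#' gridded density the integrals are evaluated by quadrature. Values are
#' clipped to `[0, 1]` only against floating-point boundary error.
#'
#' @param x spike train(s), a `"phase_histogram"`, a `"phase_density"`
#'   (see [phase_density_fixed_point()]), or a numeric vector of density
#'   values on a uniform grid `psi`.
#' @param phi sinusoid frequency; taken from `x` when it carries one.
#' @param psi grid of phase values when `x` is a bare numeric density.
#' @return `r` in `[0, 1]`.
#' @examples
#' tr <- spike_train(c(0, 10, 20, 30), 40)    # perfectly locked at phi = 0.1
#' vector_strength(tr, phi = 0.1)
#' @export
vector_strength <- function(x, phi = NULL, psi = NULL) {
  UseMethod("vector_strength")
}

#' @export
vector_strength.spike_train <- function(x, phi = NULL, psi = NULL) {
  vector_strength(list(x), phi = phi)
}

#' @export
vector_strength.list <- function(x, phi = NULL, psi = NULL) {
  stopifnot("phi must be supplied for spike trains" = !is.null(phi), phi > 0)
  times <- pooled_spike_times(x)
  if (length(times) == 0) return(0)
  clip01(Mod(mean(exp(2i * pi * phi * times))))
}

#' @export
vector_strength.phase_histogram <- function(x, phi = NULL, psi = NULL) {
  if (x$empty) return(0)
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  r_from_density(x$density, mid, x$phi, diff(x$bin_edges)[1])
}

#' @export
vector_strength.phase_density <- function(x, phi = NULL, psi = NULL) {
  r_from_density(x$p, x$psi, x$phi, x$psi[2] - x$psi[1])
}

#' @export
vector_strength.numeric <- function(x, phi = NULL, psi = NULL) {
  stopifnot(!is.null(phi), !is.null(psi), length(x) == length(psi))
  r_from_density(x, psi, phi, psi[2] - psi[1])
}

# rectangle quadrature on a uniform (periodic) phase grid
r_from_density <- function(p, psi, phi, dpsi) {
  mass <- sum(p) * dpsi
  if (abs(mass - 1) > 1e-3)
    stop(sprintf("density not normalized (integral = %.6f)", mass))
  clip01(Mod(sum(p * exp(2i * pi * phi * psi)) * dpsi))
}

clip01 <- function(r) min(max(r, 0), 1)

#' Rate-weighted phase locking
#'
#' The scalar coding measure `q = nu * r`: a signal is well encoded when the
#' response is both dense in time (high firing rate `nu`) and phase locked
#' (high vector strength `r`).
#'
#' @param nu firing rate (>= 0).
#' @param r vector strength in `[0, 1]`.
#' @return `q = nu * r`.
#' @export
q_value <- function(nu, r) {
  stopifnot(nu >= 0, r >= -1e-12, r <= 1 + 1e-12)
  nu * clip01(r)
}

sta_result_empty <- function(lag) {
  new_sta_result(lag, rep(NA_real_, length(lag)), 0L)
}

new_sta_result <- function(lag, average, n_spikes) {
  structure(list(lag = lag, average = average,
                 n_spikes = as.integer(n_spikes),
                 empty = n_spikes == 0),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("spike-triggered average over %d spikes, lags [%g, %g] ms%s\n",
              x$n_spikes, min(x$lag), max(x$lag),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Spike-triggered average of the injected noise
#'
#' Lag-aligned mean of the recorded noise path over all spikes with at least
#' `window[1]` ms of history and `window[2]` ms of future inside the record:
#' the mean input waveform around a spike,
#' \eqn{\langle \xi(t) | t_{spike} = 0\rangle}. For long runs prefer the
#' online accumulation in [simulate_fn()] (`sta_window=`), which computes the
#' identical quantity without storing the noise path.
#'
#' @param noise noise matrix (`steps x cells`) from [simulate_fn()] with
#'   `record_noise = TRUE`, in units of `xi` (increments / sqrt(dt)).
#' @param trains list of [spike_train()], one per noise column.
#' @param window `c(pre_ms, post_ms)` extent of the lag axis.
#' @param dt sample spacing of the noise path (ms).
#' @return `"sta_result"` with `lag` (ms, negative = before the spike),
#'   `average`, and `n_spikes`; flagged `empty` when no spike qualifies.
#'   `scale_to_max(sta)` gives the peak-normalized copy used when comparing
#'   model variants.
#' @export
spike_triggered_average <- function(noise, trains, window = c(100, 20), dt) {
  stopifnot(is.matrix(noise), length(window) == 2, all(window >= 0), dt > 0)
  trains <- as_train_list(trains)
  stopifnot("one spike train per noise column" =
              length(trains) == ncol(noise))
  n_pre <- round(window[1] / dt)
  n_post <- round(window[2] / dt)
  lag <- seq(-n_pre, n_post) * dt
  acc <- numeric(n_pre + n_post + 1)
  n_used <- 0L
  n_steps <- nrow(noise)
  for (c in seq_along(trains)) {
    for (t_sp in trains[[c]]$times) {
      j <- floor(t_sp / dt) + 1          # step during which w crossed w_c
      if (j - n_pre >= 1 && j + n_post <= n_steps) {
        acc <- acc + noise[(j - n_pre):(j + n_post), c]
        n_used <- n_used + 1L
      }
    }
  }
  if (n_used == 0) return(sta_result_empty(lag))
  new_sta_result(lag, acc / n_used, n_used)
}

#' @rdname spike_triggered_average
#' @param sta an `"sta_result"`.
#' @export
scale_to_max <- function(sta) {
  stopifnot(inherits(sta, "sta_result"), !sta$empty)
  sta$average <- sta$average / max(sta$average)
  sta
}

#' Averaged-periodogram power spectrum
#'
#' Welch estimate: the record is split into segments of `segment_length`
#' samples with 50% overlap, each segment is demeaned, tapered with a Hann
#' (cosine) window and periodogram-averaged. The one-sided density is
#' normalized so that `sum(power) * df` equals the signal variance
#' (Parseval).
#'
#' @param x numeric record, or an `"fn_trajectory"` (spectra of each cell's
#'   `v(t)` are averaged).
#' @param segment_length samples per segment (default: record length / 8,
#'   rounded to a power of two).
#' @param dt sample spacing (ms); taken from a trajectory object.
#' @return `"spectrum_estimate"` with `freq` (cycles/ms), `power`,
#'   `n_segments`, `df`.
#' @export
power_spectrum_v <- function(x, segment_length = NULL, dt = NULL) {
  if (inherits(x, "fn_trajectory")) {
    stopifnot("trajectory has no recorded v" = !is.null(x$v))
    specs <- lapply(seq_len(ncol(x$v)), function(c)
      power_spectrum_v(x$v[, c], segment_length, x$dt))
    out <- specs[[1]]
    if (length(specs) > 1) {
      out$power <- rowMeans(vapply(specs, `[[`, out$power, "power"))
      out$n_segments <- sum(vapply(specs, `[[`, 1L, "n_segments"))
    }
    return(out)
  }
  stopifnot(is.numeric(x), !is.null(dt), dt > 0)
  n <- length(x)
  if (is.null(segment_length))
    segment_length <- 2^floor(log2(max(n / 8, 64)))
  L <- segment_length
  if (L > n) stop("segment_length exceeds the record length")
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann taper
  wnorm <- sum(win^2)
  fs <- 1 / dt
  half <- floor(L / 2) + 1
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(fft(seg))^2 / (fs * wnorm)
    p1 <- P[seq_len(half)]
    if (L %% 2 == 0) p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
    else p1[2:half] <- 2 * p1[2:half]
    acc <- acc + p1
  }
  structure(list(freq = (seq_len(half) - 1) * fs / L,
                 power = acc / length(starts),
                 n_segments = length(starts), df = fs / L),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("Welch spectrum: %d segments, df = %g cycles/ms\n",
              x$n_segments, x$df))
  invisible(x)
}

#' Pseudo-Gaussian smoothing
#'
#' Three successive centered moving averages of width `width` samples --
#' a boxcar cascade whose kernel converges to a Gaussian shape. Length is
#' preserved; near the edges the window shrinks symmetrically so constant
#' inputs pass through unchanged.
#'
#' @param x numeric vector on a uniform grid.
#' @param width moving-average width in samples (>= 1; even widths are
#'   rounded up to the next odd value).
#' @return Smoothed vector of the same length.
#' @export
smooth_signal <- function(x, width) {
  stopifnot(is.numeric(x), width >= 1)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  if (width > length(x)) stop("width exceeds the record length")
  h <- (width - 1L) %/% 2L
  for (pass in 1:3) x <- moving_average(x, h)
  x
}

# centered moving average with symmetric edge shrink, O(n) via cumsum
moving_average <- function(x, h) {
  if (h == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  hh <- pmin(i - lo, hi - i)      # symmetric shrink at the edges
  (cs[i + hh + 1] - cs[i - hh]) / (2 * hh + 1)
}
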
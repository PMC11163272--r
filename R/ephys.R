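#' Extracellular recording container
#'
#' A single-channel voltage trace (arbitrary units) with its sampling rate.
#' The rate must exceed 12 kHz so that the default 300-6000 Hz analysis band
#' sits below Nyquist.
#'
#' @param samples numeric vector of voltage samples.
#' @param rate sampling rate in samples/s (default 20000).
#' @return An object of class `recording` with elements `samples` and `rate`.
#' @export
recording <- function(samples, rate = 20000) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 12000) {
    stop("rate must be a single number > 12000 samples/s")
  }
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, duration_s(x)))
  invisible(x)
}

#' @rdname recording
#' @param rec a `recording`.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$rate

#' Spike-train analysis configuration
#'
#' Defaults follow the standard extracellular workflow: 300-6000 Hz
#' zero-phase band-pass, detection at 5 standard deviations from the mean on
#' negative deflections, 1-ms refractory separation, waveforms cut 0.6 ms
#' before to 1.0 ms after the trough, 1-ms rasters, autocorrelogram lags
#' 1-50 ms (required by the burstiness index), and the 440-microsecond
#' trough-to-peak boundary between putative interneurons and putative
#' pyramidal neurons.
#'
#' @param band band-pass edges in Hz.
#' @param detect_sd detection threshold in standard deviations.
#' @param polarity `"neg"` (threshold `mean - k*sd`, extracellular
#'   convention) or `"abs"` (absolute deviation above the mean).
#' @param refractory_ms minimum separation between detected events.
#' @param wf_pre_ms,wf_post_ms waveform window around the trough.
#' @param raster_bin_ms raster resolution.
#' @param acg_max_lag_ms autocorrelogram maximum lag (50 for the burstiness
#'   index).
#' @param pyr_ttp_us trough-to-peak boundary in microseconds; strictly
#'   greater is putative pyramidal.
#' @param filter_order Butterworth section order of the band-pass.
#' @param subsample_refine parabolic sub-sample refinement of waveform
#'   extrema?
#' @return An `ephys_config` list.
#' @export
ephys_config <- function(band = c(300, 6000), detect_sd = 5,
                         polarity = c("neg", "abs"), refractory_ms = 1,
                         wf_pre_ms = 0.6, wf_post_ms = 1.0,
                         raster_bin_ms = 1, acg_max_lag_ms = 50L,
                         pyr_ttp_us = 440, filter_order = 3L,
                         subsample_refine = TRUE) {
  if (detect_sd <= 0) stop("detect_sd must be > 0")
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid band")
  structure(list(band = band, detect_sd = detect_sd,
                 polarity = match.arg(polarity),
                 refractory_ms = refractory_ms,
                 wf_pre_ms = wf_pre_ms, wf_post_ms = wf_post_ms,
                 raster_bin_ms = raster_bin_ms,
                 acg_max_lag_ms = as.integer(acg_max_lag_ms),
                 pyr_ttp_us = pyr_ttp_us,
                 filter_order = as.integer(filter_order),
                 subsample_refine = isTRUE(subsample_refine)),
            class = "ephys_config")
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the output is zero-phase and the DC component
#' is removed. Length is preserved.
#'
#' @param rec a [recording()].
#' @param cfg an [ephys_config()].
#' @return A filtered `recording`.
#' @export
bandpass_filter <- function(rec, cfg = ephys_config()) {
  ny <- rec$rate / 2
  if (cfg$band[2] >= ny) {
    stop("upper band edge must be below the Nyquist frequency")
  }
  bf <- signal::butter(cfg$filter_order, cfg$band / ny, type = "pass")
  recording(signal::filtfilt(bf, rec$samples), rec$rate)
}

#' Threshold spike detection
#'
#' Events are detected where the (filtered) trace deviates from its mean by
#' more than `detect_sd` standard deviations — on negative deflections by
#' default, or in absolute value with `polarity = "abs"`. Each
#' threshold-crossing segment is aligned to its extremum and events closer
#' than the refractory period to the previously kept event are dropped. A
#' zero-variance trace yields an empty result with a warning.
#'
#' @param rec a (band-passed) [recording()].
#' @param cfg an [ephys_config()].
#' @return Numeric vector of spike times in ms (strictly increasing).
#' @export
detect_spikes <- function(rec, cfg = ephys_config()) {
  x <- rec$samples
  if (!length(x)) return(numeric(0))
  mu <- mean(x)
  sdv <- sd(x)
  if (is.na(sdv) || sdv == 0) {
    warning("zero-variance signal: no spikes detectable")
    return(numeric(0))
  }
  dev <- switch(cfg$polarity, neg = mu - x, abs = abs(x - mu))
  above <- dev > cfg$detect_sd * sdv
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values)
  peaks <- vapply(seg, function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(dev[idx])]
  }, 1L)
  times <- (peaks - 1L) * 1000 / rec$rate
  # refractory: greedy in time order
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= cfg$refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Extract spike waveforms
#'
#' Cuts a window of `wf_pre_ms` before to `wf_post_ms` after each spike time
#' from the trace. Spikes too close to the recording edges are dropped; the
#' retained indices are available via the `kept` attribute.
#'
#' @param rec a [recording()].
#' @param times_ms spike times in ms (e.g. from [detect_spikes()]).
#' @param cfg an [ephys_config()].
#' @return Matrix (spikes x samples) with attribute `kept`.
#' @export
extract_waveforms <- function(rec, times_ms, cfg = ephys_config()) {
  pre <- round(cfg$wf_pre_ms * rec$rate / 1000)
  post <- round(cfg$wf_post_ms * rec$rate / 1000)
  centre <- round(times_ms * rec$rate / 1000) + 1L
  kept <- which(centre - pre >= 1L & centre + post <= length(rec$samples))
  wf <- t(vapply(centre[kept],
                 function(i) rec$samples[(i - pre):(i + post)],
                 numeric(pre + post + 1L)))
  attr(wf, "kept") <- kept
  wf
}

#' Cluster spike waveforms
#'
#' k-means on the leading principal components of the waveform matrix.
#' Seeded and deterministic for a fixed seed. If fewer than `k` distinct
#' waveforms exist the split is degenerate and an arbitrary deterministic
#' labelling is returned.
#'
#' @param waveforms matrix (spikes x samples).
#' @param k number of clusters (2 <= k <= number of waveforms).
#' @param seed RNG seed.
#' @param n_pcs number of principal components used.
#' @return Integer cluster labels, one per waveform.
#' @export
cluster_waveforms <- function(waveforms, k, seed = 1L, n_pcs = 3L) {
  n <- nrow(waveforms)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= number of waveforms")
  if (nrow(unique(waveforms)) < k) {
    return(rep_len(seq_len(k), n))  # degenerate: any split is acceptable
  }
  pc <- prcomp(waveforms, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  if (nrow(unique(sc)) < k) return(rep_len(seq_len(k), n))
  with_seed(seed, kmeans(sc, centers = k, nstart = 10L,
                         iter.max = 100L)$cluster)
}

# parabolic vertex refinement around sample i; returns fractional index
refine_extremum <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(i)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(i)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  i + max(-0.5, min(0.5, off))
}

#' Trough-to-peak duration
#'
#' Time from the waveform's global trough to the subsequent peak (the
#' maximum after the trough, required to be an interior local maximum), in
#' microseconds. With `refine = TRUE` both extrema are refined to sub-sample
#' precision by parabolic interpolation; the result is reported to 0.1
#' microseconds. Flat or monotone waveforms (trough at the last sample or
#' peak at the boundary) are undefined and return `NA`.
#'
#' @param waveform numeric vector (a mean spike waveform).
#' @param rate sampling rate in samples/s.
#' @param refine parabolic sub-sample refinement?
#' @return Duration in microseconds, or `NA_real_` if undefined.
#' @export
trough_to_peak <- function(waveform, rate, refine = TRUE) {
  y <- as.numeric(waveform)
  if (length(y) < 3L || diff(range(y)) == 0) return(NA_real_)
  ti <- which.min(y)
  if (ti >= length(y)) return(NA_real_)
  pi <- ti + which.max(y[(ti + 1L):length(y)])
  if (pi >= length(y)) return(NA_real_)  # boundary max: no true peak
  tpos <- if (refine) refine_extremum(y, ti) else ti
  ppos <- if (refine) refine_extremum(y, pi) else pi
  round((ppos - tpos) * 1e6 / rate, 1)
}

#' Classify a unit by trough-to-peak duration
#'
#' Putative pyramidal neuron (`"pPYR"`) when the trough-to-peak duration is
#' strictly greater than the boundary (440 microseconds by default),
#' otherwise putative interneuron (`"pIN"`). Undefined durations are
#' `NA_character_` (unclassified).
#'
#' @param ttp_us trough-to-peak duration(s) in microseconds.
#' @param cfg an [ephys_config()].
#' @return Character vector of `"pPYR"`/`"pIN"`/`NA`.
#' @export
classify_unit <- function(ttp_us, cfg = ephys_config()) {
  ifelse(is.na(ttp_us), NA_character_,
         ifelse(ttp_us > cfg$pyr_ttp_us, "pPYR", "pIN"))
}

#' Binary spike raster
#'
#' 1-ms (by default) binary sequence: bin `floor(t / bin)` is set to one if
#' at least one spike falls in it; multiple spikes in a bin collapse to one.
#'
#' @param times_ms spike times in ms, within `[0, duration_ms)`.
#' @param duration_ms raster duration in ms.
#' @param bin_ms bin width in ms.
#' @return Integer 0/1 vector of length `ceiling(duration_ms / bin_ms)`.
#' @export
rasterize <- function(times_ms, duration_ms, bin_ms = 1) {
  if (length(times_ms) && (min(times_ms) < 0 || max(times_ms) >= duration_ms)) {
    stop("spike times must lie in [0, duration_ms)")
  }
  n <- ceiling(duration_ms / bin_ms)
  r <- integer(n)
  r[unique(floor(times_ms / bin_ms) + 1L)] <- 1L
  r
}

#' Firing rate and inter-spike intervals
#'
#' @param times_ms spike times in ms.
#' @param duration_s recording duration in seconds (> 0).
#' @return `firing_rate()`: spikes per second. `isi_ms()`: successive
#'   differences in ms (empty for fewer than two spikes).
#' @export
firing_rate <- function(times_ms, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  length(times_ms) / duration_s
}

#' @rdname firing_rate
#' @export
isi_ms <- function(times_ms) diff(times_ms)

#' Autocorrelogram of a binary raster
#'
#' Counts of coincidences `sum(r[t] * r[t + l])` for lags `l = 1..max_lag`
#' bins. The zero-lag bin (self-pairs) is excluded: it is uninformative and
#' would make the burstiness half-mass lag degenerate. A raster shorter than
#' `max_lag` is computed over the available lags with a warning.
#'
#' @param raster binary 0/1 vector (see [rasterize()]).
#' @param max_lag maximum lag in bins (50 for the burstiness index).
#' @return Named integer vector of counts for lags `1..max_lag`.
#' @export
autocorrelogram <- function(raster, max_lag = 50L) {
  n <- length(raster)
  if (n <= max_lag) {
    warning("raster shorter than max_lag; computing available lags only")
    max_lag <- n - 1L
  }
  lags <- seq_len(max_lag)
  counts <- vapply(lags, function(l) {
    sum(raster[seq_len(n - l)] * raster[(1L + l):n])
  }, 0)
  stats::setNames(as.integer(counts), lags)
}

#' Burstiness index
#'
#' `BI = (L - dt) / L` where `L` is the maximum lag (50 ms) and `dt` is the
#' smallest lag at which the cumulative autocorrelogram reaches half its
#' total (ties break toward smaller `dt`). `BI = 0.5` for a lag-uniform
#' autocorrelogram and approaches `(L - 1)/L = 0.98` when all mass sits at
#' lag 1. Undefined (`NA`, not zero) when the autocorrelogram is empty.
#'
#' @param acg autocorrelogram counts over lags `1..L` (see
#'   [autocorrelogram()]).
#' @return BI in `[0, (L-1)/L]` with attribute `delta_t`, or `NA` when
#'   undefined.
#' @export
burstiness <- function(acg) {
  L <- length(acg)
  total <- sum(acg)
  if (total == 0) {
    return(structure(NA_real_, delta_t = NA_integer_))
  }
  dt <- which(cumsum(acg) >= total / 2)[1]
  structure((L - dt) / L, delta_t = as.integer(dt))
}

#' Full spike-sorting and unit-metrics pipeline
#'
#' Band-pass filters the recording, detects spikes, clusters their waveforms
#' into `k` units and computes per-unit metrics: mean waveform,
#' trough-to-peak duration, class (pPYR/pIN), firing rate, inter-spike
#' intervals, autocorrelogram and burstiness index. Cluster labels may also
#' be supplied externally (e.g. after manual curation) via `labels`.
#'
#' @param rec a [recording()] (raw; set `filtered = TRUE` to skip the
#'   band-pass).
#' @param k number of units to cut.
#' @param cfg an [ephys_config()].
#' @param seed seed for the clustering stage.
#' @param filtered is `rec` already band-passed?
#' @param labels optional externally curated cluster labels (one per
#'   detected spike, after edge trimming); overrides the k-means stage.
#' @return A `spike_sorting` object: list with `units` (list of
#'   `sorted_unit`), `spike_times`, `labels`, `duration_s`, `config`.
#' @export
sort_units <- function(rec, k = 2L, cfg = ephys_config(), seed = 1L,
                       filtered = FALSE, labels = NULL) {
  if (!filtered) rec <- bandpass_filter(rec, cfg)
  times <- detect_spikes(rec, cfg)
  dur_s <- duration_s(rec)
  dur_ms <- dur_s * 1000
  if (!length(times)) {
    return(structure(list(units = list(), spike_times = times,
                          labels = integer(0), duration_s = dur_s,
                          config = cfg),
                     class = "spike_sorting"))
  }
  wf <- extract_waveforms(rec, times, cfg)
  times <- times[attr(wf, "kept")]
  if (is.null(labels)) {
    labels <- cluster_waveforms(wf, k, seed = seed)
  } else if (length(labels) != nrow(wf)) {
    stop("labels must have one entry per retained spike")
  }
  units <- lapply(sort(unique(labels)), function(j) {
    st <- times[labels == j]
    mw <- colMeans(wf[labels == j, , drop = FALSE])
    ttp <- trough_to_peak(mw, rec$rate, refine = cfg$subsample_refine)
    acg <- autocorrelogram(rasterize(st, dur_ms, cfg$raster_bin_ms),
                           cfg$acg_max_lag_ms)
    structure(list(unit = j, n_spikes = length(st), spike_times = st,
                   mean_waveform = mw, ttp_us = ttp,
                   unit_class = classify_unit(ttp, cfg),
                   firing_rate = firing_rate(st, dur_s),
                   isi = isi_ms(st), acg = acg,
                   burstiness = burstiness(acg)),
              class = "sorted_unit")
  })
  structure(list(units = units, spike_times = times, labels = labels,
                 duration_s = dur_s, config = cfg),
            class = "spike_sorting")
}

#' @export
print.sorted_unit <- function(x, ...) {
  cat(sprintf("<sorted_unit %s> %d spikes, %.2f Hz, ttp %.1f us, %s, BI %s\n",
              x$unit, x$n_spikes, x$firing_rate, x$ttp_us,
              ifelse(is.na(x$unit_class), "unclassified", x$unit_class),
              ifelse(is.na(x$burstiness), "undefined",
                     sprintf("%.2f", x$burstiness))))
  invisible(x)
}

#' @export
print.spike_sorting <- function(x, ...) {
  cat(sprintf("<spike_sorting> %d spikes in %.1f s, %d unit(s)\n",
              length(x$spike_times), x$duration_s, length(x$units)))
  if (length(x$units)) print(units_table(x))
  invisible(x)
}

#' Per-unit metrics table
#'
#' @param sorting a `spike_sorting` object from [sort_units()].
#' @return data.frame with one row per unit: `unit`, `n_spikes`,
#'   `firing_rate_hz`, `ttp_us`, `class`, `burstiness`.
#' @export
units_table <- function(sorting) {
  u <- sorting$units
  data.frame(unit = vapply(u, `[[`, 1L, "unit"),
             n_spikes = vapply(u, `[[`, 1L, "n_spikes"),
             firing_rate_hz = vapply(u, `[[`, 0, "firing_rate"),
             ttp_us = vapply(u, `[[`, 0, "ttp_us"),
             class = vapply(u, `[[`, "", "unit_class"),
             burstiness = vapply(u, function(z) as.numeric(z$burstiness), 0),
             stringsAsFactors = FALSE)
}

#' Read and write recordings
#'
#' Two plain interchange formats: single-column CSV (header optional), or
#' raw little-endian float32 binary with a `<path>.meta` sidecar of
#' `key=value` lines carrying at least `rate`.
#'
#' @param path file path; `.csv` selects the CSV format.
#' @param rate sampling rate; overrides (or replaces) the sidecar value.
#' @param rec a [recording()] to write.
#' @return `read_recording()`: a `recording`. `write_recording()`: `path`,
#'   invisibly.
#' @export
read_recording <- function(path, rate = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    v <- scan(path, what = double(), sep = "\n", quiet = TRUE,
              comment.char = "#")
    if (is.null(rate)) stop("rate is required for CSV recordings")
    return(recording(v, rate))
  }
  meta_path <- paste0(path, ".meta")
  if (is.null(rate)) {
    if (!file.exists(meta_path)) stop("no rate given and no sidecar ",
                                      meta_path)
    kv <- read.delim(meta_path, sep = "=", header = FALSE,
                     stringsAsFactors = FALSE, strip.white = TRUE)
    rate <- as.numeric(kv$V2[match("rate", kv$V1)])
    if (is.na(rate)) stop("sidecar lacks a 'rate' entry")
  }
  n <- file.size(path) / 4L
  recording(readBin(path, "numeric", n = n, size = 4L,
                    endian = "little"), rate)
}

#' @rdname read_recording
#' @param format `"bin"` (float32 + sidecar) or `"csv"`.
#' @export
write_recording <- function(rec, path, format = c("bin", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    writeLines(format(rec$samples, digits = 9), path)
  } else {
    writeBin(rec$samples, path, size = 4L, endian = "little")
    writeLines(c(sprintf("rate=%g", rec$rate), "channels=1"),
               paste0(path, ".meta"))
  }
  invisible(path)
}
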
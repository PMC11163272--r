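#' Random background sequence
#'
#' Draws an i.i.d. nucleotide string; `gc` sets the G+C fraction (split
#' evenly between G and C, and between A and T). Uses the current RNG
#' stream: wrap in a seeded plan (or [with_seed]-style caller) for
#' reproducibility.
#'
#' @param n length in nt.
#' @param gc G+C fraction (default 0.5 = uniform base composition).
#' @return Character scalar.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Synthetic transcriptome plan
#'
#' Describes a seeded random transcriptome with planted exact matches of
#' controlled lengths: each plant copies a centred `match_len`-nt substring
#' of `site` into a transcript and mutates the flanking bases so the match
#' cannot extend. For a guide `g`, plant its target site `revcomp(g)` to
#' create a `guide_match` of exactly `match_len` nt.
#'
#' @param seed RNG seed.
#' @param n_transcripts number of transcripts.
#' @param lengths transcript lengths in nt (recycled).
#' @param plants list of plants, each a list with `site` (`nuc_seq` or
#'   character), `match_len`, and optional `transcript` (index) and `pos`
#'   (0-based insertion offset); missing placements are drawn at random
#'   without overlap.
#' @param gc background G+C fraction.
#' @return A `transcriptome_plan` list.
#' @export
transcriptome_plan <- function(seed, n_transcripts, lengths,
                               plants = list(), gc = 0.5) {
  lengths <- rep_len(as.integer(lengths), n_transcripts)
  for (p in plants) {
    if (p$match_len > nchar(seq_str(p$site))) {
      stop("match_len exceeds the planted site length")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 lengths = lengths, plants = plants, gc = gc),
            class = "transcriptome_plan")
}

#' Generate a synthetic transcriptome with planted matches
#'
#' Pure function of its plan: the same plan yields byte-identical output.
#' Each plant is inserted as an exact substring of length `match_len` of its
#' site, with the transcript bases flanking the insertion forced to differ
#' from the adjacent site bases so the contiguous match length is exactly
#' `match_len` (up to coincidental background matches elsewhere, which for
#' match lengths >= 15 are vanishingly unlikely at these scales).
#'
#' @param plan a [transcriptome_plan()].
#' @return list with `seqs` (named list of `nuc_seq`, ids `tx1..txN`) and
#'   `truth` (data.frame: `site`, `match_len`, `transcript_id`, `pos`).
#' @export
make_transcriptome <- function(plan) {
  stopifnot(inherits(plan, "transcriptome_plan"))
  with_seed(plan$seed, {
    chs <- lapply(plan$lengths, function(n) {
      strsplit(random_dna(n, plan$gc), "", fixed = TRUE)[[1]]
    })
    occupied <- lapply(seq_len(plan$n_transcripts), function(i) integer(0))
    truth <- list()
    bases <- c("A", "C", "G", "T")
    for (p in plan$plants) {
      site <- canon_dna(p$site)
      L <- as.integer(p$match_len)
      ti <- if (!is.null(p$transcript)) p$transcript
            else sample.int(plan$n_transcripts, 1L)
      n <- length(chs[[ti]])
      if (L + 2L > n) stop("plant longer than transcript ", ti)
      sub_start <- (nchar(site) - L) %/% 2L + 1L
      sub <- strsplit(substr(site, sub_start, sub_start + L - 1L), "",
                      fixed = TRUE)[[1]]
      if (!is.null(p$pos)) {
        pos1 <- as.integer(p$pos) + 1L
        if (pos1 < 1L || pos1 + L - 1L > n) stop("plant does not fit")
      } else {
        repeat {
          pos1 <- sample.int(n - L - 1L, 1L) + 1L  # keep 1-nt margins
          span <- (pos1 - 1L):(pos1 + L)
          if (!length(intersect(span, occupied[[ti]]))) break
        }
      }
      chs[[ti]][pos1:(pos1 + L - 1L)] <- sub
      # break extension at the flanks
      if (sub_start > 1L && pos1 > 1L) {
        blocked <- substr(site, sub_start - 1L, sub_start - 1L)
        if (chs[[ti]][pos1 - 1L] == blocked) {
          chs[[ti]][pos1 - 1L] <- sample(setdiff(bases, blocked), 1L)
        }
      }
      right <- sub_start + L
      if (right <= nchar(site) && pos1 + L <= n) {
        blocked <- substr(site, right, right)
        if (chs[[ti]][pos1 + L] == blocked) {
          chs[[ti]][pos1 + L] <- sample(setdiff(bases, blocked), 1L)
        }
      }
      occupied[[ti]] <- c(occupied[[ti]], (pos1 - 1L):(pos1 + L))
      truth[[length(truth) + 1L]] <-
        data.frame(site = site, match_len = L,
                   transcript_id = paste0("tx", ti), pos = pos1 - 1L,
                   stringsAsFactors = FALSE)
    }
    seqs <- lapply(seq_along(chs), function(i) {
      nuc_seq(paste(chs[[i]], collapse = ""), id = paste0("tx", i))
    })
    names(seqs) <- paste0("tx", seq_along(chs))
    list(seqs = seqs,
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(site = character(), match_len = integer(),
                                 transcript_id = character(),
                                 pos = integer()))
  })
}

# sample() without the scalar-x pitfall
resample <- function(x) x[sample.int(length(x))]

# one consensus/GC/run-compliant 23-nt window by rejection sampling; windows
# whose +/-1-shifted frames would also pass using the planted bases alone are
# rejected too, since no mutation outside the plant could break those frames
random_compliant_window <- function(consensus, filters, max_tries = 10000L) {
  fixed <- lapply(consensus$fixed_positions, function(a) {
    strsplit(chartr("U", "T", a), "")[[1]]
  })
  wl <- consensus$window_len
  for (i in seq_len(max_tries)) {
    ch <- strsplit(random_dna(wl), "", fixed = TRUE)[[1]]
    for (p in names(fixed)) {
      ch[as.integer(p)] <- resample(fixed[[p]])[1]
    }
    w <- paste(ch, collapse = "")
    if (!validate_candidate(w, consensus, filters)$pass) next
    shift_r <- paste(c(ch[-1L], "A"), collapse = "")   # free base is inert
    shift_l <- paste(c("A", ch[-wl]), collapse = "")
    if (validate_candidate(shift_r, consensus, filters)$pass ||
        validate_candidate(shift_l, consensus, filters)$pass) next
    return(w)
  }
  stop("could not sample a compliant window in ", max_tries, " tries")
}

#' Generate a synthetic target gene with planted candidate sites
#'
#' Builds a seeded random background sequence, inserts `n_sites`
#' rule-compliant 23-nt windows at positions at least 23 nt apart, and then
#' mutates any other window that passes all filters by chance (always at a
#' base outside every planted window) until the scan recovers exactly the
#' planted windows.
#'
#' @param seed RNG seed.
#' @param length target length in nt.
#' @param n_sites number of planted compliant windows.
#' @param positions optional 0-based window starts (pairwise >= 23 apart);
#'   drawn at random when `NULL`.
#' @param consensus a [consensus_spec()].
#' @param filters a [filter_config()].
#' @param gc background G+C fraction.
#' @param max_fix_iter cap on the accidental-window cleanup loop.
#' @return list with `target` (a `nuc_seq`) and `truth` (data.frame:
#'   `window_start`, `window`, `sense21`).
#' @export
make_target_gene <- function(seed, length = 2000L, n_sites = 1L,
                             positions = NULL,
                             consensus = consensus_spec(),
                             filters = filter_config(), gc = 0.5,
                             max_fix_iter = 500L) {
  length <- as.integer(length)
  wl <- consensus$window_len
  if (!is.null(positions)) {
    positions <- sort(as.integer(positions))
    if (length(positions) != n_sites) stop("need one position per site")
    if (any(positions < 0L | positions + wl > length)) {
      stop("planted window outside the target")
    }
    if (n_sites > 1L && any(diff(positions) < wl)) {
      stop("planted windows overlap (must be >= ", wl, " nt apart)")
    }
  }
  with_seed(seed, {
    ch <- strsplit(random_dna(length, gc), "", fixed = TRUE)[[1]]
    if (is.null(positions)) {
      repeat {
        positions <- sort(sample.int(length - wl + 1L, n_sites) - 1L)
        if (n_sites < 2L || all(diff(positions) >= wl)) break
      }
    }
    windows <- character(n_sites)
    for (i in seq_len(n_sites)) {
      windows[i] <- random_compliant_window(consensus, filters)
      ch[(positions[i] + 1L):(positions[i] + wl)] <-
        strsplit(windows[i], "", fixed = TRUE)[[1]]
    }
    planted_span <- unlist(lapply(positions, function(p) (p + 1L):(p + wl)))
    bases <- c("A", "C", "G", "T")
    for (iter in seq_len(max_fix_iter)) {
      s <- paste(ch, collapse = "")
      got <- scan_candidates(nuc_seq(s, id = "target"), consensus, filters)
      extra <- setdiff(got$window_start, positions)
      if (!length(extra)) break
      w0 <- extra[1]
      free <- setdiff((w0 + 1L):(w0 + wl), planted_span)
      if (!length(free)) stop("accidental window overlaps all plants")
      # commit the first single-base change that breaks this window
      done <- FALSE
      for (pos in resample(free)) {
        for (b in resample(setdiff(bases, ch[pos]))) {
          trial <- ch[(w0 + 1L):(w0 + wl)]
          trial[pos - w0] <- b
          if (!validate_candidate(paste(trial, collapse = ""),
                                  consensus, filters)$pass) {
            ch[pos] <- b
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (!done) stop("no single-base change breaks an accidental window")
      if (iter == max_fix_iter) stop("cleanup loop did not converge")
    }
    target <- nuc_seq(paste(ch, collapse = ""), id = "target")
    off <- consensus$sense_offset
    list(target = target,
         truth = data.frame(window_start = positions, window = windows,
                            sense21 = substring(windows, off + 1L,
                                                off + 21L),
                            stringsAsFactors = FALSE))
  })
}

#' Seeded spike trains
#'
#' `sim_poisson_train()` draws a homogeneous Poisson train with a hard
#' refractory period (each gap is `refractory_ms` plus an exponential
#' variate). `sim_bursty_train()` draws Poisson burst onsets and fills each
#' burst with `spikes_per_burst` spikes at `intra_isi_ms` spacing. Both use
#' the current RNG stream unless `seed` is given, and return times in ms
#' within `[0, duration_s * 1000)`.
#'
#' @param rate_hz mean rate of the Poisson train.
#' @param duration_s train duration in seconds.
#' @param refractory_ms hard refractory period.
#' @param seed optional RNG seed.
#' @return Numeric vector of spike times in ms.
#' @export
sim_poisson_train <- function(rate_hz, duration_s, refractory_ms = 1,
                              seed = NULL) {
  gen <- function() {
    n_guess <- ceiling(rate_hz * duration_s * 1.5) + 50L
    gaps <- refractory_ms / 1000 + rexp(n_guess, rate_hz)
    t <- cumsum(gaps)
    while (t[length(t)] < duration_s) {
      t <- c(t, t[length(t)] +
               cumsum(refractory_ms / 1000 + rexp(n_guess, rate_hz)))
    }
    t[t < duration_s] * 1000
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @rdname sim_poisson_train
#' @param burst_rate_hz rate of burst onsets.
#' @param spikes_per_burst spikes per burst.
#' @param intra_isi_ms spacing of spikes within a burst (>= refractory).
#' @export
sim_bursty_train <- function(burst_rate_hz, duration_s,
                             spikes_per_burst = 4L, intra_isi_ms = 3,
                             refractory_ms = 1, seed = NULL) {
  if (intra_isi_ms < refractory_ms) {
    stop("intra_isi_ms must be >= refractory_ms")
  }
  burst_len <- (spikes_per_burst - 1L) * intra_isi_ms
  onsets <- sim_poisson_train(burst_rate_hz, duration_s,
                              refractory_ms = burst_len + refractory_ms,
                              seed = seed)
  t <- as.vector(outer((0:(spikes_per_burst - 1L)) * intra_isi_ms, onsets,
                       `+`))
  sort(t[t < duration_s * 1000])
}

#' Parametric biphasic spike template
#'
#' Deterministic extracellular spike shape: a negative quadratic (parabolic)
#' trough lobe followed by a positive parabolic peak lobe whose vertices are
#' exactly `ttp_us` microseconds apart. Quadratic lobes make parabolic
#' sub-sample refinement of the sampled extrema exact, so planted
#' trough-to-peak durations are recovered without interpolation bias; only
#' the trough-to-peak duration and amplitude matter downstream. Lobes do not
#' overlap when `ttp_us >= trough_w_us + peak_w_us`.
#'
#' @param t_us evaluation times in microseconds relative to the trough
#'   vertex.
#' @param ttp_us trough-to-peak duration in microseconds.
#' @param amp trough amplitude (positive; the trough reaches `-amp`).
#' @param trough_w_us,peak_w_us lobe half-widths in microseconds.
#' @param peak_ratio peak amplitude as a fraction of `amp`.
#' @return Numeric vector of template values at `t_us`.
#' @export
spike_template <- function(t_us, ttp_us, amp = 1, trough_w_us = 120,
                           peak_w_us = 120, peak_ratio = 0.5) {
  lobe <- function(u) pmax(0, 1 - u^2)
  -amp * lobe(t_us / trough_w_us) +
    amp * peak_ratio * lobe((t_us - ttp_us) / peak_w_us)
}

#' Sampled mean-waveform template
#'
#' Samples [spike_template()] on a regular grid, with the trough vertex
#' placed `offset_us` after the nominal centre so that sub-sample alignment
#' is exercised.
#'
#' @param ttp_us trough-to-peak duration in microseconds.
#' @param rate sampling rate in samples/s.
#' @param pre_us,post_us window before/after the nominal trough.
#' @param offset_us sub-sample offset of the trough vertex.
#' @param ... passed to [spike_template()].
#' @return Numeric vector (a synthetic mean waveform).
#' @export
make_waveform <- function(ttp_us, rate = 20000, pre_us = 600,
                          post_us = 1000, offset_us = 0, ...) {
  step <- 1e6 / rate
  t <- seq(-pre_us, post_us, by = step)
  spike_template(t - offset_us, ttp_us, ...)
}

#' Synthetic recording plan
#'
#' Describes a seeded extracellular recording: Gaussian noise plus planted
#' units, each defined by a trough-to-peak duration, an amplitude and a
#' firing model (`"poisson"` with `rate_hz`, or `"bursty"` with
#' `burst_rate_hz`, `spikes_per_burst`, `intra_isi_ms`).
#'
#' @param seed RNG seed.
#' @param rate sampling rate (>= 20000 samples/s).
#' @param duration_s recording duration in seconds.
#' @param noise_sd Gaussian noise standard deviation.
#' @param units list of unit descriptions (see Details above).
#' @return A `recording_plan` list.
#' @export
recording_plan <- function(seed, rate = 20000, duration_s = 60,
                           noise_sd = 1, units = list()) {
  if (rate < 20000) stop("rate must be >= 20000 samples/s")
  for (u in units) {
    if (is.null(u$ttp_us) || is.null(u$amp) || u$amp <= 0) {
      stop("each unit needs ttp_us and a positive amp")
    }
    if (identical(u$model, "bursty") &&
        u$intra_isi_ms < 1) {
      stop("intra-burst ISI must respect the 1-ms refractory period")
    }
  }
  structure(list(seed = as.integer(seed), rate = rate,
                 duration_s = duration_s, noise_sd = noise_sd,
                 units = units),
            class = "recording_plan")
}

#' Generate a synthetic extracellular recording
#'
#' Pure function of its plan. Each unit's spike train is drawn from its
#' firing model; at every spike time (continuous, not grid-aligned) the
#' unit's biphasic template is added to the trace, then Gaussian noise is
#' added. Ground truth (spike times, unit, trough-to-peak duration, class)
#' is returned alongside the recording and suffices to score detection,
#' classification and rate recovery without re-generation.
#'
#' @param plan a [recording_plan()].
#' @return list with `recording` (a [recording()]) and `truth` (data.frame:
#'   `unit`, `time_ms`, `ttp_us`, `class`).
#' @export
make_recording <- function(plan) {
  stopifnot(inherits(plan, "recording_plan"))
  with_seed(plan$seed, {
    n <- round(plan$duration_s * plan$rate)
    x <- rnorm(n, 0, plan$noise_sd)
    step_us <- 1e6 / plan$rate
    truth <- list()
    for (ui in seq_along(plan$units)) {
      u <- plan$units[[ui]]
      times <- if (identical(u$model, "bursty")) {
        sim_bursty_train(u$burst_rate_hz, plan$duration_s,
                         u$spikes_per_burst, u$intra_isi_ms)
      } else {
        sim_poisson_train(u$rate_hz, plan$duration_s)
      }
      tw <- if (is.null(u$trough_w_us)) 120 else u$trough_w_us
      pw <- if (is.null(u$peak_w_us)) 120 else u$peak_w_us
      span_us <- c(-tw, u$ttp_us + pw)
      for (t_ms in times) {
        t_us <- t_ms * 1000
        i0 <- max(1L, floor((t_us + span_us[1]) / step_us) + 1L)
        i1 <- min(n, ceiling((t_us + span_us[2]) / step_us) + 1L)
        if (i0 > i1) next
        samp_us <- (i0:i1 - 1L) * step_us
        x[i0:i1] <- x[i0:i1] +
          spike_template(samp_us - t_us, u$ttp_us, amp = u$amp,
                         trough_w_us = tw, peak_w_us = pw)
      }
      truth[[ui]] <- data.frame(unit = ui, time_ms = times,
                                ttp_us = u$ttp_us,
                                class = classify_unit(u$ttp_us),
                                stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(unit = integer(), time_ms = double(),
                             ttp_us = double(), class = character())
    truth <- truth[order(truth$time_ms), , drop = FALSE]
    rownames(truth) <- NULL
    list(recording = recording(x, plan$rate), truth = truth)
  })
}
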
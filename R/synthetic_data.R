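# Protocol-faithful synthetic oddball sessions with known ground truth.
#
# A session is a sequence of blocks, each with five phases:
# fixation (2 s), target presentation (2 s), preparation (1 s),
# stimulation (~30 s of 150 ms flash cycles), rest (5 s). During stimulation
# the symbols flash one at a time under no-repeat + equiprobable constraints;
# the attended (target) symbol elicits an ERP, every flash drives a
# steady-state visual response at the flash rate.

#' Per-channel ERP template parameters
#'
#' Describes the condition-dependent ERP morphology injected at target-flash
#' onsets: a negative deflection in the 200-300 ms range followed by a
#' positive (P300) peak in the 300-400 ms range, both Gaussian-shaped, scaled
#' by a per-channel gain and a per-condition gain. Defaults place the response
#' over centro-parietal and parieto-occipital sites, with the cartoon-face
#' (CF) condition amplified relative to the standard flash (SF) at the six
#' posterior channels and identical at Fz and Cz.
#'
#' @param neg_peak_latency_ms latency of the negative deflection (ms).
#' @param neg_peak_amplitude_uV amplitude of the negative deflection
#'   (microvolts, negative).
#' @param pos_peak_latency_ms latency of the positive P300 peak (ms).
#' @param pos_peak_amplitude_uV amplitude of the P300 peak (microvolts).
#' @param peak_width_ms Gaussian standard deviation of each deflection (ms).
#' @param channel_gain named per-channel gain map.
#' @param cf_posterior_gain multiplicative gain applied at the posterior
#'   channels (P3, Pz, P4, PO7, PO8, Oz) under the CF condition.
#' @return an object of class `erp_params`.
#' @export
erp_params <- function(neg_peak_latency_ms = 250,
                       neg_peak_amplitude_uV = -4,
                       pos_peak_latency_ms = 350,
                       pos_peak_amplitude_uV = 8,
                       peak_width_ms = 45,
                       channel_gain = c(Fz = 0.4, Cz = 0.6, P3 = 0.8, Pz = 1.0,
                                        P4 = 0.8, PO7 = 0.7, PO8 = 0.7, Oz = 0.6),
                       cf_posterior_gain = 1.5) {
  if (neg_peak_latency_ms < 0 || neg_peak_latency_ms > 1000 ||
      pos_peak_latency_ms < 0 || pos_peak_latency_ms > 1000)
    stop("peak latencies must lie within [0, 1000] ms")
  if (cf_posterior_gain < 1)
    stop("cf_posterior_gain must be >= 1 (CF gain >= SF gain at posterior channels)")
  structure(list(neg_peak_latency_ms = neg_peak_latency_ms,
                 neg_peak_amplitude_uV = neg_peak_amplitude_uV,
                 pos_peak_latency_ms = pos_peak_latency_ms,
                 pos_peak_amplitude_uV = pos_peak_amplitude_uV,
                 peak_width_ms = peak_width_ms,
                 channel_gain = channel_gain,
                 cf_posterior_gain = cf_posterior_gain),
            class = "erp_params")
}

#' Simulation configuration for a synthetic oddball session
#'
#' Collects every knob of the generator. Defaults reproduce the recording
#' protocol the pipeline targets: 150 ms flash cycle (75 ms on + 75 ms off),
#' at least 280 target flashes per session, 256 Hz sampling, the 8-channel
#' montage in [P300_CHANNELS], temporally correlated AR(1) background noise,
#' and a steady-state visual response at the realized flash rate.
#'
#' @param n_symbols number of symbols on the display, 4 to 9.
#' @param condition stimulation condition, `"SF"` (standard flash) or `"CF"`
#'   (cartoon face).
#' @param min_target_flashes blocks are appended until the total number of
#'   target flashes reaches this count (default 280).
#' @param flash_on_ms,flash_off_ms flash highlight and gap durations (ms);
#'   their sum, the 150 ms flash period, is fixed by the protocol.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names electrode montage.
#' @param erp an [erp_params()] object.
#' @param noise_std background noise standard deviation (microvolts).
#' @param noise_model `"ar1"` (default) for temporally correlated noise with
#'   a realistic low-frequency-dominated spectrum, or `"white"`.
#' @param ar_coef AR(1) coefficient when `noise_model = "ar1"`.
#' @param ssvep_amplitude amplitude (microvolts) of the steady-state visual
#'   response added during stimulation phases.
#' @param artifact_rate probability that a flash-aligned window receives an
#'   injected artifact (see [inject_artifacts()]).
#' @param seed integer seed making the session reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_symbols = 5,
                       condition = c("CF", "SF"),
                       min_target_flashes = 280,
                       flash_on_ms = 75,
                       flash_off_ms = 75,
                       sampling_rate = 256,
                       channel_names = P300_CHANNELS,
                       erp = erp_params(),
                       noise_std = 9,
                       noise_model = c("ar1", "white"),
                       ar_coef = 0.95,
                       ssvep_amplitude = 1,
                       artifact_rate = 0,
                       seed = 1L) {
  condition <- match.arg(condition)
  noise_model <- match.arg(noise_model)
  if (n_symbols < 2) stop("n_symbols must be at least 2 (no-repeat constraint unsatisfiable)")
  if (n_symbols < 4 || n_symbols > 9)
    warning("n_symbols outside the protocol range [4, 9]")
  if (min_target_flashes < 1) stop("min_target_flashes must be >= 1")
  if (flash_on_ms + flash_off_ms != 150)
    stop("flash period must be 150 ms (flash_on_ms + flash_off_ms)")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must lie in [0, 1]")
  structure(list(n_symbols = as.integer(n_symbols), condition = condition,
                 min_target_flashes = as.integer(min_target_flashes),
                 flash_on_ms = flash_on_ms, flash_off_ms = flash_off_ms,
                 sampling_rate = sampling_rate, channel_names = channel_names,
                 erp = erp, noise_std = noise_std, noise_model = noise_model,
                 ar_coef = ar_coef, ssvep_amplitude = ssvep_amplitude,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Phase durations (s) of the non-stimulation block phases.
PHASE_DURATIONS <- c(fixation = 2, target_presentation = 2, preparation = 1, rest = 5)

#' Generate a flash schedule for one session
#'
#' Builds the event stream of a session: blocks of stimulation-phase flashes
#' at the 150 ms flash period (rounded to the sample grid), preceded by
#' fixation / target-presentation / preparation phases and followed by rest.
#' Within a block the flashes are complete shuffled rounds (each round one
#' permutation of all symbols) so every symbol flashes an equally often;
#' a round's permutation is redrawn whenever its first symbol equals the
#' previous round's last (no-repeat across round boundaries). Each block's
#' target symbol is drawn uniformly. Blocks are appended until the total
#' number of target flashes reaches `config$min_target_flashes`.
#'
#' The number of rounds per block is `round(30 / (0.150 * n_symbols))`,
#' i.e. the stimulation phase lasts approximately 30 s.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a data frame of events (class `event_list`): `onset_sample`
#'   (0-based), `stimulus_index` (0-based symbol id, NA for phase markers),
#'   `label` (`"target"`/`"nontarget"`, NA for phase markers), `block_id`,
#'   `phase`. The per-block target symbol is attached as attribute
#'   `block_targets`.
#' @export
make_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  fs <- config$sampling_rate
  ns <- config$n_symbols
  flash_step <- round(0.150 * fs)
  rounds_per_block <- max(1L, round(30 / (0.150 * ns)))
  n_blocks <- ceiling(config$min_target_flashes / rounds_per_block)

  rows <- vector("list", n_blocks)
  block_targets <- integer(n_blocks)
  cursor <- 0L  # 0-based sample cursor
  for (b in seq_len(n_blocks)) {
    phase_rows <- list()
    for (ph in c("fixation", "target_presentation", "preparation")) {
      phase_rows[[ph]] <- data.frame(onset_sample = cursor, stimulus_index = NA_integer_,
                                     label = NA_character_, block_id = b, phase = ph)
      cursor <- cursor + round(PHASE_DURATIONS[[ph]] * fs)
    }
    target <- sample.int(ns, 1L) - 1L
    block_targets[b] <- target
    seqs <- integer(rounds_per_block * ns)
    last <- -1L
    for (r in seq_len(rounds_per_block)) {
      perm <- sample.int(ns) - 1L
      while (perm[1] == last) perm <- sample.int(ns) - 1L
      seqs[((r - 1L) * ns + 1L):(r * ns)] <- perm
      last <- perm[ns]
    }
    flash_rows <- data.frame(
      onset_sample = cursor + (seq_along(seqs) - 1L) * flash_step,
      stimulus_index = seqs,
      label = ifelse(seqs == target, "target", "nontarget"),
      block_id = b, phase = "stimulation")
    cursor <- max(flash_rows$onset_sample) + flash_step
    rest_row <- data.frame(onset_sample = cursor, stimulus_index = NA_integer_,
                           label = NA_character_, block_id = b, phase = "rest")
    cursor <- cursor + round(PHASE_DURATIONS[["rest"]] * fs)
    rows[[b]] <- rbind(do.call(rbind, phase_rows), flash_rows, rest_row)
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  structure(ev, block_targets = block_targets, class = c("event_list", "data.frame"))
}

#' Condition- and channel-specific ERP template
#'
#' The injected single-trial ERP waveform on a 1 s post-stimulus support:
#' the sum of a negative Gaussian deflection (default 250 ms latency) and a
#' positive Gaussian P300 peak (default 350 ms), scaled by the channel gain
#' and, for the CF condition at posterior channels, by `cf_posterior_gain`.
#'
#' @param params an [erp_params()].
#' @param condition `"SF"` or `"CF"`.
#' @param channel channel name (must appear in `params$channel_gain`).
#' @param sampling_rate sampling rate in Hz.
#' @return numeric vector of `round(sampling_rate)` samples (microvolts),
#'   covering t in [0, 1) s.
#' @export
erp_template <- function(params, condition = c("SF", "CF"), channel = "Pz",
                         sampling_rate = 256) {
  stopifnot(inherits(params, "erp_params"))
  condition <- match.arg(condition)
  if (!channel %in% names(params$channel_gain))
    stop("unknown channel: ", channel)
  gain <- params$channel_gain[[channel]]
  posterior <- c("P3", "Pz", "P4", "PO7", "PO8", "Oz")
  if (condition == "CF" && channel %in% posterior)
    gain <- gain * params$cf_posterior_gain
  t_ms <- (seq_len(round(sampling_rate)) - 1) / sampling_rate * 1000
  s <- params$peak_width_ms
  gain * (params$neg_peak_amplitude_uV * exp(-0.5 * ((t_ms - params$neg_peak_latency_ms) / s)^2) +
          params$pos_peak_amplitude_uV * exp(-0.5 * ((t_ms - params$pos_peak_latency_ms) / s)^2))
}

#' Simulate a continuous oddball session
#'
#' Generates a full [continuous_recording]: background noise (AR(1) by
#' default, optionally white), a sinusoidal steady-state visual response at
#' the realized flash rate during stimulation phases, and the condition- and
#' channel-specific ERP template added at every target-flash onset. The
#' result is deterministic given `config$seed`; the schedule is drawn from a
#' seed derived from it so that it is unchanged by noise settings.
#'
#' @param config a [sim_config()].
#' @return a `continuous_recording`; when `config$artifact_rate > 0`
#'   artifacts are injected (see [inject_artifacts()]) and the ground-truth
#'   table is attached as attribute `artifact_truth`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  events <- make_schedule(config, seed = config$seed)
  n_samples <- max(events$onset_sample) + round(1.2 * fs) + round(5 * fs)
  nch <- length(config$channel_names)

  set.seed(config$seed + 1000003L)
  sig <- matrix(0, nrow = nch, ncol = n_samples,
                dimnames = list(config$channel_names, NULL))
  if (config$noise_std > 0) {
    for (ch in seq_len(nch)) {
      if (config$noise_model == "white") {
        sig[ch, ] <- stats::rnorm(n_samples, sd = config$noise_std)
      } else {
        innov_sd <- config$noise_std * sqrt(1 - config$ar_coef^2)
        sig[ch, ] <- stats::filter(stats::rnorm(n_samples, sd = innov_sd),
                                   config$ar_coef, method = "recursive")
      }
    }
  }

  flash <- events[events$phase == "stimulation", ]
  flash_step <- round(0.150 * fs)
  if (config$ssvep_amplitude > 0) {
    # one sinusoid per stimulation phase, phase-locked to its first flash
    for (b in unique(flash$block_id)) {
      fb <- flash[flash$block_id == b, ]
      s0 <- min(fb$onset_sample)
      s1 <- max(fb$onset_sample) + flash_step - 1L
      idx <- (s0:s1) + 1L
      wave <- config$ssvep_amplitude * sin(2 * pi * (0:(s1 - s0)) / flash_step)
      sig[, idx] <- sweep(sig[, idx, drop = FALSE], 2, wave, "+")
    }
  }

  tpl_len <- round(fs)
  templates <- vapply(config$channel_names, function(ch)
    erp_template(config$erp, config$condition, ch, fs), numeric(tpl_len))
  targets <- flash$onset_sample[flash$label == "target"]
  for (on in targets) {
    idx <- (on + 1L):(on + tpl_len)
    keep <- idx <= n_samples
    sig[, idx[keep]] <- sig[, idx[keep], drop = FALSE] + t(templates[keep, , drop = FALSE])
  }

  rec <- continuous_recording(
    signals = sig, channel_names = config$channel_names, sampling_rate = fs,
    events = events,
    metadata = list(subject = "01", session = "01",
                    condition = config$condition, n_symbols = config$n_symbols,
                    seed = config$seed))
  if (config$artifact_rate > 0) {
    inj <- inject_artifacts(rec, config$artifact_rate, seed = config$seed + 2000003L)
    rec <- inj$recording
    attr(rec, "artifact_truth") <- inj$truth
  }
  rec
}

#' Inject flash-aligned artifacts with known ground truth
#'
#' Contaminates randomly selected flash-aligned windows (the [-0.2, 1.0] s
#' epoch around a flash onset) with one of three engineered artifact types,
#' each designed to trip exactly one of the rejection criteria of
#' [reject_artifacts()] on one channel:
#'
#' * `"spike"` - a narrow (12 ms SD) 250 uV Gaussian transient at
#'   mid-window: peak-to-peak exceeds 200 uV while its energy is too brief
#'   to raise the whole-epoch SD above 50 uV and too low-frequency to move
#'   the band-power ratio;
#' * `"slow"` - a 2 Hz +/-60 uV alternation spanning the window: whole-epoch
#'   SD exceeds 50 uV while peak-to-peak stays under 200 uV and the power
#'   sits below 20 Hz;
#' * `"hf"` - an added 60 uV 30 Hz oscillation: band-power ratio
#'   P\[20-40\]/P\[4-40\] exceeds 0.5 while SD (~43 uV) and peak-to-peak
#'   stay under their thresholds.
#'
#' Because consecutive flashes are 150 ms apart and epochs span 1.2 s,
#' epochs neighbouring a contaminated flash partially overlap the injected
#' waveform; ground truth reports the directly injected flashes only, and
#' analyses should treat overlapping neighbours as contaminated as well.
#'
#' @param recording a `continuous_recording`.
#' @param artifact_rate per-flash contamination probability in [0, 1].
#' @param seed integer seed.
#' @param types artifact types to draw from.
#' @return list with `recording` (contaminated copy) and `truth`, a data
#'   frame with one row per contaminated flash: `flash_index` (row index
#'   into the stimulation-phase events), `onset_sample`, `type`, and
#'   `criterion` (1 = peak-to-peak, 2 = SD, 3 = band ratio).
#' @export
inject_artifacts <- function(recording, artifact_rate, seed = 1L,
                             types = c("spike", "slow", "hf")) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must lie in [0, 1]")
  flash <- recording$events[recording$events$phase == "stimulation", ]
  truth <- data.frame(flash_index = integer(), onset_sample = integer(),
                      type = character(), criterion = integer())
  if (artifact_rate == 0 || nrow(flash) == 0)
    return(list(recording = recording, truth = truth))
  set.seed(seed)
  fs <- recording$sampling_rate
  pre <- round(0.2 * fs); post <- round(1.0 * fs)
  ns_total <- ncol(recording$signals)
  hit <- which(stats::runif(nrow(flash)) < artifact_rate)
  if (length(hit) == 0) return(list(recording = recording, truth = truth))
  kind <- sample(types, length(hit), replace = TRUE)
  chan <- sample.int(nrow(recording$signals), length(hit), replace = TRUE)
  for (i in seq_along(hit)) {
    on <- flash$onset_sample[hit[i]]
    idx <- (on - pre + 1L):(on + post)
    idx <- idx[idx >= 1L & idx <= ns_total]
    n <- length(idx)
    tt <- (seq_len(n) - 1) / fs
    add <- switch(kind[i],
      spike = 250 * exp(-0.5 * ((seq_len(n) - n / 2) / (0.012 * fs))^2),
      slow = 60 * ifelse(sin(2 * pi * 2 * tt) >= 0, 1, -1),
      hf = 60 * sin(2 * pi * 30 * tt))
    recording$signals[chan[i], idx] <- recording$signals[chan[i], idx] + add
  }
  truth <- data.frame(flash_index = hit, onset_sample = flash$onset_sample[hit],
                      type = kind,
                      criterion = c(spike = 1L, slow = 2L, hf = 3L)[kind])
  rownames(truth) <- NULL
  list(recording = recording, truth = truth)
}
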
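# Shared fixtures: memoised simulated sessions run through the full
# preprocessing chain, and an independent whiten+SVD CCA oracle.

.session_cache <- new.env(parent = emptyenv())

# Simulate a session and run it through epoching, rejection, band-pass and
# trim/decimation. Memoised on the argument signature because several test
# files reuse the same small sessions.
sim_trimmed <- function(condition = "CF", targets = 40, n_symbols = 5,
                        seed = 1, noise_std = 9, gain_mult = 1) {
  key <- paste(condition, targets, n_symbols, seed, noise_std, gain_mult, sep = "|")
  if (is.null(.session_cache[[key]])) {
    erp <- erp_params(neg_peak_amplitude_uV = -4 * gain_mult,
                      pos_peak_amplitude_uV = 8 * gain_mult)
    cfg <- sim_config(n_symbols = n_symbols, condition = condition,
                      min_target_flashes = targets, seed = seed,
                      noise_std = noise_std, erp = erp)
    rec <- simulate_session(cfg)
    .session_cache[[key]] <-
      trim_decimate(bandpass_epochs(reject_artifacts(extract_epochs(rec))))
  }
  .session_cache[[key]]
}

# Independent CCA oracle: whiten each centred matrix through its SVD, then
# the canonical correlations are the singular values of the product of the
# whitened bases. Shares no code with the generalized-eigenproblem solver.
cca_svd_oracle <- function(P, Q, tol = 1e-10) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  sp <- svd(Pc)
  sq <- svd(Qc)
  kp <- sp$d > tol * sp$d[1]
  kq <- sq$d > tol * sq$d[1]
  sv <- svd(crossprod(sp$u[, kp, drop = FALSE], sq$u[, kq, drop = FALSE]))$d
  sort(pmin(sv, 1), decreasing = TRUE)
}

# Build an epoch_set directly from a data array (for filter/ERP unit tests
# that need exact analytic inputs rather than simulated sessions).
manual_epochs <- function(data, labels, fs = 256, filtered = FALSE,
                          clean = FALSE) {
  ns <- dim(data)[2]
  obj <- structure(list(
    data = data,
    labels = factor(labels, levels = c("nontarget", "target")),
    time = (seq_len(ns) - round(0.2 * fs) - 1) / fs,
    channel_names = dimnames(data)[[3]] %||% paste0("ch", seq_len(dim(data)[3])),
    sampling_rate = fs,
    event_index = seq_len(dim(data)[1]),
    filtered = filtered), class = "epoch_set")
  if (clean) {
    obj$rejection_report <- data.frame(epoch = seq_len(dim(data)[1]),
                                       kept = TRUE, crit_p2p = FALSE,
                                       crit_sd = FALSE, crit_ratio = FALSE)
    class(obj) <- c("clean_epoch_set", "epoch_set")
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
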
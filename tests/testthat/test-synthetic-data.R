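# Schedule structure, ERP template shape, session determinism, averaging
# convergence, and artifact injection.

test_that("schedules respect the count identity, no-repeat, and spacing", {
  cfg <- sim_config(n_symbols = 5, min_target_flashes = 280, seed = 4)
  ev <- make_schedule(cfg)
  fl <- ev[ev$phase == "stimulation", ]
  expect_equal(sum(fl$label == "target"), 280)
  expect_equal(sum(fl$label == "nontarget"), 1120)
  # no two consecutive flashes share a symbol, within and across rounds
  for (b in unique(fl$block_id))
    expect_true(all(diff(fl$stimulus_index[fl$block_id == b]) != 0))
  # consecutive stimulation onsets differ by exactly round(0.150 * fs)
  step <- round(0.150 * cfg$sampling_rate)
  for (b in unique(fl$block_id))
    expect_true(all(diff(fl$onset_sample[fl$block_id == b]) == step))
})

test_that("schedules are equiprobable within blocks and uniform in target", {
  cfg <- sim_config(n_symbols = 4, min_target_flashes = 10, seed = 0)
  target_counts <- integer(4)
  for (s in 1:300) {
    ev <- make_schedule(cfg, seed = s)
    fl <- ev[ev$phase == "stimulation", ]
    for (b in unique(fl$block_id)) {
      counts <- table(fl$stimulus_index[fl$block_id == b])
      expect_equal(diff(range(counts)), 0)  # exactly equal per-symbol counts
    }
    bt <- attr(ev, "block_targets")
    target_counts <- target_counts + tabulate(bt + 1L, 4)
  }
  # block targets uniform over the 4 symbols: 300 draws, 99% binomial band
  n <- sum(target_counts)
  p <- target_counts / n
  ci <- 2.58 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(p - 0.25) < ci + 0.02))
})

test_that("n_symbols below 2 is rejected", {
  expect_error(sim_config(n_symbols = 1), "at least 2")
})

test_that("the ERP template matches its closed-form area and gain ordering", {
  p <- erp_params()
  fs <- 256
  for (ch in c("Pz", "Fz")) {
    for (cond in c("SF", "CF")) {
      tpl <- erp_template(p, cond, ch, fs)
      gain <- p$channel_gain[[ch]]
      if (cond == "CF" && ch != "Fz") gain <- gain * p$cf_posterior_gain
      s <- p$peak_width_ms / 1000
      area_closed <- gain * (p$neg_peak_amplitude_uV + p$pos_peak_amplitude_uV) *
        s * sqrt(2 * pi)
      expect_equal(sum(tpl) / fs, area_closed, tolerance = 1e-6)
    }
  }
  # CF template strictly exceeds SF at posterior channels in the P300 window
  t_ms <- (seq_len(fs) - 1) / fs * 1000
  win <- t_ms >= 300 & t_ms <= 400
  expect_gt(max(erp_template(p, "CF", "Pz")[win]),
            max(erp_template(p, "SF", "Pz")[win]))
  expect_equal(erp_template(p, "CF", "Fz"), erp_template(p, "SF", "Fz"))
  # zero gain -> all-zero waveform
  p0 <- erp_params(channel_gain = c(Pz = 0))
  expect_equal(erp_template(p0, "SF", "Pz"), rep(0, fs))
  expect_error(erp_params(pos_peak_latency_ms = 1200), "within \\[0, 1000\\]")
})

test_that("noiseless sessions recover the template at isolated target flashes", {
  # 9 symbols: the 9 * 38-sample round exceeds the 307-sample epoch, so
  # some target flashes have no other target inside their window
  cfg <- sim_config(n_symbols = 9, min_target_flashes = 40, seed = 6,
                    noise_std = 0, ssvep_amplitude = 0)
  rec <- simulate_session(cfg)
  ep <- extract_epochs(rec)
  fl <- rec$events[rec$events$phase == "stimulation", ]
  tgt_on <- fl$onset_sample[fl$label == "target"]
  # epochs whose window contains no other target flash (no ERP overlap)
  iso <- vapply(seq_along(tgt_on), function(i)
    all(abs(tgt_on[-i] - tgt_on[i]) >= 307), logical(1))
  expect_gt(sum(iso), 0)
  tpl <- erp_template(cfg$erp, cfg$condition, "Pz", cfg$sampling_rate)
  i <- which(ep$labels == "target")[which(iso)[1]]
  post <- ep$time >= 0
  expect_equal(unname(ep$data[i, post, "Pz"]), tpl, tolerance = 1e-12)
  expect_equal(unname(ep$data[i, !post, "Pz"]), rep(0, sum(!post)))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(min_target_flashes = 10, seed = 11)
  r1 <- simulate_session(cfg)
  r2 <- simulate_session(cfg)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$events, r2$events)
})

test_that("across-epoch target averages converge at the noise/sqrt(N) rate", {
  rmse_for <- function(noise, targets, seed) {
    base <- sim_config(n_symbols = 5, min_target_flashes = targets,
                       noise_std = 0, ssvep_amplitude = 0, seed = seed)
    noisy <- sim_config(n_symbols = 5, min_target_flashes = targets,
                        noise_std = noise, ssvep_amplitude = 0, seed = seed)
    avg <- function(cfg) {
      ep <- extract_epochs(simulate_session(cfg))
      apply(ep$data[ep$labels == "target", , "Pz"], 2, mean)
    }
    sqrt(mean((avg(noisy) - avg(base))^2))
  }
  r4 <- rmse_for(4, 140, seed = 21)
  r8 <- rmse_for(8, 140, seed = 22)
  expect_gt(r8 / r4, 1.5)   # doubling noise doubles the residual
  expect_lt(r8 / r4, 2.6)
  r4_big <- rmse_for(4, 280, seed = 23)
  expect_lt(r4_big, r4)     # more epochs, smaller residual
})

test_that("artifact injection honours the rate and constructed properties", {
  cfg <- sim_config(n_symbols = 4, min_target_flashes = 50, seed = 8)
  rec <- simulate_session(cfg)

  none <- inject_artifacts(rec, 0, seed = 1)
  expect_identical(none$recording$signals, rec$signals)
  expect_equal(nrow(none$truth), 0)

  all_spike <- inject_artifacts(rec, 1, seed = 2, types = "spike")
  ep <- extract_epochs(all_spike$recording)
  p2p <- apply(ep$data, 1, function(m) max(apply(m, 2, function(x) max(x) - min(x))))
  expect_true(all(p2p > 200))

  # contaminated count within the binomial 99% interval
  cfg2 <- sim_config(n_symbols = 5, min_target_flashes = 200, seed = 9)
  rec2 <- simulate_session(cfg2)
  inj <- inject_artifacts(rec2, 0.1, seed = 3)
  n_flash <- sum(rec2$events$phase == "stimulation")
  expect_equal(n_flash, 1000)
  band <- stats::qbinom(c(0.005, 0.995), n_flash, 0.1)
  expect_gte(nrow(inj$truth), band[1])
  expect_lte(nrow(inj$truth), band[2])
})
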
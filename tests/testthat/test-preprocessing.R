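# Epoch extraction arithmetic, the three rejection criteria, the zero-phase
# FIR band-pass, and ERP averaging.

test_that("epoch extraction follows the [-0.2, 1.0) sample convention", {
  cfg <- sim_config(n_symbols = 5, min_target_flashes = 40, seed = 5)
  rec <- simulate_session(cfg)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data)[2], 307)       # 51 pre + 256 post at 256 Hz
  expect_equal(ep$time[52], 0)             # sample 52 is stimulus onset
  expect_equal(dim(ep$data)[1], 200)       # 40 targets x 5 symbols
})

test_that("boundary events are skipped with a message", {
  fs <- 256
  sig <- matrix(0, 1, 400)
  ev <- data.frame(onset_sample = c(10L, 100L), stimulus_index = c(0L, 1L),
                   label = c("target", "nontarget"), block_id = 1L,
                   phase = "stimulation")
  rec <- continuous_recording(sig, "Cz", fs, ev)
  expect_message(ep <- extract_epochs(rec), "skipped 1")
  expect_equal(dim(ep$data)[1], 1)
  ev_all_bad <- ev[1, ]
  rec2 <- continuous_recording(sig, "Cz", fs, ev_all_bad)
  expect_error(suppressMessages(extract_epochs(rec2)), "no extractable epochs")
})

test_that("each rejection criterion fires on its designed input", {
  ns <- 307; fs <- 256
  t <- (seq_len(ns) - 1) / fs
  mk <- function(x) manual_epochs(array(x, c(1, ns, 1)), "target", fs)

  # constant epoch: kept (band ratio defined as 0 on zero denominator)
  r0 <- reject_artifacts(mk(rep(5, ns)))
  expect_true(r0$rejection_report$kept)

  # 201 uV step: peak-to-peak criterion (strict > 200)
  r1 <- reject_artifacts(mk(c(rep(0, 150), rep(201, ns - 150))))
  expect_false(r1$rejection_report$kept)
  expect_true(r1$rejection_report$crit_p2p)

  # 200 uV exactly: not rejected by (i) (strict inequality); a square wave
  # alternating +/-100 has sd ~100 > 50 so use a brief 200 uV excursion
  brief <- rep(0, ns); brief[150:155] <- 200
  r1b <- reject_artifacts(mk(brief))
  expect_false(r1b$rejection_report$crit_p2p)

  # high-variance slow alternation: SD criterion only
  r2 <- reject_artifacts(mk(60 * ifelse(sin(2 * pi * 2 * t) >= 0, 1, -1)))
  expect_false(r2$rejection_report$kept)
  expect_true(r2$rejection_report$crit_sd)
  expect_false(r2$rejection_report$crit_p2p)

  # pure 30 Hz tone below the other limits: band-ratio criterion, ratio ~ 1
  tone <- 20 * sin(2 * pi * 30 * t)
  r3 <- reject_artifacts(mk(tone))
  expect_false(r3$rejection_report$crit_p2p)
  expect_false(r3$rejection_report$crit_sd)
  expect_true(r3$rejection_report$crit_ratio)
  psd <- p300cca:::welch_psd(tone, fs)
  ratio <- p300cca:::band_power(psd, 20, 40) / p300cca:::band_power(psd, 4, 40)
  expect_gt(ratio, 0.95)

  # rejection must precede filtering
  filt <- mk(rep(0, ns)); filt$filtered <- TRUE
  expect_error(reject_artifacts(filt), "before band-pass")
})

test_that("rejection is a pure per-epoch function (order independent)", {
  set.seed(31)
  d <- array(rnorm(20 * 307 * 2, sd = 30), c(20, 307, 2))
  d[3, , 1] <- d[3, , 1] + 250 * exp(-0.5 * ((1:307 - 150) / 3)^2)
  ep <- manual_epochs(d, rep(c("target", "nontarget"), 10))
  r_fwd <- reject_artifacts(ep)
  perm <- sample(20)
  ep_perm <- manual_epochs(d[perm, , , drop = FALSE],
                           rep(c("target", "nontarget"), 10)[perm])
  r_perm <- reject_artifacts(ep_perm)
  expect_equal(r_fwd$rejection_report$kept[perm], r_perm$rejection_report$kept)
})

test_that("the band-pass preserves 8 Hz, removes 30 Hz and DC", {
  ns <- 307; fs <- 256
  t <- (seq_len(ns) - 1) / fs
  d <- array(0, c(3, ns, 1))
  d[1, , 1] <- sin(2 * pi * 8 * t)
  d[2, , 1] <- sin(2 * pi * 30 * t)
  d[3, , 1] <- 1
  ep <- manual_epochs(d, c("target", "target", "nontarget"), clean = TRUE)
  out <- bandpass_epochs(ep)
  centre <- 120:190  # away from the zero-padded epoch edges
  expect_equal(max(abs(out$data[1, centre, 1])), 1, tolerance = 0.05)
  expect_lt(max(abs(out$data[2, centre, 1])), 10^(-30 / 20))
  expect_lt(max(abs(out$data[3, centre, 1])), 0.02)
  expect_true(out$filtered)
})

test_that("filtering is identical across channels and epoch order", {
  set.seed(13)
  d <- array(rnorm(6 * 307 * 2), c(6, 307, 2))
  ep <- manual_epochs(d, rep("target", 6), clean = TRUE)
  out <- bandpass_epochs(ep)
  # same trace placed in a different channel/epoch filters identically
  d2 <- array(0, c(1, 307, 2))
  d2[1, , 2] <- d[4, , 1]
  out2 <- bandpass_epochs(manual_epochs(d2, "target", clean = TRUE))
  expect_equal(out$data[4, , 1], out2$data[1, , 2], tolerance = 1e-10)
})

test_that("ERP averaging reproduces identical epochs and rejects empty classes", {
  ns <- 307
  x <- sin(2 * pi * 5 * (seq_len(ns) - 1) / 256)
  d <- array(rep(x, each = 4), c(4, ns, 1))
  ep <- manual_epochs(d, c("target", "target", "nontarget", "nontarget"),
                      clean = TRUE)
  erp <- compute_erp(ep)
  expect_equal(drop(erp$target), x)
  expect_equal(drop(erp$nontarget), x)
  expect_equal(erp$n_target, 2)

  only_t <- manual_epochs(d[1:2, , , drop = FALSE], c("target", "target"),
                          clean = TRUE)
  expect_error(compute_erp(only_t), "no kept epochs for condition 'nontarget'")
})

test_that("label-permuted balanced epochs yield converging class ERPs", {
  set.seed(17)
  nt <- 400; ns <- 307
  d <- array(rnorm(nt * ns, sd = 5), c(nt, ns, 1))
  labels <- sample(rep(c("target", "nontarget"), nt / 2))
  erp <- compute_erp(manual_epochs(d, labels, clean = TRUE))
  gap <- sqrt(mean((erp$target - erp$nontarget)^2))
  # difference of two independent 200-epoch means: sd * sqrt(2/200)
  expect_lt(gap, 3 * 5 * sqrt(2 / 200))
})
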
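# Trim/decimation arithmetic, the generalized-eigenproblem CCA solver
# against independent oracles, spatial-filter learning, and feature
# projection.

test_that("trim/decimation keeps 51 of 307 samples and exact values", {
  fs <- 256; ns <- 307
  t <- (seq_len(ns) - 52) / fs
  d <- array(0, c(2, ns, 1))
  d[1, , 1] <- sin(2 * pi * 8 * t)
  d[2, , 1] <- 3
  ep <- manual_epochs(d, c("target", "target"), clean = TRUE)
  ep$filtered <- TRUE
  td <- trim_decimate(ep)
  expect_equal(td$nd, 51)
  expect_equal(dim(td$data)[2], 51)
  kept_t <- t[t >= 0][seq(1, 204, by = 4)]
  expect_equal(td$time, kept_t)
  expect_equal(td$data[1, , 1], sin(2 * pi * 8 * kept_t), tolerance = 1e-9)
  expect_equal(td$data[2, , 1], rep(3, 51))

  ep$filtered <- FALSE
  expect_error(trim_decimate(ep), "band-pass filtered")
})

test_that("cca solves self-correlation and the 1-D Pearson reduction", {
  set.seed(61)
  P <- matrix(rnorm(100 * 3), 100)
  m <- cca(P, P)
  expect_equal(m$rho, rep(1, 3), tolerance = 1e-6)

  a <- rnorm(60); b <- -0.7 * a + rnorm(60)
  expect_equal(cca(cbind(a), cbind(b))$rho, abs(cor(a, b)), tolerance = 1e-6)

  expect_error(cca(matrix(rnorm(6), 2), matrix(rnorm(4), 2)),
               "underdetermined CCA")
})

test_that("cca matches independent oracles on random instances", {
  set.seed(62)
  for (i in 1:25) {
    P <- matrix(rnorm(200 * 3), 200)
    Q <- matrix(rnorm(200 * 2), 200)
    m <- cca(P, Q)
    expect_equal(m$rho, cca_svd_oracle(P, Q), tolerance = 1e-6)
    expect_equal(m$rho, cancor(scale(P, scale = FALSE),
                               scale(Q, scale = FALSE))$cor,
                 tolerance = 1e-6)
    # achieved correlation of the first canonical pair equals rho1
    r1 <- abs(cor(P %*% m$Wp[, 1], Q %*% m$Wq[, 1]))
    expect_equal(drop(r1), m$rho[1], tolerance = 1e-6)
  }
})

test_that("canonical correlations are invariant to invertible channel mixing", {
  set.seed(63)
  P <- matrix(rnorm(300 * 4), 300)
  Q <- matrix(rnorm(300 * 3), 300)
  base <- cca(P, Q)$rho
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(16), 4)
    expect_equal(cca(P %*% A, Q)$rho, base, tolerance = 1e-6)
  }
})

test_that("spatial filters recover structure from the target average", {
  # identical target epochs: perfect correlation with the replicated average
  set.seed(64)
  nd <- 51; ne <- 4
  one <- matrix(rnorm(nd * ne), nd, ne)
  d <- array(0, c(6, nd, ne))
  for (i in 1:4) d[i, , ] <- one
  d[5, , ] <- matrix(rnorm(nd * ne), nd, ne)
  d[6, , ] <- matrix(rnorm(nd * ne), nd, ne)
  td <- structure(list(data = d,
                       labels = factor(c(rep("target", 4), rep("nontarget", 2)),
                                       levels = c("nontarget", "target")),
                       time = seq_len(nd), channel_names = paste0("ch", 1:ne),
                       sampling_rate = 64, nd = nd), class = "trimmed_epochs")
  sf <- fit_spatial_filter(td, n_filters = 2)
  expect_equal(sf$rho[1], 1, tolerance = 1e-6)
  # the filtered epoch is proportional to the filtered average (same epoch)
  proj_epoch <- one %*% sf$W[, 1]
  proj_avg <- apply(d[1:4, , ], c(2, 3), mean) %*% sf$W[, 1]
  expect_equal(drop(proj_epoch), drop(proj_avg), tolerance = 1e-8)

  expect_error(fit_spatial_filter(subset <- structure(
    list(data = d[5:6, , , drop = FALSE],
         labels = factor(rep("nontarget", 2), levels = c("nontarget", "target")),
         nd = nd, channel_names = paste0("ch", 1:ne)),
    class = "trimmed_epochs")), "at least 2 target epochs")
})

test_that("the first filter weights the channel carrying the template", {
  set.seed(65)
  nt <- 120; nd <- 51; ne <- 8
  tpl <- sin(pi * seq_len(nd) / nd) * 6
  d <- array(rnorm(nt * nd * ne, sd = 2), c(nt, nd, ne))
  labels <- rep(c("target", "nontarget"), c(40, 80))
  pz <- 4
  for (i in 1:40) d[i, , pz] <- d[i, , pz] + tpl
  td <- structure(list(data = d,
                       labels = factor(labels, levels = c("nontarget", "target")),
                       channel_names = P300_CHANNELS, nd = nd,
                       sampling_rate = 64), class = "trimmed_epochs")
  sf <- fit_spatial_filter(td)
  expect_equal(which.max(abs(sf$W[, 1])), pz, ignore_attr = TRUE)
  # full filter bank spans the channel space
  sf_full <- fit_spatial_filter(td, n_filters = ne)
  expect_equal(qr(sf_full$W)$rank, ne)
})

test_that("feature extraction is a linear column-major projection", {
  set.seed(66)
  nt <- 5; nd <- 51; ne <- 8
  d <- array(rnorm(nt * nd * ne), c(nt, nd, ne))
  td <- structure(list(data = d,
                       labels = factor(rep(c("target", "nontarget"), c(3, 2)),
                                       levels = c("nontarget", "target")),
                       channel_names = P300_CHANNELS, nd = nd,
                       sampling_rate = 64), class = "trimmed_epochs")
  sf <- fit_spatial_filter(td)
  fx <- extract_features(td, sf)
  expect_equal(ncol(fx$x), 153)  # Nd * Nsf = 51 * 3

  # row i equals the column-major concatenation of X_i W
  xsf <- d[2, , ] %*% sf$W
  expect_equal(fx$x[2, ], as.numeric(xsf))

  # zero epoch -> zero features; doubling amplitude doubles features
  td2 <- td
  td2$data[1, , ] <- 0
  td2$data[2, , ] <- 2 * d[2, , ]
  fx2 <- extract_features(td2, sf)
  expect_equal(fx2$x[1, ], rep(0, 153))
  expect_equal(fx2$x[2, ], 2 * fx$x[2, ])

  td$data <- td$data[, 1:50, , drop = FALSE]
  td$nd <- 50L
  expect_error(extract_features(td, sf), "dimension mismatch")
})

test_that("refitting on permuted epochs yields the same filter up to sign", {
  td <- sim_trimmed(targets = 30, seed = 67)
  sf1 <- fit_spatial_filter(td)
  set.seed(99)
  perm <- sample(dim(td$data)[1])
  td2 <- td
  td2$data <- td$data[perm, , , drop = FALSE]
  td2$labels <- td$labels[perm]
  sf2 <- fit_spatial_filter(td2)
  for (j in 1:3) {
    agree <- min(sum((sf1$W[, j] - sf2$W[, j])^2),
                 sum((sf1$W[, j] + sf2$W[, j])^2))
    expect_lt(agree, 1e-10)
  }
})
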
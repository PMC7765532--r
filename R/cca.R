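# CCA spatial-filter feature extraction: trim + decimate, the
# target-average replication construction, the generalized-eigenvalue CCA
# solver, and per-epoch feature projection.

#' Trim and decimate band-passed epochs
#'
#' Keeps post-stimulus samples with t in [0, 0.8) s - `floor(0.8 * fs)`
#' samples - then every 4th sample starting at the first. At 256 Hz this is
#' 204 in-window samples reduced to Nd = 51. Plain subsampling is alias-free
#' here because the epochs are already band-limited to 14 Hz, well below the
#' 32 Hz Nyquist of the decimated 64 Hz rate; unfiltered input is refused.
#'
#' @param clean a band-passed `clean_epoch_set` (see [bandpass_epochs()]).
#' @param factor decimation factor.
#' @return a `trimmed_epochs` object: `data` (Nt x Nd x Ne), `labels`,
#'   `time`, `channel_names`, `sampling_rate` (decimated), `nd`.
#' @export
trim_decimate <- function(clean, factor = 4L) {
  stopifnot(inherits(clean, "epoch_set"))
  if (!isTRUE(clean$filtered))
    stop("epochs must be band-pass filtered before trim/decimation")
  fs <- clean$sampling_rate
  keep <- which(clean$time >= 0)[seq_len(floor(0.8 * fs))]
  keep <- keep[seq(1L, length(keep), by = factor)]
  structure(list(data = clean$data[, keep, , drop = FALSE],
                 labels = clean$labels,
                 time = clean$time[keep],
                 channel_names = clean$channel_names,
                 sampling_rate = fs / factor,
                 nd = length(keep)),
            class = "trimmed_epochs")
}

#' Canonical correlation analysis via the generalized eigenproblem
#'
#' Finds weight vectors `wp`, `wq` maximizing the correlation between the
#' projections `P wp` and `Q wq`. Columns are mean-centred internally and
#' covariance blocks `Cpp`, `Cqq`, `Cpq` formed; `wp` solves the eigenproblem
#' of `Cpp^-1 Cpq Cqq^-1 Cqp` (and `wq` the mirrored one), with a small
#' ridge `eps * trace/N` added to each auto-covariance diagonal so that
#' rank-deficient inputs (such as the replicated target average used by
#' [fit_spatial_filter()]) remain solvable. Eigenpairs are returned in
#' descending order of canonical correlation.
#'
#' @param P,Q observation matrices, T x N and T x M, sharing T rows with
#'   `T > max(N, M)`.
#' @param ridge relative ridge added to the auto-covariance diagonals.
#' @return a `cca_model`: `Wp` (N x k), `Wq` (M x k), `rho` (descending
#'   canonical correlations, k = min(N, M)), `dims`, and the covariance
#'   blocks `Cpp`, `Cqq`, `Cpq`.
#' @export
cca <- function(P, Q, ridge = 1e-8) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of rows")
  Tn <- nrow(P); N <- ncol(P); M <- ncol(Q)
  if (Tn <= max(N, M)) stop("underdetermined CCA: need T > max(N, M)")
  Pc <- scale(P, center = TRUE, scale = FALSE)
  Qc <- scale(Q, center = TRUE, scale = FALSE)
  Cpp <- crossprod(Pc) / (Tn - 1)
  Cqq <- crossprod(Qc) / (Tn - 1)
  Cpq <- crossprod(Pc, Qc) / (Tn - 1)
  Cpp_r <- Cpp + diag(ridge * sum(diag(Cpp)) / N, N)
  Cqq_r <- Cqq + diag(ridge * sum(diag(Cqq)) / M, M)

  k <- min(N, M)
  Mp <- solve(Cpp_r, Cpq %*% solve(Cqq_r, t(Cpq)))
  ep <- eigen(Mp)
  ord <- order(Re(ep$values), decreasing = TRUE)[seq_len(k)]
  rho <- sqrt(pmin(pmax(Re(ep$values[ord]), 0), 1 + 1e-9))
  Wp <- Re(ep$vectors[, ord, drop = FALSE])
  # paired wq follow from wq = Cqq^-1 Cqp wp (up to scale)
  Wq <- solve(Cqq_r, t(Cpq) %*% Wp)
  for (j in seq_len(k)) {
    np <- sqrt(sum(Wp[, j]^2)); if (np > 0) Wp[, j] <- Wp[, j] / np
    nq <- sqrt(sum(Wq[, j]^2)); if (nq > 0) Wq[, j] <- Wq[, j] / nq
    # orient so the canonical pair correlates positively
    cv <- stats::cov(Pc %*% Wp[, j], Qc %*% Wq[, j])
    if (is.finite(cv) && cv < 0) Wq[, j] <- -Wq[, j]
  }
  structure(list(Wp = Wp, Wq = Wq, rho = rho,
                 dims = c(T = Tn, N = N, M = M),
                 Cpp = Cpp, Cqq = Cqq, Cpq = Cpq),
            class = "cca_model")
}

#' Learn a CCA spatial filter from target epochs
#'
#' Implements the target-average replication construction: the trimmed,
#' decimated target epochs are stacked row-wise into
#' `X' ((Ntarget * Nd) x Ne)`; their across-epoch average is replicated
#' `Ntarget` times into an identically shaped `Xbar'`; and [cca()] of the
#' two yields channel weight vectors whose projections maximally correlate
#' single-trial activity with the average target response. The first
#' `n_filters` columns of `Wp`, unit-normalised with sign chosen so the
#' filtered target average's largest-magnitude sample is positive, form the
#' spatial filter.
#'
#' @param trimmed a `trimmed_epochs` object with at least 2 target epochs.
#' @param n_filters number of spatial filters Nsf (default 3).
#' @return a `spatial_filter`: `W` (Ne x Nsf), `rho`, `nd`, `n_filters`,
#'   `channel_names`.
#' @export
fit_spatial_filter <- function(trimmed, n_filters = 3L) {
  stopifnot(inherits(trimmed, "trimmed_epochs"))
  tgt <- which(trimmed$labels == "target")
  if (length(tgt) < 2) stop("need at least 2 target epochs")
  d <- trimmed$data[tgt, , , drop = FALSE]
  nt <- dim(d)[1]; nd <- dim(d)[2]; ne <- dim(d)[3]
  if (n_filters < 1 || n_filters > ne) stop("n_filters must lie in [1, Ne]")
  Xp <- matrix(aperm(d, c(2, 1, 3)), nrow = nt * nd, ncol = ne)
  xbar <- apply(d, c(2, 3), mean)                  # Nd x Ne average
  Xbar <- xbar[rep(seq_len(nd), nt), , drop = FALSE]  # replicated Ntarget times
  model <- cca(Xp, Xbar)
  W <- model$Wp[, seq_len(n_filters), drop = FALSE]
  for (j in seq_len(n_filters)) {
    proj <- xbar %*% W[, j]
    if (proj[which.max(abs(proj))] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(trimmed$channel_names, NULL)
  structure(list(W = W, rho = model$rho[seq_len(n_filters)],
                 nd = nd, n_filters = n_filters,
                 channel_names = trimmed$channel_names),
            class = "spatial_filter")
}

#' Project epochs through a spatial filter into feature vectors
#'
#' Per epoch, computes the spatially filtered data `Xsf = X W` (Nd x Nsf)
#' and concatenates its columns into a feature vector of length `Nd * Nsf`
#' (153 at the defaults Nd = 51, Nsf = 3). Applied identically to target and
#' non-target epochs.
#'
#' @param trimmed a `trimmed_epochs` object whose Nd matches the filter's.
#' @param filter a `spatial_filter`.
#' @return a `feature_set`: `x` (Nt x (Nd*Nsf) matrix), `labels`.
#' @export
extract_features <- function(trimmed, filter) {
  stopifnot(inherits(trimmed, "trimmed_epochs"), inherits(filter, "spatial_filter"))
  nt <- dim(trimmed$data)[1]; nd <- dim(trimmed$data)[2]; ne <- dim(trimmed$data)[3]
  if (nd != filter$nd) stop("dimension mismatch: epochs have Nd = ", nd,
                            ", filter expects Nd = ", filter$nd)
  if (ne != nrow(filter$W)) stop("dimension mismatch: channel counts differ")
  proj <- matrix(trimmed$data, nrow = nt * nd, ncol = ne) %*% filter$W
  x <- matrix(proj, nrow = nt)  # column-major: filter-major blocks of Nd
  structure(list(x = x, labels = trimmed$labels),
            class = "feature_set")
}
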
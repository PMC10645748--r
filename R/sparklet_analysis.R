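#' Quantal analysis configuration
#'
#' @param quantal_amplitude signal units per open channel (> 0); the unitary
#'   sparklet amplitude, supplied or calibrated with
#'   [fit_quantal_amplitude()].
#' @param max_levels maximum number of quantal levels considered.
#' @return an object of class `quantal_config`.
#' @export
quantal_config <- function(quantal_amplitude, max_levels = 10L) {
  assert_positive(quantal_amplitude, "quantal_amplitude")
  max_levels <- assert_count(max_levels, "max_levels", min = 1L)
  structure(list(quantal_amplitude = quantal_amplitude,
                 max_levels = max_levels),
            class = "quantal_config")
}

#' Construct an idealized record from per-frame integer levels
#'
#' @param levels integer open-channel count per frame.
#' @return an `idealized_record`.
#' @export
idealized_record <- function(levels) {
  if (any(levels < 0)) stopf("levels must be non-negative integers")
  new_idealized_record(levels)
}

new_idealized_record <- function(levels) {
  levels <- as.integer(levels)
  structure(list(levels = levels,
                 n_levels_reached = if (length(levels)) max(levels) else 0L,
                 duration_frames = length(levels)),
            class = "idealized_record")
}

#' Construct a sparklet trace from samples
#'
#' @param signal numeric fluorescence samples.
#' @param sampling_rate Hz (default 100).
#' @param frame optional frame indices (must be uniform).
#' @return a `sparklet_trace` data.frame.
#' @export
sparklet_trace <- function(signal, sampling_rate = 100,
                           frame = seq_along(signal)) {
  structure(data.frame(frame = frame, signal = signal),
            class = c("sparklet_trace", "data.frame"),
            sampling_rate = sampling_rate)
}

#' Idealize a sparklet trace into integer quantal levels
#'
#' Each frame is assigned the nearest integer multiple of the quantal
#' amplitude (half-amplitude decision thresholds), clamped to
#' `[0, max_levels]`. Sampling must be uniform.
#'
#' @param trace a `sparklet_trace` (columns `frame`, `signal`).
#' @param config a [quantal_config()].
#' @return an `idealized_record`: per-frame `levels`, `n_levels_reached`,
#'   `duration_frames`.
#' @export
detect_and_idealize <- function(trace, config) {
  stopifnot(inherits(config, "quantal_config"))
  if (!all(c("frame", "signal") %in% names(trace)))
    stopf("trace must have columns `frame` and `signal`")
  if (nrow(trace) < 1L) stopf("trace is empty")
  df <- diff(trace$frame)
  if (length(df) && any(abs(df - df[1]) > 1e-9))
    stopf("trace sampling is not uniform")
  lv <- round(trace$signal / config$quantal_amplitude)
  lv <- pmin(pmax(lv, 0), config$max_levels)
  new_idealized_record(lv)
}

#' Calibrate the quantal amplitude from an amplitude histogram
#'
#' Fits a mixture of equally spaced Gaussians (spacing = quantal amplitude,
#' common sd) to the signal amplitude distribution by profile grid search
#' over the spacing, the standard calibration when the unitary amplitude is
#' not known a priori.
#'
#' @param signal numeric samples.
#' @param max_levels number of levels in the mixture.
#' @param spacing_grid candidate quantal amplitudes; defaults to a grid up to
#'   the signal range.
#' @return the estimated quantal amplitude.
#' @export
fit_quantal_amplitude <- function(signal, max_levels = 5L,
                                  spacing_grid = NULL) {
  rng <- range(signal)
  if (is.null(spacing_grid))
    spacing_grid <- seq(diff(rng) / 20, diff(rng), length.out = 60)
  sdg <- max(stats::mad(signal[signal < stats::median(signal)]), diff(rng) / 50)
  ll <- vapply(spacing_grid, function(q) {
    k <- 0:max_levels
    # responsibilities-free profile likelihood: each sample scored against
    # its best-fitting level; mixture weights left free improves little here
    d <- vapply(k, function(j) stats::dnorm(signal, j * q, sdg),
                numeric(length(signal)))
    sum(log(pmax(rowMeans(d), 1e-300)))
  }, numeric(1))
  spacing_grid[which.max(ll)]
}

#' Sparklet site activity (nPs)
#'
#' Implemented as the time-weighted mean open-channel count,
#' `sum_k k * T_k / T`, where `T_k` is the number of frames spent at level
#' `k`. Sites are classed high-activity iff `nPs > cutoff` (strict).
#'
#' @param record an `idealized_record`.
#' @param cutoff activity classification cutoff (default 0.2).
#' @return a `site_activity` list: `nPs`, `activity_class` ("low"/"high"),
#'   `cutoff`.
#' @export
compute_nps <- function(record, cutoff = 0.2) {
  stopifnot(inherits(record, "idealized_record"))
  if (record$duration_frames < 1L) stopf("record has no frames")
  nps <- mean(record$levels)
  structure(list(nPs = nps,
                 activity_class = if (nps > cutoff) "high" else "low",
                 cutoff = cutoff),
            class = "site_activity")
}

#' Transition matrix of the coupled Markov chain on the open-channel count
#'
#' `N` exchangeable binary channels; each channel alone is a two-state chain
#' with stationary open probability `p` and mean open dwell time
#' `mean_open_frames` (closing rate `1/mean_open_frames` per frame, opening
#' rate `p / (mean_open_frames * (1 - p))`). Joint transitions mix an
#' independent kernel and a synchronized kernel:
#' `P = (1 - kappa) * P_indep + kappa * P_sync`. Under `P_indep` every
#' channel steps on its own; under `P_sync` a uniformly chosen leader channel
#' steps and all channels copy its new state, so only the aggregate levels 0
#' and N are reachable from a synchronized move. Because channels are
#' exchangeable under both kernels, the open-channel count is itself Markov
#' and this matrix is its exact transition law.
#'
#' @param n_channels N >= 1.
#' @param open_prob per-channel stationary open probability.
#' @param kappa coupling coefficient in `[0, 1]`.
#' @param mean_open_frames mean open dwell, frames.
#' @return an `(N+1) x (N+1)` row-stochastic matrix over levels `0..N`.
#' @export
coupled_transition_matrix <- function(n_channels, open_prob, kappa,
                                      mean_open_frames = 2) {
  N <- assert_count(n_channels, "n_channels", min = 1L)
  assert_prob(kappa, "kappa")
  q_close <- 1 / mean_open_frames
  q_open <- open_prob * q_close / (1 - open_prob)
  if (q_open >= 1)
    stopf("open_prob %.3f too large for mean open time %g frames",
          open_prob, mean_open_frames)

  P_ind <- matrix(0, N + 1, N + 1)
  for (k in 0:N) {
    # a = open channels staying open, b = closed channels opening
    pa <- stats::dbinom(0:k, k, 1 - q_close)
    pb <- stats::dbinom(0:(N - k), N - k, q_open)
    conv <- rep(0, N + 1)
    for (a in 0:k) conv[(a + 0:(N - k)) + 1] <-
        conv[(a + 0:(N - k)) + 1] + pa[a + 1] * pb
    P_ind[k + 1, ] <- conv
  }

  P_sync <- matrix(0, N + 1, N + 1)
  for (k in 0:N) {
    frac_open <- k / N
    p_all_open <- frac_open * (1 - q_close) + (1 - frac_open) * q_open
    P_sync[k + 1, N + 1] <- p_all_open
    P_sync[k + 1, 1] <- 1 - p_all_open
  }

  (1 - kappa) * P_ind + kappa * P_sync
}

#' Stationary distribution of a finite Markov chain
#'
#' @param P row-stochastic transition matrix.
#' @return the stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- unname(stats::lsfit(A, b, intercept = FALSE)$coefficients)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Estimate the coupling coefficient of a sparklet site
#'
#' Maximum-likelihood fit of `(kappa, p)` under the coupled Markov chain of
#' [coupled_transition_matrix()], evaluated on the aggregate level sequence
#' of an idealized record (conditional on the first frame). For a single
#' channel the independent and synchronized kernels coincide, so kappa is
#' unidentifiable and returned as `NA` with a flag.
#'
#' @param record an `idealized_record` with at least 100 frames.
#' @param n_channels number of channels N at the site; must be >= the number
#'   of levels reached.
#' @param mean_open_frames per-channel mean open dwell, frames.
#' @return a `coupling_estimate` list: `kappa`, `open_prob`,
#'   `log_likelihood`, `n_channels`, `identifiable`.
#' @export
estimate_kappa <- function(record, n_channels, mean_open_frames = 2) {
  stopifnot(inherits(record, "idealized_record"))
  N <- assert_count(n_channels, "n_channels", min = 1L)
  if (record$duration_frames < 100L)
    stopf("record too short for coupling estimation (< 100 frames)")
  if (N < record$n_levels_reached)
    stopf("n_channels (%d) < levels reached (%d)", N, record$n_levels_reached)
  if (N == 1L) {
    return(structure(list(kappa = NA_real_, open_prob = mean(record$levels),
                          log_likelihood = NA_real_, n_channels = 1L,
                          identifiable = FALSE),
                     class = "coupling_estimate"))
  }

  lv <- record$levels
  # transition counts
  C <- matrix(0, N + 1, N + 1)
  tab <- table(factor(lv[-length(lv)], levels = 0:N),
               factor(lv[-1], levels = 0:N))
  C[] <- as.numeric(tab)

  p_hi <- mean_open_frames / (mean_open_frames + 1) - 1e-4
  negll <- function(par) {
    P <- coupled_transition_matrix(N, par[2], par[1], mean_open_frames)
    lp <- suppressWarnings(log(P))
    lp[C == 0] <- 0
    if (any(!is.finite(lp[C > 0]))) return(1e12)
    -sum(C * lp)
  }

  starts <- expand.grid(kappa = c(0.05, 0.5, 0.95),
                        p = c(0.05, min(0.3, p_hi / 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), negll, method = "L-BFGS-B",
            lower = c(0, 1e-4), upper = c(1, p_hi)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("coupling-coefficient optimization failed")
  structure(list(kappa = best$par[1], open_prob = best$par[2],
                 log_likelihood = -best$value, n_channels = N,
                 identifiable = TRUE),
            class = "coupling_estimate")
}

#' Summarize sparklet sites across cells
#'
#' Cells are supplied as a list (one element per cell) of lists of
#' `site_activity` objects; cells with no detected sites are included and
#' contribute an nPs of 0 to the all-site mean, so silent cells lower the
#' population average as they should.
#'
#' @param cells list of per-cell lists of `site_activity` objects (empty
#'   list = silent cell).
#' @return a list: `sites_per_cell` (vector), `mean_sites_per_cell`,
#'   `mean_nps_low`, `mean_nps_high` (NA when a class is absent), and
#'   `mean_nps_all` (silent cells included as 0).
#' @export
site_summary <- function(cells) {
  stopifnot(is.list(cells))
  nsites <- vapply(cells, length, integer(1))
  acts <- unlist(cells, recursive = FALSE)
  nps <- vapply(acts, function(a) a$nPs, numeric(1))
  cls <- vapply(acts, function(a) a$activity_class, character(1))
  all_vals <- c(nps, rep(0, sum(nsites == 0L)))
  list(sites_per_cell = nsites,
       mean_sites_per_cell = if (length(nsites)) mean(nsites) else NA_real_,
       mean_nps_low = if (any(cls == "low")) mean(nps[cls == "low"]) else NA_real_,
       mean_nps_high = if (any(cls == "high")) mean(nps[cls == "high"]) else NA_real_,
       mean_nps_all = if (length(all_vals)) mean(all_vals) else NA_real_)
}
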
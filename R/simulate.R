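#' Configuration of the synthetic sEMG generator
#'
#' The generator emulates a multichannel gesture-recognition recording:
#' per trial of class g, channel c carries AR(4)-shaped (colored) Gaussian
#' noise scaled by a class-by-channel gain, plus white baseline noise.
#' Informative channels have class-dependent gains so their amplitude
#' envelope discriminates the gestures; uninformative channels have gain 1
#' for every class. This captures the amplitude/variance structure that the
#' time-domain features measure — it is a test harness, not a biophysical
#' EMG model.
#'
#' @param n_channels,n_classes Channel and gesture-class counts
#'   (defaults 8 and 7, the usual armband configuration).
#' @param sampling_rate Hz (default 1000).
#' @param trial_duration Seconds per trial (default 2).
#' @param trials_per_class Trials per gesture class (default 30).
#' @param informative_map `n_classes` x `n_channels` gain matrix; default
#'   [default_informative_map()] with planted channels 3, 5, 8.
#' @param baseline_noise_sd SD of the additive white noise (default 0.2;
#'   the colored-noise carrier has unit innovation SD).
#' @param amplitude_scale Overall output scale (default 25, putting the
#'   resting signal in the tens of units, like microvolt-scale sEMG, so the
#'   conventional zero-crossing threshold T = 10 is meaningful).
#' @param ar_shaping Order-4 AR coefficients coloring the carrier noise;
#'   must define a stationary process.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 8L, n_classes = 7L, sampling_rate = 1000,
                       trial_duration = 2, trials_per_class = 30L,
                       informative_map = NULL, baseline_noise_sd = 0.2,
                       amplitude_scale = 25,
                       ar_shaping = c(0.6, -0.3, 0.1, -0.05)) {
  if (is.null(informative_map))
    informative_map <- default_informative_map(n_channels, n_classes)
  stopifnot(nrow(informative_map) == n_classes,
            ncol(informative_map) == n_channels,
            all(informative_map > 0),
            sampling_rate > 0, trial_duration > 0, trials_per_class >= 1)
  roots <- polyroot(c(1, -ar_shaping))
  if (any(Mod(roots) <= 1))
    stop("ar_shaping is not a stationary AR process ",
         "(characteristic root on or inside the unit circle)")
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 sampling_rate = sampling_rate,
                 trial_duration = trial_duration,
                 trials_per_class = as.integer(trials_per_class),
                 informative_map = informative_map,
                 baseline_noise_sd = baseline_noise_sd,
                 amplitude_scale = amplitude_scale,
                 ar_shaping = ar_shaping),
            class = "sim_config")
}

#' Default class-by-channel gain map with planted informative channels
#'
#' Each gesture class activates a distinct non-empty subset of the planted
#' channels (the binary code of the class index), with gain `gain` on
#' active planted channels and 1 elsewhere. With 3 planted channels this
#' yields exactly 7 distinct activation patterns — one per class of the
#' default configuration.
#'
#' @param n_channels,n_classes Dimensions of the map.
#' @param informative Indices of the planted informative channels.
#' @param gain Amplitude gain of an active informative channel (default 3).
#' @return `n_classes` x `n_channels` numeric gain matrix.
#' @export
default_informative_map <- function(n_channels = 8L, n_classes = 7L,
                                    informative = c(3L, 5L, 8L), gain = 3) {
  stopifnot(all(informative >= 1), all(informative <= n_channels), gain > 0)
  map <- matrix(1, n_classes, n_channels)
  ni <- length(informative)
  npat <- 2^ni - 1
  for (g in seq_len(n_classes)) {
    pat <- ((g - 1) %% npat) + 1   # non-empty binary pattern over planted set
    bits <- as.integer(intToBits(pat))[seq_len(ni)]
    map[g, informative[bits == 1L]] <- gain
  }
  map
}

# One colored-noise trace: AR(4)-filtered Gaussian innovations, burn-in
# discarded so the trace starts in (approximate) stationarity.
colored_noise <- function(n, phi, burnin = 200L) {
  e <- stats::rnorm(n + burnin)
  x <- stats::filter(e, filter = phi, method = "recursive")
  as.numeric(x[(burnin + 1):(burnin + n)])
}

#' Generate a synthetic multichannel sEMG-like recording
#'
#' Trials are laid out class-interleaved (class 1 trial 1, class 2 trial 1,
#' ..., class 1 trial 2, ...) with per-sample labels, ready for
#' [build_feature_matrix()]. Fully reproducible from `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A [recording()] with per-sample labels `g1..gG`.
#' @export
generate_recording <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_per <- round(cfg$sampling_rate * cfg$trial_duration)
  trials <- expand.grid(class = seq_len(cfg$n_classes),
                        trial = seq_len(cfg$trials_per_class))
  blocks <- vector("list", nrow(trials))
  labels <- character(0)
  for (t in seq_len(nrow(trials))) {
    g <- trials$class[t]
    block <- matrix(0, n_per, cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      carrier <- colored_noise(n_per, cfg$ar_shaping)
      block[, ch] <- cfg$amplitude_scale *
        (cfg$informative_map[g, ch] * carrier +
           cfg$baseline_noise_sd * stats::rnorm(n_per))
    }
    blocks[[t]] <- block
    labels <- c(labels, rep(paste0("g", g), n_per))
  }
  recording(do.call(rbind, blocks), cfg$sampling_rate,
            channel_ids = paste0("ch", seq_len(cfg$n_channels)),
            labels = labels)
}
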
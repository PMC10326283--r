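# Synthetic paired corpora with known ground truth.
#
# The generator emulates the structure of a reference articulatory-acoustic
# corpus (one "reference speaker" with synchronized articulography and
# vocoder features) and a "patient" corpus of the same sentences re-uttered
# with different timing (a random monotone warp), a fixed affine speaker
# shift on the mel features, and multichannel neural signals whose
# band-limited amplitudes follow a lagged linear readout of the patient's
# articulatory and acoustic features. Everything is deterministic given the
# config seed.
#
# Latent articulation is smoothed Gaussian noise (low-pass, cutoff ~8 Hz):
# only its statistical structure (smooth, band-limited, correlated with the
# acoustics through a fixed map) matters for exercising the pipeline.
# Electrodes driven by articulatory latents are tagged "frontal", those
# driven by acoustic latents "temporal", so region analyses have a testable
# ground truth. The per-band amplitude modulation depth is kept moderate
# (0.2) so that measured band powers stay close to linear in the latent
# drives and a linear decoder with the right context window can recover the
# speech features from noise-free signals.

#' Synthetic corpus configuration
#'
#' @param n_sentences number of sentences (>= 1).
#' @param duration_range sentence duration range in seconds (both > 0).
#' @param n_electrodes number of neural channels.
#' @param n_latent latent articulatory dimensions (default 14).
#' @param readout_lags neural readout lags in ms (multiples of 10).
#' @param noise_sd 1/f neural noise level relative to the signal (unitless).
#' @param warp_strength patient timing-warp strength in [0, 1).
#' @param neural_rate raw neural sampling rate in Hz (default 1000).
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_sentences = 40L, duration_range = c(3, 5),
                         n_electrodes = 16L, n_latent = 14L,
                         readout_lags = c(-50, 0, 50), noise_sd = 0.35,
                         warp_strength = 0.3, neural_rate = 1000,
                         seed = 1L) {
  if (n_sentences < 1) stop("n_sentences must be >= 1")
  if (any(duration_range <= 0)) stop("durations must be > 0")
  if (warp_strength < 0 || warp_strength >= 1)
    stop("warp_strength must be in [0, 1)")
  if (any(readout_lags %% 10 != 0)) stop("readout lags must be multiples of 10 ms")
  if (n_electrodes %% 2 != 0 || n_electrodes < 4)
    stop("n_electrodes must be even and >= 4 (balanced offset groups)")
  structure(list(n_sentences = as.integer(n_sentences),
                 duration_range = duration_range,
                 n_electrodes = as.integer(n_electrodes),
                 n_latent = as.integer(n_latent),
                 readout_lags = readout_lags, noise_sd = noise_sd,
                 warp_strength = warp_strength, neural_rate = neural_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited unit-variance Gaussian trajectories (frames x k): white noise
# pre-shaped toward low frequencies (articulator-like spectral rolloff) and
# low-pass filtered at `cutoff` Hz
smooth_noise <- function(n, k, cutoff = 8, rate = 100, shape_hz = 2.5) {
  lp <- signal::butter(4, cutoff / (rate / 2), type = "low")
  pre <- signal::butter(2, shape_hz / (rate / 2), type = "low")
  m <- matrix(stats::rnorm((n + 200) * k), n + 200, k)
  out <- apply(m, 2, function(x)
    as.numeric(signal::filtfilt(lp, signal::filtfilt(pre, x))))
  out <- out[101:(100 + n), , drop = FALSE]
  sweep(out, 2, apply(out, 2, stats::sd), "/")
}

# raised-cosine speech gate: silence margins with smooth onset/offset ramps
speech_gate <- function(n, margin = 0.50, ramp = 0.20, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  dur <- n / rate
  up <- pmin(pmax((t - margin) / ramp, 0), 1)
  down <- pmin(pmax(((dur - margin) - t) / ramp, 0), 1)
  g <- 0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * down))
  g
}

#' The fixed articulatory-to-acoustic map of a synthetic corpus
#'
#' Smooth nonlinear (one tanh layer) frame-wise map from 14 articulatory
#' features to 25 mel-cepstral coefficients; c_0 tracks overall articulatory
#' energy so silent (rest-position) frames are quiet.
#'
#' @param ema frames x n_latent articulatory matrix.
#' @param map map parameters (from a corpus's `ground_truth$artic_map`).
#' @return frames x 25 mel matrix.
#' @export
artic_to_acoustic <- function(ema, map) {
  E <- as.matrix(unclass(ema))
  h <- tanh(E %*% map$M1 * 0.5)
  core <- h %*% map$M2
  energy <- tanh(rowSums(E^2) / ncol(E))
  mel <- core * 0.5
  mel[, 1] <- -6 + 4 * energy + 0.4 * core[, 1]
  mel
}

new_artic_map <- function(n_latent, hidden = 32L) {
  list(M1 = matrix(stats::rnorm(n_latent * hidden, sd = 1 / sqrt(n_latent)),
                   n_latent, hidden),
       M2 = matrix(stats::rnorm(hidden * 25, sd = 1 / sqrt(hidden)),
                   hidden, 25))
}

# two-state semi-Markov voicing with minimum state duration 100 ms, plus a
# smooth F0 contour in [80, 300] Hz; unvoiced and out-of-gate frames are 0
gen_f0 <- function(n, gate, rate = 100) {
  voiced <- logical(n)
  pos <- 1L
  state <- TRUE
  while (pos <= n) {
    len <- round((0.100 + stats::rexp(1, 1 / 0.25)) * rate)
    voiced[pos:min(n, pos + len - 1L)] <- state
    pos <- pos + len
    state <- !state
  }
  contour <- 160 + 45 * smooth_noise(n, 1, cutoff = 2)[, 1]
  contour <- pmin(pmax(contour, 80), 300)
  f0 <- ifelse(voiced & gate > 0.5, contour, 0)
  f0[!drop_short_runs(f0 > 0, round(0.050 * rate))] <- 0
  f0
}

#' Generate the reference-speaker corpus
#'
#' Each sentence carries a 14-feature band-limited articulatory track, a
#' 25-feature mel track produced by the corpus's fixed smooth nonlinear map,
#' a piecewise voiced/unvoiced F0 track in [80, 300] Hz, a 0/1 speech-gate
#' flag, and a waveform synthesized by the vocoder back end. Bit-identical
#' for identical seeds.
#'
#' @param config a `synth_config`.
#' @param synthesize_audio set FALSE to skip waveform synthesis when only
#'   the feature tracks are needed (faster).
#' @return list with `sentences` (list of `sentence_record`) and
#'   `ground_truth` (the articulatory-to-acoustic map parameters).
#' @export
make_reference_corpus <- function(config, synthesize_audio = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, "reference"), {
    map <- new_artic_map(config$n_latent)
    sentences <- vector("list", config$n_sentences)
    for (s in seq_len(config$n_sentences)) {
      dur <- stats::runif(1, config$duration_range[1], config$duration_range[2])
      n <- round(dur * 100)
      gate <- speech_gate(n)
      ema <- smooth_noise(n, config$n_latent) * gate
      mel <- artic_to_acoustic(ema, map)
      f0 <- gen_f0(n, gate)
      tracks <- list(
        ema = feature_track(ema, labels = paste0("ema", seq_len(config$n_latent))),
        mel = feature_track(mel, labels = paste0("c", 0:24)),
        f0 = feature_track(f0, labels = "f0"),
        speech = feature_track(as.numeric(gate > 0.1), labels = "speech"))
      audio <- if (synthesize_audio)
        mlsa_synthesize(tracks$mel, f0) else NULL
      sentences[[s]] <- sentence_record(
        id = sprintf("s%03d", s),
        text = sprintf("synthetic sentence %d", s),
        condition = if (s %% 2 == 0) "repeat" else "read",
        audio = audio, tracks = tracks, speaker = "reference")
    }
    list(sentences = sentences,
         ground_truth = list(artic_map = map),
         config = config)
  })
}

# strictly increasing random warp: patient frame j in 1..m -> fractional
# reference frame in [1, n]; identity when strength = 0
gen_warp <- function(n, m, strength) {
  if (strength == 0 && m == n) return(seq_len(n))
  u <- seq(0, 1, length.out = m)
  if (strength > 0) {
    bump <- smooth_noise(m, 1, cutoff = 1.5)[, 1]
    slope <- 1 + 0.9 * strength * bump / max(abs(bump), 1)
    # guard strict monotonicity
    slope <- pmax(slope, 0.05)
    phi <- cumsum(slope) - slope[1]
    phi <- phi / phi[m]
  } else phi <- u
  1 + phi * (n - 1)
}

# sample track rows at fractional positions (pchip per column)
warp_track <- function(m, pos) {
  m <- as.matrix(unclass(m))
  vapply(seq_len(ncol(m)), function(j)
    pchip_interp(seq_len(nrow(m)), m[, j], pos), numeric(length(pos)))
}

#' Generate the patient corpus from a reference corpus
#'
#' Each patient sentence re-utters the reference sentence along a random
#' strictly increasing time warp (strength per config) with a fixed affine
#' speaker shift on the mel features and a pitch-scaled F0. Multichannel
#' neural signals are synthesized so that band-limited carrier amplitudes
#' (and a slow 0-8 Hz component) follow lagged linear mixtures of the
#' patient's articulatory and acoustic features, plus 1/f-shaped noise at
#' `noise_sd`; articulatory-driven electrodes are tagged "frontal",
#' acoustically driven ones "temporal".
#'
#' @param ref a reference corpus from [make_reference_corpus()].
#' @param config the `synth_config` (must match the reference corpus).
#' @param synthesize_audio set FALSE to skip waveform synthesis.
#' @return list with `sentences` (each with tracks ema/mel/f0/speech and a
#'   `neural` `neural_recording`) and `ground_truth` (true warps, readout
#'   description, speaker shift, pitch ratio, plus the reference map).
#' @export
make_patient_corpus <- function(ref, config, synthesize_audio = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (length(ref$sentences) != config$n_sentences)
    stop("reference corpus does not match config (mismatched sentence sets)")
  with_seed(child_seed(config$seed, "patient"), {
    shift_gain <- stats::runif(25, 0.85, 1.15)
    shift_offs <- c(stats::runif(1, -0.3, 0.3), stats::runif(24, -0.25, 0.25))
    pitch_ratio <- 1.25
    n_lat <- config$n_latent
    warps <- vector("list", config$n_sentences)
    sentences <- vector("list", config$n_sentences)
    # pass 1: warped tracks
    for (s in seq_len(config$n_sentences)) {
      rs <- ref$sentences[[s]]
      n <- n_frames(rs$tracks$ema)
      tempo <- 1 + config$warp_strength * stats::runif(1, -0.2, 0.2)
      m <- max(2L, round(n * tempo))
      pos <- gen_warp(n, m, config$warp_strength)
      warps[[s]] <- pos
      ema <- warp_track(rs$tracks$ema, pos)
      mel <- warp_track(rs$tracks$mel, pos)
      mel <- sweep(sweep(mel, 2, shift_gain, "*"), 2, shift_offs, "+")
      f0r <- as.numeric(rs$tracks$f0)
      f0 <- f0r[clamp_idx(round(pos), n)]            # nearest neighbor
      f0[f0 > 0] <- pmin(pmax(f0[f0 > 0] * pitch_ratio, 80), 300)
      speech <- as.numeric(rs$tracks$speech)[clamp_idx(round(pos), n)]
      sentences[[s]] <- sentence_record(
        id = rs$id, text = rs$text, condition = rs$condition, audio = NULL,
        tracks = list(
          ema = feature_track(ema, labels = colnames(rs$tracks$ema)),
          mel = feature_track(mel, labels = colnames(rs$tracks$mel)),
          f0 = feature_track(f0, labels = "f0"),
          speech = feature_track(speech, labels = "speech")),
        speaker = "patient")
    }
    # latent z-score statistics across the patient corpus
    all_lat <- do.call(rbind, lapply(sentences, function(s)
      cbind(unclass(s$tracks$ema), unclass(s$tracks$mel),
            as.numeric(s$tracks$f0))))
    lat_mean <- colMeans(all_lat)
    lat_sd <- apply(all_lat, 2, stats::sd)
    lat_sd[lat_sd == 0] <- 1
    # electrode readout: the n_electrodes signal contacts split into
    # frontal (articulatory latents) and temporal (acoustic latents)
    # halves; two additional quiet strip contacts (reference and ground)
    # are appended to the montage
    n_el <- config$n_electrodes
    n_frontal <- ceiling(n_el / 2)
    # Per-electrode readout: a lag, one latent per amplitude-modulated
    # carrier, and a slow 0-8 Hz component mixing a few latents (feeding the
    # 0.5-5 Hz feature). Carriers are spaced 20 Hz apart starting at 35 Hz:
    # the 200 ms Hamming analysis window has its first spectral null at
    # 10 Hz, so each carrier sits on its neighbours' nulls and band powers
    # stay linear in their own drive; the lowest bands are left to the slow
    # component.
    n_carriers <- 9L
    f_centers <- seq(35, 195, by = 20)
    # Carrier-to-latent assignment is a global round-robin within each
    # region so that every latent is observed by a balanced number of
    # carriers across electrodes (and hence across several readout lags);
    # temporal electrodes always include F0 in their slow mixture, mirroring
    # its strong auditory-cortex representation.
    f0_idx <- n_lat + 26L
    n_temporal <- n_el - n_frontal
    # carriers: global round-robin within each region; the slow-mixture
    # slots are then given to the latents with the lowest carrier coverage,
    # so every latent is observed by a balanced number of readout channels
    region_plan <- function(lat_set, n_e, fixed_slow = integer(0)) {
      carriers <- matrix(rep(lat_set, length.out = n_e * n_carriers),
                         nrow = n_carriers)
      n_free <- 3L - length(fixed_slow)
      cover <- table(factor(carriers, levels = lat_set))
      pool <- rep(lat_set[order(cover, lat_set)], length.out = n_e * n_free)
      slows <- matrix(pool, nrow = n_free)
      list(carriers = carriers, slows = slows)
    }
    plan_f <- region_plan(seq_len(n_lat), n_frontal)
    plan_t <- region_plan(n_lat + seq_len(25), n_temporal,
                          fixed_slow = f0_idx)   # f0 in every slow mixture
    lag_plan <- rep(config$readout_lags,
                    length.out = n_el)[sample.int(n_el)]
    readout <- lapply(seq_len(n_el), function(e) {
      frontal <- e <= n_frontal
      e_in_region <- if (frontal) e else e - n_frontal
      band_k <- if (frontal) plan_f$carriers[, e_in_region]
        else plan_t$carriers[, e_in_region]
      slow_k <- if (frontal) plan_f$slows[, e_in_region]
        else c(f0_idx, plan_t$slows[seq_len(2), e_in_region])
      list(region = if (frontal) "frontal" else "temporal",
           lag_frames = lag_plan[e] / 10,
           band_latent = band_k,
           band_gain = sample(c(-1, 1), n_carriers, TRUE) *
             stats::runif(n_carriers, 0.6, 1),
           band_phase = stats::runif(n_carriers, 0, 2 * pi),
           slow_latent = slow_k,
           slow_gain = stats::runif(3, 0.6, 1.0) * sample(c(-1, 1), 3, TRUE))
    })
    mod_depth <- 0.4
    rate <- config$neural_rate
    for (s in seq_len(config$n_sentences)) {
      sen <- sentences[[s]]
      m <- n_frames(sen$tracks$ema)
      z <- cbind(unclass(sen$tracks$ema), unclass(sen$tracks$mel),
                 as.numeric(sen$tracks$f0))
      z <- sweep(sweep(z, 2, lat_mean), 2, lat_sd, "/")
      nsamp <- round(m / 100 * rate)
      t_s <- (seq_len(nsamp) - 1) / rate
      fr_grid <- (seq_len(m) - 1) / 100
      X <- matrix(0, n_el, nsamp)
      for (e in seq_len(n_el)) {
        ro <- readout[[e]]
        idx <- clamp_idx(seq_len(m) - ro$lag_frames, m)
        zd <- z[idx, , drop = FALSE]                  # lagged latents, 100 Hz
        sig <- numeric(nsamp)
        for (b in seq_len(n_carriers)) {
          drv <- zd[, ro$band_latent[b]] * ro$band_gain[b]
          # carrier amplitude = sqrt of the target band power, so the
          # measured power is linear in the (slow) drive
          amp <- (1 / sqrt(f_centers[b])) *
            sqrt(pmax(1 + mod_depth * drv, 0.1))
          amp_s <- stats::approx(fr_grid, amp, xout = t_s, rule = 2)$y
          sig <- sig + amp_s * cos(2 * pi * f_centers[b] * t_s +
                                     ro$band_phase[b])
        }
        slow_mix <- zd[, ro$slow_latent, drop = FALSE] %*% ro$slow_gain
        sig <- sig + stats::approx(fr_grid, slow_mix, xout = t_s, rule = 2)$y
        if (config$noise_sd > 0)
          sig <- sig + config$noise_sd * stats::sd(sig) * pink_noise(nsamp)
        X[e, ] <- sig
      }
      # Montage realism that also keeps the common-median reference benign:
      # electrodes carry large static polarization offsets (half positive,
      # half negative) and a quiet reference contact sits in between, so the
      # across-channel median is always the latent-free reference channel.
      # A shared mains artifact is added to every contact; the common median
      # reference removes it.
      sd_sig <- max(apply(X, 1, stats::sd))
      offsets <- rep(c(30, -30) * sd_sig, length.out = n_el)
      X <- X + offsets
      quiet <- function() if (config$noise_sd > 0)
        config$noise_sd * sd_sig * pink_noise(nsamp) else numeric(nsamp)
      X <- rbind(X, quiet(), quiet())          # reference and ground contacts
      artifact <- 2 * sd_sig * sin(2 * pi * 50 * t_s)
      X <- sweep(X, 2, artifact, "+")
      montage <- data.frame(
        channel = c(sprintf("e%02d", seq_len(n_el)), "ref", "gnd"),
        region = c(vapply(readout, `[[`, "", "region"),
                   "reference", "reference"))
      sen$neural <- neural_recording(X, rate, montage)
      if (synthesize_audio)
        sen$audio <- mlsa_synthesize(sen$tracks$mel, sen$tracks$f0)
      sentences[[s]] <- sen
    }
    list(sentences = sentences,
         ground_truth = list(artic_map = ref$ground_truth$artic_map,
                             true_warps = warps,
                             readout = readout,
                             speaker_shift = list(gain = shift_gain,
                                                  offset = shift_offs),
                             pitch_ratio = pitch_ratio,
                             latent_stats = list(mean = lat_mean, sd = lat_sd)),
         config = config)
  })
}
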
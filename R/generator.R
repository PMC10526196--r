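# Synthetic cross-sensory EEG generator.
#
# Trials are sums of six band-limited Gaussian sources. Each band's source is
# white noise band-filtered with the same IIR definitions as the analysis
# filter bank, then spatially colored by the Cholesky factor of a
# band-and-emotion-specific SPD covariance. The two emotions share a base
# covariance per band and differ by exponentially scaled eigen-gains, so
# their Frobenius separation grows monotonically with class_sep. Sensory
# modality perturbs the mixing with an invertible rotation-plus-gain whose
# magnitude scales with shift_strength (identity for the reference modality,
# audio): this is the domain shift the adversarial adapter must remove.

#' Synthetic-data generator configuration
#'
#' Defaults mirror the acquisition design the pipeline targets: 20 subjects,
#' 3 sensory modalities x 2 emotions, 10 trials of 30 s per condition at
#' 500 Hz with a 1 s pre-stimulus baseline and 31 analysis channels.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per (modality, emotion) condition.
#' @param trial_s stimulation duration per trial, seconds.
#' @param pre_s pre-stimulus baseline duration, seconds.
#' @param fs sampling rate, Hz.
#' @param n_channels channel count K.
#' @param class_sep scalar >= 0; covariance separation between emotions.
#' @param shift_strength scalar >= 0; severity of the modality domain shift.
#' @param modality_crosstalk scalar >= 0 scaling the emotion-axis component
#'   of the modality shift (1 = full sensory-emotion crosstalk, 0 = pure
#'   rotation-plus-gain shift).
#' @param sensor_noise white sensor-noise standard deviation (signal units).
#' @param subject_jitter sd of per-(subject, band) log-gain covariance jitter.
#' @param band_weights signed per-band emotion-effect weights; magnitudes
#'   concentrate class information in alpha/beta bands (the usual carriers of
#'   emotion-related spectral differences) and alternating signs encode the
#'   classic reciprocity of alpha suppression with beta enhancement, so
#'   band-wise effects partially cancel in the broadband mixture.
#' @param active_bands subset of 1..6; only these band sources are summed
#'   (all six by default). Isolating one band exposes its generating
#'   covariance directly.
#' @param channel_names optional channel labels (length n_channels), e.g. a
#'   montage ending in a reference channel "FCz".
#' @param seed RNG seed from which all per-trial streams are derived.
#' @param structure_seed optional separate seed for the population-level
#'   structure (base covariance geometry, emotion axis, modality mixing);
#'   when NULL the structure follows \code{seed}. Fixing it across
#'   replicates re-samples new subjects and trials from the same underlying
#'   population, the usual design for replicated simulation studies.
#' @return a validated \code{generatorConfig} list.
#' @export
generatorConfig <- function(n_subjects = 20L, n_trials = 10L, trial_s = 30,
                            pre_s = 1, fs = 500, n_channels = 31L,
                            class_sep = 1, shift_strength = 1,
                            modality_crosstalk = 1,
                            sensor_noise = 0.2, subject_jitter = 0.1,
                            band_weights = c(0.2, 0.3, 1, -0.8, 0.6, -0.4),
                            active_bands = 1:6, channel_names = NULL,
                            seed = 1L, structure_seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
              trial_s = trial_s, pre_s = pre_s, fs = fs,
              n_channels = as.integer(n_channels), class_sep = class_sep,
              shift_strength = shift_strength,
              modality_crosstalk = modality_crosstalk,
              sensor_noise = sensor_noise,
              subject_jitter = subject_jitter, band_weights = band_weights,
              active_bands = as.integer(active_bands),
              channel_names = channel_names,
              seed = as.integer(seed),
              structure_seed = if (is.null(structure_seed)) NULL
                               else as.integer(structure_seed))
  stopifnot(cfg$fs > 0, cfg$n_channels >= 2L, cfg$n_subjects >= 1L,
            cfg$n_trials >= 1L, cfg$class_sep >= 0, cfg$shift_strength >= 0,
            cfg$sensor_noise >= 0, cfg$pre_s >= 0,
            cfg$modality_crosstalk >= 0,
            length(cfg$band_weights) == 6L,
            all(cfg$active_bands %in% 1:6),
            is.null(cfg$channel_names) ||
              length(cfg$channel_names) == cfg$n_channels,
            all(vapply(cfg[c("trial_s", "pre_s", "fs", "class_sep",
                             "shift_strength", "sensor_noise")],
                       function(v) is.finite(v), logical(1))))
  if (abs(cfg$trial_s * cfg$fs - round(cfg$trial_s * cfg$fs)) > 1e-9)
    stop("trial_s * fs must be an integer number of samples")
  class(cfg) <- "generatorConfig"
  cfg
}

channelLabels <- function(K) sprintf("CH%02d", seq_len(K))

structSeed <- function(config) config$structure_seed %||% config$seed

# SPD base covariance for one band: a single random spatial structure
# shared by all bands (one underlying cortical geometry), scaled by a
# 1/f-like per-band power profile. The shared eigenbasis is what lets
# signed band weights cancel in the broadband mixture.
bandBaseCov <- function(config, band_index) {
  K <- config$n_channels
  B <- withSeed(deriveSeed(structSeed(config), 101L), {
    A <- matrix(stats::rnorm(K * K), K, K)
    crossprod(A) / K + diag(K)
  })
  B * c(4, 3, 2.5, 2, 1.5, 1)[band_index]
}

# Unit-norm log-gain direction of the emotion effect, shared across bands
# (each band modulates the same spatial pattern up or down, with the signed
# per-band weight deciding direction and strength).
bandEmotionDirection <- function(config, band_index) {
  K <- config$n_channels
  withSeed(deriveSeed(structSeed(config), 202L), {
    v <- stats::rnorm(K)
    v / sqrt(sum(v^2))
  })
}

# Modality gain exponent along the emotion axis: sensory-emotion crosstalk.
# The reference modality (audio) is 0; visual shifts the spectral signature
# "up" the emotion axis, audio-visual "down", each in proportion to the
# band's emotion weight and shift_strength.
modalityKappa <- function(modality) {
  c(audio = 0, visual = 0.5, audiovisual = -0.5)[[modality]]
}

#' Band- and emotion-specific generating covariance
#'
#' Builds the SPD spatial covariance of one sub-band source for one emotion:
#' \eqn{L \, diag(e^{(\pm s + \kappa_m \cdot shift) w_b v}) L^T} with
#' \eqn{L} the Cholesky factor of the band's base covariance, \eqn{v} a
#' fixed unit direction, \eqn{w_b} the signed per-band emotion weight,
#' \eqn{s} = \code{class_sep} (sign + for pleasure, - for unpleasure) and
#' \eqn{\kappa_m} the modality crosstalk coefficient (0 for the reference
#' modality). At \code{class_sep = 0} the two emotions coincide; their
#' Frobenius distance is strictly increasing in \code{class_sep}.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param band_index band 1..6.
#' @param emotion "pleasure" or "unpleasure".
#' @param modality sensory modality ("audio", the reference, by default);
#'   non-reference modalities displace the spectral signature along the same
#'   emotion axis in proportion to \code{shift_strength} — the
#'   sensory-emotion crosstalk that makes raw cross-modal training data
#'   misleading.
#' @return a K x K SPD matrix.
#' @export
makeBandCovariances <- function(config, band_index, emotion,
                                modality = "audio") {
  if (!(band_index %in% 1:6)) stop("band_index must be in 1..6")
  emotion <- match.arg(emotion, .EMOTIONS)
  modality <- match.arg(modality, .MODALITIES)
  B <- bandBaseCov(config, band_index)
  L <- t(chol(B))
  v <- bandEmotionDirection(config, band_index)
  sgn <- if (emotion == "pleasure") 1 else -1
  w <- config$band_weights[band_index]
  expo <- (sgn * config$class_sep +
           config$modality_crosstalk * modalityKappa(modality) *
             config$shift_strength) * w * v
  S <- L %*% (exp(expo) * t(L))
  (S + t(S)) / 2
}

# Invertible modality mixing: a mild rotation (expm of a fixed random
# skew-symmetric generator scaled by shift_strength) times a scalar gain;
# identity for audio. The dominant component of the modality shift is the
# emotion-axis crosstalk in makeBandCovariances, which this generic mixing
# perturbation complements.
modalityMixing <- function(config, modality) {
  K <- config$n_channels
  if (modality == "audio" || config$shift_strength == 0) return(diag(K))
  idx <- match(modality, .MODALITIES)
  res <- withSeed(deriveSeed(structSeed(config), 303L, idx), {
    W <- matrix(stats::rnorm(K * K), K, K)
    list(S = (W - t(W)) / sqrt(2 * K),      # unit-scale skew generator
         gain = 1 + config$shift_strength * 0.05 * stats::runif(1, 0.5, 1))
  })
  # expm of the skew-symmetric generator (an exact rotation): i*S is
  # Hermitian, so expm(S) = V exp(-i Lambda) V^H with i*S = V Lambda V^H.
  E <- eigen(1i * config$shift_strength * 0.1 * res$S, symmetric = TRUE)
  R <- Re(E$vectors %*% (exp(-1i * E$values) * Conj(t(E$vectors))))
  res$gain * R
}

# per-(subject, band) covariance log-gain jitter
subjectGain <- function(config, subject, band_index) {
  withSeed(deriveSeed(config$seed, 404L, subject, band_index),
           exp(stats::rnorm(1, 0, config$subject_jitter)))
}

# Band-limited unit-variance noise: white Gaussian filtered to the band,
# rescaled to unit variance per channel.
bandLimitedNoise <- function(K, n, fs, band) {
  Z <- matrix(stats::rnorm(K * n), K, n)
  Z <- butterBandpass(Z, fs, band[1], band[2])
  sds <- sqrt(rowMeans(Z^2))
  sds[sds == 0] <- 1
  Z / sds
}

#' Simulate one cross-sensory trial
#'
#' Generates a \linkS4class{Recording}: the stimulation period is the sum of
#' six band-limited sources colored by the (modality-perturbed) band/emotion
#' covariances; the pre-stimulus baseline uses the emotion-independent base
#' covariances; white sensor noise and a per-channel DC offset (for baseline
#' correction to remove) are added throughout.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param subject subject index.
#' @param modality one of "audio", "visual", "audiovisual".
#' @param emotion "pleasure" or "unpleasure".
#' @param trial trial index (selects the trial's RNG stream).
#' @return a \linkS4class{Recording}.
#' @export
simulateTrial <- function(config, subject, modality, emotion, trial = 1L) {
  modality <- match.arg(modality, .MODALITIES)
  emotion <- match.arg(emotion, .EMOTIONS)
  K <- config$n_channels
  nPre <- round(config$pre_s * config$fs)
  nStim <- round(config$trial_s * config$fs)
  bands <- bandDefinitions()
  M <- modalityMixing(config, modality)
  seed <- deriveSeed(config$seed, 505L, subject,
                     match(modality, .MODALITIES),
                     match(emotion, .EMOTIONS), trial)
  withSeed(seed, {
    X <- matrix(0, K, nPre + nStim)
    for (b in intersect(seq_len(nrow(bands)), config$active_bands)) {
      gSub <- subjectGain(config, subject, b)
      SigS <- gSub *
        (M %*% makeBandCovariances(config, b, emotion, modality) %*% t(M))
      SigP <- gSub * bandBaseCov(config, b)
      Ls <- t(chol((SigS + t(SigS)) / 2))
      Lp <- t(chol(SigP))
      lims <- c(bands$low[b], bands$high[b])
      if (nPre > 0)
        X[, seq_len(nPre)] <- X[, seq_len(nPre)] +
          Lp %*% bandLimitedNoise(K, nPre, config$fs, lims)
      X[, nPre + seq_len(nStim)] <- X[, nPre + seq_len(nStim)] +
        Ls %*% bandLimitedNoise(K, nStim, config$fs, lims)
    }
    if (config$sensor_noise > 0)
      X <- X + config$sensor_noise * matrix(stats::rnorm(length(X)), K)
    X <- X + stats::rnorm(K, 0, 2)  # per-channel DC offset (recycled by column)
    new("Recording", data = X, fs = config$fs,
        onsetIndex = as.integer(nPre + 1L),
        subject = sprintf("S%02d", subject), modality = modality,
        emotion = emotion, trial = as.integer(trial),
        channels = config$channel_names %||% channelLabels(K))
  })
}

#' Enumerate the acquisition design
#'
#' The full trial grid the generator realizes: every subject x modality x
#' emotion x trial combination, in a deterministic order.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return data.frame with columns subject, modality, emotion, trial.
#' @export
datasetGrid <- function(config) {
  g <- expand.grid(trial = seq_len(config$n_trials), emotion = .EMOTIONS,
                   modality = .MODALITIES, subject = seq_len(config$n_subjects),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("subject", "modality", "emotion", "trial")]
}

#' Simulate a cross-sensory dataset
#'
#' Realizes the full design grid (or a subject subset) as a list of
#' \linkS4class{Recording}s. Identical seeds give bit-identical datasets;
#' each trial has its own derived RNG stream, so any subset is reproducible
#' independently of the rest.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param subjects optional subject indices to restrict to.
#' @return list of \linkS4class{Recording}s.
#' @export
simulateDataset <- function(config, subjects = NULL) {
  grid <- datasetGrid(config)
  if (!is.null(subjects)) grid <- grid[grid$subject %in% subjects, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    simulateTrial(config, grid$subject[i], grid$modality[i],
                  grid$emotion[i], grid$trial[i]))
}

#' Inject Gaussian noise at a target signal-to-noise ratio
#'
#' Adds i.i.d. zero-mean Gaussian noise scaled so that
#' \eqn{10 \log_{10}(P_{signal}/P_{noise})} equals \code{snr_db} in
#' expectation, with P the mean squared amplitude over all channels and
#' samples. The realized (empirical) SNR is attached as attribute
#' \code{"realized_snr_db"}.
#'
#' @param signal numeric vector, matrix or 3-d array with nonzero power.
#' @param snr_db target SNR in dB.
#' @return the noised signal, same shape, with realized-SNR attribute.
#' @export
injectNoise <- function(signal, snr_db) {
  p <- mean(signal^2)
  if (p == 0) stop("zero-power signal: SNR undefined")
  sigma <- sqrt(p / 10^(snr_db / 10))
  g <- stats::rnorm(length(signal), 0, sigma)
  out <- signal + g
  attributes(out) <- attributes(signal)
  attr(out, "realized_snr_db") <- 10 * log10(p / mean(g^2))
  out
}
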
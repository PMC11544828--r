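# SCG signal processing: beat detection, ensemble averaging, and the four
# waveform features (RR, diastolic peak-to-peak, diastolic morphology PC-1
# score, systolic spectrum PC-1 score).

#' Analysis window parameters for SCG feature extraction
#'
#' The ensemble beat spans 0-80% of the median RR interval after the
#' fiducial, resampled to a fixed `gridN`-point grid. The systolic complex
#' is taken as the first 300 ms after the fiducial; the diastolic complex as
#' 50-80% of the median RR. The systolic magnitude spectrum is the FFT of
#' the Hann-windowed systolic segment, zero-padded to `nfft`, restricted to
#' bins at or below `maxFreq`.
#'
#' @param gridN points in the resampled beat grid.
#' @param windowFrac beat window length as a fraction of median RR.
#' @param sysWinSec systolic window (s).
#' @param diaFrac diastolic window as fractions of median RR.
#' @param maxFreq upper frequency bound of the systolic spectrum (Hz).
#' @param nfft FFT length for the systolic spectrum.
#' @param minBeats minimum usable beats for an ensemble average.
#' @param outlierR Pearson-correlation threshold against the point-wise
#'   median beat below which a beat is rejected.
#' @return A named list of window parameters.
#' @export
scgWindows <- function(gridN = 512L, windowFrac = 0.8, sysWinSec = 0.3,
                       diaFrac = c(0.5, 0.8), maxFreq = 50, nfft = 256L,
                       minBeats = 15L, outlierR = 0.5) {
  stopifnot(diaFrac[1] < diaFrac[2])
  if (diaFrac[2] > windowFrac)
    stop("configuration error: diastolic window exceeds the beat window",
         call. = FALSE)
  list(gridN = as.integer(gridN), windowFrac = windowFrac,
       sysWinSec = sysWinSec, diaFrac = diaFrac, maxFreq = maxFreq,
       nfft = as.integer(nfft), minBeats = as.integer(minBeats),
       outlierR = outlierR)
}

# Analytic (Hilbert) envelope via FFT. For a Gaussian-windowed cosine the
# envelope peaks at the burst center, which is what the detector localizes.
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect heartbeats in an SCG recording
#'
#' Band-passes the trace to the systolic band (13-45 Hz), takes the analytic
#' envelope, and picks envelope peaks separated by at least 0.4 s and above
#' 30% of the largest peak. Detected times are the systolic-complex centers.
#' If the recording already carries fiducials (e.g. generator ground truth),
#' they are returned unchanged.
#'
#' @param rec an [SCGRecording-class] of at least 10 s.
#' @param minBeats minimum acceptable beat count.
#' @return Strictly increasing numeric vector of beat times (s).
#' @export
#' @examples
#' subj <- generateCohort(cohortSpec(n = 1, nPremature = 0L,
#'                                   nBattery = 0L, seed = 3))[1, ]
#' rec <- simulateScg(subj, "rest", scgSimConfig(), seed = 1)
#' length(detectBeats(rec))
detectBeats <- function(rec, minBeats = 15L) {
  stopifnot(methods::is(rec, "SCGRecording"))
  if (!is.null(fiducialTimes(rec))) return(fiducialTimes(rec))
  fs <- sampleRate(rec)
  x <- samples(rec)
  if (length(x) / fs < 10)
    stop("invalid recording: must be at least 10 s for beat detection",
         call. = FALSE)
  # 13-45 Hz isolates the systolic complex: diastolic energy sits at or
  # below ~10 Hz and would otherwise trigger spurious beat candidates
  bf <- signal::butter(4, c(13, 45) / (fs / 2), type = "pass")
  env <- hilbertEnvelope(as.numeric(signal::filtfilt(bf, x)))

  minGap <- round(0.4 * fs)
  work <- env
  peaks <- integer(0)
  topVal <- max(work)
  repeat {
    i <- which.max(work)
    if (work[i] < 0.3 * topVal) break
    peaks <- c(peaks, i)
    lo <- max(1L, i - minGap)
    hi <- min(length(work), i + minGap)
    work[lo:hi] <- -Inf
    if (length(peaks) > length(x) / minGap + 2L) break
  }
  times <- sort((peaks - 1L) / fs)
  if (length(times) < minBeats)
    stop(sprintf("quality error: only %d beats detected (min %d)",
                 length(times), minBeats), call. = FALSE)
  times
}

# Resample beats into the fixed-length window matrix (one row per beat).
beatMatrix <- function(rec, fiducials, windows) {
  fs <- sampleRate(rec)
  x <- samples(rec)
  tx <- (seq_along(x) - 1L) / fs
  medRR <- stats::median(diff(fiducials))
  W <- windows$windowFrac * medRR
  grid <- (seq_len(windows$gridN) - 1L) * W / windows$gridN
  keep <- fiducials + W <= tx[length(tx)]
  fid <- fiducials[keep]
  mat <- t(vapply(fid, function(f)
    stats::approx(tx, x, xout = f + grid)$y, numeric(windows$gridN)))
  list(mat = mat, windowSec = W, fiducials = fid)
}

#' Compute the ensemble-average SCG heartbeat
#'
#' Extracts a fixed window (0-80% of the median RR interval) after each
#' fiducial, resampled to a fixed-length grid, rejects outlier beats whose
#' Pearson correlation with the point-wise median beat falls below
#' `windows$outlierR`, and averages the remainder point-wise. RR statistics
#' are computed from the inter-fiducial intervals.
#'
#' @param rec an [SCGRecording-class].
#' @param fiducials beat times (s); defaults to [detectBeats()] output.
#' @param windows window parameters from [scgWindows()].
#' @return An [EnsembleBeat-class].
#' @export
#' @examples
#' subj <- generateCohort(cohortSpec(n = 1, nPremature = 0L,
#'                                   nBattery = 0L, seed = 3))[1, ]
#' rec <- simulateScg(subj, "rest", scgSimConfig(), seed = 1)
#' ensembleAverage(rec)
ensembleAverage <- function(rec, fiducials = detectBeats(rec),
                            windows = scgWindows()) {
  if (length(fiducials) < windows$minBeats)
    stop(sprintf("quality error: %d fiducials, need at least %d",
                 length(fiducials), windows$minBeats), call. = FALSE)
  bm <- beatMatrix(rec, fiducials, windows)
  medBeat <- apply(bm$mat, 2L, stats::median)
  r <- apply(bm$mat, 1L, function(b) {
    if (stats::sd(b) == 0 || stats::sd(medBeat) == 0) return(1)
    stats::cor(b, medBeat)
  })
  keep <- r >= windows$outlierR
  if (sum(keep) < windows$minBeats)
    stop(sprintf("quality error: %d beats remain after outlier rejection (min %d)",
                 sum(keep), windows$minBeats), call. = FALSE)
  rr <- diff(fiducials) * 1000
  methods::new("EnsembleBeat",
               waveform = colMeans(bm$mat[keep, , drop = FALSE]),
               fs = sampleRate(rec), windowSec = bm$windowSec,
               nBeatsUsed = as.integer(sum(keep)),
               nBeatsRejected = as.integer(sum(!keep)),
               rrMean = mean(rr), rrSd = stats::sd(rr))
}

# Diastolic window of a resampled beat: fixed grid indices corresponding to
# diaFrac of the RR interval inside the windowFrac beat window.
diaWindow <- function(beat, windows) {
  n <- length(waveform(beat))
  i0 <- floor(windows$diaFrac[1] / windows$windowFrac * n) + 1L
  i1 <- floor(windows$diaFrac[2] / windows$windowFrac * n)
  if (i1 > n)
    stop("configuration error: diastolic window exceeds the beat length",
         call. = FALSE)
  waveform(beat)[i0:i1]
}

# Magnitude spectrum of the Hann-windowed systolic segment on a fixed
# frequency grid (bins <= maxFreq at the beat's native sampling rate).
sysSpectrum <- function(beat, windows) {
  fs <- sampleRate(beat)
  if (windows$sysWinSec > beat@windowSec)
    stop("configuration error: systolic window exceeds the beat length",
         call. = FALSE)
  tq <- seq(0, windows$sysWinSec, by = 1 / fs)
  gridT <- (seq_along(waveform(beat)) - 1L) * beat@windowSec /
    length(waveform(beat))
  seg <- stats::approx(gridT, waveform(beat), xout = tq)$y
  m <- length(seg)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))
  padded <- c(seg * hann, numeric(windows$nfft - m))
  mag <- Mod(stats::fft(padded))[seq_len(windows$nfft / 2L + 1L)]
  freqs <- (seq_len(windows$nfft / 2L + 1L) - 1L) * fs / windows$nfft
  keep <- freqs <= windows$maxFreq
  list(mag = mag[keep], freqs = freqs[keep])
}

spectralCentroid <- function(mag, freqs = seq_along(mag) - 1) {
  s <- sum(mag)
  if (s <= 0) return(NA_real_)
  sum(freqs * mag) / s
}

# First principal component of the rows of X (centered, unscaled):
# list(loading, scores, mean), loading unit-norm.
firstPC <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (sum(Xc^2) < 1e-18)
    stop("numerical error: zero-variance training set, PCA is degenerate",
         call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(loading = p$rotation[, 1L], scores = as.numeric(p$x[, 1L]), mean = mu)
}

#' Fit the PCA feature basis on a training set of ensemble beats
#'
#' Computes the first principal component of (a) the centered
#' diastolic-window waveforms and (b) the centered systolic magnitude
#' spectra across the training beats. Each loading vector's sign is fixed so
#' that its training scores correlate positively with the corresponding
#' spectral centroid, removing the PCA sign ambiguity deterministically.
#'
#' @param beats list of [EnsembleBeat-class] objects (>= 10), all from
#'   recordings at the same sampling rate.
#' @param windows window parameters from [scgWindows()].
#' @return A [FeatureBasis-class].
#' @export
fitFeatureBasis <- function(beats, windows = scgWindows()) {
  if (length(beats) < 10L)
    stop("invalid training set: need at least 10 ensemble beats",
         call. = FALSE)
  diaMat <- t(vapply(beats, diaWindow, windows = windows,
                     numeric(length(diaWindow(beats[[1L]], windows)))))
  specs <- lapply(beats, sysSpectrum, windows = windows)
  freqs <- specs[[1L]]$freqs
  if (!all(vapply(specs, function(s)
    isTRUE(all.equal(s$freqs, freqs)), logical(1L))))
    stop("invalid training set: beats have inconsistent spectral grids",
         call. = FALSE)
  sysMat <- t(vapply(specs, function(s) s$mag, numeric(length(freqs))))

  dia <- firstPC(diaMat)
  sys <- firstPC(sysMat)
  orient <- function(pc, proxy) {
    ok <- is.finite(proxy)
    if (sum(ok) >= 3L && stats::sd(proxy[ok]) > 0 &&
        stats::sd(pc$scores[ok]) > 0 &&
        stats::cor(pc$scores[ok], proxy[ok]) < 0) {
      pc$loading <- -pc$loading
      pc$scores <- -pc$scores
    }
    pc
  }
  diaProxy <- apply(diaMat, 1L, function(w)
    spectralCentroid(Mod(stats::fft(w - mean(w)))[seq_len(length(w) %/% 2L)]))
  sysProxy <- apply(sysMat, 1L, spectralCentroid, freqs = freqs)
  dia <- orient(dia, diaProxy)
  sys <- orient(sys, sysProxy)

  methods::new("FeatureBasis", diaMean = dia$mean,
               diaLoadings = as.numeric(dia$loading),
               sysMean = sys$mean, sysLoadings = as.numeric(sys$loading),
               sysFreqs = freqs, nTraining = length(beats),
               windows = windows)
}

#' Extract the four SCG features from an ensemble beat
#'
#' RR is the mean beat-to-beat interval of the recording (ms); the diastolic
#' peak-to-peak is max minus min over the diastolic window of the averaged
#' beat (m/s^2); the morphology and spectrum features are the projections of
#' the centered diastolic window and centered systolic magnitude spectrum on
#' the basis PC-1 loadings.
#'
#' @param beat an [EnsembleBeat-class].
#' @param basis a [FeatureBasis-class] fitted with compatible windows.
#' @return One-row data.frame with columns `rr_ms`, `dia_ptp`, `dia_morph`,
#'   `sys_spec`.
#' @export
extractFeatures <- function(beat, basis) {
  windows <- basis@windows
  dia <- diaWindow(beat, windows)
  if (length(dia) != length(basis@diaMean))
    stop("configuration error: beat and basis diastolic windows differ",
         call. = FALSE)
  spec <- sysSpectrum(beat, windows)
  if (length(spec$mag) != length(basis@sysMean) ||
      !isTRUE(all.equal(spec$freqs, basis@sysFreqs)))
    stop("configuration error: beat and basis spectral grids differ",
         call. = FALSE)
  data.frame(
    rr_ms = rrMean(beat),
    dia_ptp = max(dia) - min(dia),
    dia_morph = sum((dia - basis@diaMean) * basis@diaLoadings),
    sys_spec = sum((spec$mag - basis@sysMean) * basis@sysLoadings))
}
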
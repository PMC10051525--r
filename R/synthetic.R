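# Synthetic ECG generation ---------------------------------------------------
#
# Beats are modelled as a sum of five Gaussian bumps (P, Q, R, S, T), the
# standard phantom-ECG construction.  Class-distinguishing template
# perturbations are fixed documented constants chosen for stable, separable
# classes rather than clinical realism.

#' Describe the morphology of one synthetic heartbeat
#'
#' A beat template places the five ECG waves (P, Q, R, S, T) on a unit-length
#' time axis as Gaussian bumps.  The template is the ground truth from which
#' [make_beat()] renders a sampled waveform.
#'
#' @param wave_centers Numeric length 5; wave centres as fractions of the beat
#'   length, strictly increasing, in P, Q, R, S, T order.
#' @param wave_amplitudes Numeric length 5; wave amplitudes (Q and S are
#'   usually negative).  The R amplitude must be the maximum of the five.
#' @param wave_widths Numeric length 5; Gaussian standard deviations as
#'   fractions of the beat length, all positive.
#' @param label Class id carried along with the template (integer code).
#' @return An object of class `beat_template`.
#' @examples
#' tpl <- beat_template(c(.12, .30, .35, .40, .65),
#'                      c(.15, -.10, 1, -.18, .25),
#'                      c(.040, .012, .015, .012, .060), label = 0L)
#' beat <- make_beat(tpl, length = 187, noise_sd = 0, seed = 1)
#' @export
beat_template <- function(wave_centers, wave_amplitudes, wave_widths, label = 0L) {
  if (length(wave_centers) != 5L || length(wave_amplitudes) != 5L ||
      length(wave_widths) != 5L) {
    stop_invalid("a beat template needs exactly 5 centers, amplitudes and widths")
  }
  if (any(diff(wave_centers) <= 0)) {
    stop_invalid("wave centers must be strictly increasing (P,Q,R,S,T order)")
  }
  if (any(wave_widths <= 0)) stop_invalid("wave widths must be positive")
  if (wave_amplitudes[3L] < max(wave_amplitudes)) {
    stop_invalid("the R wave amplitude must be the maximum of the five")
  }
  structure(
    list(wave_centers = as.numeric(wave_centers),
         wave_amplitudes = as.numeric(wave_amplitudes),
         wave_widths = as.numeric(wave_widths),
         label = as.integer(label)),
    class = "beat_template"
  )
}

# Fixed per-class template constants.  N is the reference morphology; the
# other AAMI classes perturb it: S has an early P wave and a shortened pre-R
# interval, V has a widened QRS with no P wave, F blends N and V, Q is
# flattened/atypical (paced or unclassifiable morphology).
#' Built-in class templates for the synthetic generator
#'
#' @param task `"five_class"` (AAMI N, S, V, F, Q; ids 0..4) or `"binary"`
#'   (normal vs abnormal; ids 0, 1).
#' @return Named list of [beat_template()] objects in class-id order.
#' @export
class_templates <- function(task = c("five_class", "binary")) {
  task <- match.arg(task)
  n <- beat_template(c(.12, .30, .35, .40, .65),
                     c(.15, -.10, 1.00, -.18, .25),
                     c(.040, .012, .015, .012, .060), label = 0L)
  if (task == "binary") {
    # Abnormal (myocardial-infarction-like): inverted T, deep Q, wider QRS.
    ab <- beat_template(c(.12, .28, .35, .42, .65),
                        c(.10, -.35, 1.00, -.25, -.30),
                        c(.040, .020, .030, .020, .070), label = 1L)
    n$label <- 0L
    return(list(normal = n, abnormal = ab))
  }
  s <- beat_template(c(.04, .24, .29, .34, .58),
                     c(.22, -.10, 1.00, -.18, .25),
                     c(.030, .012, .015, .012, .060), label = 1L)
  v <- beat_template(c(.10, .26, .35, .46, .70),
                     c(.00, -.08, 1.00, -.45, .35),
                     c(.040, .030, .055, .045, .080), label = 2L)
  f <- beat_template(c(.11, .28, .35, .43, .67),
                     c(.075, -.09, 1.00, -.31, .30),
                     c(.040, .021, .035, .028, .070), label = 3L)
  q <- beat_template(c(.10, .28, .38, .48, .70),
                     c(.05, -.03, .45, -.05, .08),
                     c(.080, .050, .090, .050, .110), label = 4L)
  list(N = n, S = s, V = v, F = f, Q = q)
}

# Render the Gaussian-sum waveform of a template on a length-L grid (no
# noise, no rescaling); t runs over (0:(L-1))/L so wave centres land on the
# sample grid at index round(center * L) (0-based).
beat_waveform <- function(template, length) {
  t <- (seq_len(length) - 1) / length
  out <- numeric(length)
  for (i in 1:5) {
    out <- out + template$wave_amplitudes[i] *
      exp(-((t - template$wave_centers[i])^2) / (2 * template$wave_widths[i]^2))
  }
  out
}

#' Render one synthetic heartbeat
#'
#' Evaluates the template's sum of five Gaussian bumps on a regular grid, adds
#' white Gaussian noise, and min-max rescales the result to \[0, 1\].
#' Deterministic given `seed`.
#'
#' @param template A [beat_template()].
#' @param length Number of samples (>= 32); default 187, the fixed model
#'   input length.
#' @param noise_sd Standard deviation of additive white noise (>= 0), on the
#'   pre-rescaling amplitude scale where the R wave has height 1.
#' @param seed RNG seed.
#' @return Numeric vector of `length` samples in \[0, 1\].
#' @export
make_beat <- function(template, length = 187L, noise_sd = 0, seed = 0L) {
  if (!inherits(template, "beat_template")) stop_invalid("`template` must be a beat_template")
  if (!is.numeric(length) || length < 32) stop_invalid("`length` must be >= 32")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  length <- as.integer(length)
  x <- beat_waveform(template, length)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length, 0, noise_sd))
  }
  minmax01(x)
}

# Jitter a template's parameters slightly (multiplicative on amplitudes,
# additive on centres) to emulate beat-to-beat variability; draws from the
# current RNG stream.
jitter_template <- function(template, amp_jitter = 0.05, center_jitter = 0.008) {
  amps <- template$wave_amplitudes * (1 + stats::runif(5, -amp_jitter, amp_jitter))
  amps[3L] <- max(amps) + abs(amps[3L] - max(amps)) + 1e-6  # keep R dominant
  centers <- template$wave_centers + stats::runif(5, -center_jitter, center_jitter)
  for (i in 2:5) {  # keep strictly increasing
    if (centers[i] <= centers[i - 1L]) centers[i] <- centers[i - 1L] + 1e-4
  }
  beat_template(centers, amps, template$wave_widths, template$label)
}

#' Container for fixed-length labelled beats
#'
#' @param beats n x L numeric matrix of beats in \[0, 1\] (L = 187 by default).
#' @param labels Integer class ids, one per row (0-based codes: 0..4 for the
#'   five-class task, 0/1 for the binary task).
#' @param task `"five_class"` or `"binary"`.
#' @return An object of class `beat_dataset`.
#' @export
beat_dataset <- function(beats, labels, task = c("five_class", "binary")) {
  task <- match.arg(task)
  beats <- as.matrix(beats)
  labels <- as.integer(labels)
  if (nrow(beats) != length(labels)) stop_invalid("one label per beat required")
  n_classes <- if (task == "five_class") 5L else 2L
  if (length(labels) && (min(labels) < 0L || max(labels) >= n_classes)) {
    stop_invalid("labels must lie in {0..%d} for task '%s'", n_classes - 1L, task)
  }
  structure(list(beats = beats, labels = labels, task = task),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples, task=%s\n",
              nrow(x$beats), ncol(x$beats), x$task))
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:(max(x$labels))))
    cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Generate a labelled synthetic beat dataset
#'
#' Draws beats from per-class templates with mild per-beat template jitter
#' plus additive noise, giving distinct, separable classes with known labels.
#'
#' @param n_per_class Named or unnamed integer vector of per-class counts.
#'   For `task = "five_class"` order/names N, S, V, F, Q; for `"binary"`
#'   normal, abnormal.
#' @param task `"five_class"` or `"binary"`.
#' @param noise_sd Additive noise standard deviation (default 0.02).
#' @param seed RNG seed.
#' @param length Beat length in samples (default 187).
#' @return A [beat_dataset()].
#' @export
make_beat_dataset <- function(n_per_class, task = c("five_class", "binary"),
                              noise_sd = 0.02, seed = 0L, length = 187L) {
  task <- match.arg(task)
  tpls <- class_templates(task)
  k <- base::length(tpls)
  if (base::length(n_per_class) != k) {
    stop_invalid("`n_per_class` must have %d counts for task '%s'", k, task)
  }
  if (!is.null(names(n_per_class)) && all(names(n_per_class) %in% names(tpls))) {
    n_per_class <- n_per_class[names(tpls)]
  }
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 0)) stop_invalid("counts must be >= 0")
  total <- sum(n_per_class)
  with_seed(seed, {
    beats <- matrix(0, total, length)
    labels <- integer(total)
    row <- 0L
    for (ci in seq_len(k)) {
      tpl <- tpls[[ci]]
      for (b in seq_len(n_per_class[ci])) {
        row <- row + 1L
        x <- beat_waveform(jitter_template(tpl), length)
        if (noise_sd > 0) x <- x + stats::rnorm(length, 0, noise_sd)
        beats[row, ] <- minmax01(x)
        labels[row] <- tpl$label
      }
    }
    beat_dataset(beats, labels, task)
  })
}

#' Container for a synthetic single-lead recording with ground truth
#'
#' @param samples Numeric sample sequence.
#' @param fs Sampling rate in Hz.
#' @param r_peak_indices Strictly increasing 1-based sample indices of the
#'   ground-truth R peaks.
#' @param beat_labels Integer class id per peak.
#' @param label Optional rhythm-level label (e.g. `"af"`/`"non_af"`).
#' @return An object of class `synthetic_recording`.
#' @export
synthetic_recording <- function(samples, fs, r_peak_indices,
                                beat_labels = rep(0L, length(r_peak_indices)),
                                label = NULL) {
  r_peak_indices <- as.integer(r_peak_indices)
  if (length(r_peak_indices) > 1L && any(diff(r_peak_indices) <= 0L)) {
    stop_invalid("r_peak_indices must be strictly increasing")
  }
  if (length(r_peak_indices) && max(r_peak_indices) > length(samples)) {
    stop_invalid("r_peak_indices must lie inside the sample sequence")
  }
  if (length(beat_labels) != length(r_peak_indices)) {
    stop_invalid("one beat label per R peak required")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 r_peak_indices = r_peak_indices,
                 beat_labels = as.integer(beat_labels), label = label),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %.1f s at %g Hz, %d R peaks%s\n",
              length(x$samples) / x$fs, x$fs, length(x$r_peak_indices),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

# Place beat waveforms (Gaussian bumps relative to the R peak) at the given
# peak times on a sample grid of `n` samples.
render_peaks <- function(n, fs, peak_idx, template, beat_span_s) {
  x <- numeric(n)
  off_s <- (template$wave_centers - template$wave_centers[3L]) * beat_span_s
  sd_s <- template$wave_widths * beat_span_s
  t <- (seq_len(n) - 1) / fs
  for (p in peak_idx) {
    tp <- (p - 1) / fs
    for (i in 1:5) {
      if (template$wave_amplitudes[i] == 0) next
      lo <- max(1L, floor((tp + off_s[i] - 4 * sd_s[i]) * fs) + 1L)
      hi <- min(n, ceiling((tp + off_s[i] + 4 * sd_s[i]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + template$wave_amplitudes[i] *
        exp(-((t[idx] - tp - off_s[i])^2) / (2 * sd_s[i]^2))
    }
  }
  x
}

#' Generate a synthetic single-lead ECG recording
#'
#' Places `n_beats` normal-morphology beats with R-R intervals drawn uniformly
#' from `rr_mean_s` +/- `rr_jitter_s`, returning the waveform together with
#' ground-truth R-peak indices.
#'
#' @param n_beats Number of beats (>= 1).
#' @param fs Sampling rate in Hz.
#' @param rr_mean_s Mean R-R interval in seconds.
#' @param rr_jitter_s Half-width of the uniform R-R jitter, `0 <= jitter < mean`.
#' @param seed RNG seed.
#' @param noise_sd Additive white-noise standard deviation.
#' @return A [synthetic_recording()].
#' @export
make_recording <- function(n_beats, fs = 360, rr_mean_s = 0.8, rr_jitter_s = 0.1,
                           seed = 0L, noise_sd = 0) {
  if (n_beats < 1) stop_invalid("`n_beats` must be >= 1")
  if (fs <= 0) stop_invalid("`fs` must be positive")
  if (rr_jitter_s < 0 || rr_jitter_s >= rr_mean_s) {
    stop_invalid("need 0 <= rr_jitter_s < rr_mean_s")
  }
  with_seed(seed, {
    rr <- if (n_beats > 1) {
      rr_mean_s + stats::runif(n_beats - 1, -rr_jitter_s, rr_jitter_s)
    } else {
      numeric(0)
    }
    # cumulative per-interval sample counts keep spacing exact on the grid
    peak_idx <- as.integer(round(0.5 * fs) + 1L + c(0L, cumsum(round(rr * fs))))
    n <- max(peak_idx) + as.integer(ceiling(0.8 * rr_mean_s * fs))
    tpl <- class_templates("five_class")$N
    x <- render_peaks(n, fs, peak_idx, tpl, beat_span_s = rr_mean_s)
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    synthetic_recording(x, fs, peak_idx)
  })
}

#' Generate a synthetic rhythm strip (AF or regular rhythm)
#'
#' Non-AF strips have a near-constant R-R interval (coefficient of variation
#' < 0.05) and visible P waves; AF strips draw R-R intervals with high
#' variability (CV >= 0.2) and suppress the P wave, adding a small
#' fibrillatory baseline oscillation.
#'
#' @param duration_s Strip duration in seconds, within \[9, 61\].
#' @param fs Sampling rate in Hz (default 300).
#' @param af Logical; generate atrial fibrillation?
#' @param seed RNG seed.
#' @param rr_mean_s Mean R-R interval in seconds (default 0.8).
#' @param noise_sd Additive white-noise standard deviation.
#' @return A [synthetic_recording()] with `label` `"af"` or `"non_af"`.
#' @export
make_rhythm_strip <- function(duration_s, fs = 300, af = FALSE, seed = 0L,
                              rr_mean_s = 0.8, noise_sd = 0.01) {
  if (duration_s < 9 || duration_s > 61) {
    stop_invalid("`duration_s` must lie in [9, 61]")
  }
  if (fs <= 0) stop_invalid("`fs` must be positive")
  n <- round(duration_s * fs)
  with_seed(seed, {
    n_rr <- ceiling(duration_s / rr_mean_s) + 2L
    draw_rr <- function() {
      if (af) rr_mean_s * (1 + stats::runif(n_rr, -0.45, 0.45))
      else    rr_mean_s + stats::runif(n_rr, -0.015, 0.015)
    }
    # Rejection-sample the R-R sequence until its CV certifies the class
    # structure (irregular for AF, near-regular otherwise).
    for (i in 1:100) {
      rr <- draw_rr()
      cv <- stats::sd(rr) / mean(rr)
      if ((af && cv >= 0.2) || (!af && cv < 0.05)) break
    }
    peak_idx <- as.integer(round(0.4 * fs) + 1L + c(0L, cumsum(round(rr * fs))))
    peak_idx <- peak_idx[peak_idx <= n - round(0.3 * fs)]
    tpl <- class_templates("five_class")$N
    if (af) tpl$wave_amplitudes[1L] <- 0  # suppressed P wave
    x <- render_peaks(n, fs, peak_idx, tpl, beat_span_s = rr_mean_s)
    if (af) {
      # fibrillatory f-waves: small irregular ~7 Hz baseline oscillation
      t <- (seq_len(n) - 1) / fs
      x <- x + 0.04 * sin(2 * pi * 7 * t + stats::runif(1, 0, 2 * pi)) +
        0.02 * sin(2 * pi * 5.3 * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    synthetic_recording(x, fs, peak_idx,
                        beat_labels = rep(as.integer(af), length(peak_idx)),
                        label = if (af) "af" else "non_af")
  })
}
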
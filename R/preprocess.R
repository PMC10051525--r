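# Pre-processing: beat extraction, AAMI label mapping, FIR four-channel
# transform, and sliding-window segmentation.

#' AAMI EC57 label map
#'
#' Total mapping from beat annotation names (and the usual MIT-BIH
#' single-character annotation symbols) to the five AAMI EC57 categories
#' N, S, V, F, Q.
#'
#' @return Named character vector: annotation -> category letter.
#' @export
aami_label_map <- function() {
  c(
    "Normal" = "N", "Left bundle branch block" = "N",
    "Right bundle branch block" = "N", "Atrial escape" = "N",
    "Nodal escape" = "N",
    "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
    "Atrial premature" = "S", "Aberrant atrial premature" = "S",
    "Nodal premature" = "S", "Supra-ventricular premature" = "S",
    "A" = "S", "a" = "S", "J" = "S", "S" = "S",
    "Premature ventricular contraction" = "V", "Ventricular escape" = "V",
    "V" = "V", "E" = "V",
    "Fusion of ventricular and normal" = "F", "F" = "F",
    "Paced" = "Q", "Fusion of paced and normal" = "Q",
    "Unclassifiable" = "Q", "/" = "Q", "f" = "Q", "Q" = "Q"
  )
}

#' Map beat annotations to AAMI class ids
#'
#' Classes are coded in fixed order N=0, S=1, V=2, F=3, Q=4.  Annotations not
#' present in the map fall back to category Q (unclassifiable) with a warning.
#'
#' @param annotations Character vector of annotation names or symbols.
#' @param label_map Named character vector as returned by [aami_label_map()].
#' @return Integer vector of class ids in `{0..4}`.
#' @export
map_labels <- function(annotations, label_map = aami_label_map()) {
  cats <- unname(label_map[annotations])
  unknown <- is.na(cats)
  if (any(unknown)) {
    warning(sprintf("%d unknown annotation(s) mapped to Q: %s",
                    sum(unknown),
                    paste(unique(annotations[unknown]), collapse = ", ")),
            call. = FALSE)
    cats[unknown] <- "Q"
  }
  match(cats, c("N", "S", "V", "F", "Q")) - 1L
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Local maxima of x at or above `threshold`, thinned so that no two kept
# peaks are closer than `refractory` samples (the taller peak wins).
find_r_peaks <- function(x, threshold = 0.9, refractory = 25L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) return(integer(0))
  kept <- cand[1L]
  for (p in cand[-1L]) {
    last <- kept[length(kept)]
    if (p - last >= refractory) {
      kept <- c(kept, p)
    } else if (x[p] > x[last]) {
      kept[length(kept)] <- p
    }
  }
  kept
}

#' Extract fixed-length beats from a raw ECG signal
#'
#' Implements the usual R-anchored beat-table pipeline: resample to
#' `target_fs`, cut into 10-s windows, min-max normalize each window to
#' \[0, 1\], detect candidate R peaks as local maxima with normalized
#' amplitude >= `peak_threshold` under a refractory gap, set the nominal R-R
#' interval to the median peak spacing of the window, and for each peak keep
#' the half-open window `[peak, peak + rr_factor * RR)` truncated or
#' zero-padded to `beat_len` samples.
#'
#' Windows with fewer than two detected peaks are skipped with a warning;
#' an empty result is allowed (e.g. on a flat signal).
#'
#' @param x A [synthetic_recording()] or a numeric signal vector.
#' @param fs Sampling rate of `x` in Hz (taken from the recording if omitted).
#' @param target_fs Resampling target in Hz (default 125).
#' @param beat_len Output beat length in samples (default 187).
#' @param window_s Analysis window length in seconds (default 10).
#' @param peak_threshold Normalized amplitude threshold for R-peak candidates.
#' @param refractory_s Minimum spacing between detected peaks in seconds.
#' @param rr_factor Beat window length as a multiple of the nominal R-R.
#' @return List with `beats` (an unlabeled [beat_dataset()]-style n x
#'   `beat_len` matrix in \[0, 1\]), `peaks` (detected R-peak indices, 1-based,
#'   in the resampled signal), and `fs` (= `target_fs`).
#' @export
extract_beats <- function(x, fs = NULL, target_fs = 125, beat_len = 187L,
                          window_s = 10, peak_threshold = 0.9,
                          refractory_s = 0.2, rr_factor = 1.2) {
  if (inherits(x, "synthetic_recording")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs) || fs <= 0) stop_invalid("`fs` must be a positive sampling rate")
  if (length(x) < 2 * fs) stop_invalid("signal too short: need at least 2 s")
  if (fs != target_fs) {
    p <- round(target_fs * 1000)
    q <- round(fs * 1000)
    g <- gcd_int(p, q)
    x <- signal::resample(x, p = p / g, q = q / g)
  }
  wlen <- round(window_s * target_fs)
  refractory <- max(1L, round(refractory_s * target_fs))
  starts <- seq(1L, length(x), by = wlen)
  beats <- list()
  peaks_all <- integer(0)
  for (s0 in starts) {
    s1 <- min(s0 + wlen - 1L, length(x))
    if (s1 - s0 + 1L < refractory) next
    w <- minmax01(x[s0:s1])
    pk <- find_r_peaks(w, peak_threshold, refractory)
    if (length(pk) < 2L) {
      if (max(w) > 0) {
        warning(sprintf("window at sample %d: fewer than 2 R peaks; skipped", s0),
                call. = FALSE)
      }
      next
    }
    rr <- stats::median(diff(pk))
    span <- max(2L, round(rr_factor * rr))
    for (p in pk) {
      seg <- w[p:min(p + span - 1L, length(w))]
      if (length(seg) > beat_len) seg <- seg[seq_len(beat_len)]
      if (length(seg) < beat_len) seg <- c(seg, numeric(beat_len - length(seg)))
      beats[[length(beats) + 1L]] <- seg
    }
    peaks_all <- c(peaks_all, pk + s0 - 1L)
  }
  mat <- if (length(beats)) do.call(rbind, beats) else matrix(0, 0L, beat_len)
  list(beats = mat, peaks = peaks_all, fs = target_fs)
}

#' FIR four-channel transform
#'
#' Expands a single-channel ECG signal into four channels by zero-phase FIR
#' band-pass filtering over four sub-bands (defaults cover P/T-wave, QRS and
#' high-frequency content at a 300 Hz sampling rate).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param bands List of four `c(low, high)` Hz pairs with
#'   `0 < low < high < fs/2`.
#' @param order FIR filter order (Hamming window design; default 100, i.e.
#'   101 taps).
#' @return `length(x)` x 4 numeric matrix; column k is the band-k filtered
#'   signal.
#' @export
fir_four_channel <- function(x, fs,
                             bands = list(c(0.5, 5), c(5, 15),
                                          c(15, 40), c(40, 100)),
                             order = 100L) {
  if (length(bands) != 4L) stop_invalid("`bands` must list exactly 4 (low, high) pairs")
  for (b in bands) {
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] >= fs / 2) {
      stop_invalid("each band needs 0 < low < high < fs/2 (fs = %g)", fs)
    }
  }
  out <- matrix(0, length(x), 4L)
  for (k in 1:4) {
    h <- signal::fir1(order, bands[[k]] / (fs / 2), type = "pass")
    out[, k] <- signal::filtfilt(h, x)
  }
  out
}

#' Container for labelled multichannel segments
#'
#' @param segments m x window x channels numeric array.
#' @param labels Integer binary labels (0 = non-AF, 1 = AF), one per segment.
#' @param source_id Recording identifier per segment.
#' @return An object of class `segment_dataset`.
#' @export
segment_dataset <- function(segments, labels, source_id = rep(NA_character_, length(labels))) {
  if (length(dim(segments)) != 3L) stop_invalid("`segments` must be a 3-d array")
  if (dim(segments)[1L] != length(labels)) stop_invalid("one label per segment required")
  if (length(source_id) != length(labels)) stop_invalid("one source_id per segment required")
  structure(list(segments = segments, labels = as.integer(labels),
                 source_id = source_id),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_dataset> %d segments of %d x %d, %d AF / %d non-AF\n",
              d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Sliding-window segmentation of a multichannel signal
#'
#' Windows start at offsets `1, 1+step, 1+2*step, ...` while the full window
#' fits, giving `floor((n - window)/step) + 1` segments; every segment
#' inherits the recording-level label.
#'
#' @param multichannel n x channels numeric matrix.
#' @param label Binary recording label (0/1).
#' @param window Window length in samples (default 3000).
#' @param step Step between window starts (>= 1).
#' @param source_id Recording identifier propagated to each segment.
#' @return A [segment_dataset()]; zero segments (with a warning) when
#'   `n < window`.
#' @export
sliding_segments <- function(multichannel, label, window = 3000L, step,
                             source_id = NA_character_) {
  multichannel <- as.matrix(multichannel)
  n <- nrow(multichannel)
  ch <- ncol(multichannel)
  window <- as.integer(window)
  step <- as.integer(step)
  if (step < 1L) stop_invalid("`step` must be >= 1")
  if (n < window) {
    warning(sprintf("recording %s shorter than window (%d < %d); dropped",
                    source_id, n, window), call. = FALSE)
    return(segment_dataset(array(0, c(0L, window, ch)), integer(0), character(0)))
  }
  starts <- seq(1L, n - window + 1L, by = step)
  segs <- array(0, c(length(starts), window, ch))
  for (i in seq_along(starts)) {
    segs[i, , ] <- multichannel[starts[i]:(starts[i] + window - 1L), ]
  }
  segment_dataset(segs, rep(as.integer(label), length(starts)),
                  rep(source_id, length(starts)))
}

#' Build a segment dataset from rhythm recordings
#'
#' Applies the FIR four-channel transform to each recording, then sliding
#' segmentation with a label-dependent step (AF recordings use the small
#' step, non-AF the large one) to rebalance the two classes.
#'
#' @param recordings List of [synthetic_recording()]s (label `"af"` or
#'   `"non_af"`), or of lists with `samples`, `fs`, `label`.
#' @param window Segment length (default 3000).
#' @param step_af,step_nonaf Sliding steps for AF / non-AF recordings.
#' @param bands,order Passed to [fir_four_channel()].
#' @return A [segment_dataset()] pooling all recordings.
#' @export
build_segment_dataset <- function(recordings, window = 3000L,
                                  step_af = 50L, step_nonaf = 500L,
                                  bands = list(c(0.5, 5), c(5, 15),
                                               c(15, 40), c(40, 100)),
                                  order = 100L) {
  parts <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    lab <- as.integer(identical(rec$label, "af") || identical(rec$label, 1L))
    mc <- fir_four_channel(rec$samples, rec$fs, bands = bands, order = order)
    parts[[i]] <- sliding_segments(mc, lab, window = window,
                                   step = if (lab == 1L) step_af else step_nonaf,
                                   source_id = sprintf("rec%03d", i))
  }
  segs <- do.call(abind3, lapply(parts, function(p) p$segments))
  segment_dataset(segs,
                  unlist(lapply(parts, function(p) p$labels)),
                  unlist(lapply(parts, function(p) p$source_id)))
}

# rbind for 3-d arrays along the first margin
abind3 <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, function(a) dim(a)[1L] > 0L, logical(1))]
  if (!length(xs)) return(array(0, c(0L, 3000L, 4L)))
  d <- dim(xs[[1L]])
  n <- sum(vapply(xs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[1L]
    if (k) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}
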
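# Readers/writers: beat-table CSV, signal CSV, a minimal WFDB-style record
# pair (text header + 16-bit little-endian samples), checkpoints, manifests.

#' Read a beat table from CSV
#'
#' Expects 188 comma-separated columns per row: 187 amplitude values in
#' \[0, 1\] followed by an integer class label (no header by default, the
#' common distribution format of pre-split beat tables).  Malformed rows —
#' non-finite values, values outside \[0, 1\] (beyond 1e-9), labels outside
#' the task's class set — are rejected with their line numbers in a warning.
#'
#' @param path CSV file path.
#' @param task `"five_class"` or `"binary"` (sets the admissible label range).
#' @param header Does the file carry a header line?
#' @param beat_len Expected beat length (default 187; column count must be
#'   `beat_len + 1`).
#' @return A [beat_dataset()].
#' @export
read_beat_csv <- function(path, task = c("five_class", "binary"),
                          header = FALSE, beat_len = 187L) {
  task <- match.arg(task)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  if (file.size(path) == 0L) {
    warning(sprintf("empty beat table: %s", path), call. = FALSE)
    return(beat_dataset(matrix(0, 0L, beat_len), integer(0), task))
  }
  df <- utils::read.csv(path, header = header)
  if (nrow(df) == 0L) {
    warning(sprintf("empty beat table: %s", path), call. = FALSE)
    return(beat_dataset(matrix(0, 0L, beat_len), integer(0), task))
  }
  if (ncol(df) != beat_len + 1L) {
    stop_invalid("%s: expected %d columns (%d values + label), found %d",
                 path, beat_len + 1L, beat_len, ncol(df))
  }
  m <- as.matrix(df)
  beats <- m[, seq_len(beat_len), drop = FALSE]
  labels <- m[, beat_len + 1L]
  n_classes <- if (task == "five_class") 5L else 2L
  bad <- !apply(is.finite(beats), 1L, all) |
    apply(beats, 1L, function(r) min(r) < -1e-9 || max(r) > 1 + 1e-9) |
    !is.finite(labels) | labels != round(labels) |
    labels < 0 | labels >= n_classes
  if (any(bad)) {
    warning(sprintf("%s: rejected %d malformed row(s) at line(s) %s", path,
                    sum(bad),
                    paste(which(bad) + as.integer(header), collapse = ", ")),
            call. = FALSE)
  }
  beat_dataset(beats[!bad, , drop = FALSE], as.integer(labels[!bad]), task)
}

#' Write a beat table to CSV
#'
#' @param dataset A [beat_dataset()].
#' @param path Output path.
#' @param header Write a header line?
#' @export
write_beat_csv <- function(dataset, path, header = FALSE) {
  df <- as.data.frame(cbind(dataset$beats, dataset$labels))
  names(df) <- c(sprintf("v%03d", seq_len(ncol(dataset$beats))), "label")
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, qmethod = "double")
  invisible(path)
}

#' Read a flat signal CSV (one sample per row)
#'
#' @param path CSV file path (single column, no header).
#' @param fs Sampling rate of the stored signal in Hz.
#' @return List with `samples` and `fs`.
#' @export
read_signal_csv <- function(path, fs) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  list(samples = as.numeric(utils::read.csv(path, header = FALSE)[[1L]]), fs = fs)
}

#' Write a signal to CSV (one sample per row)
#'
#' @param x Numeric signal or [synthetic_recording()].
#' @param path Output path.
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "synthetic_recording")) x <- x$samples
  utils::write.table(matrix(x, ncol = 1L), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a minimal WFDB-style record
#'
#' Writes `<base>.hea` (text header: record name, signal count, sampling
#' rate, length; one signal line with format 16, gain and baseline) and
#' `<base>.dat` (16-bit little-endian integers, `adc = round(x * gain) +
#' baseline`).
#'
#' @param x Numeric signal or [synthetic_recording()].
#' @param base Path base (without extension).
#' @param fs Sampling rate (taken from the recording if omitted).
#' @param gain ADC gain in units per mV (default 200).
#' @param baseline ADC baseline offset (default 0).
#' @param description Signal description string (default `"II"`).
#' @return `base`, invisibly.
#' @export
write_wfdb_record <- function(x, base, fs = NULL, gain = 200, baseline = 0L,
                              description = "II") {
  if (inherits(x, "synthetic_recording")) {
    fs <- fs %||% x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop_invalid("`fs` required")
  adc <- as.integer(pmin(pmax(round(x * gain) + baseline, -32768), 32767))
  rec <- basename(base)
  hea <- c(sprintf("%s 1 %g %d", rec, fs, length(adc)),
           sprintf("%s.dat 16 %g %d 0 %d 0 0 %s", rec, gain, baseline,
                   adc[1L], description))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(base)
}

#' Read a minimal WFDB-style record
#'
#' Parses `<base>.hea` and reads format-16 samples from `<base>.dat`.  For
#' multi-signal records the lead described as `"II"` is selected; otherwise
#' the first channel is used with a message.  If `<base>.ann.csv` (plain-text
#' annotation table with columns `sample,symbol`) exists it is returned too;
#' a missing annotation file yields beats-only mode with a warning.
#'
#' @param base Path base (without extension).
#' @param lead Preferred signal description (default `"II"`).
#' @return List with `samples` (physical units), `fs`, `n`, and
#'   `annotations` (data.frame or `NULL`).
#' @export
read_wfdb_record <- function(base, lead = "II") {
  hea_path <- paste0(base, ".hea")
  dat_path <- paste0(base, ".dat")
  for (p in c(hea_path, dat_path)) {
    if (!file.exists(p)) stop_invalid("file not found: %s", p)
  }
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  head_fields <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_fields[2L])
  fs <- as.numeric(head_fields[3L])
  nsamp <- if (length(head_fields) >= 4L) as.integer(head_fields[4L]) else NA_integer_
  sig_lines <- lines[1L + seq_len(nsig)]
  fmt <- vapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]][2L], character(1))
  fmt_base <- sub("[x:+].*$", "", fmt)
  if (any(fmt_base != "16")) {
    stop_invalid("only WFDB signal format 16 is supported (found %s)",
                 paste(unique(fmt), collapse = ", "))
  }
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    gb <- strsplit(f[3L], "[(/]")[[1L]]
    list(gain = as.numeric(gb[1L]),
         baseline = if (length(gb) > 1L) as.numeric(sub("\\)", "", gb[2L])) else
           if (length(f) >= 5L) as.numeric(f[5L]) else 0,
         description = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
                       else NA_character_)
  }
  sigs <- lapply(sig_lines, parse_sig)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = file.size(dat_path) %/% 2L, size = 2L,
                 endian = "little", signed = TRUE)
  if (nsig > 1L) {
    mat <- matrix(raw, ncol = nsig, byrow = TRUE)
    pick <- which(vapply(sigs, function(s) identical(s$description, lead), logical(1)))
    if (!length(pick)) {
      pick <- 1L
      message(sprintf("lead '%s' not found; using channel 1", lead))
    }
    adc <- mat[, pick[1L]]
    sig <- sigs[[pick[1L]]]
  } else {
    adc <- raw
    sig <- sigs[[1L]]
  }
  gain <- if (is.finite(sig$gain) && sig$gain > 0) sig$gain else 200
  samples <- (adc - (sig$baseline %||% 0)) / gain
  ann_path <- paste0(base, ".ann.csv")
  annotations <- NULL
  if (file.exists(ann_path)) {
    annotations <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  } else {
    warning(sprintf("no annotation table (%s); beats-only mode", ann_path),
            call. = FALSE)
  }
  list(samples = samples, fs = fs,
       n = if (is.na(nsamp)) length(samples) else nsamp,
       annotations = annotations)
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds `weights.rds` (parameter and state arrays)
#' and `config.json` (the [model_config()] serialized as JSON).
#'
#' @param model An `ecg_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` ([save_checkpoint()]) or an `ecg_model`
#'   ([load_checkpoint()]).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(params = model$params, state = model$state), file.path(dir, "weights.rds"))
  cfg <- unclass(model$cfg)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  wpath <- file.path(dir, "weights.rds")
  cpath <- file.path(dir, "config.json")
  for (p in c(wpath, cpath)) if (!file.exists(p)) stop_invalid("file not found: %s", p)
  cfg_l <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  cfg <- model_config(input_len = cfg_l$input_len, in_channels = cfg_l$in_channels,
                      n_classes = cfg_l$n_classes, stem_filters = cfg_l$stem_filters,
                      stem_kernel = cfg_l$stem_kernel,
                      block_filters = cfg_l$block_filters,
                      block_kernel = cfg_l$block_kernel, pool_size = cfg_l$pool_size,
                      dropout = cfg_l$dropout, se_ratio = cfg_l$se_ratio,
                      evo_variant = cfg_l$evo_variant, evo_groups = cfg_l$evo_groups,
                      use_se = cfg_l$use_se, use_evo = cfg_l$use_evo,
                      use_gc = cfg_l$use_gc, head_hidden = cfg_l$head_hidden)
  w <- readRDS(wpath)
  structure(list(cfg = cfg, params = w$params, state = w$state,
                 n_params = sum(vapply(w$params, length, integer(1)))),
            class = "ecg_model")
}

#' Build a run manifest
#'
#' Records the configuration snapshot, seed, package version, content hashes
#' of the input data files, and the output paths; written as JSON before
#' training starts so every artifact-producing run is reproducible.
#'
#' @param config List or config object to snapshot.
#' @param seed The run seed.
#' @param data_files Character vector of input file paths to fingerprint
#'   (MD5).
#' @param outputs Character vector of output paths.
#' @return Manifest list.
#' @export
run_manifest <- function(config, seed, data_files = character(0),
                         outputs = character(0)) {
  existing <- data_files[file.exists(data_files)]
  hashes <- if (length(existing)) as.list(tools::md5sum(existing)) else list()
  list(package = "ecgnet",
       version = as.character(utils::packageVersion("ecgnet")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config = if (is.list(config)) unclass(config) else config,
       data_fingerprints = hashes,
       outputs = outputs)
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
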
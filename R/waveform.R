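#' Construct a waveform object
#'
#' A waveform is the elementary audio container of voxfuse: a mono vector of
#' dimensionless float amplitudes (nominally in \[-1, 1\]) plus a sampling
#' rate in Hz. All audio-facing functions in the package accept and return
#' this class.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param rate Sampling rate in samples per second. Must be > 0.
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("waveform samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate)), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
    length(x$samples), x$rate, duration(x),
    if (length(x$samples)) max(abs(x$samples)) else 0
  ))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

is_waveform <- function(x) inherits(x, "waveform")

assert_waveform <- function(w, allow_empty = FALSE) {
  if (!is_waveform(w)) stop("expected a `waveform` object", call. = FALSE)
  if (!allow_empty && length(w$samples) == 0L) {
    stop("empty waveform (0 samples)", call. = FALSE)
  }
  invisible(w)
}

# ---- RIFF WAV I/O ----------------------------------------------------------
# Mono RIFF/WAVE only, 16-bit PCM (format 1) and 32-bit IEEE float (format 3).

#' Read a mono WAV file
#'
#' Supports the two dialects the toolkit writes: 16-bit PCM and 32-bit IEEE
#' float. Multi-channel files are rejected (the screening pipeline assumes
#' mono recordings).
#'
#' @param path Path to a RIFF WAV file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path, call. = FALSE)
      if (fmt$channels != 1L) {
        stop("multi-channel WAV not supported (", fmt$channels, " channels)", call. = FALSE)
      }
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n, size = 2, endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        x <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bits)",
          call. = FALSE
        )
      }
      return(waveform(x, fmt$rate))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L)) # skip unknown chunk (word-aligned)
    }
  }
}

#' Write a mono WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = c("pcm16", "float32")) {
  assert_waveform(w)
  bit_depth <- match.arg(bit_depth)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  if (bit_depth == "pcm16") {
    bytes_per <- 2L; fmt_code <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; fmt_code <- 3L; bits <- 32L
  }
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") {
    x <- pmin(pmax(w$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(x * 32768)), con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps generators pure functions of their spec.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Deterministic per-module substream of a global seed (keeps every stage
# independently reproducible from one user-facing seed).
seed_substream <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
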
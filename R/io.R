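# RIFF WAVE and cochleogram container I/O.  WAV support is deliberately
# minimal: mono or first-channel PCM16 and IEEE float32, which covers the
# synthetic material this package produces and consumes.

#' Write a RIFF WAVE file
#'
#' @param f A [sampled_signal()] (samples are clipped to [-1, 1] for PCM16).
#' @param path Output path.
#' @param format `"float32"` (lossless round-trip) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(f, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(f, "sampled_signal"))
  format <- match.arg(format)
  n <- length(f$samples)
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  block <- bits / 8L
  data_bytes <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(round(f$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(f$rate) * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmin(1, pmax(-1, f$samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(f$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a RIFF WAVE file
#'
#' Supports PCM16 and IEEE float32; multi-channel files are reduced to the
#' first channel.
#'
#' @param path Input path.
#' @return A [sampled_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NULL; rate <- NULL; bits <- NULL; channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop("malformed WAV: data before fmt chunk")
      nval <- sz / (bits / 8)
      if (fmt_code == 1 && bits == 16) {
        samples <- readBin(con, "integer", n = nval, size = 2,
                           endian = "little", signed = TRUE) / 32767
      } else if (fmt_code == 3 && bits == 32) {
        samples <- readBin(con, "numeric", n = nval, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV format (code ", fmt_code, ", ", bits, " bit)")
      }
      break
    } else {
      invisible(readBin(con, "raw", n = sz + sz %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (channels > 1) samples <- samples[seq(1, length(samples), by = channels)]
  sampled_signal(samples, rate)
}

#' Write a cochleogram to a flat binary container
#'
#' Layout (little-endian): magic "CCH1" (4 bytes), int32 nscale, int32
#' ntime, float64 rate, float64 scales[nscale], then the complex field as
#' interleaved float64 Re/Im, row-major (scale rows contiguous).
#'
#' @param coch A cochleogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cochleogram <- function(coch, path) {
  stopifnot(inherits(coch, "cochleogram"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("CCH1", con, eos = NULL)
  writeBin(c(nrow(coch$Z), ncol(coch$Z)), con, size = 4, endian = "little")
  writeBin(as.numeric(coch$rate), con, size = 8, endian = "little")
  writeBin(as.numeric(coch$scales), con, size = 8, endian = "little")
  for (j in seq_len(nrow(coch$Z))) {
    row <- coch$Z[j, ]
    writeBin(as.numeric(rbind(Re(row), Im(row))), con, size = 8,
             endian = "little")
  }
  invisible(path)
}

#' Read a cochleogram container written by [write_cochleogram()]
#'
#' Polar fields are recomputed; the interior-column bookkeeping defaults to
#' the full range less one sample at each end.
#'
#' @param path Input path.
#' @param p Optional [filter_params()] to attach.
#' @param gm Optional [group_model()] to attach.
#' @return A cochleogram.
#' @export
read_cochleogram <- function(path, p = NULL, gm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CCH1")) stop("not a cochleogram container: ", path)
  dims <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  rate <- readBin(con, "numeric", size = 8, endian = "little")
  scales <- readBin(con, "numeric", n = dims[1], size = 8, endian = "little")
  Z <- matrix(NA_complex_, dims[1], dims[2])
  for (j in seq_len(dims[1])) {
    buf <- readBin(con, "numeric", n = 2 * dims[2], size = 8,
                   endian = "little")
    Z[j, ] <- complex(real = buf[c(TRUE, FALSE)],
                      imaginary = buf[c(FALSE, TRUE)])
  }
  dl <- diff(log(scales))
  coch <- structure(list(Z = Z, scales = scales,
                         times = (seq_len(dims[2]) - 1) / rate, rate = rate,
                         dloga = if (length(dl)) dl[1] else NA_real_,
                         logr = NULL, phase = NULL, mask = NULL,
                         interior_cols = 2:(dims[2] - 1),
                         params = p, gm = gm,
                         row_masked = rep(FALSE, dims[1])),
                    class = "cochleogram")
  polar_fields(coch)
}

#' Export a cochleogram as delimited text
#'
#' Tab-separated `a`, `t`, `re`, `im` with a commented header (large!).
#' @param coch A cochleogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cochleogram_text <- function(coch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cochleogram %d x %d, rate %g", nrow(coch$Z),
                     ncol(coch$Z), coch$rate), con)
  writeLines("# a\tt\tre\tim", con)
  for (j in seq_len(nrow(coch$Z)))
    utils::write.table(
      data.frame(a = coch$scales[j], t = coch$times,
                 re = Re(coch$Z[j, ]), im = Im(coch$Z[j, ])),
      con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
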
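# Readers/writers: PicoQuant PTU event streams (PicoHarp T3), FLIM image
# reconstruction from line markers, CSV decay histograms, TIFF label masks.

PTU_MAGIC <- "PQTTTR"
PTU_VERSION <- "1.0.00"
REC_PICOHARP_T3 <- 66307  # 0x00010303

TY_EMPTY8 <- 4294901768      # 0xFFFF0008
TY_BOOL8 <- 8                # 0x00000008
TY_INT8 <- 268435464         # 0x10000008
TY_BITSET64 <- 285212680     # 0x11000008
TY_FLOAT8 <- 536870920       # 0x20000008
TY_TDATETIME <- 553648136    # 0x21000008
TY_FLOAT8_ARRAY <- 537001983 # 0x2001FFFF
TY_ANSISTRING <- 1073872895  # 0x4001FFFF
TY_WIDESTRING <- 1073938431  # 0x4002FFFF
TY_BINARYBLOB <- 4294967295  # 0xFFFFFFFF

# unsigned 32-bit <-> double helpers (R lacks native uint32)
u32_from_i32 <- function(v) {
  v <- as.double(v)
  ifelse(v < 0, v + 4294967296, v)
}
i32_from_u32 <- function(v) {
  as.integer(ifelse(v >= 2147483648, v - 4294967296, v))
}

read_i64le <- function(con) {
  lo <- u32_from_i32(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  hi <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hi * 4294967296 + lo
}
write_i64le <- function(con, v) {
  hi <- floor(v / 4294967296)
  lo <- v - hi * 4294967296
  writeBin(i32_from_u32(lo), con, size = 4L, endian = "little")
  writeBin(as.integer(hi), con, size = 4L, endian = "little")
}

#' Write a minimal PicoQuant PTU file
#'
#' Emits a tagged PTU header followed by PicoHarp T3 TTTR records, inserting
#' macro-time overflow records as needed. Intended for fixture generation and
#' round-trip testing against [read_ptu()].
#'
#' @param events Tibble/data frame with columns `macro_time` (absolute clock
#'   ticks, sorted ascending), `micro_time` (TCSPC bin index, 0-4095),
#'   `channel` (0-14) and `marker` (0 for photons; 1-15 marker bit flags for
#'   marker events, whose `micro_time` is ignored).
#' @param path Output file path.
#' @param resolution_ns Micro-time (TCSPC bin) resolution in ns.
#' @param global_resolution_ns Macro-time clock period in ns.
#' @param extra_tags Named list of extra header tags (numeric -> Int8,
#'   double -> written as Float8 when not whole, character -> AnsiString).
#' @return `path`, invisibly.
#' @export
write_ptu <- function(events, path, resolution_ns = 0.05,
                      global_resolution_ns = 12.5, extra_tags = list()) {
  ev <- tibble::as_tibble(events)
  n <- nrow(ev)
  if (n > 0 && is.unsorted(ev$macro_time)) {
    abort_flimr("events must be sorted by macro_time", "flimr_encoding_error")
  }
  if (n > 0 && any(ev$marker == 0 &
                   (ev$micro_time < 0 | ev$micro_time > 4095))) {
    abort_flimr("micro_time exceeds the 12-bit PicoHarp T3 field",
                "flimr_encoding_error")
  }
  if (n > 0 && any(ev$marker == 0 & (ev$channel < 0 | ev$channel > 14))) {
    abort_flimr("photon channel must be 0-14 (15 is the special channel)",
                "flimr_encoding_error")
  }
  # encode records with interleaved overflow records (one per 65536 wrap)
  if (n > 0) {
    ofl_idx <- floor(ev$macro_time / 65536)
    nsync <- ev$macro_time - ofl_idx * 65536
    is_mark <- ev$marker > 0
    dtime <- ifelse(is_mark, ev$marker, ev$micro_time)
    chan <- ifelse(is_mark, 15, ev$channel)
    rec <- chan * 268435456 + dtime * 65536 + nsync
    ofl_rec <- 15 * 268435456  # channel 15, dtime 0, nsync 0
    delta <- diff(c(0, ofl_idx))
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      pieces[[i]] <- c(rep(ofl_rec, delta[i]), rec[i])
    }
    records <- unlist(pieces)
  } else {
    records <- numeric(0)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%-8s", PTU_MAGIC)), con)
  raw_ver <- c(charToRaw(PTU_VERSION), as.raw(c(0, 0)))
  writeBin(raw_ver[1:8], con)
  wtag <- function(ident, typ, value) {
    id <- charToRaw(ident)
    writeBin(c(id, raw(32L - length(id))), con)
    writeBin(-1L, con, size = 4L, endian = "little")
    writeBin(i32_from_u32(typ), con, size = 4L, endian = "little")
    if (typ == TY_INT8) {
      write_i64le(con, value)
    } else if (typ == TY_FLOAT8) {
      writeBin(as.double(value), con, size = 8L, endian = "little")
    } else if (typ == TY_ANSISTRING) {
      s <- c(charToRaw(value), as.raw(0))
      pad <- (8 - length(s) %% 8) %% 8
      write_i64le(con, length(s) + pad)
      writeBin(c(s, raw(pad)), con)
    } else if (typ == TY_EMPTY8) {
      write_i64le(con, 0)
    } else {
      abort_flimr("unsupported tag type for writing", "flimr_encoding_error")
    }
  }
  wtag("TTResultFormat_TTTRRecType", TY_INT8, REC_PICOHARP_T3)
  wtag("TTResult_NumberOfRecords", TY_INT8, length(records))
  wtag("MeasDesc_Resolution", TY_FLOAT8, resolution_ns * 1e-9)
  wtag("MeasDesc_GlobalResolution", TY_FLOAT8, global_resolution_ns * 1e-9)
  for (nm in names(extra_tags)) {
    v <- extra_tags[[nm]]
    if (is.character(v)) {
      wtag(nm, TY_ANSISTRING, v)
    } else if (is.numeric(v) && v == round(v)) {
      wtag(nm, TY_INT8, v)
    } else {
      wtag(nm, TY_FLOAT8, v)
    }
  }
  wtag("Header_End", TY_EMPTY8, 0)
  if (length(records) > 0) {
    writeBin(i32_from_u32(records), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a PicoQuant PTU file
#'
#' Decodes the tagged header, then the TTTR record section. PicoHarp T3 is
#' the supported record type: overflow records extend the macro time and
#' marker records are surfaced as events with `marker > 0`.
#'
#' @param path Path to a `.ptu` file.
#' @return A list with `header` (named list of tags, plus `resolution_ns`,
#'   `global_resolution_ns`, `record_type`, `n_records`) and `events`
#'   (tibble `macro_time`, `micro_time`, `channel`, `marker`).
#' @export
read_ptu <- function(path) {
  if (!file.exists(path)) {
    abort_flimr(sprintf("file not found: %s", path), "flimr_parse_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!startsWith(magic, PTU_MAGIC)) {
    abort_flimr("not a PTU file (bad magic string)", "flimr_format_error")
  }
  readBin(con, "raw", 8L)  # version
  tags <- list()
  repeat {
    ident_raw <- readBin(con, "raw", 32L)
    if (length(ident_raw) < 32L) {
      abort_flimr(sprintf("truncated PTU header at byte %d", seek(con)),
                  "flimr_parse_error")
    }
    ident <- rawToChar(ident_raw[ident_raw != as.raw(0)])
    readBin(con, "integer", 1L, size = 4L, endian = "little")  # idx
    typ <- u32_from_i32(readBin(con, "integer", 1L, size = 4L,
                                endian = "little"))
    value <- if (typ %in% c(TY_INT8, TY_BITSET64)) {
      read_i64le(con)
    } else if (typ %in% c(TY_FLOAT8, TY_TDATETIME)) {
      readBin(con, "double", 1L, size = 8L, endian = "little")
    } else if (typ == TY_BOOL8) {
      read_i64le(con) != 0
    } else if (typ == TY_EMPTY8) {
      read_i64le(con)
      NA
    } else if (typ == TY_ANSISTRING) {
      len <- read_i64le(con)
      s <- readBin(con, "raw", len)
      rawToChar(s[s != as.raw(0)])
    } else if (typ %in% c(TY_WIDESTRING, TY_BINARYBLOB, TY_FLOAT8_ARRAY)) {
      len <- read_i64le(con)
      readBin(con, "raw", len)
      NA
    } else {
      abort_flimr(sprintf("unknown PTU tag type 0x%08X at byte %d",
                          typ, seek(con)), "flimr_parse_error")
    }
    if (ident == "Header_End") break
    tags[[ident]] <- value
  }
  req <- c("TTResultFormat_TTTRRecType", "TTResult_NumberOfRecords",
           "MeasDesc_Resolution")
  miss <- setdiff(req, names(tags))
  if (length(miss) > 0L) {
    abort_flimr(sprintf("PTU header missing mandatory tags: %s",
                        paste(miss, collapse = ", ")), "flimr_parse_error")
  }
  rectype <- tags[["TTResultFormat_TTTRRecType"]]
  if (rectype != REC_PICOHARP_T3) {
    abort_flimr(sprintf("unsupported TTTR record type 0x%08X (PicoHarp T3 only)",
                        rectype), "flimr_unsupported_format")
  }
  n_rec <- tags[["TTResult_NumberOfRecords"]]
  data_start <- seek(con)
  raw_rec <- readBin(con, "integer", n_rec, size = 4L, endian = "little")
  if (length(raw_rec) < n_rec) {
    abort_flimr(sprintf("truncated PTU record section at byte %d (%d of %d records)",
                        data_start + 4 * length(raw_rec), length(raw_rec), n_rec),
                "flimr_parse_error")
  }
  v <- u32_from_i32(raw_rec)
  nsync <- v %% 65536
  dtime <- floor(v / 65536) %% 4096
  chan <- floor(v / 268435456)
  special <- chan == 15
  is_ofl <- special & dtime == 0
  # macro-time base: overflows seen strictly before each record
  ofl_before <- (cumsum(is_ofl) - is_ofl) * 65536
  macro <- nsync + ofl_before
  keep <- !is_ofl
  events <- tibble::tibble(
    macro_time = macro[keep],
    micro_time = as.integer(ifelse(special[keep], 0L, dtime[keep])),
    channel = as.integer(ifelse(special[keep], 15L, chan[keep])),
    marker = as.integer(ifelse(special[keep], dtime[keep], 0L))
  )
  header <- c(tags, list(
    record_type = rectype,
    n_records = n_rec,
    resolution_ns = tags[["MeasDesc_Resolution"]] * 1e9,
    global_resolution_ns = (tags[["MeasDesc_GlobalResolution"]] %||% NA) * 1e9
  ))
  list(header = header, events = events)
}

#' Marker-bit configuration for image reconstruction
#'
#' Acquisition software varies in which marker bits flag line starts, line
#' stops and frames, so the mapping is configuration, never hard-coded.
#'
#' @param line_start,line_stop,frame Marker bit values (powers of two).
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(line_start = 1L, line_stop = 2L, frame = 4L) {
  structure(list(line_start = as.integer(line_start),
                 line_stop = as.integer(line_stop),
                 frame = as.integer(frame)),
            class = "marker_config")
}

#' Reconstruct a FLIM image from a TTTR event stream
#'
#' Photons between a line-start and the matching line-stop marker are
#' assigned to columns by linear interpolation of macro time across the
#' line; rows advance per line and frames accumulate (bin-wise sum), so a
#' multi-frame stream sums like multi-timepoint acquisition. Photons outside
#' any line interval are dropped and counted in the `discarded` attribute.
#'
#' @param events Event tibble as from [read_ptu()].
#' @param dims Image dimensions `c(rows, cols)`.
#' @param markers A [marker_config()].
#' @param resolution_ns Micro-time bin width in ns.
#' @param n_bins Number of micro-time bins (default: max observed + 1).
#' @return A [flim_image()] with attributes `discarded` (photon count) and
#'   `n_frames`.
#' @export
reconstruct_flim_image <- function(events, dims, markers = marker_config(),
                                   resolution_ns = 0.05, n_bins = NULL) {
  rows <- dims[1]
  cols <- dims[2]
  is_marker <- events$marker > 0
  ph <- events[!is_marker, ]
  mk <- events[is_marker, ]
  starts <- mk$macro_time[bitwAnd(mk$marker, markers$line_start) > 0]
  stops <- mk$macro_time[bitwAnd(mk$marker, markers$line_stop) > 0]
  frames <- mk$macro_time[bitwAnd(mk$marker, markers$frame) > 0]
  if (length(starts) != length(stops)) {
    abort_flimr(sprintf("unbalanced line markers: %d starts vs %d stops (line %d)",
                        length(starts), length(stops),
                        min(length(starts), length(stops)) + 1L),
                "flimr_reconstruction_error")
  }
  if (length(starts) == 0L) {
    abort_flimr("no line markers present", "flimr_reconstruction_error")
  }
  if (any(stops <= starts)) {
    bad <- which(stops <= starts)[1]
    abort_flimr(sprintf("line %d stops before it starts", bad),
                "flimr_reconstruction_error")
  }
  nb <- n_bins %||% (max(ph$micro_time, 0L) + 1L)
  ord <- order(ph$macro_time)
  pmt <- ph$macro_time[ord]
  pmicro <- ph$micro_time[ord]
  cube <- array(0L, dim = c(rows, cols, nb))
  assigned <- 0
  # row bookkeeping: rows advance per line, reset at frame markers (or wrap)
  frame_of_line <- findInterval(starts, sort(frames))
  line_in_frame <- stats::ave(seq_along(starts), frame_of_line,
                              FUN = seq_along)
  for (i in seq_along(starts)) {
    r <- ((line_in_frame[i] - 1L) %% rows) + 1L
    lo <- findInterval(starts[i] - 0.5, pmt) + 1L
    hi <- findInterval(stops[i] + 0.5, pmt)
    if (hi < lo) next
    sel <- lo:hi
    frac <- (pmt[sel] - starts[i]) / (stops[i] - starts[i])
    cc <- pmin(pmax(floor(frac * cols) + 1L, 1L), cols)
    idx <- r + (cc - 1L) * rows + pmicro[sel] * rows * cols
    tab <- tabulate(idx, nbins = rows * cols * nb)
    nz <- which(tab > 0L)
    cube[nz] <- cube[nz] + tab[nz]
    assigned <- assigned + length(sel)
  }
  img <- flim_image(cube, dt = resolution_ns)
  attr(img, "discarded") <- nrow(ph) - assigned
  attr(img, "n_frames") <- max(1L, length(frames))
  img
}

#' Serialise a FLIM image as a synthetic line-scanned event stream
#'
#' Inverse of [reconstruct_flim_image()] for fixture generation: each photon
#' of a pixel is placed at the macro time of its column centre within its
#' row's line interval, with line start/stop markers around every row and a
#' frame marker at the start. Reconstruction with the same marker
#' configuration recovers the count cube exactly.
#'
#' @param image A [flim_image()].
#' @param markers A [marker_config()].
#' @param ticks_per_pixel Macro ticks allotted per pixel along a line.
#' @param line_gap Macro ticks between a line stop and the next start.
#' @return Event tibble suitable for [write_ptu()].
#' @export
flim_image_to_events <- function(image, markers = marker_config(),
                                 ticks_per_pixel = 16L, line_gap = 64L) {
  d <- dim(image$counts)
  rows <- d[1]; cols <- d[2]; nb <- d[3]
  line_len <- cols * ticks_per_pixel
  period <- line_len + line_gap
  evs <- vector("list", rows + 1L)
  evs[[1]] <- tibble::tibble(macro_time = 0, micro_time = 0L, channel = 15L,
                             marker = markers$frame)
  for (r in seq_len(rows)) {
    t0 <- 1 + (r - 1) * period
    t1 <- t0 + line_len
    sl <- image$counts[r, , , drop = TRUE]  # cols x bins
    nz <- which(sl > 0L, arr.ind = TRUE)
    ph <- if (length(nz) > 0L) {
      cc <- rep(nz[, 1], sl[nz])
      bb <- rep(nz[, 2], sl[nz])
      tibble::tibble(
        macro_time = t0 + (cc - 0.5) * ticks_per_pixel,
        micro_time = as.integer(bb - 1L),
        channel = 0L,
        marker = 0L
      )
    } else {
      NULL
    }
    evs[[r + 1L]] <- dplyr::bind_rows(
      tibble::tibble(macro_time = t0, micro_time = 0L, channel = 15L,
                     marker = markers$line_start),
      ph,
      tibble::tibble(macro_time = t1, micro_time = 0L, channel = 15L,
                     marker = markers$line_stop)
    )
  }
  out <- dplyr::bind_rows(evs)
  out$macro_time <- round(out$macro_time)
  dplyr::arrange(out, .data$macro_time)
}

#' Read a decay histogram from CSV
#'
#' Two numeric columns (time in ns, counts); a header row is optional and
#' rows may be in any order. Spacing must be uniform.
#'
#' @param path CSV path.
#' @return Tibble with `time_ns` and integer `counts`.
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) {
    abort_flimr(sprintf("file not found: %s", path), "flimr_parse_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L) {
    abort_flimr("decay CSV needs two columns: time, counts", "flimr_format_error")
  }
  df <- df[, 1:2]
  names(df) <- c("time_ns", "counts")
  if (!is.numeric(df$time_ns) || !is.numeric(df$counts)) {
    abort_flimr("decay CSV columns must be numeric", "flimr_format_error")
  }
  df <- df[order(df$time_ns), ]
  if (any(df$counts < 0)) {
    abort_flimr("negative counts in decay CSV", "flimr_format_error")
  }
  validate_time_grid(df$time_ns, min_bins = 2L)
  tibble::tibble(time_ns = df$time_ns, counts = as.integer(round(df$counts)))
}

#' Write a decay histogram to CSV
#'
#' @param hist Tibble with `time_ns` and `counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(hist, path) {
  cols <- decay_cols(hist, value_cols = "counts")
  readr::write_csv(tibble::tibble(time_ns = cols$time_ns,
                                  counts = cols$value), path)
  invisible(path)
}

#' Read a 16-bit TIFF label mask
#'
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param mask Integer matrix (labels 0-65535).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (any(mask < 0) || any(mask > 65535)) {
    abort_flimr("labels must fit 16 bits", "flimr_format_error")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
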
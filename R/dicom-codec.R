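# Minimal DICOM Part-10 codec: explicit VR little endian only.
# Covers the subset of the standard needed for image-storage slices
# (CT/PT/MR) and RT Structure Sets: short/long element forms, nested
# sequences with defined or undefined lengths, the common VRs, and the
# group-0002 file meta header. Not a general-purpose DICOM library.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

SOP_CLASS <- c(
  CT       = "1.2.840.10008.5.1.4.1.1.2",
  PT       = "1.2.840.10008.5.1.4.1.1.128",
  MR       = "1.2.840.10008.5.1.4.1.1.4",
  RTSTRUCT = "1.2.840.10008.5.1.4.1.1.481.3"
)

# VRs whose element header uses the 12-byte long form
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
# string-like VRs, space padded (UI is NUL padded)
.str_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
              "PN", "SH", "ST", "TM", "UI", "UT")

.u16le <- function(v) {
  v <- as.integer(v)
  v[v < 0L] <- v[v < 0L] + 65536L
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.u32le <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; v <- v %/% 256
  as.raw(rbind(b0, b1, b2, v %% 256))
}

.rd_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.rd_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# --- value encoding -------------------------------------------------------

.fmt_ds <- function(x) {
  # DS values are at most 16 bytes; %.10g keeps mm-scale geometry exact
  vapply(x, function(v) sprintf("%.10g", v), character(1))
}

.encode_value <- function(vr, val) {
  if (vr == "SQ") {
    items <- lapply(val, function(ds) {
      body <- .encode_dataset(ds)
      c(.u16le(c(0xFFFE, 0xE000)), .u32le(length(body)), body)
    })
    return(do.call(c, c(items, list(raw(0)))))
  }
  if (vr %in% c("OB", "UN")) return(as.raw(val))
  if (vr == "OW") {
    if (is.raw(val)) return(val)
    return(writeBin(as.integer(val), raw(), size = 2L, endian = "little"))
  }
  if (vr == "US") return(.u16le(val))
  if (vr == "SS") return(.u16le(val))
  if (vr == "UL") return(.u32le(val))
  if (vr == "FL") return(writeBin(as.numeric(val), raw(), size = 4L, endian = "little"))
  if (vr == "FD") return(writeBin(as.numeric(val), raw(), size = 8L, endian = "little"))
  if (vr %in% .str_vrs) {
    s <- if (vr == "DS" && is.numeric(val)) .fmt_ds(val)
         else if (vr == "IS") sprintf("%d", as.integer(val))
         else as.character(val)
    out <- charToRaw(paste(s, collapse = "\\"))
    if (length(out) %% 2L == 1L)
      out <- c(out, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    return(out)
  }
  stop("unsupported VR for encoding: ", vr)
}

.encode_element <- function(group, elem, vr, val) {
  body <- .encode_value(vr, val)
  hdr <- c(.u16le(c(group, elem)), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), .u32le(length(body)), body)
  } else {
    stopifnot(length(body) < 65536)
    c(hdr, .u16le(length(body)), body)
  }
}

# dataset: list of elements, each list(g=, e=, vr=, val=); written sorted
.encode_dataset <- function(ds) {
  ord <- order(vapply(ds, function(el) el$g * 65536 + el$e, numeric(1)))
  parts <- lapply(ds[ord], function(el) .encode_element(el$g, el$e, el$vr, el$val))
  do.call(c, c(parts, list(raw(0))))
}

el <- function(g, e, vr, val) list(g = g, e = e, vr = vr, val = val)

# --- file write -----------------------------------------------------------

dcm_write <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- list(
    el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    el(0x0002, 0x0002, "UI", sop_class_uid),
    el(0x0002, 0x0003, "UI", sop_instance_uid),
    el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.1594.1")
  )
  meta_body <- .encode_dataset(meta)
  meta_len <- .encode_element(0x0002, 0x0000, "UL", length(meta_body))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta_body), con)
  writeBin(.encode_dataset(dataset), con)
  invisible(path)
}

# --- value decoding -------------------------------------------------------

.decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (n == 0L && vr != "SQ") {
    return(switch(vr, US = , SS = , UL = , FL = , FD = numeric(0),
                  OB = , OW = , UN = raw(0), character(0)))
  }
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "US") return(readBin(bytes, integer(), n %/% 2L, size = 2L,
                                 signed = FALSE, endian = "little"))
  if (vr == "SS") return(readBin(bytes, integer(), n %/% 2L, size = 2L,
                                 signed = TRUE, endian = "little"))
  if (vr == "UL") return(readBin(bytes, integer(), n %/% 4L, size = 4L,
                                 endian = "little"))
  if (vr == "FL") return(readBin(bytes, numeric(), n %/% 4L, size = 4L,
                                 endian = "little"))
  if (vr == "FD") return(readBin(bytes, numeric(), n %/% 8L, size = 8L,
                                 endian = "little"))
  if (vr == "AT") return(readBin(bytes, integer(), n %/% 2L, size = 2L,
                                 signed = FALSE, endian = "little"))
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (vr %in% c("DS", "IS")) return(as.numeric(parts))
  parts
}

.key <- function(g, e) sprintf("%04x%04x", g, e)

# parse elements of one dataset from raw; returns list(ds=named list, pos=)
# `end` NA means parse until item/sequence delimiter or end of buffer
.parse_dataset <- function(raw, pos, end = NA) {
  ds <- list()
  limit <- if (is.na(end)) length(raw) else end - 1L
  while (pos <= limit) {
    g <- .rd_u16(raw, pos); e <- .rd_u16(raw, pos + 2L)
    if (g == 0xFFFE && e == 0xE00D) return(list(ds = ds, pos = pos + 8L)) # item delim
    if (g == 0xFFFE && e == 0xE0DD) return(list(ds = ds, pos = pos + 8L)) # seq delim
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(raw, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .rd_u16(raw, pos + 6L)
      pos <- pos + 8L
    }
    if (vr == "SQ" || (vr == "UN" && len == 4294967295)) {
      parsed <- .parse_sequence(raw, pos, len)
      ds[[.key(g, e)]] <- list(vr = "SQ", val = parsed$items)
      pos <- parsed$pos
    } else {
      if (len == 4294967295)
        stop("undefined length outside a sequence at element ", .key(g, e))
      bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
      ds[[.key(g, e)]] <- list(vr = vr, val = .decode_value(vr, bytes))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos)
}

.parse_sequence <- function(raw, pos, len) {
  items <- list()
  end <- if (len == 4294967295) NA else pos + len
  repeat {
    if (!is.na(end) && pos >= end) break
    if (pos + 7L > length(raw)) break
    g <- .rd_u16(raw, pos); e <- .rd_u16(raw, pos + 2L)
    ilen <- .rd_u32(raw, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) break
    if (!(g == 0xFFFE && e == 0xE000))
      stop("malformed sequence: expected item tag, got ", .key(g, e))
    if (ilen == 4294967295) {
      parsed <- .parse_dataset(raw, pos, NA)
    } else {
      parsed <- .parse_dataset(raw, pos, pos + ilen)
      parsed$pos <- pos + ilen
    }
    items[[length(items) + 1L]] <- parsed$ds
    pos <- parsed$pos
  }
  list(items = items, pos = pos)
}

dcm_read <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part-10 file (missing DICM marker): ", path)
  pos <- 133L
  # file meta group (always explicit LE)
  meta <- list()
  while (pos <= length(raw) && .rd_u16(raw, pos) == 0x0002) {
    e <- .rd_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(raw, pos + 8L); pos <- pos + 12L
    } else {
      len <- .rd_u16(raw, pos + 6L); pos <- pos + 8L
    }
    bytes <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    meta[[.key(0x0002, e)]] <- list(vr = vr, val = .decode_value(vr, bytes))
    pos <- pos + len
  }
  ts <- meta[["00020010"]]$val
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax '", ts,
         "' (only explicit VR little endian ", TS_EXPLICIT_LE, " is supported)")
  list(meta = meta, data = .parse_dataset(raw, pos)$ds)
}

# convenience accessors over the parsed named list
# convert a parsed dataset back into the writer's element-list form
# (used to construct deliberately damaged fixtures in tests)
rebuild_elements <- function(ds) {
  lapply(names(ds), function(key) {
    g <- strtoi(substr(key, 1, 4), 16L)
    e <- strtoi(substr(key, 5, 8), 16L)
    vr <- ds[[key]]$vr
    val <- ds[[key]]$val
    if (vr == "SQ") val <- lapply(val, rebuild_elements)
    if (vr == "IS") val <- as.integer(val)
    el(g, e, vr, val)
  })
}

dcm_get <- function(ds, g, e, default = NULL) {
  v <- ds[[.key(g, e)]]
  if (is.null(v)) default else v$val
}

dcm_require <- function(ds, g, e, what) {
  v <- ds[[.key(g, e)]]
  if (is.null(v)) stop("missing required DICOM tag (", .key(g, e), ") ", what)
  v$val
}
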
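# Minimal DICOM codec: explicit VR, little endian (transfer syntax
# 1.2.840.10008.1.2.1) covering the attribute subset used by the RT Plan,
# RT Dose and RT Structure Set modules this package models. A dataset is a
# named list keyed by 8-hex-digit tags ("GGGGEEEE", uppercase); each element
# is list(vr, value) where value is a character scalar (string VRs), an
# integer/double vector (binary numeric VRs), a raw vector (OB/OW) or, for
# SQ, an unnamed list of nested datasets.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

# VRs that use the 4-byte (long form) length field
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
# string VRs padded with space; UI pads with NUL
.string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                 "PN", "SH", "ST", "TM", "UT")

dcm_tag <- function(group, elem) {
  sprintf("%04X%04X", group, elem)
}

dcm_el <- function(vr, value) list(vr = vr, value = value)

dcm_get <- function(ds, tag) {
  el <- ds[[tag]]
  if (is.null(el)) NULL else el$value
}

# numeric value(s) of a DS/IS element (backslash-delimited decimal strings)
dcm_num <- function(ds, tag) {
  v <- dcm_get(ds, tag)
  if (is.null(v)) return(NULL)
  if (is.numeric(v)) return(v)
  as.numeric(strsplit(v, "\\\\", fixed = FALSE)[[1]])
}

dcm_str <- function(ds, tag) {
  v <- dcm_get(ds, tag)
  if (is.null(v)) NULL else trimws(v)
}

.u16raw <- function(x) {
  x <- as.integer(x)
  writeBin(ifelse(x > 32767L, x - 65536L, x), raw(), size = 2L,
           endian = "little")
}

.u32raw <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

.pad_even <- function(s, pad) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

# serialize one element body (value bytes only)
.encode_value <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- .encode_dataset(item)
      c(.u16raw(c(0xFFFE, 0xE000)), .u32raw(length(body)), body)
    })
    return(do.call(c, c(list(raw(0)), items)))
  }
  switch(vr,
    UI = .pad_even(value, as.raw(0L)),
    US = .u16raw(value),
    UL = .u32raw(value),
    SS = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    SL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4L, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OB = ,
    OW = as.raw(value),
    # remaining string VRs, space padded
    .pad_even(paste(value, collapse = "\\"), charToRaw(" "))
  )
}

.encode_element <- function(tag, el) {
  grp <- strtoi(substr(tag, 1, 4), 16L)
  ele <- strtoi(substr(tag, 5, 8), 16L)
  body <- .encode_value(el$vr, el$value)
  hdr <- c(.u16raw(c(grp, ele)), charToRaw(el$vr))
  if (el$vr %in% .long_vrs) {
    hdr <- c(hdr, as.raw(c(0L, 0L)), .u32raw(length(body)))
  } else {
    hdr <- c(hdr, .u16raw(length(body)))
  }
  c(hdr, body)
}

.encode_dataset <- function(ds) {
  tags <- sort(names(ds))
  parts <- lapply(tags, function(tg) .encode_element(tg, ds[[tg]]))
  do.call(c, c(list(raw(0)), parts))
}

#' Write a DICOM file (explicit VR little endian)
#'
#' Low-level writer used by the RT Plan / RT Dose / RT Structure Set
#' writers. Prepends the 128-byte preamble, "DICM" magic and a file meta
#' information group derived from the dataset's SOP class/instance UIDs.
#'
#' @param ds dataset (named list of elements keyed by "GGGGEEEE" tags); must
#'   contain SOPClassUID (00080016) and SOPInstanceUID (00080018)
#' @param path output file path
#' @return `path`, invisibly
#' @keywords internal
dcm_write <- function(ds, path) {
  sop_class <- dcm_str(ds, "00080016")
  sop_inst <- dcm_str(ds, "00080018")
  stopifnot(!is.null(sop_class), !is.null(sop_inst))
  meta <- list(
    "00020001" = dcm_el("OB", as.raw(c(0L, 1L))),
    "00020002" = dcm_el("UI", sop_class),
    "00020003" = dcm_el("UI", sop_inst),
    "00020010" = dcm_el("UI", EXPLICIT_VR_LE),
    "00020012" = dcm_el("UI", "2.25.424242421561")
  )
  meta_body <- .encode_dataset(meta)
  meta_all <- c(.encode_element("00020000",
                                dcm_el("UL", length(meta_body))), meta_body)
  out <- c(raw(128L), charToRaw("DICM"), meta_all, .encode_dataset(ds))
  writeBin(out, path)
  invisible(path)
}

# --- reading -----------------------------------------------------------

.rd_u16 <- function(buf, pos) {
  v <- readBin(buf[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
               endian = "little")
  v
}

.rd_u32 <- function(buf, pos) {
  # returns NA for the undefined-length marker 0xFFFFFFFF
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v == -1L) NA_integer_ else v
}

.decode_value <- function(vr, bytes) {
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8L, size = 8L,
                 endian = "little"),
    OB = ,
    OW = ,
    UN = bytes,
    UI = rawToChar(bytes[bytes != as.raw(0L)]),
    rawToChar(bytes)
  )
}

# parse elements of buf[pos..end]; returns list(ds=, pos=); stop_at_item_delim
# is used inside undefined-length sequence items
.parse_dataset <- function(buf, pos, end) {
  ds <- list()
  while (pos <= end) {
    grp <- .rd_u16(buf, pos); ele <- .rd_u16(buf, pos + 2L)
    if (grp == 0xFFFE && ele == 0xE00D) {  # item delimitation
      pos <- pos + 8L
      return(list(ds = ds, pos = pos, delim = TRUE))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .rd_u16(buf, pos + 6L)
      pos <- pos + 8L
    }
    tag <- dcm_tag(grp, ele)
    if (vr == "SQ") {
      parsed <- .parse_sequence(buf, pos, len)
      ds[[tag]] <- dcm_el("SQ", parsed$items)
      pos <- parsed$pos
    } else {
      if (is.na(len)) stop("undefined length only supported for SQ")
      bytes <- if (len > 0L) buf[pos:(pos + len - 1L)] else raw(0)
      ds[[tag]] <- dcm_el(vr, .decode_value(vr, bytes))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos, delim = FALSE)
}

.parse_sequence <- function(buf, pos, len) {
  items <- list()
  seq_end <- if (is.na(len)) length(buf) else pos + len - 1L
  while (pos <= seq_end) {
    grp <- .rd_u16(buf, pos); ele <- .rd_u16(buf, pos + 2L)
    if (grp == 0xFFFE && ele == 0xE0DD) {  # sequence delimitation
      pos <- pos + 8L
      break
    }
    if (!(grp == 0xFFFE && ele == 0xE000)) {
      stop("malformed sequence: expected item tag")
    }
    item_len <- .rd_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (is.na(item_len)) {
      parsed <- .parse_dataset(buf, pos, length(buf))
      if (!parsed$delim) stop("unterminated undefined-length item")
    } else {
      parsed <- .parse_dataset(buf, pos, pos + item_len - 1L)
    }
    items[[length(items) + 1L]] <- parsed$ds
    pos <- parsed$pos
    if (is.na(len) && pos > length(buf)) stop("unterminated sequence")
  }
  list(items = items, pos = pos)
}

#' Read a DICOM file (explicit VR little endian)
#'
#' @param path file path
#' @return list with components `meta` (file meta group) and `data` (main
#'   dataset), both in the element-list representation of [dcm_write()]
#' @keywords internal
dcm_read <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 134L || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  pos <- 133L
  # file meta group: explicit VR, delimited by its group length element
  grp_len_el <- .parse_dataset(buf, pos, pos + 11L)
  meta_len <- grp_len_el$ds[["00020000"]]$value
  pos <- grp_len_el$pos
  meta <- .parse_dataset(buf, pos, pos + meta_len - 1L)
  ts <- dcm_str(meta$ds, "00020010")
  if (!is.null(ts) && ts != EXPLICIT_VR_LE) {
    stop("unsupported transfer syntax: ", ts)
  }
  body <- .parse_dataset(buf, meta$pos, length(buf))
  list(meta = meta$ds, data = body$ds)
}

# deterministic study-level UID from a label (digits-only suffix)
.dcm_uid <- function(label) {
  h <- utf8ToInt(paste0("planscope:", label))
  acc <- 7
  for (k in h) acc <- (acc * 131 + k) %% 999999937
  sprintf("2.25.1561%09d", acc)
}

# DS formatting: fixed decimals, <= 16 bytes per DICOM DS length limit
.ds_fmt <- function(x, digits) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  if (any(nchar(s) > 16L)) stop("DS value exceeds 16 characters")
  paste(s, collapse = "\\")
}
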
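# Minimal DICOM engine: explicit-VR little-endian only, which is the
# transfer syntax this package writes. Enough of PS3.5/PS3.6 to round-trip
# RT-PLAN, RT-DOSE and RT-STRUCT objects; anything else raises an explicit
# format error rather than guessing.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_SOP_RTPLAN   <- "1.2.840.10008.5.1.4.1.1.481.5"
DCM_SOP_RTDOSE   <- "1.2.840.10008.5.1.4.1.1.481.2"
DCM_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
DCM_IMPL_UID <- "1.2.826.0.1.3680043.10.424.1"

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
dcm_text_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                  "PN", "SH", "ST", "TM", "UI", "UT")

# One element: list(group, element, vr, value). SQ values are lists of
# datasets; a dataset is a list of elements.
del <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(raw_u16(lo), raw_u16(hi))
}

dcm_pad <- function(payload, vr) {
  if (length(payload) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB", "OW", "UN")) as.raw(0L) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  payload
}

dcm_format_ds <- function(x) {
  paste(vapply(x, function(v) {
    s <- sprintf("%.10g", v)
    if (nchar(s) > 16L) s <- sprintf("%.8g", v)
    s
  }, character(1)), collapse = "\\")
}

dcm_encode_value <- function(vr, value) {
  switch(vr,
    DS = charToRaw(dcm_format_ds(value)),
    IS = charToRaw(paste(as.integer(value), collapse = "\\")),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    OB = as.raw(value),
    OW = as.raw(value),
    charToRaw(paste(as.character(value), collapse = "\\"))  # text VRs
  )
}

dcm_encode_element <- function(e) {
  payload <- if (e$vr == "SQ") {
    do.call(c, c(list(raw(0)), lapply(e$value, function(item) {
      body <- dcm_encode_dataset(item)
      c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(body)), body)
    })))
  } else {
    dcm_pad(dcm_encode_value(e$vr, e$value), e$vr)
  }
  header <- c(raw_u16(e$group), raw_u16(e$element), charToRaw(e$vr))
  header <- if (e$vr %in% dcm_long_vrs) {
    c(header, as.raw(c(0L, 0L)), raw_u32(length(payload)))
  } else {
    c(header, raw_u16(length(payload)))
  }
  c(header, payload)
}

dcm_encode_dataset <- function(ds) {
  ord <- order(vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1)))
  do.call(c, c(list(raw(0)), lapply(ds[ord], dcm_encode_element)))
}

# Content-derived UID so identical objects get identical UIDs (reports stay
# byte-reproducible); not globally unique, which is fine for synthetic data.
dcm_uid <- function(seed_string) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(seed_string, tf)
  h <- unname(tools::md5sum(tf))
  paste0(DCM_IMPL_UID, ".",
         strtoi(substr(h, 1, 6), 16L), ".",
         strtoi(substr(h, 7, 12), 16L), ".",
         strtoi(substr(h, 13, 18), 16L))
}

dcm_write <- function(ds, path, sop_class_uid, sop_instance_uid) {
  body <- dcm_encode_dataset(ds)
  meta <- dcm_encode_dataset(list(
    del(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    del(0x0002, 0x0002, "UI", sop_class_uid),
    del(0x0002, 0x0003, "UI", sop_instance_uid),
    del(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE),
    del(0x0002, 0x0012, "UI", DCM_IMPL_UID)
  ))
  meta <- c(dcm_encode_element(del(0x0002, 0x0000, "UL", length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

dcm_u16_at <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
dcm_u32_at <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

dcm_decode_value <- function(vr, payload) {
  n <- length(payload)
  txt <- function() {
    p <- payload
    # strip trailing padding (space or NUL) before rawToChar, which rejects NULs
    while (length(p) > 0L && (p[length(p)] == as.raw(0L) || p[length(p)] == as.raw(32L))) {
      p <- p[-length(p)]
    }
    rawToChar(p)
  }
  switch(vr,
    DS = { s <- txt(); if (s == "") numeric(0) else as.numeric(strsplit(s, "\\\\")[[1]]) },
    IS = { s <- txt(); if (s == "") integer(0) else as.integer(strsplit(s, "\\\\")[[1]]) },
    UL = readBin(payload, "integer", n = n / 4, size = 4, endian = "little"),
    US = readBin(payload, "integer", n = n / 2, size = 2, signed = FALSE, endian = "little"),
    FD = readBin(payload, "double", n = n / 8, size = 8, endian = "little"),
    FL = readBin(payload, "double", n = n / 4, size = 4, endian = "little"),
    OB = payload,
    OW = payload,
    UN = payload,
    { s <- txt(); if (grepl("\\\\", s)) strsplit(s, "\\\\")[[1]] else s }
  )
}

# Parses elements in bytes[pos..end]; returns list(elements, pos). If
# stop_at_item_delim, stops after consuming an (FFFE,E00D) item delimiter.
dcm_parse_dataset <- function(bytes, pos, end, stop_at_item_delim = FALSE) {
  elements <- list()
  while (pos <= end) {
    group <- dcm_u16_at(bytes, pos)
    element <- dcm_u16_at(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {
      len <- dcm_u32_at(bytes, pos)
      pos <- pos + 4L
      if (element == 0xE00D && stop_at_item_delim) return(list(elements = elements, pos = pos))
      arc_format_error("unexpected DICOM delimiter item in dataset")
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% dcm_long_vrs) {
      len <- dcm_u32_at(bytes, pos + 2L)
      pos <- pos + 6L
    } else {
      len <- dcm_u16_at(bytes, pos)
      pos <- pos + 2L
    }
    if (vr == "SQ") {
      items <- list()
      sq_end <- if (len == 4294967295) end else pos + len - 1
      repeat {
        if (len != 4294967295 && pos > sq_end) break
        g2 <- dcm_u16_at(bytes, pos)
        e2 <- dcm_u16_at(bytes, pos + 2L)
        ilen <- dcm_u32_at(bytes, pos + 4L)
        pos <- pos + 8L
        if (g2 == 0xFFFE && e2 == 0xE0DD) break  # sequence delimiter
        if (g2 != 0xFFFE || e2 != 0xE000) arc_format_error("malformed DICOM sequence item")
        if (ilen == 4294967295) {
          r <- dcm_parse_dataset(bytes, pos, end, stop_at_item_delim = TRUE)
        } else {
          r <- dcm_parse_dataset(bytes, pos, pos + ilen - 1)
        }
        items[[length(items) + 1L]] <- r$elements
        pos <- r$pos
      }
      elements[[length(elements) + 1L]] <- del(group, element, "SQ", items)
    } else {
      payload <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      elements[[length(elements) + 1L]] <- del(group, element, vr, dcm_decode_value(vr, payload))
    }
  }
  list(elements = elements, pos = pos)
}

#' Read a DICOM file into a raw element tree
#'
#' Low-level reader for explicit-VR little-endian DICOM files (the only
#' transfer syntax this package writes); other syntaxes raise a format error.
#' Most users want [read_rtplan()], [read_rtdose()] or [read_rtstruct()].
#'
#' @param path file path.
#' @return A list of elements `list(group, element, vr, value)`; sequence
#'   values are lists of nested element lists.
#' @export
dcm_read <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) arc_format_error(sprintf("'%s' is not a DICOM file", path))
  bytes <- readBin(path, raw(), n)
  if (rawToChar(bytes[129:132]) != "DICM") {
    arc_format_error(sprintf("'%s' is not a DICOM file (missing DICM marker)", path))
  }
  pos <- 133L
  # file meta group (always explicit LE)
  meta <- list()
  while (pos <= n && dcm_u16_at(bytes, pos) == 0x0002) {
    r <- dcm_parse_dataset(bytes, pos, pos)  # parse exactly one element
    meta <- c(meta, r$elements)
    pos <- r$pos
  }
  ts <- dcm_find(meta, 0x0002, 0x0010)
  if (is.null(ts) || ts != DCM_TS_EXPLICIT_LE) {
    arc_format_error(sprintf("unsupported DICOM transfer syntax '%s' (only explicit VR little endian is handled)",
                             if (is.null(ts)) "<missing>" else ts))
  }
  dcm_parse_dataset(bytes, pos, n)$elements
}

# First matching element value, or NULL.
dcm_find <- function(ds, group, element) {
  for (e in ds) {
    if (e$group == group && e$element == element) return(e$value)
  }
  NULL
}

# ---- RT-PLAN ---------------------------------------------------------------

#' Write an arc plan as a DICOM RT-PLAN file
#'
#' Emits a minimal conformant RT-PLAN: one beam with an MLCX beam-limiting
#' device, leaf position boundaries, a control-point sequence (gantry angle,
#' cumulative meterset weight, `LeafJawPositions` with bank A followed by
#' bank B), the beam meterset in the fraction group, and the prescription in
#' a dose reference. SOP instance UIDs are derived from the plan content so
#' identical plans produce identical files.
#'
#' @param plan an [arc_plan()].
#' @param path output path (conventionally `.dcm`).
#' @param beam_name beam label written to the file.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path, beam_name = "ARC1") {
  n <- n_control_points(plan)
  np <- plan$machine$n_pairs
  cps <- vector("list", n)
  for (i in seq_len(n)) {
    cps[[i]] <- list(
      del(0x300A, 0x0112, "IS", i - 1L),
      del(0x300A, 0x011A, "SQ", list(list(
        del(0x300A, 0x00B8, "CS", "MLCX"),
        del(0x300A, 0x011C, "DS", c(plan$bank_a[i, ], plan$bank_b[i, ]))
      ))),
      del(0x300A, 0x011E, "DS", plan$gantry_angle[i]),
      del(0x300A, 0x0134, "DS", plan$cum_weight[i])
    )
  }
  beam <- list(
    del(0x300A, 0x00B4, "DS", plan$machine$sad),
    del(0x300A, 0x00B6, "SQ", list(list(
      del(0x300A, 0x00B8, "CS", "MLCX"),
      del(0x300A, 0x00BC, "IS", np),
      del(0x300A, 0x00BE, "DS", plan$machine$leaf_pair_boundaries)
    ))),
    del(0x300A, 0x00C0, "IS", 1L),
    del(0x300A, 0x00C2, "LO", beam_name),
    del(0x300A, 0x00C6, "CS", "PHOTON"),
    del(0x300A, 0x010E, "DS", 1),
    del(0x300A, 0x0110, "IS", n),
    del(0x300A, 0x0111, "SQ", cps)
  )
  nfx <- if (!is.null(plan$prescription)) plan$prescription$n_fractions else 1L
  ds <- list(
    del(0x0008, 0x0016, "UI", DCM_SOP_RTPLAN),
    del(0x0008, 0x0060, "CS", "RTPLAN"),
    del(0x300A, 0x0002, "SH", "arcmetrics"),
    del(0x300A, 0x0070, "SQ", list(list(
      del(0x300A, 0x0071, "IS", 1L),
      del(0x300A, 0x0078, "IS", nfx),
      del(0x300A, 0x0080, "IS", 1L),
      del(0x300C, 0x0004, "SQ", list(list(
        del(0x300A, 0x0086, "DS", plan$total_mu),
        del(0x300C, 0x0006, "IS", 1L)
      )))
    ))),
    del(0x300A, 0x00B0, "SQ", list(beam))
  )
  if (!is.null(plan$prescription)) {
    ds <- c(ds, list(del(0x300A, 0x0010, "SQ", list(list(
      del(0x300A, 0x0012, "IS", 1L),
      del(0x300A, 0x0016, "LO", sprintf("IDL %.2f", plan$prescription$idl_percent)),
      del(0x300A, 0x0026, "DS", rx_total_gy(plan$prescription))
    )))))
  }
  uid <- dcm_uid(paste(c(plan$gantry_angle, plan$cum_weight, plan$total_mu,
                         as.vector(plan$bank_a)), collapse = ","))
  ds <- c(ds, list(del(0x0008, 0x0018, "UI", uid)))
  dcm_write(ds, path, DCM_SOP_RTPLAN, uid)
}

#' Read a DICOM RT-PLAN file into an arc plan
#'
#' Parses the beam's MLCX leaf boundaries and control-point sequence. Leaf
#' positions are mapped so that the first `N` `LeafJawPositions` values (the
#' file's bank "1", the negative-x side at the isocenter plane) become
#' `bank_a` and the remaining `N` become `bank_b`. Gantry angle and leaf
#' positions are carried forward when a control point omits them; cumulative
#' meterset weights are normalized so the final weight is 1.
#'
#' @param path RT-PLAN file.
#' @param beam beam selector: an integer matched against `BeamNumber` (then
#'   positionally), or a character matched against `BeamName`.
#' @return An [arc_plan()]. A plan without an MLCX device raises an
#'   unsupported-plan error; non-monotone metersets or crossed banks raise a
#'   malformed-plan error.
#' @export
read_rtplan <- function(path, beam = 1L) {
  ds <- dcm_read(path)
  beams <- dcm_find(ds, 0x300A, 0x00B0)
  if (is.null(beams) || length(beams) == 0L) {
    arc_unsupported_plan(sprintf("'%s' contains no BeamSequence", path))
  }
  bi <- NULL
  if (is.character(beam)) {
    for (i in seq_along(beams)) {
      if (identical(dcm_find(beams[[i]], 0x300A, 0x00C2), beam)) bi <- i
    }
    if (is.null(bi)) arc_input_error(sprintf("no beam named '%s' in '%s'", beam, path))
  } else {
    for (i in seq_along(beams)) {
      bn <- dcm_find(beams[[i]], 0x300A, 0x00C0)
      if (!is.null(bn) && bn == beam) bi <- i
    }
    if (is.null(bi)) {
      if (beam >= 1 && beam <= length(beams)) bi <- as.integer(beam)
      else arc_input_error(sprintf("no beam number %s in '%s'", beam, path))
    }
  }
  b <- beams[[bi]]
  boundaries <- NULL
  for (dev in dcm_find(b, 0x300A, 0x00B6) %||% list()) {
    if (identical(dcm_find(dev, 0x300A, 0x00B8), "MLCX")) {
      boundaries <- dcm_find(dev, 0x300A, 0x00BE)
    }
  }
  if (is.null(boundaries)) {
    arc_unsupported_plan(sprintf("beam %d of '%s' has no MLCX beam-limiting device", bi, path))
  }
  np <- length(boundaries) - 1L
  cps <- dcm_find(b, 0x300A, 0x0111)
  if (is.null(cps) || length(cps) < 2L) arc_malformed_plan("RT-PLAN beam has fewer than 2 control points")
  n <- length(cps)
  ang <- numeric(n); w <- numeric(n)
  bank_a <- matrix(NA_real_, n, np); bank_b <- matrix(NA_real_, n, np)
  for (i in seq_len(n)) {
    cp <- cps[[i]]
    g <- dcm_find(cp, 0x300A, 0x011E)
    ang[i] <- if (!is.null(g)) g else ang[i - 1L]
    wt <- dcm_find(cp, 0x300A, 0x0134)
    if (is.null(wt)) arc_malformed_plan("RT-PLAN control point lacks a cumulative meterset weight")
    w[i] <- wt
    pos <- NULL
    for (dev in dcm_find(cp, 0x300A, 0x011A) %||% list()) {
      if (identical(dcm_find(dev, 0x300A, 0x00B8), "MLCX")) {
        pos <- dcm_find(dev, 0x300A, 0x011C)
      }
    }
    if (!is.null(pos)) {
      if (length(pos) != 2L * np) arc_malformed_plan("LeafJawPositions length does not match leaf pair count")
      bank_a[i, ] <- pos[seq_len(np)]
      bank_b[i, ] <- pos[np + seq_len(np)]
    } else if (i > 1L) {
      bank_a[i, ] <- bank_a[i - 1L, ]
      bank_b[i, ] <- bank_b[i - 1L, ]
    } else {
      arc_malformed_plan("first control point lacks MLCX leaf positions")
    }
  }
  if (w[n] <= 0) arc_malformed_plan("RT-PLAN final cumulative meterset weight is not positive")
  w <- w / w[n]
  fg <- dcm_find(ds, 0x300A, 0x0070)
  total_mu <- NULL
  nfx <- 1L
  if (!is.null(fg) && length(fg) > 0L) {
    nfx_v <- dcm_find(fg[[1]], 0x300A, 0x0078)
    if (!is.null(nfx_v)) nfx <- nfx_v
    for (rb in dcm_find(fg[[1]], 0x300C, 0x0004) %||% list()) {
      rbn <- dcm_find(rb, 0x300C, 0x0006)
      bn <- dcm_find(b, 0x300A, 0x00C0)
      if (is.null(rbn) || is.null(bn) || rbn == bn) {
        total_mu <- dcm_find(rb, 0x300A, 0x0086)
      }
    }
  }
  if (is.null(total_mu)) arc_malformed_plan("RT-PLAN lacks a BeamMeterset for the selected beam")
  rx <- NULL
  dr <- dcm_find(ds, 0x300A, 0x0010)
  if (!is.null(dr) && length(dr) > 0L) {
    tot <- dcm_find(dr[[1]], 0x300A, 0x0026)
    desc <- dcm_find(dr[[1]], 0x300A, 0x0016)
    idl <- if (!is.null(desc) && grepl("^IDL ", desc)) as.numeric(sub("^IDL ", "", desc)) else 100
    if (!is.null(tot)) rx <- prescription_spec(tot / nfx, nfx, idl)
  }
  sad <- dcm_find(b, 0x300A, 0x00B4) %||% 1000
  machine <- machine_model(sad = sad, leaf_pair_boundaries = boundaries,
                           max_leaf_position = max(200, ceiling(max(abs(c(bank_a, bank_b))))))
  arc_plan(machine, ang, bank_a, bank_b, w, total_mu, rx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- RT-DOSE ---------------------------------------------------------------

#' Write / read a DICOM RT-DOSE file
#'
#' Stores the dose grid as 32-bit unsigned pixel data with a `DoseGridScaling`
#' factor, frames along z, rows along y and columns along x (identity
#' orientation). The reader accepts 16- or 32-bit unsigned data on a uniform
#' frame spacing and returns doses in Gy.
#'
#' @param d a [dose_grid()].
#' @param path file path.
#' @return `write_rtdose()` returns `path` invisibly; `read_rtdose()` returns
#'   a [dose_grid()].
#' @export
write_rtdose <- function(d, path) {
  shp <- d$grid$shape
  mx <- max(d$dose)
  scaling <- if (mx > 0) mx / 2147483646 else 1
  ints <- as.integer(round(as.vector(d$dose) / scaling))
  uid <- dcm_uid(paste(c(shp, d$grid$origin, mx, sum(d$dose)), collapse = ","))
  ds <- list(
    del(0x0008, 0x0016, "UI", DCM_SOP_RTDOSE),
    del(0x0008, 0x0018, "UI", uid),
    del(0x0008, 0x0060, "CS", "RTDOSE"),
    del(0x0020, 0x0032, "DS", d$grid$origin),
    del(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    del(0x0028, 0x0002, "US", 1L),
    del(0x0028, 0x0004, "CS", "MONOCHROME2"),
    del(0x0028, 0x0008, "IS", shp[3]),
    del(0x0028, 0x0010, "US", shp[2]),
    del(0x0028, 0x0011, "US", shp[1]),
    del(0x0028, 0x0030, "DS", c(d$grid$spacing[2], d$grid$spacing[1])),
    del(0x0028, 0x0100, "US", 32L),
    del(0x0028, 0x0101, "US", 32L),
    del(0x0028, 0x0102, "US", 31L),
    del(0x0028, 0x0103, "US", 0L),
    del(0x3004, 0x0002, "CS", "GY"),
    del(0x3004, 0x0004, "CS", "PHYSICAL"),
    del(0x3004, 0x000A, "CS", "PLAN"),
    del(0x3004, 0x000C, "DS", (seq_len(shp[3]) - 1) * d$grid$spacing[3]),
    del(0x3004, 0x000E, "DS", scaling),
    del(0x7FE0, 0x0010, "OW", writeBin(ints, raw(), size = 4, endian = "little"))
  )
  dcm_write(ds, path, DCM_SOP_RTDOSE, uid)
}

#' @rdname write_rtdose
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read(path)
  nx <- dcm_find(ds, 0x0028, 0x0011)
  ny <- dcm_find(ds, 0x0028, 0x0010)
  nz <- dcm_find(ds, 0x0028, 0x0008) %||% 1L
  if (is.null(nx) || is.null(ny)) arc_format_error("RT-DOSE lacks Rows/Columns")
  orient <- dcm_find(ds, 0x0020, 0x0037)
  if (!is.null(orient) && !isTRUE(all.equal(orient, c(1, 0, 0, 0, 1, 0)))) {
    arc_format_error("RT-DOSE with non-identity ImageOrientationPatient is not supported")
  }
  px <- dcm_find(ds, 0x0028, 0x0030)
  gfo <- dcm_find(ds, 0x3004, 0x000C)
  dz <- if (length(gfo) >= 2) diff(gfo) else 1
  if (length(dz) > 1 && max(abs(diff(dz))) > 1e-6) {
    arc_format_error("RT-DOSE has non-uniform frame offsets")
  }
  grid <- grid_spec(origin = dcm_find(ds, 0x0020, 0x0032) %||% c(0, 0, 0),
                    spacing = c(px[2], px[1], dz[1]),
                    shape = c(nx, ny, nz))
  bits <- dcm_find(ds, 0x0028, 0x0100) %||% 32L
  payload <- dcm_find(ds, 0x7FE0, 0x0010)
  if (is.null(payload)) arc_format_error("RT-DOSE lacks PixelData")
  nvox <- as.numeric(nx) * ny * nz
  vals <- if (bits == 32L) {
    v <- readBin(payload, "integer", n = nvox, size = 4, endian = "little")
    v <- as.numeric(v)
    v[v < 0] <- v[v < 0] + 4294967296
    v
  } else if (bits == 16L) {
    readBin(payload, "integer", n = nvox, size = 2, signed = FALSE, endian = "little")
  } else {
    arc_format_error(sprintf("RT-DOSE BitsAllocated %d is not supported", bits))
  }
  scaling <- dcm_find(ds, 0x3004, 0x000E) %||% 1
  dose_grid(grid, array(vals * scaling, grid$shape))
}

# ---- RT-STRUCT -------------------------------------------------------------

#' Write / read a DICOM RT-STRUCT file
#'
#' Minimal structure-set support: named regions of interest with
#' `CLOSED_PLANAR` contours. The reader returns, per structure, the name and
#' a list of `n x 3` contour vertex matrices (mm) which can be rasterized
#' with [contours_to_mask()].
#'
#' @param structs list of `list(name =, contours = list(<n x 3 matrix>, ...))`.
#' @param path file path.
#' @return `write_rtstruct()` returns `path` invisibly; `read_rtstruct()`
#'   returns a list of structures as above.
#' @export
write_rtstruct <- function(structs, path) {
  rois <- list(); roic <- list()
  for (i in seq_along(structs)) {
    rois[[i]] <- list(del(0x3006, 0x0022, "IS", i),
                      del(0x3006, 0x0026, "LO", structs[[i]]$name))
    cseq <- lapply(structs[[i]]$contours, function(m) {
      m <- as.matrix(m)
      list(del(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
           del(0x3006, 0x0046, "IS", nrow(m)),
           del(0x3006, 0x0050, "DS", as.vector(t(m))))
    })
    roic[[i]] <- list(del(0x3006, 0x0040, "SQ", cseq),
                      del(0x3006, 0x0084, "IS", i))
  }
  uid <- dcm_uid(paste(vapply(structs, `[[`, "", "name"), collapse = ","))
  ds <- list(
    del(0x0008, 0x0016, "UI", DCM_SOP_RTSTRUCT),
    del(0x0008, 0x0018, "UI", uid),
    del(0x0008, 0x0060, "CS", "RTSTRUCT"),
    del(0x3006, 0x0020, "SQ", rois),
    del(0x3006, 0x0039, "SQ", roic)
  )
  dcm_write(ds, path, DCM_SOP_RTSTRUCT, uid)
}

#' @rdname write_rtstruct
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read(path)
  rois <- dcm_find(ds, 0x3006, 0x0020) %||% list()
  names_by_num <- list()
  for (r in rois) {
    names_by_num[[as.character(dcm_find(r, 0x3006, 0x0022))]] <-
      dcm_find(r, 0x3006, 0x0026)
  }
  out <- list()
  for (rc in dcm_find(ds, 0x3006, 0x0039) %||% list()) {
    num <- as.character(dcm_find(rc, 0x3006, 0x0084))
    contours <- lapply(dcm_find(rc, 0x3006, 0x0040) %||% list(), function(cs) {
      v <- dcm_find(cs, 0x3006, 0x0050)
      matrix(v, ncol = 3, byrow = TRUE)
    })
    out[[length(out) + 1L]] <- list(name = names_by_num[[num]] %||% paste0("ROI", num),
                                    contours = contours)
  }
  out
}
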
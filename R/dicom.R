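# Minimal DICOM reader, explicit-VR little-endian only, written because the
# imaging stack available to this package has no DICOM support. It covers
# exactly what an RT Plan control-point import needs: nested sequences
# (defined or undefined lengths), string/decimal value representations, and
# binary numeric VRs. It is not a general DICOM implementation.

dicom_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                      "PN", "SH", "ST", "TM", "UI", "UT")
dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# cursor over a raw vector
dicom_cursor <- function(raw) {
  env <- new.env(parent = emptyenv())
  env$raw <- raw; env$pos <- 1L
  env
}
cur_read <- function(cur, n) {
  out <- cur$raw[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}
cur_u16 <- function(cur) readBin(cur_read(cur, 2L), "integer", size = 2,
                                 endian = "little", signed = FALSE)
cur_u32 <- function(cur) {
  b <- cur_read(cur, 4L)
  sum(as.numeric(b) * c(1, 256, 65536, 16777216))
}
cur_tag <- function(cur) sprintf("%04X,%04X", cur_u16(cur), cur_u16(cur))

# parse one dataset, stopping at end_pos or at a delimiter tag
dicom_parse_dataset <- function(cur, end_pos) {
  out <- list()
  while (cur$pos < end_pos) {
    tag <- cur_tag(cur)
    if (tag %in% c("FFFE,E00D", "FFFE,E0DD")) { cur_u32(cur); break }
    vr <- rawToChar(cur_read(cur, 2L))
    if (vr %in% dicom_long_vrs) {
      cur_read(cur, 2L)  # reserved
      len <- cur_u32(cur)
    } else len <- cur_u16(cur)
    if (vr == "SQ") {
      out[[tag]] <- dicom_parse_sequence(cur, len)
    } else {
      if (len == 4294967295) stop("undefined length outside a sequence: ", tag)
      val <- cur_read(cur, len)
      out[[tag]] <- dicom_decode(val, vr)
    }
  }
  out
}

dicom_parse_sequence <- function(cur, len) {
  end_pos <- if (len == 4294967295) length(cur$raw) + 1L else cur$pos + len
  items <- list()
  while (cur$pos < end_pos) {
    tag <- cur_tag(cur)
    if (tag == "FFFE,E0DD") { cur_u32(cur); break }
    if (tag != "FFFE,E000") stop("malformed sequence: expected item, got ", tag)
    ilen <- cur_u32(cur)
    iend <- if (ilen == 4294967295) length(cur$raw) + 1L else cur$pos + ilen
    items[[length(items) + 1L]] <- dicom_parse_dataset(cur, iend)
    if (len != 4294967295 && cur$pos >= end_pos) break
  }
  items
}

dicom_decode <- function(val, vr) {
  if (length(val) == 0) return(NULL)
  if (vr %in% dicom_string_vrs) {
    s <- trimws(rawToChar(val[val != as.raw(0)]))
    if (vr %in% c("DS", "IS")) return(as.numeric(strsplit(s, "\\\\")[[1]]))
    return(s)
  }
  switch(vr,
    US = readBin(val, "integer", n = length(val) / 2, size = 2,
                 endian = "little", signed = FALSE),
    UL = readBin(val, "integer", n = length(val) / 4, size = 4,
                 endian = "little"),
    SS = readBin(val, "integer", n = length(val) / 2, size = 2,
                 endian = "little"),
    SL = readBin(val, "integer", n = length(val) / 4, size = 4,
                 endian = "little"),
    FL = readBin(val, "double", n = length(val) / 4, size = 4,
                 endian = "little"),
    FD = readBin(val, "double", n = length(val) / 8, size = 8,
                 endian = "little"),
    val)
}

#' Read control-point geometry from a DICOM-RT Plan file
#'
#' Extracts the per-control-point gantry angle, ring angle, cumulative
#' meterset weight and (when present) MLC leaf positions from an RT Plan.
#' DICOM carries no standard ring-rotation attribute for O-ring systems
#' (the vendor attribute is private), so the tag used as the ring angle is
#' configurable and defaults to PatientSupportAngle `(300A,0122)`. Angles
#' absent on later CPs are carried forward per the DICOM convention; a file
#' with no ring attribute at all loads with ring 0 and a warning. Missing
#' MLC sequences are reported as absent, never guessed. Only explicit-VR
#' little-endian files are supported.
#'
#' @param path Path to a DICOM-RT Plan file.
#' @param ring_tag Tag (`"GGGG,EEEE"`) read as the ring angle. Default
#'   `"300A,0122"`.
#' @return List with one element per beam, each a list with `cp` (data frame
#'   `gantry`, `ring`, `cumulative_meterset_weight`), `mlc` (list of
#'   left/right matrices or `NULL`) and `has_mlc`.
#' @export
read_dicom_rt_plan <- function(path, ring_tag = "300A,0122") {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  cur <- dicom_cursor(raw)
  cur$pos <- 133L
  ds <- dicom_parse_dataset(cur, length(raw) + 1L)
  if (!is.null(ds[["0008,0060"]]) && ds[["0008,0060"]] != "RTPLAN")
    stop("not an RT Plan file (Modality = ", ds[["0008,0060"]], ")")
  beams <- ds[["300A,00B0"]]
  if (is.null(beams)) stop("no BeamSequence (300A,00B0) in file")
  ring_seen <- FALSE
  out <- lapply(beams, function(beam) {
    cps <- beam[["300A,0111"]]
    if (is.null(cps)) stop("beam has no ControlPointSequence (300A,0111)")
    g <- NA_real_; r <- NA_real_
    rows <- vector("list", length(cps))
    mlc <- vector("list", length(cps))
    has_mlc <- FALSE
    for (i in seq_along(cps)) {
      item <- cps[[i]]
      if (!is.null(item[["300A,011E"]])) g <- item[["300A,011E"]][1]
      if (!is.null(item[[ring_tag]])) { r <- item[[ring_tag]][1]
                                        ring_seen <<- TRUE }
      w <- item[["300A,0134"]]
      rows[[i]] <- data.frame(
        gantry = g, ring = if (is.na(r)) 0 else r,
        cumulative_meterset_weight = if (is.null(w)) NA_real_ else w[1])
      bld <- item[["300A,011A"]]
      if (!is.null(bld)) {
        for (dev in bld) {
          if (identical(dev[["300A,00B8"]], "MLCX")) {
            pos <- dev[["300A,011C"]]
            n <- length(pos) / 2
            mlc[[i]] <- list(left = pos[1:n], right = pos[(n + 1):(2 * n)])
            has_mlc <- TRUE
          }
        }
      }
    }
    list(cp = do.call(rbind, rows), mlc = if (has_mlc) mlc else NULL,
         has_mlc = has_mlc)
  })
  if (!ring_seen)
    warning("no ring angle attribute (", ring_tag,
            ") found; ring defaults to 0 (coplanar)")
  out
}
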
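# Independent synthetic DICOM-RT Plan writer (explicit VR little endian,
# defined lengths) used to exercise the reader. Builds raw bytes directly;
# shares nothing with the package's parser.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
dcm_u32 <- function(x) {
  b <- integer(4); x <- as.numeric(x)
  for (i in 1:4) { b[i] <- x %% 256; x <- x %/% 256 }
  as.raw(b)
}
dcm_pad <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

# short-form element (string VRs used here)
dcm_el <- function(group, elem, vr, value) {
  v <- if (is.raw(value)) value else dcm_pad(value)
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), dcm_u16(length(v)), v)
}

# long-form (SQ) element with defined length
dcm_sq <- function(group, elem, items) {
  body <- do.call(c, lapply(items, function(it)
    c(dcm_u16(0xFFFE), dcm_u16(0xE000), dcm_u32(length(it)), it)))
  c(dcm_u16(group), dcm_u16(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    dcm_u32(length(body)), body)
}

dcm_ds <- function(x) paste(format(x, digits = 10, trim = TRUE),
                            collapse = "\\")

# cps: data.frame(gantry, ring, weight); mlc: list of list(left, right) in
# mm (or NULL); ring written to PatientSupportAngle by default
write_synthetic_rtplan <- function(path, cps, mlc = NULL,
                                   write_ring = TRUE) {
  items <- lapply(seq_len(nrow(cps)), function(i) {
    it <- dcm_el(0x300A, 0x011E, "DS", dcm_ds(cps$gantry[i]))
    if (write_ring)
      it <- c(it, dcm_el(0x300A, 0x0122, "DS", dcm_ds(cps$ring[i])))
    it <- c(it, dcm_el(0x300A, 0x0134, "DS", dcm_ds(cps$weight[i])))
    if (!is.null(mlc)) {
      dev <- c(dcm_el(0x300A, 0x00B8, "CS", "MLCX"),
               dcm_el(0x300A, 0x011C, "DS",
                      dcm_ds(c(mlc[[i]]$left, mlc[[i]]$right))))
      it <- c(it, dcm_sq(0x300A, 0x011A, list(dev)))
    }
    it
  })
  beam <- dcm_sq(0x300A, 0x0111, items)
  ds <- c(
    dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_el(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_sq(0x300A, 0x00B0, list(beam)))
  writeBin(c(raw(128), charToRaw("DICM"), ds), path)
  invisible(path)
}
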
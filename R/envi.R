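#' Write a datacube to ENVI format
#'
#' ENVI files are a plain-text header (`<path>.hdr`) plus a raw binary
#' payload. Supported interleaves are band-sequential (BSQ), line
#' interleaved (BIL) and pixel interleaved (BIP); int16 cubes are written
#' as ENVI data type 2 (bit-exact round trip), real cubes as type 5
#' (64-bit IEEE float).
#'
#' @param cube an `hsi_cube`.
#' @param path payload file path; the header is written to `<path>.hdr`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param byte_order 0 (little-endian, default) or 1 (big-endian).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       byte_order = 0L) {
  assert_cube(cube)
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  int16 <- cube$dtype_origin == "int16"
  hdr <- c(
    "ENVI",
    "description = { hsifuse datacube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", if (int16) 2L else 5L),
    paste0("interleave = ", interleave),
    paste0("byte order = ", as.integer(byte_order)),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  v <- flatten_interleave(cube$values, interleave)
  endian <- if (byte_order == 0L) "little" else "big"
  con <- file(path, "wb")
  on.exit(close(con))
  if (int16) writeBin(as.integer(v), con, size = 2L, endian = endian)
  else writeBin(as.double(v), con, size = 8L, endian = endian)
  invisible(path)
}

#' Read a datacube from ENVI format
#'
#' Parses the text header (`samples`, `lines`, `bands`, `data type`,
#' `interleave`, `byte order`, `wavelength`) and the raw payload. A header
#' whose declared dimensions disagree with the payload size is reported as
#' file corruption rather than silently truncated.
#'
#' @param path payload file path; header searched at `<path>.hdr` (or
#'   `path` itself if it already ends in `.hdr`).
#' @return An `hsi_cube`; int16 payloads round-trip bit-exactly.
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  dat_path <- sub("\\.hdr$", "", path)
  if (!file.exists(dat_path)) stop("ENVI payload not found: ", dat_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing required field(s): ", paste(miss, collapse = ", "))
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  il <- tolower(h[["interleave"]])
  if (!il %in% c("bsq", "bil", "bip")) stop("unsupported interleave: ", il)
  bo <- if (is.null(h[["byte order"]])) 0L else as.integer(h[["byte order"]])
  endian <- if (bo == 0L) "little" else "big"
  size <- switch(as.character(dt), "2" = 2L, "4" = 4L, "5" = 8L, "12" = 2L,
                 stop("unsupported ENVI data type: ", dt))
  n <- ns * nl * nb
  expected_bytes <- n * size
  actual_bytes <- file.size(dat_path)
  if (actual_bytes != expected_bytes)
    stop("ENVI payload size (", actual_bytes, " bytes) does not match header",
         " dimensions (", expected_bytes, " bytes expected): corrupt file")
  con <- file(dat_path, "rb")
  on.exit(close(con))
  v <- if (dt %in% c(2L, 12L))
    readBin(con, "integer", n = n, size = size, signed = dt == 2L,
            endian = endian)
  else
    readBin(con, "double", n = n, size = size, endian = endian)
  values <- unflatten_interleave(as.double(v), nl, ns, nb, il)
  wl <- if (!is.null(h[["wavelength"]]))
    as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  else NULL
  if (!is.null(wl) && length(wl) != nb)
    stop("header declares ", nb, " bands but ", length(wl), " wavelengths")
  datacube(values, wl, if (dt == 2L) "int16" else "real")
}

# key = value pairs; braced values may span lines
parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header (missing magic line)")
  out <- list()
  # match either key = { ... } (possibly multiline) or key = value

  pat <- "(?m)^([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    val <- gsub("[{}]", "", val)
    val <- gsub("\\s+", " ", trimws(val))
    out[[key]] <- val
  }
  out
}

# ENVI payloads are row-major within each ordering; R arrays are
# column-major, hence the aperm before/after flattening.
flatten_interleave <- function(values, interleave) {
  as.vector(switch(interleave,
    bsq = aperm(values, c(2, 1, 3)),  # sample fastest, then line, then band
    bil = aperm(values, c(2, 3, 1)),  # sample, band, line
    bip = aperm(values, c(3, 2, 1))   # band, sample, line
  ))
}

unflatten_interleave <- function(v, nl, ns, nb, interleave) {
  switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1))
  )
}
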
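# Minimal NRRD0004 I/O for axis-aligned scalar volumes.
#
# Covers the subset this package emits and consumes: 3D arrays, raw or gzip
# encoding, little-endian, `space directions` a diagonal matrix. The header
# grammar follows the NRRD format definition (key: value lines terminated by
# a blank line, data following inline).

nrrd_type_map <- list(
  "double" = list(what = "double", size = 8L),
  "float"  = list(what = "double", size = 4L),
  "short"  = list(what = "integer", size = 2L),
  "int"    = list(what = "integer", size = 4L),
  "signed char" = list(what = "integer", size = 1L),
  "uchar"  = list(what = "integer", size = 1L),
  "unsigned char" = list(what = "integer", size = 1L),
  "unsigned short" = list(what = "integer", size = 2L)
)

parse_nrrd_vectors <- function(s) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries -> NULL
  toks <- regmatches(s, gregexpr("\\(([^)]*)\\)|none", s))[[1]]
  lapply(toks, function(t) {
    if (t == "none") return(NULL)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) != 1L || !grepl("^NRRD000[1-9]", magic))
    stop_format(sprintf("'%s' is not an NRRD file", path))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop_format(sprintf("unexpected end of NRRD header in '%s'", path))
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) hdr[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dimension <- as.integer(hdr[["dimension"]] %||% NA)
  if (is.na(dimension) || dimension != 3L)
    stop_format(sprintf("NRRD '%s': only 3D volumes are supported", path))
  sizes <- as.integer(strsplit(hdr[["sizes"]] %||% "", "\\s+")[[1]])
  if (length(sizes) != 3L || anyNA(sizes))
    stop_metadata(sprintf("NRRD '%s': missing or invalid sizes", path))
  type <- hdr[["type"]] %||% ""
  tm <- nrrd_type_map[[type]]
  if (is.null(tm))
    stop_format(sprintf("NRRD '%s': unsupported type '%s'", path, type))
  encoding <- hdr[["encoding"]] %||% "raw"
  endian <- hdr[["endian"]] %||% "little"
  if (!endian %in% c("little"))
    stop_format(sprintf("NRRD '%s': only little-endian data supported", path))

  spacing <- NULL; origin <- c(0, 0, 0)
  if (!is.null(hdr[["space directions"]])) {
    dirs <- parse_nrrd_vectors(hdr[["space directions"]])
    dirs <- Filter(Negate(is.null), dirs)
    if (length(dirs) != 3L)
      stop_metadata(sprintf("NRRD '%s': need 3 space directions", path))
    M <- do.call(rbind, dirs)
    if (max(abs(M - diag(diag(M)))) > 1e-6 || any(diag(M) <= 0))
      stop_format(sprintf("NRRD '%s': only axis-aligned space directions supported", path))
    spacing <- diag(M)
  } else if (!is.null(hdr[["spacings"]])) {
    spacing <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])[1:3]
  }
  if (is.null(spacing) || anyNA(spacing) || any(spacing <= 0))
    stop_metadata(sprintf("NRRD '%s': missing voxel spacing metadata", path))
  if (!is.null(hdr[["space origin"]])) {
    o <- parse_nrrd_vectors(hdr[["space origin"]])[[1]]
    if (length(o) == 3L && !anyNA(o)) origin <- o
  }

  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding == "gzip" || encoding == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop_format(sprintf("NRRD '%s': unsupported encoding '%s'", path, encoding))
  }
  if (length(payload) < n * tm$size)
    stop_format(sprintf("NRRD '%s': truncated data block", path))
  vals <- readBin(payload, tm$what, n = n, size = tm$size, endian = "little",
                  signed = !grepl("^u", type))
  # NRRD stores the first axis fastest, matching R's column-major order
  list(data = array(as.numeric(vals), dim = sizes),
       spacing = spacing, origin = origin)
}

write_nrrd <- function(data, spacing, origin, path) {
  hdr <- c(
    "NRRD0004",
    "# written by canalregen",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    "space dimension: 3",
    sprintf("space directions: (%s,0,0) (0,%s,0) (0,0,%s)",
            format(spacing[1], digits = 17), format(spacing[2], digits = 17),
            format(spacing[3], digits = 17)),
    sprintf("space origin: (%s)",
            paste(format(origin, digits = 17), collapse = ",")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    ""
  )
  ok <- tryCatch({
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(memCompress(writeBin(as.numeric(data), raw(), size = 8L,
                                  endian = "little"),
                         type = "gzip"), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_io(sprintf("cannot write NRRD file '%s'", path))
  invisible(path)
}
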
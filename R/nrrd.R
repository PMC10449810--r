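# Minimal NRRD (Nearly Raw Raster Data) reader/writer for 3D volumes.
# Supports attached data, raw or gzip encoding, little-endian scalar types.
# Spacing is taken from "spacings" or diagonal "space directions"; a file
# with neither is rejected because physical units are required downstream.

nrrd_type_map <- list(
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "int8" = list(what = "integer", size = 1L, signed = TRUE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "float" = list(what = "double", size = 4L, signed = TRUE),
  "double" = list(what = "double", size = 8L, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-9]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(fields[[key]])) stop("NRRD header missing '", key, "' field")
    fields[[key]]
  }
  ndim <- as.integer(need("dimension"))
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != ndim) stop("NRRD sizes/dimension mismatch")
  typ <- nrrd_type_map[[tolower(need("type"))]]
  if (is.null(typ)) stop("unsupported NRRD type: ", fields$type)
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (is.null(spacing) || length(spacing) != ndim || any(!is.finite(spacing)))
    stop("NRRD file carries no per-axis spacing; refusing to guess physical units")
  encoding <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  n <- prod(sizes)
  raw_bytes <- readBin(con, "raw", n = file.info(path)$size)
  if (encoding %in% c("gzip", "gz")) {
    raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding)
  }
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  values <- readBin(raw_bytes, typ$what, n = n, size = typ$size,
                    signed = typ$signed, endian = endian)
  if (length(values) != n) stop("NRRD data truncated")
  list(data = array(values, dim = sizes), spacing = spacing)
}

write_nrrd <- function(data, spacing, path, type = c("double", "uint8"),
                       encoding = c("gzip", "raw")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  data <- as.array(data)
  header <- c(
    "NRRD0004",
    "# written by emphymap",
    paste0("type: ", type),
    paste0("dimension: ", length(dim(data))),
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 15), collapse = " ")),
    paste0("encoding: ", encoding),
    "endian: little",
    ""
  )
  payload <- if (type == "uint8") {
    as.raw(as.integer(data))
  } else {
    writeBin(as.numeric(data), raw(), size = 8L, endian = "little")
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}
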
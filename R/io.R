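guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  switch(ext,
         off = "off", ply = "ply",
         gii = "gifti", gifti = "gifti",
         "freesurfer")
}

#' Read a hemisphere surface mesh
#'
#' Reads OFF, PLY (ASCII or binary little-endian), GIFTI surface, or
#' FreeSurfer binary surface files into a [trimesh]. Coordinates are
#' interpreted as RAS millimetres. Non-triangular faces and truncated or
#' malformed files raise errors naming the file.
#'
#' @param path file path.
#' @param format `"off"`, `"ply"`, `"gifti"`, `"freesurfer"`, or `"auto"`
#'   (default: guessed from the extension; FreeSurfer surfaces, which have
#'   no conventional extension, are the fallback).
#' @param side hemisphere label for the resulting mesh.
#' @return a [trimesh].
#' @export
read_surface <- function(path, format = c("auto", "off", "ply", "gifti",
                                          "freesurfer"),
                         side = c("whole", "left", "right")) {
  format <- match.arg(format)
  side <- match.arg(side)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  parsed <- tryCatch(
    switch(format,
           off = read_off(path),
           ply = read_ply(path),
           gifti = read_gifti_surface(path),
           freesurfer = read_freesurfer_surface(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  trimesh(parsed$vertices, parsed$faces, side = side)
}

#' Write a hemisphere surface mesh
#'
#' Writes OFF, ASCII PLY, GIFTI (ASCII-encoded), or FreeSurfer binary
#' surface files. Inverse of [read_surface] up to floating-point
#' serialisation precision (exact for FreeSurfer/GIFTI float32 only to
#' float32 precision; OFF/PLY are written with 17 significant digits and
#' round-trip doubles exactly).
#'
#' @param mesh a [trimesh].
#' @param path output path.
#' @param format one of `"off"`, `"ply"`, `"gifti"`, `"freesurfer"`
#'   (default: guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = c("auto", "off", "ply",
                                                 "gifti", "freesurfer")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         gifti = write_gifti_surface(mesh, path),
         freesurfer = write_freesurfer_surface(mesh, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

## ---- OFF ----

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L || !grepl("^OFF", lines[[1L]]))
    stop("not an OFF file (missing OFF header)")
  counts <- scan(text = lines[[2L]], quiet = TRUE)
  if (length(counts) < 2L) stop("malformed OFF count line")
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf) stop("truncated OFF file")
  v <- scan(text = lines[3:(2L + nv)], quiet = TRUE)
  if (length(v) != 3L * nv) stop("malformed OFF vertex block")
  f <- lapply(lines[(3L + nv):(2L + nv + nf)], function(l)
    scan(text = l, quiet = TRUE))
  if (any(vapply(f, function(x) x[1L], numeric(1L)) != 3L))
    stop("non-triangular face in OFF file")
  f <- t(vapply(f, function(x) x[2:4], numeric(3L)))
  list(vertices = matrix(v, ncol = 3L, byrow = TRUE), faces = f + 1L)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(v), nrow(f), 0L)), con)
  writeLines(paste(fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L])),
             con)
  writeLines(paste(3L, f[, 1L], f[, 2L], f[, 3L]), con)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("truncated PLY header")
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (read_hline() != "ply") stop("not a PLY file")
  format <- NULL; order <- NULL
  nv <- NA_integer_; nf <- NA_integer_
  elem <- NULL
  vprops <- character(0)
  repeat {
    line <- read_hline()
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") {
      format <- tok[2L]
      order <- if (identical(format, "binary_big_endian")) "big" else "little"
    } else if (tok[1L] == "element") {
      elem <- tok[2L]
      if (elem == "vertex") nv <- as.integer(tok[3L])
      if (elem == "face") nf <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && identical(elem, "vertex")) {
      vprops <- c(vprops, tok[length(tok)])
    } else if (tok[1L] == "end_header") break
  }
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face elements")
  if (!all(c("x", "y", "z") %in% vprops))
    stop("PLY vertex element lacks x/y/z properties")
  if (format == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nv + nf) stop("truncated PLY body")
    v <- scan(text = txt[seq_len(nv)], quiet = TRUE)
    v <- matrix(v, ncol = length(vprops), byrow = TRUE)
    colnames(v) <- vprops
    f <- lapply(txt[nv + seq_len(nf)], function(l) scan(text = l,
                                                        quiet = TRUE))
    if (any(vapply(f, function(x) x[1L], numeric(1L)) != 3L))
      stop("non-triangular face in PLY file")
    f <- t(vapply(f, function(x) x[2:4], numeric(3L)))
  } else {
    v <- matrix(NA_real_, nv, length(vprops))
    for (i in seq_len(nv))
      v[i, ] <- readBin(con, "numeric", length(vprops), size = 4L,
                        endian = order)
    colnames(v) <- vprops
    f <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      if (length(k) == 0L) stop("truncated PLY body")
      if (k != 3L) stop("non-triangular face in PLY file")
      f[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = order)
    }
    if (anyNA(v) || anyNA(f)) stop("truncated PLY body")
  }
  list(vertices = unname(v[, c("x", "y", "z"), drop = FALSE]),
       faces = f + 1L)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y",
               "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L])),
             con)
  writeLines(paste(3L, f[, 1L], f[, 2L], f[, 3L]), con)
}

## ---- FreeSurfer binary surface ----

read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (length(magic) < 3L ||
      !identical(magic, c(255L, 255L, 254L)))
    stop("not a FreeSurfer triangle surface (bad magic)")
  # comment line terminated by '\n', followed by a second '\n'
  nl <- 0L
  while (nl < 2L) {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer header")
    if (b == as.raw(10L)) nl <- nl + 1L else nl <- 0L
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (length(nv) == 0L || length(nf) == 0L || nv < 3L || nf < 1L)
    stop("truncated FreeSurfer header")
  v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  if (length(v) != 3L * nv || length(f) != 3L * nf)
    stop("truncated FreeSurfer body")
  list(vertices = matrix(v, ncol = 3L, byrow = TRUE),
       faces = matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

write_freesurfer_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeBin(charToRaw("created by braintorque\n\n"), con)
  writeBin(nrow(mesh$vertices), con, size = 4L, endian = "big")
  writeBin(nrow(mesh$faces), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
}

## ---- GIFTI surface ----

decode_gifti_data <- function(node, n, what) {
  enc <- xml2::xml_attr(node, "Encoding")
  endian <- xml2::xml_attr(node, "Endian")
  endian <- if (identical(endian, "BigEndian")) "big" else "little"
  dtype <- xml2::xml_attr(node, "DataType")
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary"))
      raw <- memDecompress(raw, type = "gzip")
    vals <- if (grepl("FLOAT", dtype))
      readBin(raw, "numeric", n, size = 4L, endian = endian)
    else readBin(raw, "integer", n, size = 4L, endian = endian)
  }
  if (length(vals) != n) stop("GIFTI ", what, " data truncated")
  vals
}

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L) stop("no DataArray elements")
  get_array <- function(intent, what) {
    hit <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (length(hit) == 0L) stop("GIFTI file lacks ", what, " array")
    hit[[1L]]
  }
  pts <- get_array("NIFTI_INTENT_POINTSET", "pointset")
  tri <- get_array("NIFTI_INTENT_TRIANGLE", "triangle")
  dim1 <- function(node) as.integer(xml2::xml_attr(node, "Dim0"))
  npt <- dim1(pts); ntr <- dim1(tri)
  v <- decode_gifti_data(pts, 3L * npt, "pointset")
  f <- decode_gifti_data(tri, 3L * ntr, "triangle")
  ord <- xml2::xml_attr(pts, "ArrayIndexingOrder")
  byrow <- !identical(ord, "ColumnMajorOrder")
  list(vertices = matrix(v, ncol = 3L, byrow = byrow),
       faces = matrix(as.integer(f), ncol = 3L, byrow = byrow) + 1L)
}

write_gifti_surface <- function(mesh, path) {
  array_xml <- function(intent, dtype, n, values) {
    paste0(
      '<DataArray Intent="', intent, '" DataType="', dtype,
      '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', n,
      '" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n<Data>',
      paste(values, collapse = " "),
      "</Data>\n</DataArray>")
  }
  v <- t(mesh$vertices)
  f <- t(mesh$faces - 1L)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    array_xml("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
              nrow(mesh$vertices), fmt_num(as.numeric(v))), "\n",
    array_xml("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
              nrow(mesh$faces), as.integer(f)), "\n</GIFTI>\n")
  writeLines(xml, path)
}

## ---- record tables ----

record_columns <- function() {
  c("subject_id", "species", "sex",
    "length_left", "length_right", "length_whole",
    "height_left", "height_right", "height_whole",
    "width_left", "width_right", "width_whole",
    "ratio_length_width", "ratio_height_width",
    "dL", "dH", "dW",
    "petalia_frontal", "petalia_occipital",
    "shift_frontal", "shift_occipital",
    "bending_frontal", "bending_occipital",
    "config_petalia", "config_shift", "config_bending", "config_tie")
}

#' Write torque records to CSV (+ full-precision JSON sidecar)
#'
#' Writes a cohort of measurements as a CSV with a stable column order,
#' numeric values rounded to the configured number of decimals (rounding
#' happens only here; full precision is kept in memory and in the JSON
#' sidecar `<path>.json`, which also records the pipeline configuration and
#' package version for provenance).
#'
#' @param records a cohort tibble ([measure_cohort]), a single
#'   `torque_record`, or a list of them.
#' @param path output CSV path.
#' @param config the [torque_config] that produced the records.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, config = torque_config()) {
  if (inherits(records, "torque_record")) records <- list(records)
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  records <- records[, record_columns()]
  rounded <- records
  num <- vapply(rounded, is.numeric, logical(1L))
  rounded[num] <- lapply(rounded[num], round, digits = config$rounding)
  utils::write.csv(rounded, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(records = records,
                  config = unclass(config),
                  package = "braintorque",
                  version = as.character(utils::packageVersion("braintorque")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a torque-record CSV
#'
#' @param path CSV path written by [write_records] (or `<path>.json` is
#'   consulted for full precision when `full_precision = TRUE` and the
#'   sidecar exists).
#' @param full_precision read from the JSON sidecar when available.
#' @return tibble of records.
#' @export
read_records <- function(path, full_precision = FALSE) {
  sidecar <- paste0(path, ".json")
  if (full_precision && file.exists(sidecar)) {
    out <- jsonlite::fromJSON(sidecar)$records
    return(tibble::as_tibble(out))
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
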
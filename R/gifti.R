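# Minimal GIFTI reader/writer (xml2 + base64). Covers the subset used here:
# float32/int32 data arrays, Base64Binary and GZipBase64Binary encodings,
# little-endian, row-major. Geometry (.surf.gii: POINTSET + TRIANGLE) and
# per-vertex functional data (.func.gii: one data array per map/timepoint).

gifti_datatype <- function(x) {
  switch(x,
         "NIFTI_TYPE_FLOAT32" = list(what = "numeric", size = 4L),
         "NIFTI_TYPE_FLOAT64" = list(what = "numeric", size = 8L),
         "NIFTI_TYPE_INT32" = list(what = "integer", size = 4L),
         stop("unsupported GIFTI DataType: ", x))
}

decode_gifti_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- gifti_datatype(xml2::xml_attr(node, "DataType"))
  dims <- vapply(paste0("Dim", 0:5),
                 function(a) suppressWarnings(as.integer(xml2::xml_attr(node, a))),
                 integer(1))
  dims <- dims[!is.na(dims)]
  ntot <- prod(dims)
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//d1:Data|.//Data"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  if (identical(enc, "GZipBase64Binary")) {
    raw <- memDecompress(raw, type = "gzip")
  } else if (!identical(enc, "Base64Binary")) {
    stop("unsupported GIFTI Encoding: ", enc)
  }
  endian <- xml2::xml_attr(node, "Endian")
  endian <- if (identical(endian, "BigEndian")) "big" else "little"
  vals <- readBin(raw, what = dtype$what, n = ntot, size = dtype$size,
                  endian = endian)
  if (length(vals) != ntot) stop("GIFTI data array is truncated")
  if (length(dims) == 2L) {
    # RowMajorOrder on disk
    vals <- matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  }
  list(intent = xml2::xml_attr(node, "Intent"), values = vals, dims = dims,
       meta = gifti_metadata(node))
}

gifti_metadata <- function(node) {
  md <- xml2::xml_find_all(node, "./d1:MetaData/d1:MD|./MetaData/MD")
  out <- list()
  for (m in md) {
    nm <- xml2::xml_text(xml2::xml_find_first(m, "./d1:Name|./Name"))
    out[[nm]] <- xml2::xml_text(xml2::xml_find_first(m, "./d1:Value|./Value"))
  }
  out
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//d1:DataArray|//DataArray")
  if (length(nodes) == 0L) stop("no DataArray elements in GIFTI file: ", path)
  lapply(nodes, decode_gifti_array)
}

encode_gifti_payload <- function(values, what, size) {
  if (what == "numeric") values <- as.numeric(values) else values <- as.integer(values)
  jsonlite::base64_enc(writeBin(values, raw(), size = size, endian = "little"))
}

gifti_array_node <- function(values, intent, datatype, meta = NULL) {
  dt <- gifti_datatype(datatype)
  if (is.matrix(values)) {
    dims <- dim(values)
    flat <- as.vector(t(values)) # row-major on disk
  } else {
    dims <- length(values)
    flat <- as.vector(values)
  }
  attrs <- c(
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)))
  for (i in seq_along(dims)) {
    attrs[paste0("Dim", i - 1L)] <- as.character(dims[i])
  }
  attrs <- c(attrs, Encoding = "Base64Binary", Endian = "LittleEndian",
             ExternalFileName = "", ExternalFileOffset = "")
  meta_xml <- ""
  if (length(meta)) {
    mds <- vapply(names(meta), function(nm) {
      sprintf("<MD><Name><![CDATA[%s]]></Name><Value><![CDATA[%s]]></Value></MD>",
              nm, meta[[nm]])
    }, character(1))
    meta_xml <- paste0("<MetaData>", paste(mds, collapse = ""), "</MetaData>")
  }
  payload <- encode_gifti_payload(flat, dt$what, dt$size)
  paste0("<DataArray ",
         paste(sprintf('%s="%s"', names(attrs), attrs), collapse = " "), ">",
         meta_xml, "<Data>", payload, "</Data></DataArray>")
}

write_gifti_document <- function(array_xml, path) {
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns="http://www.nitrc.org/frs/download.php/1594/gifti.xsd" ',
    'Version="1.0" NumberOfDataArrays="', length(array_xml), '">',
    paste(array_xml, collapse = ""), "</GIFTI>\n")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Write a surface mesh as GIFTI geometry (.surf.gii)
#'
#' @param mesh `surface_mesh`.
#' @param path output path.
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  arrays <- c(
    gifti_array_node(mesh$vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
    gifti_array_node(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32"))
  write_gifti_document(arrays, path)
}

#' Read a GIFTI geometry file (.surf.gii)
#'
#' @param path file path.
#' @return `surface_mesh`.
#' @export
read_gifti_surface <- function(path) {
  arrays <- read_gifti_arrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  pv <- which(intents == "NIFTI_INTENT_POINTSET")
  tv <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(pv) != 1L || length(tv) != 1L) {
    stop("GIFTI surface needs exactly one POINTSET and one TRIANGLE array")
  }
  surface_mesh(arrays[[pv]]$values, arrays[[tv]]$values + 1L)
}

# functional data (vertex_map or vertex_series) -> .func.gii
write_gifti_data <- function(x, path) {
  if (inherits(x, "vertex_map")) {
    arrays <- gifti_array_node(x$values, "NIFTI_INTENT_NONE",
                               "NIFTI_TYPE_FLOAT32",
                               meta = list(Name = x$kind, sedconnKind = x$kind))
  } else if (inherits(x, "vertex_series")) {
    arrays <- vapply(seq_len(x$n_timepoints), function(t) {
      meta <- if (t == 1L) list(TimeStep = format(x$dt, digits = 17)) else NULL
      gifti_array_node(x$data[, t], "NIFTI_INTENT_TIME_SERIES",
                       "NIFTI_TYPE_FLOAT32", meta = meta)
    }, character(1))
  } else {
    stop("x must be a vertex_map or vertex_series")
  }
  write_gifti_document(arrays, path)
}

read_gifti_data <- function(path) {
  arrays <- read_gifti_arrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  if (length(arrays) == 1L && intents[1L] != "NIFTI_INTENT_TIME_SERIES") {
    a <- arrays[[1L]]
    kind <- a$meta$sedconnKind
    if (is.null(kind)) kind <- "zmap"
    return(vertex_map(a$values, kind))
  }
  n <- length(arrays[[1L]]$values)
  if (!all(vapply(arrays, function(a) length(a$values), integer(1)) == n)) {
    stop("GIFTI time-series arrays have inconsistent vertex counts")
  }
  dt <- arrays[[1L]]$meta$TimeStep
  if (is.null(dt)) {
    warning("GIFTI series has no TimeStep metadata; assuming dt = 1 s")
    dt <- 1
  }
  data <- vapply(arrays, `[[`, numeric(n), "values")
  vertex_series(data, as.numeric(dt))
}
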
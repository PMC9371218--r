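manifest_columns <- c("slice_id", "region_label", "quality_label",
                      "image_path")

check_manifest <- function(manifest) {
  if (!is.data.frame(manifest)) {
    stop("manifest must be a data.frame", call. = FALSE)
  }
  miss <- setdiff(c("slice_id", "quality_label"), names(manifest))
  if (length(miss) > 0L) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(manifest)
}

#' Read and validate a dataset manifest
#'
#' Reads a CSV with header `slice_id,region_label,quality_label,image_path`,
#' preserving row order and validating that slice ids are unique, quality
#' labels are binary, and region labels are positive integers. Schema errors
#' name the offending row.
#'
#' @param path Path to the manifest CSV.
#' @return A `data.frame` with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest file '%s' does not exist", path), call. = FALSE)
  }
  man <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse manifest '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  miss <- setdiff(manifest_columns, names(man))
  if (length(miss) > 0L) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(man) == 0L) stop("manifest has no records", call. = FALSE)
  if (anyDuplicated(man$slice_id)) {
    row <- which(duplicated(man$slice_id))[1]
    stop(sprintf("duplicate slice_id '%s' at manifest row %d",
                 man$slice_id[row], row), call. = FALSE)
  }
  q <- suppressWarnings(as.integer(man$quality_label))
  bad <- which(is.na(q) | !(q %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop(sprintf("non-binary quality_label '%s' at manifest row %d",
                 man$quality_label[bad[1]], bad[1]), call. = FALSE)
  }
  r <- suppressWarnings(as.integer(man$region_label))
  bad <- which(is.na(r) | r < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("invalid region_label '%s' at manifest row %d",
                 man$region_label[bad[1]], bad[1]), call. = FALSE)
  }
  data.frame(slice_id = man$slice_id, region_label = r, quality_label = q,
             image_path = man$image_path, stringsAsFactors = FALSE)
}

#' Write a dataset manifest
#'
#' @param manifest Manifest `data.frame`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  utils::write.csv(manifest[, manifest_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a grayscale slice from PNG or TIFF
#'
#' Pixel values are mapped to the integer 0--255 scale. Multi-channel images
#' are collapsed by channel averaging.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    arr <- apply(arr, c(1, 2), mean)
  }
  quantize_gray(arr * 255)
}

#' Write a grayscale slice as 8-bit PNG
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @param path Output `.png` path.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Graph serialization
#'
#' Writes/reads a graph either as GraphML (via igraph) or as a plain-text
#' edge list that also records isolated vertices, so both formats round-trip
#' the vertex and edge sets losslessly. The edge-list format is
#' line-oriented: a header line, one `v <name>` line per vertex, one
#' `e <name1> <name2>` line per edge.
#'
#' @param graph An [igraph::igraph] graph with named vertices.
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `read_graph_file()` returns an [igraph::igraph] graph;
#'   `write_graph_file()` returns `path` invisibly.
#' @name graph_io
#' @export
write_graph_file <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    lines <- c("ctnet-edgelist v1",
               paste("v", nm),
               if (nrow(el) > 0L) paste("e", el[, 1], el[, 2]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname graph_io
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("graph file '%s' does not exist", path), call. = FALSE)
  }
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "ctnet-edgelist v1") {
    stop("not a ctnet edge-list file", call. = FALSE)
  }
  lines <- lines[-1]
  vlines <- lines[startsWith(lines, "v ")]
  elines <- lines[startsWith(lines, "e ")]
  verts <- sub("^v ", "", vlines)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (length(elines) > 0L) {
    parts <- strsplit(sub("^e ", "", elines), " ", fixed = TRUE)
    ends <- t(vapply(parts, function(p) p[1:2], character(2)))
    g <- igraph::add_edges(g, rbind(match(ends[, 1], verts),
                                    match(ends[, 2], verts)))
  }
  g
}

#' Read a flat key-value run configuration
#'
#' Parses `key = value` lines (`#` comments and blank lines ignored), with
#' numeric and logical coercion where unambiguous. CLI flags override file
#' values.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else {
      val
    }
  }
  out
}
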
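#' Read a surface mesh (PLY or OFF)
#'
#' Dispatches on the file extension: ASCII PLY (with an optional
#' per-vertex `altitude` property) or OFF. Coordinates are millimetres.
#'
#' @param path File path ending in `.ply` or `.off`.
#' @return A [surface_mesh].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop_hinge("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         off = read_off(path),
         stop_hinge("unsupported surface format: .", ext))
}

#' Write a surface mesh (PLY or OFF)
#' @param mesh A [surface_mesh].
#' @param path Output path ending in `.ply` or `.off` (altitude is only
#'   preserved by PLY).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stop_hinge("unsupported surface format: .", ext))
  invisible(path)
}

write_ply <- function(mesh, path) {
  nv <- n_vertices(mesh)
  nf <- n_faces(mesh)
  has_alt <- !is.null(mesh$altitude)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (has_alt) "property float altitude",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vmat <- if (has_alt) cbind(mesh$vertices, mesh$altitude) else mesh$vertices
  vlines <- apply(vmat, 1, function(r) paste(format(r, digits = 17),
                                             collapse = " "))
  flines <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r),
                                                        collapse = " "))
  writeLines(c(hdr, vlines, flines), path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply") {
    stop_hinge("malformed PLY (line 1): missing 'ply' magic in ", path)
  }
  end <- match("end_header", lines)
  if (is.na(end)) stop_hinge("malformed PLY: no end_header in ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  vprops <- grep("^property (float|double) ", hdr, value = TRUE)
  pnames <- sub("^property (float|double) ", "", vprops)
  if (length(nv) != 1L || length(nf) != 1L) {
    stop_hinge("malformed PLY header in ", path)
  }
  if (end + nv + nf > length(lines)) {
    stop_hinge("truncated PLY: expected ", nv + nf, " body lines in ", path)
  }
  vbody <- lines[end + seq_len(nv)]
  vmat <- matrix(as.numeric(unlist(strsplit(trimws(vbody), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  if (ncol(vmat) != length(pnames)) {
    stop_hinge("malformed PLY vertex rows (expected ", length(pnames),
               " values per line) in ", path)
  }
  fbody <- lines[end + nv + seq_len(nf)]
  fmat <- if (nf > 0) {
    m <- matrix(as.integer(unlist(strsplit(trimws(fbody), "\\s+"))),
                nrow = nf, byrow = TRUE)
    if (any(m[, 1] != 3L)) stop_hinge("non-triangular face in ", path)
    m[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(0), 0, 3)
  alt <- if ("altitude" %in% pnames) vmat[, match("altitude", pnames)]
  surface_mesh(vmat[, 1:3, drop = FALSE], fmat, altitude = alt)
}

write_off <- function(mesh, path) {
  vlines <- apply(mesh$vertices, 1,
                  function(r) paste(format(r, digits = 17), collapse = " "))
  flines <- apply(mesh$faces - 1L, 1,
                  function(r) paste(c(3L, r), collapse = " "))
  writeLines(c("OFF", sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)),
               vlines, flines), path)
}

read_off <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || trimws(lines[1]) != "OFF") {
    stop_hinge("malformed OFF (line 1) in ", path)
  }
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  nf <- counts[2]
  if (2 + nv + nf > length(lines)) stop_hinge("truncated OFF file ", path)
  vmat <- matrix(as.numeric(unlist(strsplit(trimws(lines[2 + seq_len(nv)]),
                                            "\\s+"))),
                 nrow = nv, byrow = TRUE)
  fmat <- if (nf > 0) {
    m <- matrix(as.integer(unlist(strsplit(trimws(lines[2 + nv + seq_len(nf)]),
                                           "\\s+"))),
                nrow = nf, byrow = TRUE)
    m[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(0), 0, 3)
  surface_mesh(vmat[, 1:3, drop = FALSE], fmat)
}

#' Write a per-vertex scalar field as one-column text
#' @param values Numeric per-vertex vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vertex_scalar <- function(values, path) {
  writeLines(format(values, digits = 17), path)
  invisible(path)
}

#' Read a per-vertex scalar field from one-column text
#' @param path File path.
#' @return Numeric vector.
#' @export
read_vertex_scalar <- function(path) as.numeric(readLines(path))

#' Write streamlines in TCK format
#'
#' MRtrix track format: ASCII header, then little-endian float32 point
#' triples with NaN-triple separators and an Inf-triple terminator.
#'
#' @param streamlines A `streamline_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  body_parts <- lapply(streamlines$polylines, function(p) {
    c(as.vector(t(p)), rep(NaN, 3))
  })
  body <- c(unlist(body_parts), rep(Inf, 3))
  hdr0 <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 streamlines$total_count, "\nfile: . ")
  off <- nchar(hdr0) + 16          # room for the offset digits and END
  hdr_full <- paste0(hdr0, off, "\nEND\n")
  stopifnot(nchar(hdr_full) <= off)
  writeBin(charToRaw(hdr_full), con)
  seek(con, off)
  writeBin(body, con, size = 4, endian = "little")
  invisible(path)
}

#' Read streamlines from TCK format
#' @param path File path.
#' @return A `streamline_set`.
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop_hinge("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0L) stop_hinge("malformed TCK: no END in header of ",
                                        path)
  hdr <- rawToChar(raw[1:(hdr_end + 3)])
  if (!startsWith(hdr, "mrtrix tracks")) {
    stop_hinge("malformed TCK (byte 1): missing magic in ", path)
  }
  off_line <- regmatches(hdr, regexpr("file: \\. [0-9]+", hdr))
  if (length(off_line) == 0L) stop_hinge("malformed TCK: no file offset in ",
                                         path)
  off <- as.integer(sub("file: \\. ", "", off_line))
  n_float <- (length(raw) - off) %/% 4
  vals <- readBin(raw[(off + 1):length(raw)], "numeric", n = n_float,
                  size = 4, endian = "little")
  if (length(vals) %% 3 != 0) {
    stop_hinge("truncated TCK body (byte ", off + length(vals) * 4,
               ") in ", path)
  }
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  if (!any(is_end) || !is_end[nrow(pts)]) {
    stop_hinge("truncated TCK: missing end-of-file triple in ", path)
  }
  last <- which(is_end)[1]
  breaks <- c(0L, which(is_sep[seq_len(last - 1)]), last)
  polys <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    rows <- (breaks[b] + 1L):(breaks[b + 1L] - 1L)
    if (length(rows) >= 1 && rows[1] <= rows[length(rows)]) {
      seg <- pts[rows, , drop = FALSE]
      if (nrow(seg) >= 2) polys[[length(polys) + 1L]] <- seg
    }
  }
  streamline_set(polys)
}

#' Read a connectivity matrix (dense CSV or edge-list CSV)
#'
#' Edge lists need columns `i`, `j`, `weight`; anything else is read as
#' a dense square matrix with or without header.
#'
#' @param path File path.
#' @param n_nodes Node count (required for edge lists, optional
#'   otherwise).
#' @return A [weighted_network].
#' @export
read_matrix <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop_hinge("file not found: ", path)
  first <- readLines(path, n = 1)
  if (grepl("^\\s*\"?i\"?\\s*,", first)) {
    df <- read.csv(path)
    if (!all(c("i", "j", "weight") %in% names(df))) {
      stop_hinge("edge list needs columns i, j, weight: ", path)
    }
    n <- n_nodes %||% max(df$i, df$j)
    W <- matrix(0, n, n)
    W[cbind(df$i, df$j)] <- df$weight
    W[cbind(df$j, df$i)] <- df$weight
    weighted_network(W)
  } else {
    has_header <- grepl("[A-Za-z]", first)
    M <- as.matrix(read.csv(path, header = has_header))
    dimnames(M) <- NULL
    weighted_network(M)
  }
}

#' Write a network as a dense CSV matrix
#' @param net A [weighted_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(net, path) {
  write.table(net$weights, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a network as a sparse edge-list CSV (i, j, weight; i < j)
#' @param net A [weighted_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   weight = net$weights[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a crest graph (nodes, edges, hinges) as JSON
#' @param crest A `crest_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crest_graph <- function(crest, path) {
  obj <- list(
    nodes = crest$nodes,
    edges = crest$edges,
    hinges = as.list(crest$hinges),
    length_threshold = crest$length_threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a crest graph written by [write_crest_graph()]
#' @param path File path.
#' @return A `crest_graph` (without the segmentation attachment).
#' @export
read_crest_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(nodes = as.integer(obj$nodes),
         edges = matrix(as.integer(obj$edges), ncol = 2),
         hinges = as_tibble(obj$hinges),
         length_threshold = obj$length_threshold),
    class = "crest_graph"
  )
}
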
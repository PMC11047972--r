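# Readers and writers: SWC, 3D TIFF stacks, Vaa3D-style marker files,
# flat YAML configs, JSON reports and the annotated outputs.

#' Read an SWC reconstruction
#'
#' Seven whitespace-separated columns (id, type, x, y, z, radius, parent),
#' `#` comments; unsorted ids and forward references are tolerated.
#'
#' @param path file path
#' @return a `neuron_tree`
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) .nc_stop("nc_input_error", "no such file: %s", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  keep <- nzchar(ln)
  if (!any(keep)) .nc_stop("nc_parse_error", "empty SWC file: %s", path)
  lineno <- which(keep)
  fields <- strsplit(ln[keep], "[ \t,]+")
  bad <- which(lengths(fields) < 7L)
  if (length(bad))
    .nc_stop("nc_parse_error", "%s: line %d has fewer than 7 fields",
             path, lineno[bad[1]])
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:7])))
  if (anyNA(m))
    .nc_stop("nc_parse_error", "%s: non-numeric field near line %d",
             path, lineno[which(rowSums(is.na(m)) > 0)[1]])
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  dup <- which(duplicated(nodes$id))
  if (length(dup))
    .nc_stop("nc_parse_error", "%s: duplicate id %d at line %d",
             path, nodes$id[dup[1]], lineno[dup[1]])
  tryCatch(neuron_tree(nodes),
           nc_structural_error = function(e)
             .nc_stop("nc_parse_error", "%s: %s", path, conditionMessage(e)))
}

#' Write an SWC reconstruction
#'
#' @param tree a `neuron_tree`
#' @param path output path
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  ln <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# id type x y z radius parent", ln), path)
  invisible(path)
}

#' Read a 3D TIFF stack as an image volume
#'
#' 8- or 16-bit grayscale stacks; the result is indexed `(z, y, x)` and
#' `dtype_max` records the full-scale value.
#'
#' @param path TIFF path
#' @return an `image_volume`
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) .nc_stop("nc_input_error", "no such file: %s", path)
  sl <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(sl)) sl <- list(sl)
  if (length(sl) < 2L)
    .nc_stop("nc_format_error", "%s: expected a 3D stack, got %d slice(s)",
             path, length(sl))
  if (length(dim(sl[[1]])) != 2L)
    .nc_stop("nc_format_error", "%s: RGB/multichannel input not supported",
             path)
  bps <- attr(sl[[1]], "bits.per.sample") %||% if (max(unlist(sl)) > 255) 16 else 8
  nz <- length(sl); ny <- nrow(sl[[1]]); nx <- ncol(sl[[1]])
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- sl[[z]]
  image_volume(arr, if (bps >= 16) 65535 else 255)
}

#' Write an image volume as a 3D TIFF stack
#'
#' @param vol an `image_volume`
#' @param path output path
#' @param bits 8 or 16
#' @export
write_volume <- function(vol, path, bits = if (vol$dtype_max > 255) 16 else 8) {
  full <- if (bits >= 16) 65535 else 255
  d <- dim(vol$data)
  sl <- lapply(seq_len(d[1]), function(z)
    matrix(vol$data[z, , ] / full, d[2], d[3]))
  tiff::writeTIFF(sl, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Read a soma marker (Vaa3D marker CSV dialect)
#'
#' Columns `x, y, z[, radius, ...]`, 0-based coordinates, `#` comments.
#' A missing radius defaults to 5.
#'
#' @param path marker file
#' @return list `x`, `y`, `z`, `radius`
#' @export
read_marker <- function(path) {
  if (!file.exists(path)) .nc_stop("nc_input_error", "no such file: %s", path)
  ln <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) .nc_stop("nc_parse_error", "empty marker file: %s", path)
  f <- strsplit(ln[1], ",")[[1]]
  f <- suppressWarnings(as.numeric(f[seq_len(min(4, length(f)))]))
  if (length(f) < 3L || anyNA(f[1:3]))
    .nc_stop("nc_parse_error", "%s: need at least x,y,z", path)
  list(x = f[1], y = f[2], z = f[3],
       radius = if (length(f) >= 4 && !is.na(f[4]) && f[4] > 0) f[4] else 5)
}

#' Write a marker file (Vaa3D marker CSV dialect)
#'
#' @param xyz numeric matrix n x 3 (0-based voxel coordinates)
#' @param path output path
#' @param radius,name marker attributes
#' @export
write_marker <- function(xyz, path, radius = 2, name = "hint") {
  xyz <- matrix(xyz, ncol = 3)
  hdr <- "#x,y,z,radius,shape,name,comment"
  ln <- sprintf("%.3f,%.3f,%.3f,%g,1,%s,", xyz[, 1], xyz[, 2], xyz[, 3],
                radius, name)
  writeLines(c(hdr, ln), path)
  invisible(path)
}

#' Read / write a flat run configuration
#'
#' A flat YAML map of parameter name to value; round-trips losslessly.
#' @param path config path
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .nc_stop("nc_config_error", "no such file: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) .nc_stop("nc_config_error", "%s: expected a flat map", path)
  cfg
}

#' @rdname read_config
#' @param cfg named list
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Artifact label -> SWC structure type code (Vaa3D-style color conventions):
# 255 white = high confidence, 256 fuchsine = confirmed, 260 red =
# over-tracing, 261 yellow = branch-skeleton error, 262 blue = branch-branch
# error, 263 green = branch-missing host, 264 = low confidence.
label_type_codes <- c(NONE = 255L, CONFIRMED = 256L, OVER_TRACING = 260L,
                      CONN_ERR_BRANCH_SKELETON = 261L,
                      CONN_ERR_BRANCH_BRANCH = 262L,
                      BRANCH_MISSING = 263L, LOW_CONFIDENCE = 264L,
                      INCOMPLETE_TRACING = 255L)

#' Write the annotated outputs of a detection pass
#'
#' Produces `<prefix>_annotated.swc` (type codes encode the artifact
#' labels), `<prefix>_skeleton.swc` (candidate skeleton branches as
#' disconnected chains), `<prefix>_incomplete.marker` (positions of
#' incomplete tracing) and `<prefix>_report.json`.
#'
#' @param report an `artifact_report` from [classify_branches()]
#' @param prefix output path prefix
#' @return named character vector of the files written, invisibly
#' @export
write_outputs <- function(report, prefix) {
  ctx <- report$ctx
  tree <- ctx$tree
  nd <- tree$nodes
  nd$type <- 255L
  for (i in seq_len(nrow(report$branches))) {
    code <- label_type_codes[[report$branches$label[i]]]
    own <- ctx$branches[[i]]$node_path[-1]
    nd$type[nd$id %in% own] <- code
  }
  ann <- paste0(prefix, "_annotated.swc")
  write_swc(neuron_tree(nd, validate = FALSE), ann)

  skp <- paste0(prefix, "_skeleton.swc")
  rows <- list()
  nid <- 1L
  for (sk in ctx$skeleton) {
    ch <- sk$chain_xyz
    for (i in seq_len(nrow(ch))) {
      rows[[length(rows) + 1L]] <-
        sprintf("%d 257 %.3f %.3f %.3f 1 %d", nid, ch[i, 1], ch[i, 2],
                ch[i, 3], if (i == 1L) -1L else nid - 1L)
      nid <- nid + 1L
    }
  }
  writeLines(c("# candidate skeleton branches", unlist(rows)), skp)

  mk <- paste0(prefix, "_incomplete.marker")
  inc <- which(report$branches$label == "INCOMPLETE_TRACING")
  pos <- matrix(numeric(0), 0, 3)
  for (i in inc) {
    tip <- tail(ctx$branches[[i]]$node_path, 1)
    pos <- rbind(pos, node_xyz(tree, tip))
  }
  write_marker(pos, mk, name = "incomplete-tracing")

  js <- paste0(prefix, "_report.json")
  payload <- list(branches = report$branches, skeletons = report$skeletons)
  jsonlite::write_json(payload, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(annotated = ann, skeleton = skp, marker = mk, report = js))
}

#' Read user-confirmed branch ids
#'
#' One branch id per line, `#` comments.
#' @param path annotation file
#' @export
read_confirmed <- function(path) {
  if (is.null(path)) return(integer(0))
  if (!file.exists(path)) .nc_stop("nc_input_error", "no such file: %s", path)
  ln <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  as.integer(ln[nzchar(ln)])
}
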
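.schema_version <- "1"

#' Save and load measurement matrices as JSON
#'
#' The JSON document carries the structure parameters, the selection list,
#' the target sparsity, the achieved injectivity number and the seed, plus
#' a schema version; the binary matrix is rebuilt from the selection on
#' load and re-validated against the block constraint.
#'
#' @param design A `design_result` (or a `group_matrix` with attached
#'   selection).
#' @param path Output path (`.json`).
#' @param dense_csv Optional path: also export the assembled block-diagonal
#'   matrix as a dense 0/1 CSV.
#' @return `path`, invisibly.
#' @export
write_matrix_json <- function(design, path, dense_csv = NULL) {
  if (inherits(design, "group_matrix")) {
    st <- attr(design, "structure")
    doc <- list(selection = attr(design, "selection"), s = NA, sin = NA,
                seed = NA)
  } else {
    stopifnot(inherits(design, "design_result"))
    st <- design$structure
    doc <- list(selection = design$best_selection, s = design$s,
                sin = design$best_sin, seed = design$seed)
  }
  doc <- c(list(schema_version = .schema_version,
                block_size = st$block_size,
                blocks_per_group = st$blocks_per_group,
                num_groups = st$num_groups, m0 = st$m0), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  if (!is.null(dense_csv)) {
    A <- assemble_block_diagonal(
      make_cs_matrix(doc$selection, st))
    utils::write.table(unclass(A), dense_csv, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix_json
#' @return `read_matrix_json()`: a list with `structure` ([cs_structure()]),
#'   `selection`, `matrix` (validated `group_matrix`), `s`, `sin`, `seed`.
#' @export
read_matrix_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(doc$schema_version), .schema_version)) {
    stop("unsupported matrix schema version: ", doc$schema_version,
         call. = FALSE)
  }
  st <- cs_structure(doc$block_size, doc$blocks_per_group, doc$num_groups,
                     doc$m0)
  sel <- matrix(as.integer(doc$selection), st$m0, st$blocks_per_group)
  M <- make_cs_matrix(sel, st)   # validates; names row/block on failure
  list(structure = st, selection = sel, matrix = M,
       s = doc$s, sin = doc$sin, seed = doc$seed)
}

#' Save and load disk phantoms as JSON
#'
#' @param phantom A [disk_phantom()].
#' @param path Output path (`.json`).
#' @return `path` invisibly; `read_phantom_json()` returns the phantom.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "disk_phantom"))
  doc <- list(schema_version = .schema_version, R = attr(phantom, "R"),
              disks = as.data.frame(phantom))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(doc$schema_version), .schema_version)) {
    stop("unsupported phantom schema version: ", doc$schema_version,
         call. = FALSE)
  }
  d <- doc$disks
  if (length(d) == 0 || is.null(d$x)) {
    return(disk_phantom(R = doc$R))
  }
  disk_phantom(x = d$x, y = d$y, radius = d$radius, amplitude = d$amplitude,
               profile = d$profile, kappa = d$kappa, R = doc$R)
}

#' Save and load detector data (plain-text array container)
#'
#' The array is written as a headerless CSV (one row per channel) with a
#' JSON sidecar (`<path>.json`) carrying kind, geometry, grid and schema
#' version, so the pair is portable and diff-able. Values round-trip at
#' full double precision.
#'
#' @param data A `detector_data`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` invisibly; `read_detector_csv()` returns the
#'   `detector_data`.
#' @export
write_detector_csv <- function(data, path) {
  stopifnot(inherits(data, "detector_data"))
  meta <- list(schema_version = .schema_version, kind = data$kind,
               R = data$geometry$R, n = data$geometry$n,
               Omega = data$geometry$Omega, q = data$grid$q,
               rows = nrow(data$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(format(data$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_detector_csv
#' @export
read_detector_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), .schema_version)) {
    stop("unsupported detector-data schema version: ", meta$schema_version,
         call. = FALSE)
  }
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  if (nrow(vals) != meta$rows || ncol(vals) != meta$q) {
    stop("detector-data shape ", nrow(vals), "x", ncol(vals),
         " does not match sidecar (", meta$rows, "x", meta$q, ")",
         call. = FALSE)
  }
  detector_data(vals, meta$kind,
                sensor_geometry(R = meta$R, n = meta$n, Omega = meta$Omega),
                time_grid(R = meta$R, q = meta$q))
}

#' Save and load images (plain-text array container)
#'
#' Same CSV + JSON sidecar convention as [write_detector_csv()].
#'
#' @param image An [image_grid()].
#' @param path CSV path; sidecar is `<path>.json`.
#' @return `path` invisibly; `read_image_csv()` returns the `image_grid`.
#' @export
write_image_csv <- function(image, path) {
  stopifnot(inherits(image, "image_grid"))
  meta <- list(schema_version = .schema_version, R = image$R,
               Nr = image$Nr)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(format(image$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), .schema_version)) {
    stop("unsupported image schema version: ", meta$schema_version,
         call. = FALSE)
  }
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  image_grid(R = meta$R, Nr = meta$Nr, values = vals)
}

#' Export an image as PNG for quick inspection
#'
#' Linear grayscale over the value range; row 1 of the array is the lowest
#' `y`, so the file is flipped to display `y` upward.
#'
#' @param image An [image_grid()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "image_grid"))
  v <- image$values
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  png::writePNG((v[rev(seq_len(nrow(v))), ] - rng[1]) / diff(rng), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the resolved configuration, seeds, package version, input and
#' output file checksums and a timestamp, so a run can be audited and
#' reproduced from the manifest alone.
#'
#' @param path Manifest path (`.json`).
#' @param config Named list of resolved configuration values.
#' @param seeds Named list/vector of seeds used.
#' @param files Character vector of files to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           files = character(0)) {
  files <- files[file.exists(files)]
  doc <- list(
    schema_version = .schema_version,
    package = "cspat",
    version = as.character(utils::packageVersion("cspat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
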
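# Persistence: ASCII PLY / legacy VTK for meshes, HDF5 containers (via
# rhdf5 when available, .rds fallback otherwise) for simulated series,
# BSP recordings, transfer matrices and tensor datasets.

.has_h5 <- function() requireNamespace("rhdf5", quietly = TRUE)

.h5_or_rds <- function(path) {
  if (grepl("\\.rds$", path)) "rds"
  else if (.has_h5()) "h5"
  else "rds"
}

.swap_ext <- function(path, ext) sub("\\.[A-Za-z0-9]+$", ext, path)

#' Write an atrial mesh as ASCII PLY
#'
#' Per-vertex properties: coordinates, fiber direction (nx, ny, nz),
#' region_id and fibrosis flag.
#' @param mesh atrial_mesh
#' @param path output file
#' @export
write_mesh_ply <- function(mesh, path) {
  n <- nrow(mesh$node_coords); t <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               "property int region_id", "property int fibrosis",
               sprintf("element face %d", t),
               "property list uchar int vertex_indices",
               "end_header"), con)
  verts <- cbind(mesh$node_coords, mesh$fiber_dir, mesh$region_id,
                 as.integer(mesh$fibrotic))
  writeLines(apply(verts, 1, function(r)
    paste(c(sprintf("%.8f", r[1:6]), sprintf("%d", as.integer(r[7:8]))),
          collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY written by [write_mesh_ply()]
#' @param path file path
#' @param d_long,d_trans diffusion coefficients to attach
#' @return atrial_mesh
#' @export
read_mesh_ply <- function(path, d_long = NULL, d_trans = NULL) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[hdr_end + seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
  fl <- lines[hdr_end + nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(fl, " "), as.integer))[, 2:4] + 1L
  coords <- vm[, 1:3, drop = FALSE]
  if (is.null(d_long)) {
    e <- .edges_from_triangles(fm)
    h <- mean(sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                            coords[e[, 2], , drop = FALSE])^2)))
    d_long <- 0.042 * h^2
  }
  if (is.null(d_trans)) d_trans <- d_long / 2
  fiber <- vm[, 4:6, drop = FALSE]
  nrm <- sqrt(rowSums(fiber^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop_af("fiber directions in %s are far from unit norm", path)
  fiber <- fiber / nrm     # undo ASCII round-off
  mesh <- structure(list(
    node_coords = coords, triangles = fm,
    neighbors = .adjacency_list(fm, nv),
    fiber_dir = fiber,
    region_id = as.integer(vm[, 7]),
    region_names = ATRIAL_REGIONS,
    d_long = d_long, d_trans = d_trans,
    fibrotic = vm[, 8] > 0,
    geometry_params = list(source = path),
    rng_seed = NA_integer_), class = "atrial_mesh")
  validate_atrial_mesh(mesh)
  mesh
}

#' Write an atrial mesh as legacy ASCII VTK PolyData
#' @param mesh atrial_mesh
#' @param path output file
#' @export
write_mesh_vtk <- function(mesh, path) {
  n <- nrow(mesh$node_coords); t <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atrial surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(mesh$node_coords, 1, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", t, 4L * t), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS region_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", mesh$region_id), con)
  writeLines(c("SCALARS fibrosis int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(mesh$fibrotic)), con)
  writeLines("VECTORS fiber_dir float", con)
  writeLines(apply(mesh$fiber_dir, 1, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}

#' Persist a simulated episode
#'
#' HDF5 layout: `/vm` (N x S), `/fs`, `/labels`, attributes `seed` and
#' `protocol` (JSON).  Falls back to `.rds` when rhdf5 is unavailable or
#' the path ends in `.rds`.
#' @param vm vm_series
#' @param path output path (`.h5` or `.rds`)
#' @export
write_vm_series <- function(vm, path) {
  if (.h5_or_rds(path) == "rds") {
    saveRDS(vm, .swap_ext(path, ".rds"))
    return(invisible(.swap_ext(path, ".rds")))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(vm$vm, path, "vm")
  rhdf5::h5write(vm$fs, path, "fs")
  rhdf5::h5write(as.integer(vm$labels), path, "labels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.integer(vm$seed %||% NA_integer_), fid, "seed")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(unclass(vm$protocol), auto_unbox = TRUE,
                                  null = "null")), fid, "protocol")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_vm_series
#' @export
read_vm_series <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  if (!.has_h5()) stop_af("rhdf5 unavailable; cannot read %s", path)
  vm <- rhdf5::h5read(path, "vm")
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  fid <- rhdf5::H5Fopen(path)
  seed <- tryCatch(rhdf5::h5readAttributes(fid, "/")$seed,
                   error = function(e) NA_integer_)
  prot <- tryCatch(jsonlite::fromJSON(
    rhdf5::h5readAttributes(fid, "/")$protocol), error = function(e) NULL)
  rhdf5::H5Fclose(fid)
  structure(list(vm = vm, fs = fs,
                 duration_s = ncol(vm) / fs, labels = labels,
                 protocol = if (!is.null(prot))
                   structure(prot, class = "stimulus_protocol"),
                 seed = seed, mesh_fingerprint = NULL),
            class = "vm_series")
}

#' Persist a transfer matrix (HDF5: /a, /a_wct, /wct_indices + provenance)
#' @param tm transfer_matrix
#' @param path output path
#' @export
write_transfer_matrix <- function(tm, path) {
  if (.h5_or_rds(path) == "rds") {
    saveRDS(tm, .swap_ext(path, ".rds"))
    return(invisible(.swap_ext(path, ".rds")))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tm$a, path, "a")
  rhdf5::h5write(tm$a_wct, path, "a_wct")
  rhdf5::h5write(as.integer(tm$wct_indices), path, "wct_indices")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(tm$provenance$mesh %||% "", fid, "mesh")
  rhdf5::h5writeAttribute(tm$provenance$torso %||% "", fid, "torso")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  if (!.has_h5()) stop_af("rhdf5 unavailable; cannot read %s", path)
  at <- rhdf5::h5readAttributes(path, "/")
  structure(list(a = rhdf5::h5read(path, "a"),
                 a_wct = rhdf5::h5read(path, "a_wct"),
                 wct_indices = as.integer(rhdf5::h5read(path, "wct_indices")),
                 provenance = list(mesh = at$mesh, torso = at$torso)),
            class = "transfer_matrix")
}

#' Persist a BSP recording (HDF5: /bsp, /fs + snr/filter attrs)
#' @param bsp bsp_recording
#' @param path output path
#' @export
write_bsp_recording <- function(bsp, path) {
  if (.h5_or_rds(path) == "rds") {
    saveRDS(bsp, .swap_ext(path, ".rds"))
    return(invisible(.swap_ext(path, ".rds")))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(bsp$potentials, path, "bsp")
  rhdf5::h5write(bsp$fs, path, "fs")
  if (!is.null(bsp$labels))
    rhdf5::h5write(as.integer(bsp$labels), path, "labels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(bsp$snr_db %||% NA_real_, fid, "snr_db")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(bsp$filter %||% list(),
                                  auto_unbox = TRUE)), fid, "filter")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Persist a labeled tensor dataset
#'
#' HDF5 layout: `/images` (n x H x W x C), `/labels`, `/episode_id`,
#' `/frame_idx`, plus layout/normalization attributes from the manifest.
#' @param ds labeled_dataset
#' @param path output path (`.h5`, `.rds` fallback)
#' @export
write_labeled_dataset <- function(ds, path) {
  if (.h5_or_rds(path) == "rds") {
    saveRDS(ds, .swap_ext(path, ".rds"))
    return(invisible(.swap_ext(path, ".rds")))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ds$images, path, "images")
  rhdf5::h5write(as.integer(ds$labels), path, "labels")
  rhdf5::h5write(as.integer(ds$episode), path, "episode_id")
  rhdf5::h5write(as.integer(ds$frame_idx), path, "frame_idx")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(ds$manifest, auto_unbox = TRUE)),
    fid, "manifest")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  if (!.has_h5()) stop_af("rhdf5 unavailable; cannot read %s", path)
  at <- rhdf5::h5readAttributes(path, "/")
  structure(list(
    images = rhdf5::h5read(path, "images"),
    labels = as.integer(rhdf5::h5read(path, "labels")),
    episode = as.integer(rhdf5::h5read(path, "episode_id")),
    frame_idx = as.integer(rhdf5::h5read(path, "frame_idx")),
    manifest = tryCatch(jsonlite::fromJSON(at$manifest),
                        error = function(e) list())),
    class = "labeled_dataset")
}

#' @rdname write_bsp_recording
#' @export
read_bsp_recording <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  if (!.has_h5()) stop_af("rhdf5 unavailable; cannot read %s", path)
  at <- rhdf5::h5readAttributes(path, "/")
  labels <- tryCatch(as.integer(rhdf5::h5read(path, "labels")),
                     error = function(e) NULL)
  filt <- tryCatch(jsonlite::fromJSON(at$filter), error = function(e) NULL)
  if (length(filt) == 0) filt <- NULL
  new_bsp_recording(rhdf5::h5read(path, "bsp"),
                    as.numeric(rhdf5::h5read(path, "fs")),
                    snr_db = if (is.finite(at$snr_db))
                      as.numeric(at$snr_db),
                    filter = filt, labels = labels)
}
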
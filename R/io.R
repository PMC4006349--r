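#' Read a scalar image into a field
#'
#' Dispatches on extension: PNG (8/16-bit grayscale, 2-D, unit spacing,
#' values scaled to \[0, 255\]), NIfTI (`.nii` / `.nii.gz`, spacing from the
#' header) or NRRD (`.nrrd`, attached raw or ascii encodings). Axis order is
#' (row, col\[, slice\]).
#'
#' @param path input file.
#' @return a `scalar_field` with the grid spacing from the header (unit for
#'   PNG).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
    png = {
      v <- png::readPNG(path)
      if (length(dim(v)) == 3L) v <- v[, , 1L]  # collapse gray+alpha
      scalar_field(v * 255, grid_spec(dim(v)))
    },
    nii = {
      img <- RNifti::readNifti(path)
      sp <- RNifti::pixdim(img)
      v <- as.array(img)
      attributes(v) <- list(dim = dim(v))
      scalar_field(v, grid_spec(dim(v), sp[seq_along(dim(v))]))
    },
    nrrd = read_nrrd(path),
    stop("unknown image format: .", ext)
  )
}

#' Write a field to PNG, NIfTI or NRRD
#'
#' PNG output is clamped to \[0, 255\] and stored at 16-bit depth; NIfTI and
#' NRRD store float values with the grid spacing in the header.
#'
#' @param field a `scalar_field` (or `level_set`).
#' @param path output file; format from extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(field, path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  v <- field$values
  switch(ext,
    png = {
      if (length(dim(v)) != 2L) stop("PNG output requires a 2-D field")
      png::writePNG(pmin(pmax(v / 255, 0), 1), path)
    },
    nii = {
      img <- RNifti::asNifti(structure(v, pixdim = field$grid$spacing),
                             datatype = "float")
      RNifti::writeNifti(img, path)
    },
    nrrd = write_nrrd(field, path),
    stop("unknown image format: .", ext)
  )
  invisible(path)
}

# --- minimal NRRD (attached raw/ascii encodings) -------------------------
# No NRRD reader exists among the available R packages, so the subset of
# the format the package emits (and common float/int types) is parsed here.

nrrd_types <- c(double = "double", float = "double", uchar = "integer",
                `unsigned char` = "integer", short = "integer",
                int = "integer")
nrrd_sizes <- c(double = 8L, float = 4L, uchar = 1L, `unsigned char` = 1L,
                short = 2L, int = 4L)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("corrupt header: not an NRRD file")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("corrupt header: no blank line before data")
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1L]]
    if (length(kv) == 3L) fields[[tolower(kv[2L])]] <- kv[3L]
  }
  type <- fields[["type"]]
  if (is.null(type) || !type %in% names(nrrd_types))
    stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "[ \t]+")[[1L]])
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(trimws(fields[["spacings"]]), "[ \t]+")[[1L]])
  else rep(1, length(sizes))
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  if (enc == "raw") {
    endian <- if (!is.null(fields[["endian"]]) &&
                  fields[["endian"]] == "big") "big" else "little"
    v <- readBin(con, what = nrrd_types[[type]], n = n,
                 size = nrrd_sizes[[type]], endian = endian,
                 signed = !type %in% c("uchar", "unsigned char"))
  } else if (enc %in% c("ascii", "text", "txt")) {
    v <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(v) != n) stop("corrupt NRRD: expected ", n, " values")
  scalar_field(array(as.double(v), sizes), grid_spec(sizes, spacing))
}

write_nrrd <- function(field, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "type: double",
           paste("dimension:", length(field$grid$shape)),
           paste("sizes:", paste(field$grid$shape, collapse = " ")),
           paste("spacings:", paste(format(field$grid$spacing, digits = 17),
                                    collapse = " ")),
           paste("encoding:", encoding),
           if (encoding == "raw") "endian: little",
           "")
  writeLines(hdr, con)
  if (encoding == "raw") {
    writeBin(as.vector(field$values), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(format(as.vector(field$values), digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

# --- run outputs and manifest -------------------------------------------

cfg_to_list <- function(cfg) {
  list(model = unclass(cfg$model), control = unclass(cfg$control),
       cfl = cfg$cfl, dt_max = cfg$dt_max, redist_every = cfg$redist_every,
       max_steps = cfg$max_steps, steady_tol = cfg$steady_tol,
       steady_window = cfg$steady_window, sigma_x = cfg$sigma_x,
       sigma_I = cfg$sigma_I, click_gain = cfg$click_gain, seed = cfg$seed)
}

cfg_from_list <- function(x) {
  session_config(
    model = do.call(region_model, x$model[!vapply(x$model, is.null, TRUE)]),
    control = do.call(control_config, x$control),
    cfl = x$cfl, dt_max = x$dt_max, redist_every = x$redist_every,
    max_steps = x$max_steps, steady_tol = x$steady_tol,
    steady_window = x$steady_window, sigma_x = x$sigma_x,
    sigma_I = x$sigma_I, click_gain = x$click_gain, seed = x$seed)
}

#' Read a session configuration from YAML
#'
#' Keys mirror [session_config()]: `model` (`kind`, `r_loc`,
#' `lambda_smooth`), `control` (`lambda0`, `lambda1`, `rho`, `U_M`,
#' `alpha`, `eps`), and the top-level step/termination settings. Missing
#' keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `session_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  base <- cfg_to_list(session_config())
  merged <- utils::modifyList(base, x)
  cfg_from_list(merged)
}

#' Write run outputs and a reproducibility manifest
#'
#' Emits the final label mask `(phi > 0)` in the requested image format and
#' geometry, snapshots of phi / psi_hat / U, the per-step diagnostics CSV,
#' the ingested click stream, and a JSON manifest holding the full resolved
#' configuration, the seed, the package version and per-file checksums —
#' enough to reproduce the run bit-exactly with [rerun_manifest()].
#'
#' @param outdir output directory (created if needed).
#' @param result a [run_session()] result.
#' @param I the input intensity field.
#' @param cfg the `session_config` used.
#' @param format mask/snapshot format: `"png"`, `"nii"` or `"nrrd"`.
#'   Default `"png"` for 2-D, `"nii"` otherwise.
#' @param image_path optional path of the original input image, recorded in
#'   the manifest (and used by [rerun_manifest()]).
#' @return the manifest as a list, invisibly; files under `outdir`.
#' @export
write_outputs <- function(outdir, result, I, cfg, format = NULL,
                          image_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(format)) format <- if (ndim(I) == 2L) "png" else "nii"
  pth <- function(f) file.path(outdir, f)
  mask <- with_values(I, (result$phi$values > 0) * 255)
  write_image(mask, pth(paste0("mask.", format)))
  snapfmt <- if (format == "png") "nrrd" else format  # snapshots need signed reals
  write_image(result$phi, pth(paste0("phi.", snapfmt)))
  write_image(result$psi_hat, pth(paste0("psi_hat.", snapfmt)))
  write_image(result$U$field, pth(paste0("U.", snapfmt)))
  utils::write.csv(result$diagnostics, pth("diagnostics.csv"),
                   row.names = FALSE)
  if (!is.null(result$clicks)) write_clicks(result$clicks, pth("clicks.csv"))
  if (is.null(image_path)) {
    # lossless snapshot of the input so a rerun sees identical intensities
    image_path <- pth("input.nrrd")
    write_image(I, image_path)
  }
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package = "contourctl",
    version = as.character(utils::packageVersion("contourctl")),
    seed = cfg$seed,
    config = cfg_to_list(cfg),
    eps = result$phi$eps,
    resolved = list(U_M = result$control$U_M, alpha = result$control$alpha),
    image = image_path,
    clicks = if (!is.null(result$clicks)) pth("clicks.csv") else NULL,
    mask = pth(paste0("mask.", format)),
    diagnostics = pth("diagnostics.csv"),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Re-run a session from its manifest
#'
#' Reads the manifest written by [write_outputs()], reloads the input image
#' and click stream, rebuilds the configuration and initial contour, and
#' reruns [run_session()]. With identical inputs the trajectory — and hence
#' the output mask — is bit-identical.
#'
#' @param manifest_path path to `manifest.json`.
#' @param phi0 the initial `level_set` (the manifest records the
#'   configuration, not the seed geometry, so the caller supplies it).
#' @param outdir where to write the reproduced outputs.
#' @return the new [run_session()] result, invisibly.
#' @export
rerun_manifest <- function(manifest_path, phi0, outdir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- cfg_from_list(man$config)
  I <- read_image(man$image)
  clicks <- if (!is.null(man$clicks) && file.exists(man$clicks))
    read_clicks(man$clicks) else NULL
  res <- run_session(I, phi0, clicks = clicks, cfg = cfg)
  write_outputs(outdir, res, I, cfg,
                format = tolower(sub(".*\\.", "", man$mask)),
                image_path = man$image)
  invisible(res)
}
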
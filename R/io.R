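#' Read a volume from a NIfTI file
#'
#' Values, spacing and origin survive a [write_volume()] / `read_volume()`
#' round trip bit-exactly for integer HU (volumes are stored as float64).
#'
#' @param path file ending in `.nii` or `.nii.gz`.
#' @return an [image_volume].
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop(sprintf("unsupported volume format: '%s' (NIfTI .nii/.nii.gz only)", path))
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read '%s' as NIfTI: %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  # NIfTI stores (x, y, z); the package convention is (z, y, x)
  data <- aperm(arr, c(3, 2, 1))
  pix <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  orig_xyz <- xf[1:3, 4]
  # the writer uses a plain diagonal LPS-agnostic affine: diag(spacing), origin
  image_volume(data, spacing = rev(pix[1:3]), origin = rev(orig_xyz))
}

#' Write a volume to a NIfTI file
#'
#' @param vol an [image_volume].
#' @param path destination `.nii` or `.nii.gz`.
#' @param sidecar optional named list written next to the volume as
#'   `<path>.json` (seed, config hash, provenance).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = NULL) {
  if (!is_image_volume(vol)) stop("`vol` must be an image_volume")
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop(sprintf("unsupported volume format: '%s' (NIfTI .nii/.nii.gz only)", path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arr <- aperm(vol$data, c(3, 2, 1))  # back to NIfTI (x, y, z)
  sp <- rev(vol$spacing)
  og <- rev(vol$origin)
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- og
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, sp)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(sidecar)) write_sidecar(path, sidecar)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a structure set as one NIfTI mask file per structure
#' @param structs a [structure_set].
#' @param dir directory to hold `<name>.nii.gz` files.
#' @param sidecar optional metadata list replicated per mask.
#' @return `dir`, invisibly.
#' @export
write_structures <- function(structs, dir, sidecar = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(structs$masks)) {
    v <- image_volume(array(as.numeric(structs$masks[[nm]]),
                            dim = dim(structs$masks[[1]])),
                      structs$spacing, structs$origin)
    write_volume(v, file.path(dir, paste0(nm, ".nii.gz")), sidecar = sidecar)
  }
  invisible(dir)
}

#' @rdname write_structures
#' @export
read_structures <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no mask files in %s", dir))
  masks <- list()
  geom <- NULL
  for (f in files) {
    v <- read_volume(f)
    masks[[sub("\\.nii(\\.gz)?$", "", basename(f))]] <- v$data > 0.5
    geom <- v
  }
  structure_set(masks, geom$spacing, geom$origin)
}

# Deterministic seed derivation: every stage/subject gets an independent,
# reproducible stream from one master seed.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- digest::digest(key, algo = "xxhash32", serialize = FALSE)
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483646L) + 1L
}

config_hash <- function(x) digest::digest(x, algo = "xxhash64")
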
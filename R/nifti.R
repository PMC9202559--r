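# Minimal NIfTI-1 backend.  No R NIfTI package is assumed: the format is a
# fixed 348-byte header followed by voxel data, which base R reads and
# writes directly (gzip transparently via gzfile).  Only what BraTS-style
# volumes need is supported: 3D single-frame images, dtypes uint8 / int16 /
# int32 / float32 / float64, little-endian, sform affine, scl slope/inter.

.NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# parse a field out of a raw header; NIfTI-1 fixed offsets (0-based `at`)
.hfield <- function(hdr, at, what, n, size, endian, signed = TRUE) {
  readBin(hdr[(at + 1L):(at + n * size)], what, n, size = size,
          signed = signed, endian = endian)
}

#' Read a NIfTI-1 volume
#'
#' Supports 3D single-frame images with dtypes uint8/int16/int32/float32/
#' float64; `scl_slope`/`scl_inter` are applied; the sform is returned as
#' the affine (identity if `sform_code` is 0).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return list with `data` (numeric array), `affine` (4x4 voxel-to-world),
#'   `pixdim` (voxel spacings).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) format_error(sprintf("truncated NIfTI header: %s", path))
  endian <- "little"
  if (.hfield(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (.hfield(hdr, 0L, "integer", 1L, 4L, endian) != 348L)
      format_error(sprintf("not a NIfTI-1 file: %s", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1" && magic != "ni1")
    format_error(sprintf("bad NIfTI magic in %s", path))
  dimv       <- .hfield(hdr,  40L, "integer", 8L, 2L, endian)
  datatype   <- .hfield(hdr,  70L, "integer", 1L, 2L, endian)
  pixdim     <- .hfield(hdr,  76L, "double",  8L, 4L, endian)
  vox_offset <- .hfield(hdr, 108L, "double",  1L, 4L, endian)
  scl_slope  <- .hfield(hdr, 112L, "double",  1L, 4L, endian)
  scl_inter  <- .hfield(hdr, 116L, "double",  1L, 4L, endian)
  sform_code <- .hfield(hdr, 254L, "integer", 1L, 2L, endian)
  affine <- diag(4)
  if (sform_code > 0L)
    affine <- rbind(matrix(.hfield(hdr, 280L, "double", 12L, 4L, endian),
                           nrow = 3L, byrow = TRUE),
                    c(0, 0, 0, 1))
  nd <- dimv[1]
  if (nd < 1L || nd > 7L) format_error("corrupt NIfTI dim field")
  shape <- dimv[1L + seq_len(nd)]
  shape <- shape[shape > 0]
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    format_error(sprintf("unsupported NIfTI datatype code %d", datatype))
  n <- prod(shape)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) format_error("truncated NIfTI data section")
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  data <- array(as.numeric(vals) * scl_slope + scl_inter, dim = shape)
  list(data = data, affine = affine, pixdim = pixdim[2:4])
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric or integer array (3D).
#' @param path output path; `.gz` suffix selects gzip.
#' @param affine 4x4 voxel-to-world transform, written as the sform.
#' @param datatype one of `"float32"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32") {
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 validation_error(sprintf("unsupported datatype '%s'", datatype)))
  dt <- .NIFTI_DTYPES[[as.character(code)]]
  shape <- dim(data)
  if (is.null(shape) || length(shape) != 3L)
    validation_error("write_nifti supports 3D arrays")
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))  # dim[8]
  w_raw(14L)                        # intent_p*, intent_code
  w_i16(code); w_i16(dt$bitpix); w_i16(0L)
  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  w_f32(c(1, pix, 1, 0, 0, 0))      # pixdim[8] (qfac = 1)
  w_f32(352); w_f32(1); w_f32(0)    # vox_offset, scl_slope, scl_inter
  w_raw(4L)                         # slice_end (2), slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(80L + 24L)                  # descrip, aux_file
  w_i16(0L); w_i16(1L)              # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0, 0, 0, 0))        # quatern b,c,d + qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                        # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)
  w_raw(4L)                         # extension flag: none
  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

read_nifti_affine <- function(path) read_nifti(path)$affine

#' Read one BraTS-style case from NIfTI files
#'
#' Accepts per-modality paths plus an optional label mask.  Raw label 4
#' (BraTS native enhancing label) is remapped to 3; all other labels must
#' already be in 0..3.
#'
#' @param t1,t1ce,t2,flair file paths to the four modality volumes.
#' @param mask optional path to the integer label volume.
#' @param case_id identifier; default derived from the t1 filename.
#' @return a `case_bundle`.
#' @export
read_case <- function(t1, t1ce, t2, flair, mask = NULL, case_id = NULL) {
  paths <- c(t1 = t1, t1ce = t1ce, t2 = t2, flair = flair)
  vols <- lapply(paths, function(p) read_nifti(p)$data)
  names(vols) <- MODALITIES
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    format_error(sprintf("modality shapes disagree: %s",
                         paste(unique(shapes), collapse = " vs ")))
  m <- NULL
  if (!is.null(mask)) {
    m <- read_nifti(mask)$data
    if (!identical(dim(m), dim(vols[[1]])))
      format_error("mask shape does not match modalities")
    m <- remap_labels(m)
  }
  if (is.null(case_id))
    case_id <- sub("(_t1)?\\.nii(\\.gz)?$", "", basename(t1))
  affine <- read_nifti_affine(t1)
  new_case_bundle(vols, m, affine, case_id)
}

#' Remap raw BraTS labels to the package's 0..3 scheme
#'
#' A bijection on observed values: 4 -> 3, identity elsewhere; any label
#' outside \{0, 1, 2, 3, 4\} is a format error.
#'
#' @param labels integer array/vector.
#' @return integer array of the same shape with values in 0..3.
#' @export
remap_labels <- function(labels) {
  u <- unique(as.vector(labels))
  if (!all(u %in% c(0, 1, 2, 3, 4)))
    format_error(sprintf("labels outside {0,1,2,3,4}: %s",
                         paste(sort(setdiff(u, 0:4)), collapse = ", ")))
  out <- as.integer(round(labels))
  out[out == 4L] <- 3L
  dim(out) <- dim(labels)
  out
}

#' Write a case (and its mask) as NIfTI files
#'
#' Files are named `{case_id}_{t1,t1ce,t2,flair,seg}.nii.gz`; modalities are
#' float32, the mask uint8, both carrying the bundle's affine as sform.
#'
#' @param case a `case_bundle`.
#' @param dir output directory (created if needed).
#' @param gzip write gzipped files (default TRUE).
#' @return character vector of written paths, invisibly.
#' @export
write_case <- function(case, dir, gzip = TRUE) {
  if (!inherits(case, "case_bundle")) validation_error("case must be a case_bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- character(0)
  for (m in MODALITIES) {
    p <- file.path(dir, paste0(case$case_id, "_", m, ext))
    write_nifti(case$modalities[[m]], p, case$affine, "float32")
    paths <- c(paths, p)
  }
  if (!is.null(case$mask)) {
    p <- file.path(dir, paste0(case$case_id, "_seg", ext))
    write_nifti(case$mask, p, case$affine, "uint8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a predicted label mask as uint8 NIfTI
#'
#' @param mask integer 3D array with labels in 0..3.
#' @param path output path.
#' @param affine source affine to propagate.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, affine = diag(4)) {
  if (!all(unique(as.vector(mask)) %in% 0:3))
    validation_error("mask labels must be in {0,1,2,3}")
  write_nifti(mask, path, affine, "uint8")
}
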
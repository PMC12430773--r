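#' Multi-sequence MRI volume container
#'
#' Bundles three co-registered 3D intensity grids (T1WI, T2WI and
#' contrast-enhanced T1) for one patient, together with the voxel spacing and
#' world origin they share. All downstream stages (bias correction,
#' resampling, habitat clustering, feature extraction) consume this container.
#'
#' @param t1,t2,t1c 3D numeric arrays of identical dimensions: the T1-weighted,
#'   T2-weighted and contrast-enhanced T1-weighted intensity grids.
#' @param spacing_mm Numeric length-3, voxel size along each axis in mm.
#' @param origin Numeric length-3 world offset in mm (default zero).
#'
#' @return An object of class `msvol`: a list with elements `t1`, `t2`, `t1c`,
#'   `spacing_mm` and `origin`.
#' @export
multiseq_volume <- function(t1, t2, t1c, spacing_mm, origin = c(0, 0, 0)) {
  stop_if_not_grid3d(t1, "t1")
  stop_if_not_grid3d(t2, "t2")
  stop_if_not_grid3d(t1c, "t1c")
  check_same_grid(t1, t2, c("t1", "t2"))
  check_same_grid(t1, t1c, c("t1", "t1c"))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be three positive numbers.")
  }
  structure(
    list(t1 = t1, t2 = t2, t1c = t1c,
         spacing_mm = spacing_mm, origin = as.numeric(origin)),
    class = "msvol"
  )
}

#' @export
print.msvol <- function(x, ...) {
  cat(sprintf("<msvol> %s voxels @ %s mm\n",
              paste(dim(x$t1), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' Region mask container
#'
#' Holds the binary tumor mask, the (possibly not yet computed) peritumoral
#' ring mask and the exclusion mask (cavities/bone) on a common grid.
#'
#' @param tumor Logical/binary 3D array: the delineated tumor.
#' @param ring Optional logical 3D array: the peritumoral ring; may be `NULL`
#'   before [make_peritumoral_ring()] has been run.
#' @param exclusion Optional logical 3D array of voxels excluded from the ring
#'   (e.g. bone or air); `NULL` means nothing is excluded.
#' @param spacing_mm Voxel spacing in mm.
#'
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(tumor, ring = NULL, exclusion = NULL, spacing_mm) {
  stop_if_not_grid3d(tumor, "tumor")
  tumor <- tumor > 0
  if (!is.null(exclusion)) {
    check_same_grid(tumor, exclusion, c("tumor", "exclusion"))
    exclusion <- exclusion > 0
  }
  if (!is.null(ring)) {
    check_same_grid(tumor, ring, c("tumor", "ring"))
    ring <- ring > 0
    if (any(ring & tumor)) abort("ring and tumor masks overlap.")
    if (!is.null(exclusion) && any(ring & exclusion)) {
      abort("ring and exclusion masks overlap.")
    }
  }
  structure(
    list(tumor = tumor, ring = ring, exclusion = exclusion,
         spacing_mm = as.numeric(spacing_mm)),
    class = "region_masks"
  )
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks> tumor %d voxels, ring %s, exclusion %s\n",
              sum(x$tumor),
              if (is.null(x$ring)) "<unset>" else sum(x$ring),
              if (is.null(x$exclusion)) "<none>" else sum(x$exclusion)))
  invisible(x)
}

#' Write and read a multi-sequence volume as NIfTI files
#'
#' One NIfTI file per sequence (`<prefix>_T1.nii`, `<prefix>_T2.nii`,
#' `<prefix>_T1C.nii`), with voxel spacing recorded in the header.
#'
#' @param vol An [multiseq_volume()] object.
#' @param prefix File path prefix (directory must exist).
#' @return `write_msvol` returns the written paths invisibly; `read_msvol`
#'   returns an `msvol`.
#' @export
write_msvol <- function(vol, prefix) {
  stopifnot(inherits(vol, "msvol"))
  paths <- paste0(prefix, "_", c("T1", "T2", "T1C"), ".nii")
  seqs <- list(vol$t1, vol$t2, vol$t1c)
  for (i in 1:3) {
    img <- RNifti::asNifti(seqs[[i]], reference = NULL)
    RNifti::pixdim(img) <- vol$spacing_mm
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' @rdname write_msvol
#' @export
read_msvol <- function(prefix) {
  paths <- paste0(prefix, "_", c("T1", "T2", "T1C"), ".nii")
  imgs <- lapply(paths, RNifti::readNifti)
  sp <- RNifti::pixdim(imgs[[1]])[1:3]
  multiseq_volume(
    t1 = array(as.numeric(imgs[[1]]), dim = dim(imgs[[1]])),
    t2 = array(as.numeric(imgs[[2]]), dim = dim(imgs[[2]])),
    t1c = array(as.numeric(imgs[[3]]), dim = dim(imgs[[3]])),
    spacing_mm = sp
  )
}

#' Write a binary or integer label mask as NIfTI
#'
#' @param mask 3D array (logical or integer).
#' @param path Output file path (`.nii`).
#' @param spacing_mm Voxel spacing in mm.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path, spacing_mm) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(img), dim = dim(img))
}
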
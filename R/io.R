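#' Write a DWI phantom to disk
#'
#' NIfTI volumes plus FSL-dialect plain-text `bvals`/`bvecs` (one row per
#' axis), ground-truth diffusivity/FA maps, and the region label volume.
#'
#' @param phantom a [generate_dwi_phantom()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_dwi_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- rep(phantom$spec$voxel_size, 3)
  paths <- c(
    dwi = file.path(dir, "dwi.nii.gz"),
    bvals = file.path(dir, "dwi.bval"),
    bvecs = file.path(dir, "dwi.bvec"),
    labels = file.path(dir, "labels.nii.gz"),
    dxx = file.path(dir, "truth_dxx.nii.gz"),
    dyy = file.path(dir, "truth_dyy.nii.gz"),
    dzz = file.path(dir, "truth_dzz.nii.gz"),
    fa = file.path(dir, "truth_fa.nii.gz"))
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(vs[1], length(dim(arr)))
    img
  }
  RNifti::writeNifti(as_img(phantom$dwi), paths["dwi"])
  writeLines(paste(format(phantom$bvals, trim = TRUE), collapse = " "),
             paths["bvals"])
  write(t(phantom$bvecs), paths["bvecs"], ncolumns = ncol(phantom$bvecs))
  RNifti::writeNifti(as_img(phantom$labels * 1), paths["labels"])
  for (m in c("dxx", "dyy", "dzz", "fa"))
    RNifti::writeNifti(as_img(phantom$truth[[m]]), paths[m])
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read DWI data from NIfTI + bval/bvec files
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-dialect plain-text files (b-values on one
#'   line; directions as three rows).
#' @return list with `dwi` (4D array), `bvals`, `bvecs` (3 x nvol),
#'   `voxel_size`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3) stop("bvec file must have three rows (x, y, z)")
  vs <- RNifti::pixdim(img)[1]
  list(dwi = unclass(img)[, , , , drop = FALSE], bvals = bvals,
       bvecs = bvecs, voxel_size = vs)
}

#' Read a 3D or 4D NIfTI volume as a plain array
#' @param path NIfTI file.
#' @return list with `data` (array) and `voxel_size`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[1])
}

#' Write a cohort table as TSV
#'
#' @param cohort data.frame from [generate_cohort()] or assembled manually.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @importFrom utils read.table
NULL
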
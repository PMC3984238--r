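#' Write a DWI dataset to disk (NIfTI + bval/bvec + sidecars)
#'
#' Writes `dwi.nii.gz`, `mask.nii.gz`, `f.bval`/`f.bvec`, ground-truth
#' parameter maps (`truth_md.nii.gz` etc.) when present, and an
#' `artifacts.json` truth sidecar when artifacts were injected.
#'
#' @param dataset a `dwi_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_dwi_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- dataset$voxel_size
  RNifti::writeNifti(nifti_with_pixdim(dataset$data, pix),
                     file.path(dir, "dwi.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(dataset$mask, pix),
                     file.path(dir, "mask.nii.gz"))
  write_gradient_table(dataset$grad, file.path(dir, "f.bval"),
                       file.path(dir, "f.bvec"))
  if (!is.null(dataset$truth)) {
    for (p in c("md", "fa", "mk", "s0")) {
      RNifti::writeNifti(nifti_with_pixdim(dataset$truth[[p]], pix),
                         file.path(dir, paste0("truth_", p, ".nii.gz")))
    }
  }
  if (!is.null(dataset$truth_labels)) {
    jsonlite::write_json(dataset$truth_labels,
                         file.path(dir, "artifacts.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a DWI dataset from NIfTI + bval/bvec (+ optional mask)
#'
#' @param dwi_file 4D NIfTI path.
#' @param bval_file,bvec_file FSL-style gradient files.
#' @param mask_file optional 3D NIfTI mask path.
#' @param sigma known noise sd (0 if unknown; affects only the log floor).
#' @return a `dwi_dataset`.
#' @export
read_dwi_dataset <- function(dwi_file, bval_file, bvec_file,
                             mask_file = NULL, sigma = 0) {
  img <- RNifti::readNifti(dwi_file)
  data <- as.array(img)
  if (length(dim(data)) != 4) stop("dwi file must be 4D")
  grad <- read_gradient_table(bval_file, bvec_file)
  if (nrow(grad) != dim(data)[4]) stop("gradient table does not match volume count")
  mask <- if (is.null(mask_file)) NULL else
    as.integer(as.array(RNifti::readNifti(mask_file)) > 0) |>
      array(dim(data)[1:3])
  pix <- RNifti::pixdim(img)[1:3]
  new_dwi_dataset(data, grad, mask, pix, sigma)
}

#' Write a QC report to TSV + JSON summary
#'
#' @param qc a `qc_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- qc$scores[, c("slice", "bval", "direction_index", "lpcc", "ncc",
                      "lpcc_norm", "ncc_norm", "threshold", "rejected")]
  write.table(sc, file.path(dir, "qc_report.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_scored = nrow(qc$scores), n_rejected = sum(qc$scores$rejected),
         rejection_rate = mean(qc$scores$rejected),
         b0_excluded = qc$b0[!qc$b0$kept, c("slice", "volume")],
         window = qc$window, nsigma = qc$nsigma),
    file.path(dir, "qc_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write fitted parameter maps and the fit log
#'
#' @param fit a `dki_fit`.
#' @param dir output directory.
#' @param voxel_size voxel dimensions in mm.
#' @return invisibly, the directory.
#' @export
write_fit_maps <- function(fit, dir, voxel_size = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c("mk", "md", "fa", "s0")) {
    RNifti::writeNifti(nifti_with_pixdim(fit$maps[[p]], voxel_size),
                       file.path(dir, paste0(p, ".nii.gz")))
  }
  RNifti::writeNifti(nifti_with_pixdim(fit$theta, voxel_size),
                     file.path(dir, "tensors.nii.gz"))
  jsonlite::write_json(
    list(mode = fit$mode, C = fit$C, min_dirs = fit$min_dirs,
         protocol = fit$protocol),
    file.path(dir, "fit_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an MSE report to TSV
#'
#' @param report an `mse_report`.
#' @param file output TSV path.
#' @return invisibly, the path.
#' @export
write_mse_report <- function(report, file) {
  write.table(report$summary, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

nifti_with_pixdim <- function(arr, pix) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(pix, length(dim(arr)))
  img
}
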
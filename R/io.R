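# Readers/writers for the standard interchange formats. NIfTI support goes
# through RNifti when available; delimited matrices through base utils.

#' Read group maps from NIfTI or a delimited matrix
#'
#' A 4D NIfTI holds one volume per network (flattened voxel-major in C
#' order); a delimited file holds the N x K matrix with a header of network
#' labels.
#'
#' @param path file path (.nii/.nii.gz or delimited text).
#' @param sep field separator for text input.
#' @return N x K numeric matrix; NIfTI spatial dimensions are attached as
#'   attribute \code{"spatial_dim"}.
#' @export
read_group_maps <- function(path, sep = ",") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- read_nifti(path)
    d <- dim(img)
    if (length(d) != 4L) stop(sprintf("expected a 4D NIfTI of maps: %s", path))
    out <- matrix(as.numeric(img), prod(d[1:3]), d[4L])
    colnames(out) <- sprintf("net%02d", seq_len(d[4L]))
    attr(out, "spatial_dim") <- d[1:3]
    out
  } else {
    as.matrix(utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE))
  }
}

#' Read one subject's BOLD run from NIfTI or a delimited matrix
#'
#' @inheritParams read_group_maps
#' @return N x T numeric matrix.
#' @export
read_bold_run <- function(path, sep = ",") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- read_nifti(path)
    d <- dim(img)
    if (length(d) != 4L) stop(sprintf("expected a 4D NIfTI run: %s", path))
    out <- matrix(as.numeric(img), prod(d[1:3]), d[4L])
    attr(out, "spatial_dim") <- d[1:3]
    out
  } else {
    as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  }
}

read_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  tryCatch(RNifti::readNifti(path),
           error = function(e) stop(sprintf("cannot read NIfTI file '%s': %s",
                                            path, conditionMessage(e))))
}

#' Write a voxels-by-series matrix as a 4D NIfTI box
#'
#' Reshapes the flat voxel index into a 3D box (padding with zeros) with one
#' volume per column, for interoperability with imaging tools.
#'
#' @param x N x K (or N x T) matrix.
#' @param path output .nii or .nii.gz path.
#' @param spatial_dim optional length-3 box dimensions; default a near-cubic
#'   box holding N voxels.
#' @return the path, invisibly.
#' @export
write_nifti_box <- function(x, path, spatial_dim = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  x <- as_matrix_numeric(x, "x")
  n <- nrow(x)
  if (is.null(spatial_dim)) {
    side <- ceiling(n^(1 / 3))
    spatial_dim <- c(side, side, ceiling(n / side^2))
  }
  vol <- array(0, c(spatial_dim, ncol(x)))
  flat <- matrix(0, prod(spatial_dim), ncol(x))
  flat[seq_len(n), ] <- x
  vol[] <- flat
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

write_matrix_csv <- function(x, path, row_names = FALSE) {
  utils::write.csv(as.data.frame(x), path, row.names = row_names)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
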
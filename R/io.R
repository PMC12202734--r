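#' Write a flip-angle train to a plain-text file
#'
#' One angle in degrees per line, printed with six decimals; the format
#' matches the external VFA lists loadable by scanner sequences. Lines
#' starting with `#` are comments.
#'
#' @param alpha flip angles in degrees.
#' @param path output file path.
#' @param comment optional comment written as a header line.
#' @return `path`, invisibly.
#' @export
write_vfa <- function(alpha, path, comment = NULL) {
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 180))
    stopf("all flip angles must lie in [0, 180] degrees")
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, sprintf("%.6f", alpha))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flip-angle train from a plain-text file
#'
#' @param path input file; one angle in degrees per line, `#` comments and
#'   blank lines allowed.
#' @param ETL optional expected train length; a mismatch is an error.
#' @return Numeric vector of flip angles in degrees.
#' @export
read_vfa <- function(path, ETL = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  vals <- suppressWarnings(as.numeric(trimws(raw[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stopf("cannot parse flip angle on line %d of %s", bad, path)
  }
  out_of_range <- which(vals < 0 | vals > 180)
  if (length(out_of_range)) {
    bad <- which(keep)[out_of_range[1]]
    stopf("flip angle outside [0, 180] on line %d of %s", bad, path)
  }
  if (!is.null(ETL) && length(vals) != ETL)
    stopf("%s contains %d angles but ETL is %d", path, length(vals), ETL)
  vals
}

#' Write a signal response as CSV
#'
#' @param S a `signal_response` or numeric vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(S, path) {
  s <- if (inherits(S, "signal_response")) S$S else as.numeric(S)
  utils::write.csv(data.frame(echo = seq_along(s), amplitude = s),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an optimisation loss history as CSV
#'
#' @param result a `vfa_optimization` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loss_history_csv <- function(result, path) {
  if (!inherits(result, "vfa_optimization"))
    stopf("'result' must be a vfa_optimization")
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}

#' Write a magnitude image to NIfTI, PNG or CSV
#'
#' NIfTI output requires the RNifti package, PNG the png package (values are
#' rescaled to the unit range for PNG); any other extension is written as a
#' headerless CSV matrix.
#'
#' @param image numeric matrix or `sim_image`.
#' @param path output path; the format follows the extension
#'   (`.nii`/`.nii.gz`, `.png`, else CSV).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- if (inherits(image, "sim_image")) image$image else as.matrix(image)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stopf("NIfTI output requires the 'RNifti' package")
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("PNG output requires the 'png' package")
    rng <- range(img)
    scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    png::writePNG(scaled, path)
  } else {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
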
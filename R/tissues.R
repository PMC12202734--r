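#' Tissue relaxation parameters
#'
#' @param name tissue label (e.g. "WM").
#' @param T1 longitudinal relaxation time in ms, > 0.
#' @param T2 transverse relaxation time in ms, 0 < T2 <= T1.
#' @param M0 relative proton density in [0, 1].
#' @return Object of class `tissue_params`.
#' @export
tissue_params <- function(name, T1, T2, M0 = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("'name' must be a non-empty string")
  check_number(T1, "T1", lower = .Machine$double.eps, allow_inf = TRUE)
  check_number(T2, "T2", lower = .Machine$double.eps, allow_inf = TRUE)
  if (T1 < T2) stopf("tissue '%s': T1 (%.0f ms) must be >= T2 (%.0f ms)",
                     name, T1, T2)
  check_number(M0, "M0", lower = 0, upper = 1)
  structure(list(name = name, T1 = T1, T2 = T2, M0 = M0),
            class = "tissue_params")
}

#' Default brain tissue parameters at 7T
#'
#' White matter uses T1 = 1500 ms and T2 = 50 ms, the values the VFA design in
#' this package is calibrated for. Grey-matter and CSF values are
#' representative 7T defaults and can be overridden per tissue.
#'
#' @param overrides optional named list; each element is itself a list with
#'   any of `T1`, `T2`, `M0` replacing the default for that tissue, e.g.
#'   `list(CSF = list(T1 = 4300))`.
#' @return List of three `tissue_params` objects named WM, GM, CSF.
#' @examples
#' default_tissue_params()$WM$T2  # 50 ms
#' @export
default_tissue_params <- function(overrides = NULL) {
  base <- list(
    WM  = list(T1 = 1500, T2 = 50,   M0 = 0.75),
    GM  = list(T1 = 2000, T2 = 55,   M0 = 0.85),
    CSF = list(T1 = 4500, T2 = 2000, M0 = 1.00)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(base))
        stopf("unknown tissue '%s' in overrides", nm)
      for (fld in names(overrides[[nm]]))
        base[[nm]][[fld]] <- overrides[[nm]][[fld]]
    }
  }
  out <- lapply(names(base), function(nm)
    tissue_params(nm, base[[nm]]$T1, base[[nm]]$T2, base[[nm]]$M0))
  names(out) <- names(base)
  out
}

#' Object descriptor: tissues plus their disjoint spatial masks
#'
#' Houses the physical properties (T1, T2, M0) of each tissue class together
#' with one binary mask per tissue marking its spatial support on a common 2D
#' grid. Masks must be pairwise disjoint; voxels outside every mask carry no
#' signal (background, or zero-signal inclusions such as vessels).
#'
#' @param tissues named list of [tissue_params()] objects.
#' @param masks named list of logical matrices, one per tissue, all of the
#'   same dimension; names must match `tissues`.
#' @return Object of class `object_descriptor` with fields `tissues`, `masks`
#'   and `grid_shape`.
#' @export
object_descriptor <- function(tissues, masks) {
  if (length(tissues) == 0L) stopf("at least one tissue is required")
  if (!identical(sort(names(tissues)), sort(names(masks))))
    stopf("names of 'tissues' and 'masks' must match")
  masks <- masks[names(tissues)]
  dims <- lapply(masks, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("every mask must be a matrix")
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("all masks must share the same grid shape")
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(total > 1L)) stopf("tissue masks must be pairwise disjoint")
  if (sum(total) == 0L) stopf("at least one mask must be nonempty")
  structure(list(tissues = tissues, masks = masks,
                 grid_shape = dims[[1]]),
            class = "object_descriptor")
}

#' @export
print.object_descriptor <- function(x, ...) {
  cat(sprintf("object descriptor on a %d x %d grid\n",
              x$grid_shape[1], x$grid_shape[2]))
  for (nm in names(x$tissues)) {
    t <- x$tissues[[nm]]
    cat(sprintf("  %-4s T1=%5.0f ms  T2=%6.1f ms  M0=%.2f  voxels=%d\n",
                nm, t$T1, t$T2, t$M0, sum(x$masks[[nm]])))
  }
  invisible(x)
}

ellipse_mask <- function(nx, ny, cx, cy, rx, ry) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Seeded synthetic 2D brain-like phantom
#'
#' Builds a simple digital head phantom with nested, slightly jittered
#' elliptical compartments: an outer CSF rim, a grey-matter ribbon, a
#' white-matter core and two CSF-filled ventricles, plus (optionally) a few
#' one-voxel zero-signal inclusions mimicking blood vessels. It stands in for
#' voxelated segmented-brain datasets; the second grid axis is the
#' phase-encoding direction.
#'
#' @param grid_shape integer vector `c(Nx, Ny)`, both >= 16.
#' @param seed integer seed; identical seed and shape give a bit-identical
#'   phantom. The session RNG state is left untouched.
#' @param tissues tissue table as returned by [default_tissue_params()].
#' @param vessels number of one-voxel zero-signal inclusions carved out of
#'   the white-matter core (default 4; 0 disables them).
#' @return An [object_descriptor()].
#' @examples
#' ph <- make_synthetic_brain(c(64, 64), seed = 1)
#' sapply(ph$masks, sum)
#' @export
make_synthetic_brain <- function(grid_shape, seed = 1,
                                 tissues = default_tissue_params(),
                                 vessels = 4) {
  if (length(grid_shape) != 2L || any(grid_shape < 16))
    stopf("'grid_shape' must be two integers, each >= 16")
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  check_number(seed, "seed")
  with_seed(seed, {
    jit <- function(scale) stats::runif(1, -scale, scale)
    cx <- nx / 2 + nx * jit(0.02)
    cy <- ny / 2 + ny * jit(0.02)
    rx <- nx * (0.44 + jit(0.015))
    ry <- ny * (0.42 + jit(0.015))
    head  <- ellipse_mask(nx, ny, cx, cy, rx, ry)
    brain <- ellipse_mask(nx, ny, cx, cy, 0.90 * rx, 0.90 * ry)
    core  <- ellipse_mask(nx, ny, cx, cy, 0.74 * rx, 0.74 * ry)
    vent1 <- ellipse_mask(nx, ny, cx - 0.16 * rx + nx * jit(0.01), cy,
                          0.11 * rx, 0.22 * ry)
    vent2 <- ellipse_mask(nx, ny, cx + 0.16 * rx + nx * jit(0.01), cy,
                          0.11 * rx, 0.22 * ry)
    vents <- vent1 | vent2
    csf <- (head & !brain) | (vents & core)
    gm  <- brain & !core
    wm  <- core & !vents
    if (vessels > 0) {
      cand <- which(wm & !gm & !csf)
      cand <- cand[order(stats::runif(length(cand)))]
      drop <- cand[seq_len(min(vessels, length(cand)))]
      wm[drop] <- FALSE
    }
    object_descriptor(tissues[c("WM", "GM", "CSF")],
                      list(WM = wm, GM = gm, CSF = csf))
  })
}

#' Read a label-image phantom
#'
#' Builds an [object_descriptor()] from an integer-coded tissue label map
#' stored either as a delimited text matrix (CSV) or as a greyscale PNG whose
#' integer pixel values code the tissues.
#'
#' @param path file path (`.csv` or `.png`).
#' @param labels named integer vector mapping tissue names to label values,
#'   e.g. `c(WM = 1, GM = 2, CSF = 3)`; label 0 (and anything unmapped) is
#'   background.
#' @param tissues tissue table providing T1/T2/M0 per named tissue.
#' @return An [object_descriptor()].
#' @export
read_label_phantom <- function(path, labels = c(WM = 1, GM = 2, CSF = 3),
                               tissues = default_tissue_params()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("reading PNG label maps requires the 'png' package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * 255)
  } else {
    lab <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(lab) <- NULL
  }
  masks <- lapply(labels, function(v) lab == v)
  names(masks) <- names(labels)
  object_descriptor(tissues[names(labels)], masks)
}
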
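#' Construct a two-channel SRS image
#'
#' An SRS image holds two aligned nonnegative intensity grids measured at
#' Raman shifts of 2845 cm^-1 (the "CH2" channel, dominated by lipid CH2
#' bonds) and 2930 cm^-1 (the "CH3" channel, dominated by protein/DNA CH3
#' bonds), plus acquisition metadata.  Grids are numeric matrices, row-major
#' image convention: origin at the top-left, rows run down, columns right.
#'
#' @param image_id character scalar identifier.
#' @param ch2,ch3 numeric matrices of identical dimension with finite,
#'   nonnegative intensities.
#' @param pixel_size_nm pixel edge length in nanometres (default 467, the
#'   preset of the clinical SRS microscope this pipeline models).
#' @param scan_depth_um scan depth below the coverslip in micrometres
#'   (metadata only; default 10).
#' @return An object of class `srs_image`.
#' @export
srs_image <- function(image_id, ch2, ch3, pixel_size_nm = 467,
                      scan_depth_um = 10) {
  stopifnot(is.character(image_id), length(image_id) == 1)
  ch2 <- as.matrix(ch2); ch3 <- as.matrix(ch3)
  if (!all(dim(ch2) == dim(ch3))) {
    stop("channel dimension mismatch: ch2 is ", nrow(ch2), "x", ncol(ch2),
         ", ch3 is ", nrow(ch3), "x", ncol(ch3))
  }
  if (!all(is.finite(ch2)) || !all(is.finite(ch3))) {
    stop("intensities must be finite")
  }
  if (min(ch2) < 0 || min(ch3) < 0) stop("intensities must be >= 0")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  structure(
    list(image_id = image_id, ch2 = ch2, ch3 = ch3,
         pixel_size_nm = pixel_size_nm, scan_depth_um = scan_depth_um),
    class = "srs_image"
  )
}

#' @export
print.srs_image <- function(x, ...) {
  cat(sprintf("<srs_image '%s'> %d x %d px, pixel %g nm, depth %g um\n",
              x$image_id, nrow(x$ch2), ncol(x$ch2), x$pixel_size_nm,
              x$scan_depth_um))
  invisible(x)
}

#' @export
dim.srs_image <- function(x) dim(x$ch2)

#' Build the three-channel learning tensor from an SRS image
#'
#' CNN backbones expect three input planes; plane 1 carries CH2, plane 2
#' CH3, and plane 3 the per-pixel spectral difference CH3 - CH2 (signed:
#' lipid-dominant tissue such as adipose has CH2 > CH3, and clipping the
#' difference at zero would erase that contrast).
#'
#' @param img an [srs_image].
#' @return An object of class `three_channel_image` with matrices `plane1`,
#'   `plane2`, `plane3`.
#' @export
build_three_channel <- function(img) {
  stopifnot(inherits(img, "srs_image"))
  structure(
    list(image_id = img$image_id, plane1 = img$ch2, plane2 = img$ch3,
         plane3 = img$ch3 - img$ch2),
    class = "three_channel_image"
  )
}

#' Scale a three-channel tensor into [0, 1] for model input
#'
#' @param t a `three_channel_image`.
#' @param strategy `"per_channel_minmax"` (default) rescales each plane by
#'   its own min/max, removing per-acquisition gain differences;
#'   `"global_fixed_range"` maps a fixed intensity range (default
#'   `c(-1, 1)`, covering the signed difference plane) identically for all
#'   planes, clipping outside values; `"min_subtract_fixed_range"`
#'   subtracts each plane's minimum (dark-level / acquisition-offset
#'   correction) and then divides by the fixed range width, so absolute
#'   contrast between tissue classes is preserved while per-image offsets
#'   are removed.
#' @param range numeric length-2 range for the fixed-range strategies.
#' @return A `three_channel_image` with all planes in `[0, 1]`.  A constant
#'   plane maps to all zeros.
#' @export
normalize_for_model <- function(t, strategy = c("per_channel_minmax",
                                                "global_fixed_range",
                                                "min_subtract_fixed_range"),
                                range = c(-1, 1)) {
  stopifnot(inherits(t, "three_channel_image"))
  strategy <- match.arg(strategy)
  scale1 <- function(p) {
    if (strategy == "per_channel_minmax") {
      lo <- min(p); hi <- max(p)
      if (hi == lo) return(p * 0)
      (p - lo) / (hi - lo)
    } else if (strategy == "min_subtract_fixed_range") {
      pmin(pmax((p - min(p)) / (range[2] - range[1]), 0), 1)
    } else {
      lo <- range[1]; hi <- range[2]
      pmin(pmax((p - lo) / (hi - lo), 0), 1)
    }
  }
  t$plane1 <- scale1(t$plane1)
  t$plane2 <- scale1(t$plane2)
  t$plane3 <- scale1(t$plane3)
  t
}

#' Default parameters of the virtual-H&E look-up table
#'
#' The clinical instrument renders two-channel SRS data through a
#' proprietary look-up table into images resembling H&E-stained sections.
#' This package uses a fully documented stand-in: Beer-Lambert two-dye
#' color mixing in optical-density space.  CH3 signal (protein/DNA, i.e.
#' nuclei) absorbs with a hematoxylin-like optical-density triple, CH2
#' signal (lipid/cytoplasm) with an eosin-like one, and zero signal leaves
#' the white background.
#'
#' @param hematoxylin_od,eosin_od RGB optical densities of the two
#'   endmember dyes (defaults are the standard H&E stain vectors used in
#'   color deconvolution).
#' @param gain_h,gain_e scalar gains applied to CH3 and CH2 before mixing.
#' @return A named list of LUT parameters.
#' @export
srh_lut_params <- function(hematoxylin_od = c(0.65, 0.70, 0.29),
                           eosin_od = c(0.07, 0.99, 0.11),
                           gain_h = 2.0, gain_e = 1.2) {
  list(hematoxylin_od = hematoxylin_od, eosin_od = eosin_od,
       gain_h = gain_h, gain_e = gain_e)
}

#' Render a virtual-H&E (SRH) image from a two-channel SRS image
#'
#' Deterministic per-pixel mapping
#' `rgb = exp(-(gain_h * ch3 * od_h + gain_e * ch2 * od_e))`:
#' pixels dominated by CH3 render toward hematoxylin purple, pixels
#' dominated by CH2 toward eosin pink, and pixels with no signal stay
#' white.  Increasing CH3 at fixed CH2 monotonically deepens the
#' hematoxylin contribution (never reduces purple saturation).
#'
#' @param img an [srs_image] with intensities in `[0, 1]`.
#' @param lut_params parameters from [srh_lut_params()].
#' @return An object of class `srh_image` with an `rgb` array
#'   (height x width x 3, values in `[0, 1]`) and the `lut_params` used.
#' @export
render_srh <- function(img, lut_params = srh_lut_params()) {
  stopifnot(inherits(img, "srs_image"))
  h <- nrow(img$ch2); w <- ncol(img$ch2)
  rgb <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    od <- lut_params$gain_h * img$ch3 * lut_params$hematoxylin_od[k] +
      lut_params$gain_e * img$ch2 * lut_params$eosin_od[k]
    rgb[, , k] <- exp(-od)
  }
  structure(list(image_id = img$image_id, rgb = rgb,
                 lut_params = lut_params),
            class = "srh_image")
}

#' Read / write two-channel SRS TIFF files
#'
#' SRS images are stored as two-directory 16-bit TIFFs (directory 1 = CH2,
#' directory 2 = CH3, intensities on the `[0, 1]` scale quantized to the
#' 1/65535 grid so the round trip is bit-exact) with a JSON metadata
#' sidecar (`<path>.json`) holding `image_id`, `pixel_size_nm` and
#' `scan_depth_um`.
#'
#' @param path TIFF file path.
#' @return `read_srs_tiff` returns an [srs_image]; `write_srs_tiff`
#'   invisibly returns `path`.
#' @export
read_srs_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read SRS TIFF: ", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 2) {
    stop("expected a 2-channel SRS TIFF (CH2, CH3) but found ",
         length(planes), " channel(s) in ", path)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)
  } else {
    list()
  }
  srs_image(
    image_id = meta$image_id %||% sub("\\.tiff?$", "", basename(path)),
    ch2 = planes[[1]], ch3 = planes[[2]],
    pixel_size_nm = meta$pixel_size_nm %||% 467,
    scan_depth_um = meta$scan_depth_um %||% 10
  )
}

#' @rdname read_srs_tiff
#' @param img an [srs_image] with intensities in `[0, 1]`.
#' @export
write_srs_tiff <- function(img, path) {
  stopifnot(inherits(img, "srs_image"))
  if (max(img$ch2) > 1 || max(img$ch3) > 1) {
    stop("write_srs_tiff stores intensities on the [0, 1] scale; ",
         "normalize before writing")
  }
  tiff::writeTIFF(list(quantize16(img$ch2), quantize16(img$ch3)), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(image_id = img$image_id, pixel_size_nm = img$pixel_size_nm,
         scan_depth_um = img$scan_depth_um),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname read_srs_tiff
#' @param rgb an `srh_image` or a height x width x 3 array in `[0, 1]`.
#' @export
write_png <- function(rgb, path) {
  if (inherits(rgb, "srh_image")) rgb <- rgb$rgb
  png::writePNG(rgb, path)
  invisible(path)
}
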
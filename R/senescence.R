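# Canopy senescence scoring: pixels are classified green vs yellow/brown by
# proximity to reference shades in YCbCr chroma space; the white photo
# background is excluded first.  Distances use (Cb, Cr) only, which makes
# the classification robust to brightness (luma) variation.

# ITU-R BT.601 full-range RGB (0..255) <-> YCbCr
rgbToYCbCr <- function(r, g, b) {
  list(Y  = 0.299 * r + 0.587 * g + 0.114 * b,
       Cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
       Cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b)
}

ycbcrToRGB <- function(Y, Cb, Cr) {
  list(r = Y + 1.402 * (Cr - 128),
       g = Y - 0.344136 * (Cb - 128) - 0.714136 * (Cr - 128),
       b = Y + 1.772 * (Cb - 128))
}

#' Reference-shade palette for canopy classification
#'
#' Green and yellow/brown reference shades (8-bit RGB triplets), the chroma
#' tolerance, and the white-background rule. A pixel is assigned to the
#' class of its nearest reference shade in (Cb, Cr) if that distance is at
#' most `tolerance`; otherwise it is background. Pixels satisfying the
#' white rule (high luma, near-neutral chroma) are background regardless.
#'
#' The shipped shades were chosen to span typical leaf greens and senescent
#' yellows/browns; they and every threshold are configurable, since such
#' reference values are camera- and scene-specific.
#'
#' @param green matrix of RGB rows (0-255) for green shades.
#' @param yellow matrix of RGB rows for yellow/brown shades.
#' @param tolerance maximum (Cb, Cr) Euclidean distance to a shade.
#' @param whiteY minimum luma of the white-background rule.
#' @param whiteChroma maximum |Cb-128| and |Cr-128| of the white rule.
#' @return a `ShadePalette` list.
#' @export
shadePalette <- function(green = NULL, yellow = NULL, tolerance = 20,
                         whiteY = 220, whiteChroma = 12) {
  if (is.null(green))
    green <- rbind(c(60, 120, 40), c(85, 150, 60), c(45, 95, 35),
                   c(110, 165, 85))
  if (is.null(yellow))
    yellow <- rbind(c(200, 180, 60), c(180, 150, 50), c(150, 110, 45),
                    c(120, 85, 40))
  stopifnot_arg(nrow(green) > 0 && nrow(yellow) > 0,
                "palettes must be non-empty")
  stopifnot_arg(tolerance >= 0, "tolerance must be >= 0")
  structure(list(green = green, yellow = yellow, tolerance = tolerance,
                 whiteY = whiteY, whiteChroma = whiteChroma),
            class = "ShadePalette")
}

# normalize an image argument to an h x w x 3 array on the 0..255 scale
.asRGB255 <- function(image) {
  stopifnot_arg(is.array(image) && length(dim(image)) == 3 &&
                  dim(image)[3] >= 3, "image must be an h x w x 3+ array")
  stopifnot_arg(prod(dim(image)[1:2]) > 0, "image is empty")
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) <= 1) img <- img * 255
  img
}

#' Classify canopy pixels into background, green and yellow/brown
#'
#' Converts the image to YCbCr (BT.601 full range), forces pixels matching
#' the white-background rule to background, and assigns every other pixel
#' to the class of its nearest palette shade in (Cb, Cr) when that distance
#' is within the tolerance, else to background.
#'
#' @param image numeric array `h x w x 3` (RGB, 0-1 or 0-255; an alpha
#'   channel is ignored).
#' @param palette a [shadePalette()].
#' @return integer matrix `h x w` with 0 = background, 1 = green,
#'   2 = yellow/brown.
#' @export
classifyPixels <- function(image, palette = shadePalette()) {
  img <- .asRGB255(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  yc <- rgbToYCbCr(as.vector(img[, , 1]), as.vector(img[, , 2]),
                   as.vector(img[, , 3]))
  shades <- rbind(palette$green, palette$yellow)
  cls <- rep(1:2, c(nrow(palette$green), nrow(palette$yellow)))
  sc <- rgbToYCbCr(shades[, 1], shades[, 2], shades[, 3])
  d2 <- outer(yc$Cb, sc$Cb, `-`)^2 + outer(yc$Cr, sc$Cr, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  lab <- ifelse(sqrt(d2[cbind(seq_along(nearest), nearest)]) <=
                  palette$tolerance, cls[nearest], 0L)
  white <- yc$Y >= palette$whiteY &
    abs(yc$Cb - 128) <= palette$whiteChroma &
    abs(yc$Cr - 128) <= palette$whiteChroma
  lab[white] <- 0L
  matrix(as.integer(lab), h, w)
}

#' Score a canopy image
#'
#' Leaf areas from [classifyPixels()]: the white background is excluded,
#' and the yellow/brown percentage is taken out of the total leaf area
#' (green + yellow/brown). An image with no leaf pixels gives a missing
#' fraction with a warning.
#'
#' @inheritParams classifyPixels
#' @return a [CanopyScore-class].
#' @export
canopyScore <- function(image, palette = shadePalette()) {
  lab <- classifyPixels(image, palette)
  green <- sum(lab == 1L); yellow <- sum(lab == 2L)
  total <- green + yellow
  frac <- if (total == 0) {
    warning("no leaf pixels found; yellow fraction undefined")
    NA_real_
  } else 100 * yellow / total
  new("CanopyScore", totalArea = total, greenArea = green,
      yellowArea = yellow, yellowFraction = frac)
}

#' Senescence increase between two photo dates
#'
#' The change in the yellow/brown percentage of the leaf area between an
#' earlier and a later photograph of the same plant (percent points;
#' positive = more senescent). Undefined scores propagate.
#'
#' @param scoreT1,scoreT2 [CanopyScore-class] objects for the earlier and
#'   later date.
#' @return numeric percent-point change `fraction(t2) - fraction(t1)`.
#' @export
senescenceChange <- function(scoreT1, scoreT2) {
  stopifnot_arg(is(scoreT1, "CanopyScore") && is(scoreT2, "CanopyScore"),
                "both arguments must be CanopyScore objects")
  scoreT2@yellowFraction - scoreT1@yellowFraction
}

#' Generate a synthetic canopy image with known ground truth
#'
#' Paints a leaf blob (pixels nearest the image centre) on a white
#' background. The outermost `yellowFractionOfLeaf` of the leaf pixels are
#' painted with yellow/brown palette shades, the rest with green shades;
#' optional Gaussian chroma noise (in Cb and Cr) is added before converting
#' back to 8-bit RGB. Pixel counts are exact by construction, so the truth
#' labels define the expected classification.
#'
#' @param width,height image size in pixels.
#' @param leafFraction fraction of image pixels that are leaf, in [0, 1].
#' @param yellowFractionOfLeaf fraction of leaf pixels that are
#'   yellow/brown, in [0, 1].
#' @param noiseSD standard deviation of the chroma noise (8-bit units).
#' @param seed integer seed.
#' @param palette a [shadePalette()] supplying the paint shades.
#' @return list with `image` (`h x w x 3` array, 0-255) and `labels`
#'   (truth matrix coded as in [classifyPixels()]).
#' @export
generateCanopyImage <- function(width, height, leafFraction,
                                yellowFractionOfLeaf, noiseSD = 0,
                                seed = 1L, palette = shadePalette()) {
  stopifnot_arg(leafFraction >= 0 && leafFraction <= 1 &&
                  yellowFractionOfLeaf >= 0 && yellowFractionOfLeaf <= 1,
                "fractions must be in [0, 1]")
  npix <- width * height
  nLeaf <- round(leafFraction * npix)
  nYellow <- round(yellowFractionOfLeaf * nLeaf)
  rowi <- rep(seq_len(height), width)
  coli <- rep(seq_len(width), each = height)
  d <- (rowi - (height + 1) / 2)^2 + (coli - (width + 1) / 2)^2
  ord <- order(d, rowi, coli)   # deterministic blob from the centre out
  labels <- integer(npix)
  leafIdx <- ord[seq_len(nLeaf)]
  labels[leafIdx] <- 1L
  if (nYellow > 0)
    labels[leafIdx[seq(nLeaf - nYellow + 1, nLeaf)]] <- 2L  # outer ring
  set.seed(deriveSeed(seed, 907))
  img <- matrix(255, npix, 3)
  for (k in 1:2) {
    shades <- if (k == 1) palette$green else palette$yellow
    ii <- which(labels == k)
    if (!length(ii)) next
    pick <- shades[sample.int(nrow(shades), length(ii), replace = TRUE), ,
                   drop = FALSE]
    img[ii, ] <- pick
  }
  if (noiseSD > 0) {
    ii <- which(labels > 0)
    yc <- rgbToYCbCr(img[ii, 1], img[ii, 2], img[ii, 3])
    yc$Cb <- yc$Cb + rnorm(length(ii), 0, noiseSD)
    yc$Cr <- yc$Cr + rnorm(length(ii), 0, noiseSD)
    rgb <- ycbcrToRGB(yc$Y, yc$Cb, yc$Cr)
    img[ii, ] <- cbind(rgb$r, rgb$g, rgb$b)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = array(img, dim = c(height, width, 3)),
       labels = matrix(labels, height, width))
}

#' Read and write canopy images and label rasters
#'
#' Thin wrappers over the png package: `readCanopyImage()` loads a PNG as
#' an `h x w x 3` RGB array on the 0-255 scale; `writeLabelImage()` saves a
#' label raster as a grayscale PNG (background black, green mid-gray,
#' yellow/brown white) for visual inspection.
#'
#' @param path PNG file path.
#' @param labels integer label matrix from [classifyPixels()].
#' @name canopy-io
NULL

#' @rdname canopy-io
#' @export
readCanopyImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  .asRGB255(img)
}

#' @rdname canopy-io
#' @export
writeLabelImage <- function(labels, path) {
  png::writePNG(labels / 2, path)
  invisible(path)
}
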
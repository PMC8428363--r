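#' Hematoxylin / DAB stain unmixing
#'
#' Optical-density color deconvolution for H-DAB immunohistochemistry.
#' Transmitted intensity follows Beer-Lambert absorption, so the per-channel
#' optical density `-log(I)` is a linear mix of the stain absorption spectra.
#' The standard published H-DAB vectors are used, with a third orthogonal
#' residual channel completing the basis.
#'
#' @name stainUnmixing
NULL

# unit-norm OD vectors (R, G, B)
stainVectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- pracmaFreeCross(h, d) # residual channel, orthogonal complement
  r <- r / sqrt(sum(r^2))
  cbind(hema = h, dab = d, res = r)
}

pracmaFreeCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Unmix an RGB raster into hematoxylin and DAB density channels
#'
#' @param img numeric array height x width x 3 with values in `(0, 1]`.
#' @return A list with matrices `hema`, `dab`, `res`: per-pixel stain
#'   densities (optical-density units; non-negative apart from noise).
#' @export
#' @examples
#' img <- array(0.9, dim = c(4, 4, 3))
#' ch <- stainChannels(img)
#' dim(ch$dab)
stainChannels <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  eps <- 1 / 255
  od <- -log(pmax(img, eps))
  m <- stainVectors()
  minv <- solve(m)
  h <- dim(img)[1]; w <- dim(img)[2]
  flat <- matrix(od, ncol = 3L) # (h*w) x 3, channels in columns
  amounts <- flat %*% t(minv)
  list(
    hema = matrix(amounts[, 1], h, w),
    dab = matrix(amounts[, 2], h, w),
    res = matrix(amounts[, 3], h, w)
  )
}

# Compose an RGB image from stain density maps (inverse of stainChannels).
composeStains <- function(hema, dab) {
  m <- stainVectors()
  h <- nrow(hema); w <- ncol(hema)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    img[, , ch] <- exp(-(hema * m[ch, "hema"] + dab * m[ch, "dab"]))
  }
  img[img > 1] <- 1
  img[img < 0] <- 0
  img
}
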
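# Decomposition filter banks. Coefficients are the standard orthogonal
# decomposition filters; coif1 is the default analysis wavelet.
wavelet_filters <- function(name = c("coif1", "haar")) {
  name <- match.arg(name)
  if (name == "coif1") {
    lo <- c(-0.015655728135791993, -0.07273261951252645,
            0.3848648468648578, 0.8525720202116004,
            0.3378976624574818, -0.07273261951252645)
  } else {
    lo <- c(1, 1) / sqrt(2)
  }
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) transform with symmetric boundary
#' extension; every sub-band has the same grid shape as the input. The
#' eight sub-bands are keyed `LLL` ... `HHH`, where the letters apply to
#' the (z, y, x) axes in that order (vendor convention), `L` = low-pass,
#' `H` = high-pass.
#'
#' @param volume an `image_volume` or 3D array.
#' @param wavelet `"coif1"` (default) or `"haar"`.
#' @return A named list of eight 3D arrays (class `wavelet_bank`).
#' @export
wavelet_decompose <- function(volume, wavelet = "coif1") {
  vox <- if (inherits(volume, "image_volume")) volume$voxels else volume
  d <- dim(vox)
  filt <- wavelet_filters(wavelet)
  if (any(d < 2))
    stop("degenerate axis (length < 2): axis ",
         paste(which(d < 2), collapse = ", "))
  keys <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bank <- lapply(keys, function(key) {
    letters3 <- strsplit(key, "")[[1]]  # (z, y, x)
    arr <- vox
    for (pos in 1:3) {
      axis <- 4L - pos  # z -> axis 3, y -> axis 2, x -> axis 1
      k <- if (letters3[pos] == "L") filt$lo else filt$hi
      arr <- cpp_conv_axis(arr, k, axis)
    }
    arr
  })
  names(bank) <- keys
  structure(bank, class = "wavelet_bank")
}
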
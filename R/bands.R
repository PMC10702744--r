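#' Canonical 17-channel EEG montage order
#'
#' The fixed channel order used throughout the package: six temporal
#' electrodes (FT7, FT8, T7, T8, TP7, TP8) followed by eleven posterior
#' electrodes. CPZ is the reference electrode and is never part of the
#' data channels.
#'
#' @return Character vector of 17 channel names in canonical order.
#' @export
canonical_channels <- function() {
  c("FT7", "FT8", "T7", "T8", "TP7", "TP8",
    "CP1", "CP2", "P1", "PZ", "P2",
    "PO3", "POZ", "PO4", "O1", "OZ", "O2")
}

#' Frequency band schemes for differential-entropy extraction
#'
#' Two schemes are built in. `"5band"` is the classical rhythm
#' decomposition: delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz,
#' gamma 31-50 Hz (closed intervals). `"2Hz"` divides 1-50 Hz into 25
#' contiguous 2-Hz bands \eqn{[k, k+2)} for odd k from 1 to 49; the last band
#' is truncated at 50 Hz so the scheme covers exactly the same range as the
#' rhythm bands.
#'
#' @param name `"5band"` or `"2Hz"`.
#' @return An object of class `band_scheme`: a list with `name`, and `bands`,
#'   an n x 2 matrix of (low, high) edges in Hz, plus `right_closed`, a
#'   logical vector saying whether each band includes its upper edge.
#' @export
band_scheme <- function(name = c("5band", "2Hz")) {
  name <- match.arg(name)
  if (name == "5band") {
    bands <- rbind(
      delta = c(1, 3), theta = c(4, 7), alpha = c(8, 13),
      beta = c(14, 30), gamma = c(31, 50)
    )
    right_closed <- rep(TRUE, 5L)
  } else {
    lows <- seq(1, 49, by = 2)
    bands <- cbind(lows, pmin(lows + 2, 50))
    rownames(bands) <- sprintf("b%02d_%g_%gHz", seq_along(lows),
                               bands[, 1], bands[, 2])
    # half-open [low, high) except the final band, closed at 50 Hz
    right_closed <- c(rep(FALSE, 24L), TRUE)
  }
  colnames(bands) <- c("low", "high")
  structure(list(name = name, bands = bands, right_closed = right_closed),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("band_scheme '", x$name, "': ", nrow(x$bands), " bands, ",
      min(x$bands), "-", max(x$bands), " Hz\n", sep = "")
  invisible(x)
}

#' Band labels of the fused 30-band axis
#'
#' Fused differential-entropy tensors carry the 5 rhythm bands first and the
#' 25 uniform 2-Hz bands second.
#'
#' @return Character vector of length 30.
#' @export
fused_band_names <- function() {
  c(rownames(band_scheme("5band")$bands), rownames(band_scheme("2Hz")$bands))
}
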
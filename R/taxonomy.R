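#' WAB sub-band taxonomy
#'
#' The seven Gaussian sub-band classes of the Water Association Band, each
#' with a fixed frequency window and a hydrogen-bond-network attribution
#' running from strongly destructured (chaotropic environment, low
#' wavenumber) to strongly structured / ice-like (kosmotropic, high
#' wavenumber). Five classes (W0b, W1, W2a, W3, W4) are mandatory — they
#' occur in every sample — while the duplications W0a and W2b are optional
#' and only admitted when model selection warrants them.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (cm-1),
#'   `attribution`, `mandatory`.
#' @export
subband_classes <- function() {
  data.frame(
    name = c("W0a", "W0b", "W1", "W2a", "W2b", "W3", "W4"),
    lo   = c(2000, 2015, 2045, 2080, 2120, 2170, 2230),
    hi   = c(2010, 2035, 2065, 2120, 2160, 2200, 2270),
    attribution = c("strongly destructured", "strongly destructured",
                    "destructured", "weakly destructured (bulk-like)",
                    "weakly structured (bulk-like)", "structured",
                    "strongly structured (ice-like)"),
    mandatory = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Mandatory sub-band class names
#' @return Character vector `c("W0b", "W1", "W2a", "W3", "W4")`.
#' @export
mandatory_classes <- function() {
  cls <- subband_classes()
  cls$name[cls$mandatory]
}

#' Assign a peak center to a sub-band class
#'
#' Returns the class whose window contains `center`. The 2120 cm-1 boundary
#' shared by W2a and W2b is assigned to W2a by convention. Centers falling in
#' an inter-window gap are assigned to the nearest class with
#' `in_window = FALSE`; a gap-midpoint tie is broken toward the
#' lower-frequency class.
#'
#' @param center Peak frequency in cm-1, within `[2000, 2500]`.
#' @return A list with elements `name` and `in_window`.
#' @export
assign_band <- function(center) {
  stopifnot(is.numeric(center), length(center) == 1L)
  if (center < 2000 || center > 2500) {
    stop(sprintf("center %.1f cm-1 outside the WAB range [2000, 2500]",
                 center), call. = FALSE)
  }
  cls <- subband_classes()
  inside <- which(cls$lo <= center & center <= cls$hi)
  if (length(inside) > 0L) {
    # shared boundaries go to the lower-frequency class (2120 -> W2a)
    return(list(name = cls$name[inside[1]], in_window = TRUE))
  }
  dist <- pmin(abs(center - cls$lo), abs(center - cls$hi))
  list(name = cls$name[which.min(dist)], in_window = FALSE)
}
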
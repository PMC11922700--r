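#' Standard 32-channel 10-10 montage
#'
#' Returns the fixed 32-electrode layout used throughout the package: channel
#' labels from the international 10-10 system together with approximate 2-D
#' scalp coordinates on the unit disc (nose up, +y anterior, +x right). The
#' coordinates are used only to build spatial templates (ocular topographies,
#' oscillator gradients), never for source modelling.
#'
#' @return A `data.frame` with columns `label`, `x`, `y` and `group`
#'   (a coarse scalp region: frontal, frontocentral, central, centroparietal,
#'   parietal, occipital).
#' @export
#' @examples
#' m <- montage1010()
#' nrow(m)   # 32
montage1010 <- function() {
  tab <- rbind(
    c("Fp1", -0.31,  0.95, "frontal"),
    c("Fpz",  0.00,  1.00, "frontal"),
    c("Fp2",  0.31,  0.95, "frontal"),
    c("F7",  -0.81,  0.59, "frontal"),
    c("F3",  -0.37,  0.52, "frontal"),
    c("Fz",   0.00,  0.50, "frontal"),
    c("F4",   0.37,  0.52, "frontal"),
    c("F8",   0.81,  0.59, "frontal"),
    c("FC5", -0.69,  0.28, "frontocentral"),
    c("FC1", -0.21,  0.26, "frontocentral"),
    c("FC2",  0.21,  0.26, "frontocentral"),
    c("FC6",  0.69,  0.28, "frontocentral"),
    c("T7",  -1.00,  0.00, "central"),
    c("C3",  -0.50,  0.00, "central"),
    c("Cz",   0.00,  0.00, "central"),
    c("C4",   0.50,  0.00, "central"),
    c("T8",   1.00,  0.00, "central"),
    c("CP5", -0.69, -0.28, "centroparietal"),
    c("CP1", -0.21, -0.26, "centroparietal"),
    c("CP2",  0.21, -0.26, "centroparietal"),
    c("CP6",  0.69, -0.28, "centroparietal"),
    c("P7",  -0.81, -0.59, "parietal"),
    c("P3",  -0.37, -0.52, "parietal"),
    c("Pz",   0.00, -0.50, "parietal"),
    c("P4",   0.37, -0.52, "parietal"),
    c("P8",   0.81, -0.59, "parietal"),
    c("PO3", -0.29, -0.75, "occipital"),
    c("POz",  0.00, -0.75, "occipital"),
    c("PO4",  0.29, -0.75, "occipital"),
    c("O1",  -0.31, -0.95, "occipital"),
    c("Oz",   0.00, -1.00, "occipital"),
    c("O2",   0.31, -0.95, "occipital")
  )
  data.frame(
    label = tab[, 1],
    x = as.numeric(tab[, 2]),
    y = as.numeric(tab[, 3]),
    group = tab[, 4],
    stringsAsFactors = FALSE
  )
}

#' Resolve a channel-group name to channel labels
#'
#' @param montage montage data.frame as returned by [montage1010()].
#' @param group a scalp-region name present in `montage$group`, `"all"`, or a
#'   character vector of explicit channel labels.
#' @return Character vector of channel labels.
#' @export
channelGroup <- function(montage, group) {
  if (length(group) == 1 && group == "all") return(montage$label)
  if (length(group) == 1 && group %in% montage$group) {
    return(montage$label[montage$group == group])
  }
  bad <- setdiff(group, montage$label)
  if (length(bad)) {
    stop("Unknown channel group or labels: ", paste(bad, collapse = ", "))
  }
  group
}

#' Canonical ocular topography templates
#'
#' Two unit-normalised spatial patterns over the montage used both to inject
#' synthetic ocular artifacts and to match independent components for
#' rejection: a vertical eye-movement / blink pattern (frontal-polar maximum,
#' decaying with distance from the eyes) and a horizontal saccade pattern
#' (left/right antisymmetric, lateral-frontal maximum).
#'
#' @param montage montage data.frame.
#' @param threshold absolute spatial correlation in (0,1) above which an
#'   independent component is declared ocular.
#' @return List with unit-norm numeric vectors `vertical`, `horizontal` (one
#'   entry per channel) and the scalar `threshold`.
#' @export
ocularTemplates <- function(montage = montage1010(), threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  d2 <- montage$x^2 + (montage$y - 1.05)^2
  vertical <- exp(-d2 / (2 * 0.45^2))
  horizontal <- montage$x * exp(-(montage$y - 0.75)^2 / (2 * 0.45^2))
  vertical <- vertical / sqrt(sum(vertical^2))
  horizontal <- horizontal / sqrt(sum(horizontal^2))
  names(vertical) <- names(horizontal) <- montage$label
  list(vertical = vertical, horizontal = horizontal, threshold = threshold)
}
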
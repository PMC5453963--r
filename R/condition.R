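#' Structural body size as the first principal component
#'
#' PC1 of the standardized morphometric matrix (wing, tarsus, culmen, gonys
#' height), used as the structural-size axis. The correlation (standardized)
#' matrix is used because the measurements are on different scales. The sign
#' is fixed so larger wings give larger scores.
#'
#' @param morpho data.frame with columns `wing`, `tarsus`, `culmen`,
#'   `gonys` (mm); rows with missing measurements are excluded with a
#'   warning.
#' @return numeric PC1 score per bird (NA for excluded rows), with the
#'   proportion of variance explained as attribute `"var_explained"`.
#' @export
body_size_pc1 <- function(morpho) {
  cols <- c("wing", "tarsus", "culmen", "gonys")
  stopifnot(all(cols %in% names(morpho)))
  M <- as.matrix(morpho[, cols])
  ok <- stats::complete.cases(M)
  if (sum(ok) < 3) stop("need at least 3 complete birds for a PCA")
  if (any(!ok)) warning(sum(!ok), " birds with missing measurements excluded")
  pc <- stats::prcomp(M[ok, , drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  if (stats::cor(scores, M[ok, "wing"]) < 0) scores <- -scores
  out <- rep(NA_real_, nrow(morpho))
  out[ok] <- scores
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Body condition index: mass-on-size residuals
#'
#' Ordinary least-squares regression of body mass on the PC1 structural-size
#' score, pooled across sexes and years (one common size-mass line); the
#' BCI is the residual in grams, an index of energetic reserves.
#'
#' @param mass body mass at capture (g).
#' @param pc1 structural-size scores from [body_size_pc1()].
#' @return numeric BCI per bird (NA where mass or score is missing).
#' @export
bci <- function(mass, pc1) {
  ok <- is.finite(mass) & is.finite(pc1)
  if (sum(ok) < 3) stop("need at least 3 birds to fit the size-mass line")
  fit <- stats::lm(mass[ok] ~ pc1[ok])
  out <- rep(NA_real_, length(mass))
  out[ok] <- stats::resid(fit)
  out
}

#' Mass gain per day at sea
#'
#' (recapture mass - capture mass) / trip duration in days.
#'
#' @param mass_capture,mass_recapture masses (g).
#' @param duration_days trip duration (days, positive).
#' @return g per day.
#' @export
mass_gain_per_day <- function(mass_capture, mass_recapture, duration_days) {
  if (any(duration_days <= 0, na.rm = TRUE))
    stop("trip duration must be positive")
  (mass_recapture - mass_capture) / duration_days
}
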
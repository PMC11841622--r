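## Polarimetry: forward model and inversion between four polarized intensity
## components and the dipole orientation (theta, phi), wobble-cone correction,
## inter-state angles, and rotation into the molecule-local frame.
## Angles are degrees at the interface, radians internally.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Wobble-cone order parameter
#'
#' Fast restricted rotation of the fluorophore within a half-cone of angle
#' \code{delta} attenuates the polarized modulation of the four channels by an
#' order parameter \eqn{S(\delta) = \cos\delta (1 + \cos\delta) / 2}, the
#' standard wobble-in-cone second-rank factor.  \eqn{S(0) = 1} and S decreases
#' monotonically with delta.
#'
#' @param delta wobble half-cone angle in degrees, in [0, 54.7).
#' @return order parameter in (0, 1].
#' @export
orderParameter <- function(delta) {
  stopifnot(all(delta >= 0), all(delta < 54.7))
  cd <- cos(.deg2rad(delta))
  cd * (1 + cd) / 2
}

#' Expected polarized intensity components for a dipole orientation
#'
#' Forward model consistent with the intensity-ratio inversion used by
#' \code{\link{estimateAngles}}: for total intensity \eqn{I_{tot}} and order
#' parameter \eqn{S(\delta)},
#' \deqn{I_0 = \frac{I_{tot}}{4}(1 + S \sin\theta \cos 2\phi),\quad
#'       I_{90} = \frac{I_{tot}}{4}(1 - S \sin\theta \cos 2\phi),}
#' \deqn{I_{45} = \frac{I_{tot}}{4}(1 + S \sin\theta \sin 2\phi),\quad
#'       I_{135} = \frac{I_{tot}}{4}(1 - S \sin\theta \sin 2\phi).}
#' The four components always sum to \code{itot}.
#'
#' @param theta inclination angle(s), degrees in [0, 90].
#' @param phi rotation angle(s), degrees in (-90, 90].
#' @param delta wobble half-cone angle, degrees.
#' @param itot total intensity (counts/frame), >= 0.
#' @return matrix with columns I0, I45, I90, I135.
#' @export
forwardIntensities <- function(theta, phi, delta = 0, itot = 1) {
  stopifnot(all(itot >= 0))
  S <- orderParameter(delta)
  th <- .deg2rad(theta); ph <- .deg2rad(phi)
  a <- S * sin(th) * cos(2 * ph)
  b <- S * sin(th) * sin(2 * ph)
  out <- cbind(I0 = (1 + a), I45 = (1 + b), I90 = (1 - a), I135 = (1 - b)) *
    itot / 4
  out
}

#' Estimate dipole orientation from four polarized intensity components
#'
#' Inverts the forward model:
#' \eqn{\phi = \frac{1}{2}\,\mathrm{atan2}(I_{45}-I_{135},\, I_0-I_{90})} and
#' \eqn{\sin\theta_{app} = 2\sqrt{(I_0-I_{90})^2 + (I_{45}-I_{135})^2} /
#' (I_0+I_{45}+I_{90}+I_{135})}, followed by the wobble correction
#' \eqn{\theta = \arcsin(\min(1, \sin\theta_{app}/S(\delta)))}.  Both angles
#' depend only on intensity ratios, so the estimate is invariant to scaling
#' all four inputs by a constant.
#'
#' @param i0,i45,i90,i135 intensity components (counts); raw counts if
#'   \code{cal} carries gains/backgrounds, corrected intensities otherwise.
#' @param cal a \linkS4class{Calibration}; gains and backgrounds are applied
#'   as \code{(I - background) / gain} before inversion, and \code{cal@delta}
#'   sets the order parameter.
#' @return data.frame with columns \code{theta}, \code{phi} (degrees) and
#'   \code{flag} (\code{"ok"}, \code{"degenerate"} for an undefined phi at
#'   theta = 0, or \code{"clipped"} when the apparent \eqn{\sin\theta}
#'   exceeds S(delta)).
#' @export
estimateAngles <- function(i0, i45, i90, i135, cal = Calibration()) {
  g <- cal@gains; b <- cal@backgrounds
  i0 <- (i0 - b[1]) / g[1]; i45 <- (i45 - b[2]) / g[2]
  i90 <- (i90 - b[3]) / g[3]; i135 <- (i135 - b[4]) / g[4]
  tot <- i0 + i45 + i90 + i135
  if (any(tot <= 0))
    stop("undefined orientation: corrected total intensity is not positive")
  dx <- i0 - i90; dy <- i45 - i135
  r <- 2 * sqrt(dx^2 + dy^2) / tot
  S <- orderParameter(cal@delta)
  flag <- rep("ok", length(tot))
  degen <- (dx == 0 & dy == 0)
  phi <- ifelse(degen, 0, .rad2deg(atan2(dy, dx) / 2))
  flag[degen] <- "degenerate"
  sth <- r / S
  clip <- sth > 1
  flag[clip & !degen] <- "clipped"
  theta <- .rad2deg(asin(pmin(1, sth)))
  ## phi convention (-90, 90]
  phi[phi <= -90] <- phi[phi <= -90] + 180
  data.frame(theta = theta, phi = phi, flag = flag, stringsAsFactors = FALSE)
}

#' Direct angle between two dipole orientations
#'
#' Geodesic angle between two orientation axes, folded to [0, 90] degrees by
#' the line symmetry of the dipole:
#' \eqn{\Omega = \arccos|\cos\theta_a\cos\theta_b +
#' \sin\theta_a\sin\theta_b\cos(\phi_a-\phi_b)|}.
#'
#' @param thetaA,phiA,thetaB,phiB orientation angles in degrees (vectorized).
#' @return angle(s) Omega in degrees, in [0, 90].
#' @export
omegaAngle <- function(thetaA, phiA, thetaB, phiB) {
  ta <- .deg2rad(thetaA); tb <- .deg2rad(thetaB)
  dph <- .deg2rad(phiA - phiB)
  c <- cos(ta) * cos(tb) + sin(ta) * sin(tb) * cos(dph)
  .rad2deg(acos(pmin(1, abs(c))))
}

#' Convert orientation angles to Cartesian unit vectors
#'
#' Inclination theta is measured from the z axis and rotation phi in the x-y
#' plane: \code{x = sin(theta) cos(phi)}, \code{y = sin(theta) sin(phi)},
#' \code{z = cos(theta)}.
#'
#' @param theta,phi angles in degrees.
#' @return n x 3 matrix of unit vectors.
#' @export
anglesToVec <- function(theta, phi) {
  th <- .deg2rad(theta); ph <- .deg2rad(phi)
  cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

#' Convert unit vectors to canonical orientation angles
#'
#' Folds each axis into the canonical quarter-sphere implied by the intensity
#' measurement (theta in [0, 90], phi in (-90, 90]): the dipole is a line, so
#' v and -v are identified, and the polarized components determine phi only
#' modulo 180 degrees.
#'
#' @param v n x 3 matrix of vectors (not necessarily normalized).
#' @return data.frame with columns theta, phi (degrees).
#' @export
vecToAngles <- function(v) {
  v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  v <- v / n
  flip <- v[, 3] < 0
  v[flip, ] <- -v[flip, ]
  theta <- .rad2deg(acos(pmin(1, pmax(-1, v[, 3]))))
  phi <- .rad2deg(atan2(v[, 2], v[, 1]))
  hi <- !is.na(phi) & phi > 90
  lo <- !is.na(phi) & phi <= -90
  phi[hi] <- phi[hi] - 180
  phi[lo] <- phi[lo] + 180
  data.frame(theta = theta, phi = phi)
}

#' Rotate orientation vectors into the molecule-local frame
#'
#' The local frame is defined by the mean orientations of two reference
#' states: the local x axis is the mean of the first reference state (so its
#' mean phi becomes 0 and mean theta 90 degrees) and the local x-y plane is
#' spanned by the two reference means (so the second reference also maps to
#' theta = 90), with the sign of the z axis chosen so that the second
#' reference's phi is positive.
#'
#' @param vectors n x 3 matrix of orientation vectors.
#' @param c1Mean,c4Mean reference mean orientation vectors (length 3); must
#'   not be (anti)parallel.
#' @return list with \code{vectors} (rotated n x 3 matrix, same norms),
#'   \code{rotation} (3 x 3 matrix whose rows are the local axes) and
#'   \code{angles} (canonical theta/phi of the rotated vectors).
#' @export
toLocalFrame <- function(vectors, c1Mean, c4Mean) {
  c1 <- c1Mean / sqrt(sum(c1Mean^2))
  c4 <- c4Mean / sqrt(sum(c4Mean^2))
  zraw <- c(c1[2] * c4[3] - c1[3] * c4[2],
            c1[3] * c4[1] - c1[1] * c4[3],
            c1[1] * c4[2] - c1[2] * c4[1])
  nz <- sqrt(sum(zraw^2))
  if (nz < 1e-12)
    stop("degenerate reference means: C1 and C4 are (anti)parallel")
  zax <- zraw / nz
  yax <- c(zax[2] * c1[3] - zax[3] * c1[2],
           zax[3] * c1[1] - zax[1] * c1[3],
           zax[1] * c1[2] - zax[2] * c1[1])
  ## sign convention: the second reference state has positive local phi
  if (sum(yax * c4) < 0) {
    zax <- -zax
    yax <- -yax
  }
  R <- rbind(x = c1, y = yax, z = zax)
  vectors <- matrix(vectors, ncol = 3)
  rotated <- vectors %*% t(R)
  colnames(rotated) <- c("x", "y", "z")
  list(vectors = rotated, rotation = R, angles = vecToAngles(rotated))
}
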
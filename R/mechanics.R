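#' Material constructor
#'
#' @param mu shear modulus (Pa).
#' @param bulkPenalty volumetric penalty modulus (Pa); at least 50 mu so the
#'   effective Poisson ratio stays near-incompressible.
#' @param stiffnessSchedule function of the growth fraction in [0, 1]
#'   returning the special-area stiffness multiplier; must start at 1 and be
#'   non-decreasing.  The default is the identity-at-start linear ramp to 1
#'   (no stiffening).
#' @return a \linkS4class{Material}
#' @export
material <- function(mu = 330, bulkPenalty = 200 * mu,
                     stiffnessSchedule = function(f) 1) {
  new("Material", mu = mu, bulkPenalty = bulkPenalty,
      stiffnessSchedule = stiffnessSchedule)
}

#' Linear stiffness ramp for the stiff special area
#'
#' Multiplier interpolated linearly in the growth fraction from 1 at the
#' start of growth to \code{final} at full growth.
#'
#' @param final final stiffness multiplier (e.g. 2, 4 or 8).
#' @return a function usable as \code{stiffnessSchedule}
#' @export
stiffnessRamp <- function(final) {
  force(final)
  function(f) 1 + (final - 1) * max(0, min(1, f))
}

#' Isotropic growth tensor
#'
#' G = g I: the identity scaled by the growth multiplier, so growth is equal
#' in all directions and det G = g^d.
#'
#' @param g growth multiplier, >= 1 (resorption is not modelled).
#' @param dim spatial dimension of the kinematic model (2 or 3).
#' @return a dim x dim matrix
#' @examples
#' growthTensor(1.2)          # diag(1.2, 1.2, 1.2), det 1.728
#' det(growthTensor(2, 2))    # 4
#' @export
growthTensor <- function(g, dim = 3L) {
  if (g < 1) stop("growth multiplier must be >= 1 (resorption not modelled)")
  diag(g, dim)
}

#' Elastic part of the deformation gradient
#'
#' Multiplicative split F = A G: the growth tensor G changes volume without
#' stress, the elastic tensor A = F G^-1 carries the stress.
#'
#' @param F total deformation gradient (d x d, det F > 0).
#' @param G growth tensor (d x d, det G > 0).
#' @return the elastic tensor A with A \%*\% G = F
#' @export
elasticTensor <- function(F, G) {
  if (det(F) <= 0) stop("det F must be positive")
  dG <- det(G)
  if (abs(dG) < 1e-300) stop("singular growth tensor")
  if (dG <= 0) stop("det G must be positive")
  F %*% solve(G)
}

#' Cauchy stress of the near-incompressible neo-Hookean solid
#'
#' Strain energy per unit grown volume
#' \deqn{W(A) = \mu/2 (\lambda_1^2 + ... + \lambda_d^2 - d - 2 \log J) +
#'       \kappa/2 (J - 1)^2, \quad J = \det A,}
#' whose deviatoric part is the classical neo-Hookean sum of squared
#' principal stretches and whose volumetric penalty replaces the exact
#' incompressibility Lagrange multiplier: the reported pressure term is
#' p = bulkPenalty (det A - 1).  The stress is
#' \deqn{\sigma = \mu (B - I)/J + p I, \quad B = A A^T.}
#'
#' @param A elastic tensor (2x2 or 3x3, det A > 0).
#' @param mat a \linkS4class{Material} (or list with mu, bulkPenalty).
#' @return list with \code{sigma} (symmetric stress matrix, Pa), \code{p}
#'   (penalty pressure, Pa), \code{W} (strain energy density, Pa) and
#'   \code{lambdas} (principal elastic stretches).
#' @examples
#' cauchyStress(diag(2), material())$sigma   # zero at A = I
#' @export
cauchyStress <- function(A, mat = material()) {
  d <- nrow(A)
  J <- det(A)
  if (J <= 0) stop("element inversion: det A must be positive")
  mu <- mat@mu; K <- mat@bulkPenalty
  B <- A %*% t(A)
  p <- K * (J - 1)
  sigma <- mu * (B - diag(d)) / J + p * diag(d)
  sigma <- (sigma + t(sigma)) / 2
  lam <- sqrt(pmax(eigen(B, symmetric = TRUE, only.values = TRUE)$values, 0))
  W <- mu / 2 * (sum(lam^2) - d - 2 * log(J)) + K / 2 * (J - 1)^2
  list(sigma = sigma, p = p, W = W, lambdas = lam)
}
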
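#' Carotid stiffness panel from diameters and pressures
#'
#' Computes the five stiffness-related metrics from the systolic/diastolic
#' diameter pair and the brachial pressure pair:
#' \deqn{RDC = (D_s - D_d)/D_d \times 100\ (\%)}
#' \deqn{\beta = \ln(P_s/P_d) / ((D_s - D_d)/D_d)}
#' \deqn{AC = \pi (D_s^2 - D_d^2) / (4 (P_s - P_d))\ (mm^2/kPa)}
#' \deqn{PWV = \sqrt{\beta P_s / (2\rho)}\ (m/s)}
#' \deqn{E = (P_s - P_d) / ((D_s - D_d)/D_d)\ (kPa)}
#' Pressures enter beta as a unit-free ratio; AC and E convert the pulse
#' pressure to kPa and PWV converts the systolic pressure to Pa
#' (1 mmHg = 133.322 Pa).
#'
#' @param dSmm,dDmm systolic and diastolic diameter, mm (dS >= dD > 0).
#' @param pressures a \linkS4class{PressurePair} (mmHg).
#' @param rho blood density, kg/m^3 (default 1050, body temperature).
#' @param side label ("LC", "RC", "average").
#' @return a \linkS4class{StiffnessPanel}.
#' @examples
#' p <- new("PressurePair", pS = 113, pD = 63)
#' stiffnessPanel(6.4, 5.5, p)  # RDC 16.364 %, beta 3.571, PWV 5.06 m/s, ...
#' @export
stiffnessPanel <- function(dSmm, dDmm, pressures, rho = 1050, side = "LC") {
  .assertScalar(dSmm, "dSmm", positive = TRUE)
  .assertScalar(dDmm, "dDmm", positive = TRUE)
  if (dSmm < dDmm) stop("dSmm must be >= dDmm")
  validObject(pressures)
  pS <- pressures@pS; pD <- pressures@pD
  strain <- (dSmm - dDmm) / dDmm
  if (strain == 0)
    stop("zero strain (dS = dD): the stiffness index and elastic modulus ",
         "are undefined (RDC would be 0, AC 0)")
  dpKpa <- (pS - pD) * MMHG_TO_PA / 1000
  rdc <- strain * 100
  beta <- log(pS / pD) / strain
  ac <- pi * (dSmm^2 - dDmm^2) / (4 * dpKpa)
  pwv <- sqrt(beta * pS * MMHG_TO_PA / (2 * rho))
  emod <- dpKpa / strain
  new("StiffnessPanel", rdc = rdc, beta = beta, ac = ac, pwv = pwv,
      emod = emod, side = side, pressures = pressures, rho = rho)
}

#' Average the stiffness panels of the two sides
#'
#' Metric-level arithmetic mean of the left and right panels (the panels
#' must share pressures and blood density).
#'
#' @param left,right \linkS4class{StiffnessPanel}s.
#' @return a \linkS4class{StiffnessPanel} with side "average".
#' @export
averageSides <- function(left, right) {
  if (!isTRUE(all.equal(c(left@pressures@pS, left@pressures@pD, left@rho),
                        c(right@pressures@pS, right@pressures@pD,
                          right@rho))))
    stop("panels must share pressures and blood density")
  new("StiffnessPanel",
      rdc = (left@rdc + right@rdc) / 2,
      beta = (left@beta + right@beta) / 2,
      ac = (left@ac + right@ac) / 2,
      pwv = (left@pwv + right@pwv) / 2,
      emod = (left@emod + right@emod) / 2,
      side = "average", pressures = left@pressures, rho = left@rho)
}

#' Stiffness panels as a data frame
#'
#' One row per panel with diameters omitted (they live on the measurement
#' objects); convenient for the cohort CSV outputs.
#'
#' @param ... \linkS4class{StiffnessPanel}s (or a list of them).
#' @return data.frame with side, rdc, beta, ac, pwv, emod, p_s, p_d, rho.
#' @export
panelTable <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !is(panels[[1]], "StiffnessPanel"))
    panels <- panels[[1]]
  do.call(rbind, lapply(panels, function(p)
    data.frame(side = p@side, rdc = p@rdc, beta = p@beta, ac = p@ac,
               pwv = p@pwv, emod = p@emod, p_s = p@pressures@pS,
               p_d = p@pressures@pD, rho = p@rho)))
}
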
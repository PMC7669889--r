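## Michaelis-Menten model evaluation and fitting, and the isomerase
## equilibrium calculation used for assay design.

#' Kinetic parameters
#'
#' @param kcat turnover number, 1/s.
#' @param km Michaelis constant, mM.
#' @param kcat_se,km_se standard errors.
#' @param enzyme_conc assay enzyme concentration, uM (metadata).
#' @return a validated list.
#' @export
kineticParams <- function(kcat, km, kcat_se = NA_real_, km_se = NA_real_,
                          enzyme_conc = NA_real_) {
  stopifnot(kcat > 0, km > 0)
  list(kcat = kcat, km = km, kcat_se = kcat_se, km_se = km_se,
       enzyme_conc = enzyme_conc)
}

#' Michaelis-Menten rate
#'
#' v = kcat * s / (km + s).
#'
#' @param s substrate concentration(s), mM (same unit as `km`).
#' @param params a [kineticParams()].
#' @return rate(s), same unit as `kcat`.
#' @export
#' @examples
#' mmRate(0.9, kineticParams(kcat = 4.7, km = 0.9))  # half-saturation
mmRate <- function(s, params) {
  stopifnot(all(s >= 0))
  params$kcat * s / (params$km + s)
}

#' Fit the Michaelis-Menten model to assay data
#'
#' Nonlinear least squares (Levenberg-Marquardt) with deterministic
#' initialization: kcat from the maximal observed rate, km from the
#' substrate concentration nearest half-maximal rate.  Standard errors come
#' from the parameter covariance of the fit.
#'
#' @param data data.frame with columns `substrate_mM` and `rate`.
#' @param weighting `"none"` (default) or `"inv_v2"` (weights 1/v^2).
#' @return a [kineticParams()] with standard errors filled in.
#' @export
fitMm <- function(data, weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("substrate_mM", "rate") %in% names(data)))
  if (nrow(data) < 4)
    stop("need at least 4 assay points, got ", nrow(data), call. = FALSE)
  s <- data$substrate_mM; v <- data$rate
  if (length(unique(s)) < 2)
    stop("all substrate concentrations are equal; km is unidentifiable",
         call. = FALSE)
  kcat0 <- max(v)
  km0 <- s[which.min(abs(v - kcat0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s[s > 0])
  w <- if (weighting == "inv_v2") 1 / pmax(v, 1e-12)^2 else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ kcat * substrate_mM / (km + substrate_mM),
                      data = data, weights = w,
                      start = list(kcat = kcat0, km = km0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- summary(fit)$coefficients
  kineticParams(kcat = co["kcat", "Estimate"], km = co["km", "Estimate"],
                kcat_se = co["kcat", "Std. Error"],
                km_se = co["km", "Std. Error"])
}

#' Equilibrium Ru5P concentration of an isomerase-coupled assay
#'
#' An R5P pool pre-equilibrated by ribose-5-phosphate isomerase partitions
#' as Ru5P = total * Keq / (1 + Keq), with Keq the R5P -> Ru5P isomerization
#' equilibrium constant (0.458).
#'
#' @param r5pInitial initial ribose 5-phosphate, mM.
#' @param keq equilibrium constant (default 0.458).
#' @return equilibrium Ru5P concentration, mM.
#' @export
#' @examples
#' ru5pEquilibrium(16)   # approx 5.03 mM from a 16 mM R5P stock
ru5pEquilibrium <- function(r5pInitial, keq = 0.458) {
  stopifnot(r5pInitial > 0, keq > 0)
  r5pInitial * keq / (1 + keq)
}
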
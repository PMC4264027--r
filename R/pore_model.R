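#' Describe a nanopore geometry and measurement condition
#'
#' Bundles the quantities entering the conductance model: pore diameter,
#' effective (and optionally physical) membrane thickness, electrolyte
#' conductivity and applied bias. Geometry is in nm, conductivity in S/m,
#' bias in mV; with these units the model returns conductance directly in nS.
#'
#' @param diameter_nm Pore diameter d in nm (TEM estimate); must be > 0.
#' @param h_eff_nm Effective membrane thickness in nm; must be >= 0. Smaller
#'   than the physical thickness for hourglass-shaped pores.
#' @param sigma_S_per_m Electrolyte conductivity in S/m. Default 11.1,
#'   the value for 1 M KCl.
#' @param bias_mV Applied voltage in mV (may be `NA` when only conductance
#'   is needed).
#' @param h_phys_nm Deposited membrane thickness in nm, if known.
#' @return An object of class `pore_spec`.
#' @examples
#' pore_spec(diameter_nm = 1.5, h_eff_nm = 2.4)
#' @export
pore_spec <- function(diameter_nm, h_eff_nm, sigma_S_per_m = 11.1,
                      bias_mV = NA_real_, h_phys_nm = NA_real_) {
  if (!is.numeric(diameter_nm) || diameter_nm <= 0)
    stop("diameter_nm must be positive")
  if (!is.numeric(h_eff_nm) || h_eff_nm < 0)
    stop("h_eff_nm must be non-negative")
  if (!is.numeric(sigma_S_per_m) || sigma_S_per_m <= 0)
    stop("sigma_S_per_m must be positive")
  if (!is.na(h_phys_nm) && h_eff_nm > h_phys_nm)
    stop("h_eff_nm must not exceed h_phys_nm")
  structure(list(diameter_nm = diameter_nm, h_eff_nm = h_eff_nm,
                 sigma_S_per_m = sigma_S_per_m, bias_mV = bias_mV,
                 h_phys_nm = h_phys_nm),
            class = "pore_spec")
}

# closed form shared by pore_conductance() and the thickness fit;
# vectorised over d (nm) and h (nm); returns nS (S/m * nm == nS).
.conductance_nS <- function(d_nm, h_eff_nm, sigma_S_per_m) {
  sigma_S_per_m / (4 * h_eff_nm / (pi * d_nm^2) + 1 / d_nm)
}

#' Open-pore conductance from pore geometry
#'
#' Cylindrical-channel-plus-access-resistance model
#' \deqn{G = \sigma \left[\frac{4 h_{eff}}{\pi d^2} + \frac{1}{d}\right]^{-1}}
#' with the channel term vanishing as \eqn{h_{eff} \to 0}, leaving the
#' access-limited conductance \eqn{G = \sigma d}. The single formula lives
#' here so an alternative geometry model can be swapped in one place.
#'
#' @param spec A [pore_spec()].
#' @return Conductance in nS.
#' @examples
#' pore_conductance(pore_spec(1.4, 2.4))   # ~4.88 nS
#' @export
pore_conductance <- function(spec) {
  stopifnot(inherits(spec, "pore_spec"))
  .conductance_nS(spec$diameter_nm, spec$h_eff_nm, spec$sigma_S_per_m)
}

#' Open-pore current at the applied bias
#'
#' \eqn{I_0 = G V}: conductance from [pore_conductance()] times bias.
#'
#' @param spec A [pore_spec()] with `bias_mV` set.
#' @return Current in nA (nS * mV / 1000).
#' @export
open_pore_current <- function(spec) {
  stopifnot(inherits(spec, "pore_spec"))
  if (is.na(spec$bias_mV)) stop("bias_mV must be set")
  pore_conductance(spec) * spec$bias_mV / 1000
}

#' Fit the effective membrane thickness from conductance-vs-diameter data
#'
#' Unweighted nonlinear least squares of the conductance model over a set of
#' (diameter, conductance) points with the electrolyte conductivity held
#' fixed, estimating the one free parameter h_eff. The inverse model is
#' linear in h_eff, which supplies the starting value; the reported estimate
#' comes from least squares on conductance itself.
#'
#' @param points Data frame or matrix with columns diameter (nm) and
#'   conductance (nS); at least two points with distinct diameters.
#' @param sigma_S_per_m Electrolyte conductivity in S/m (default 11.1).
#' @return List with `h_eff_nm`, `rss` (residual sum of squares, nS^2),
#'   `fitted_nS`, and the `nls` fit object.
#' @examples
#' d <- 1:10
#' g <- pore_conductance(pore_spec(1, 0))  # access-only check
#' @export
fit_effective_thickness <- function(points, sigma_S_per_m = 11.1) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("d", "g")
  if (nrow(points) < 2) stop("insufficient data: need >= 2 points")
  if (anyDuplicated(points$d)) stop("diameters must be distinct")
  if (any(points$d <= 0) || any(points$g <= 0))
    stop("diameters and conductances must be positive")
  # inverse model: (sigma/g - 1/d) * pi d^2 / 4 = h_eff, exact when noiseless
  h0 <- mean((sigma_S_per_m / points$g - 1 / points$d) * pi * points$d^2 / 4)
  h0 <- max(h0, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ .conductance_nS(d, h, sigma_S_per_m),
                      data = points, start = list(h = h0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("effective-thickness fit failed: ",
                             conditionMessage(e)))
  list(h_eff_nm = unname(stats::coef(fit)[["h"]]),
       rss = sum(stats::resid(fit)^2),
       fitted_nS = stats::fitted(fit),
       fit = fit)
}

#' Dielectric loss description of a nanopore device
#'
#' @param temperature_K Absolute temperature in K.
#' @param loss_tangent Dielectric dissipation factor of the substrate
#'   (dimensionless; ~1e-4 for quartz).
#' @param c_eff_F Effective capacitance of the device in farad (membrane
#'   plus parasitic elements; ~70 pF for quartz, ~1600 pF for Si presets).
#' @return An object of class `dielectric_spec`.
#' @export
dielectric_spec <- function(temperature_K = 298, loss_tangent = 1e-4,
                            c_eff_F = 70e-12) {
  if (temperature_K <= 0) stop("temperature_K must be positive")
  if (loss_tangent < 0) stop("loss_tangent must be non-negative")
  if (c_eff_F < 0) stop("c_eff_F must be non-negative")
  structure(list(temperature_K = temperature_K, loss_tangent = loss_tangent,
                 c_eff_F = c_eff_F), class = "dielectric_spec")
}

#' Dielectric-noise PSD coefficient
#'
#' The coefficient multiplying frequency in the current-noise PSD of a lossy
#' dielectric, \eqn{S_D = 8 \pi k_B T D_{loss} C_{eff}}, in A^2/Hz^2.
#' Linear in each of temperature, loss tangent and capacitance.
#'
#' @param spec A [dielectric_spec()].
#' @return Coefficient in A^2/Hz^2.
#' @examples
#' dielectric_psd_coefficient(dielectric_spec(298, 1e-4, 70e-12))  # ~7.2e-34
#' @export
dielectric_psd_coefficient <- function(spec) {
  stopifnot(inherits(spec, "dielectric_spec"))
  kB <- 1.380649e-23
  8 * pi * kB * spec$temperature_K * spec$loss_tangent * spec$c_eff_F
}

#' Read a conductance-vs-diameter point set
#'
#' Two-column TSV (diameter_nm, conductance_nS); lines starting with `#`
#' are treated as comments.
#'
#' @param path File path.
#' @return Data frame with columns `diameter_nm`, `conductance_nS`.
#' @export
read_conductance_points <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#",
                          col.names = c("diameter_nm", "conductance_nS"))
  df
}
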
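# Dry heat loss per body region: radiative exchange plus forced convection.
#
# All public entry points take areas in mm^2 (as morphometrics produces them)
# and convert to m^2 at exactly one point (mm2_to_m2), so a silent 1e6 unit
# error cannot arise from mixing conventions between modules. Temperatures
# are degC everywhere; Kelvin appears only inside the radiative term.

MM2_PER_M2 <- 1e6
MM_PER_M <- 1e3

mm2_to_m2 <- function(area_mm2) area_mm2 / MM2_PER_M2

#' Radiative heat exchange
#'
#' \eqn{Q_r = \epsilon \sigma A (T_s^4 - T_a^4)} with temperatures in Kelvin.
#' Positive when the surface is warmer than the surroundings; a surface
#' colder than ambient gives a negative value (radiative gain), which is not
#' clamped.
#'
#' @param ts Surface temperature, degC.
#' @param ta Ambient (radiative environment) temperature, degC.
#' @param area Surface area in m^2.
#' @param emissivity Surface emissivity.
#' @param stefan_boltzmann Stefan-Boltzmann constant, W m^-2 K^-4.
#' @return Radiative heat flow in W.
#' @export
#' @examples
#' radiative_heat(30, 20, 1e-4) # ~0.0587 W
radiative_heat <- function(ts, ta, area, emissivity = 0.96,
                           stefan_boltzmann = 5.6703e-8) {
  check_positive(area, "area")
  emissivity * stefan_boltzmann * area *
    ((ts + C_TO_K)^4 - (ta + C_TO_K)^4)
}

#' Reynolds number
#'
#' \eqn{Re = V D / \nu} for air moving at velocity \eqn{V} past a body of
#' characteristic dimension \eqn{D}.
#'
#' @param velocity Air velocity, m/s.
#' @param d Characteristic dimension, m.
#' @param nu Kinematic viscosity of air, m^2/s.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(velocity, d, nu) {
  check_positive(nu, "nu")
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  velocity * d / nu
}

#' Nusselt number from the forced-convection power law
#'
#' \eqn{Nu = c Re^n} with region-specific empirical constants.
#'
#' @param re Reynolds number.
#' @param c,n Empirical constants for the body region.
#' @return Dimensionless Nusselt number.
#' @export
nusselt <- function(re, c, n) {
  if (any(re < 0)) stop("'re' must be non-negative", call. = FALSE)
  c * re^n
}

#' Convective heat-transfer coefficient
#'
#' \eqn{h_c = Nu \, k / D}.
#'
#' @param nu_number Nusselt number.
#' @param k Thermal conductivity of air, W m^-1 K^-1.
#' @param d Characteristic dimension, m (must be positive).
#' @return Heat-transfer coefficient in W m^-2 K^-1.
#' @export
convective_coefficient <- function(nu_number, k, d) {
  check_positive(d, "d")
  nu_number * k / d
}

#' Forced-convective heat exchange
#'
#' \eqn{Q_c = h_c A (T_s - T_a)}. Antisymmetric in the two temperatures; a
#' surface colder than the air yields negative heat loss.
#'
#' @param hc Heat-transfer coefficient, W m^-2 K^-1.
#' @param area Surface area, m^2.
#' @param ts,ta Surface and ambient temperature, degC.
#' @return Convective heat flow in W.
#' @export
convective_heat <- function(hc, area, ts, ta) {
  check_positive(area, "area")
  hc * area * (ts - ta)
}

#' Region-specific convection parameters
#'
#' Empirical forced-convection constants \eqn{(c, n)} and the rule for the
#' vertical characteristic dimension per region: cylinder-like constants
#' (0.174, 0.618) for bill and legs, sphere-like (0.34, 0.6) for the body;
#' dimension = half bill depth at the base for the bill, tarsus length for
#' the legs, and cube-root body volume for the body.
#'
#' @param region One of "bill", "legs", "body".
#' @return List with elements \code{region}, \code{c}, \code{n}.
#' @export
region_convection_params <- function(region = c("bill", "legs", "body")) {
  region <- match.arg(region)
  if (region == "body") list(region = region, c = 0.34, n = 0.6)
  else list(region = region, c = 0.174, n = 0.618)
}

#' Characteristic dimension for a body region
#'
#' @param region One of "bill", "legs", "body".
#' @param bill_depth_base Bill depth at the base, mm (bill rule: depth / 2).
#' @param tarsus_length Tarsus length, mm.
#' @param body_volume Body volume, cm^3 (body rule: volume^(1/3)).
#' @return Characteristic dimension in m.
#' @export
characteristic_dimension <- function(region = c("bill", "legs", "body"),
                                     bill_depth_base = NULL,
                                     tarsus_length = NULL,
                                     body_volume = NULL) {
  region <- match.arg(region)
  d_m <- switch(region,
    bill = {
      check_positive(bill_depth_base, "bill_depth_base")
      (bill_depth_base / 2) / MM_PER_M
    },
    legs = {
      check_positive(tarsus_length, "tarsus_length")
      tarsus_length / MM_PER_M
    },
    body = {
      check_positive(body_volume, "body_volume")
      body_volume^(1 / 3) / 100  # cm -> m
    })
  d_m
}

#' Dry heat loss from one body region
#'
#' Sum of radiative exchange and forced convection for one region at one
#' observation: \eqn{Q = Q_r + Q_c}. Thermal conductivity is evaluated at the
#' film temperature by default (configurable to ambient); kinematic
#' viscosity is evaluated at ambient temperature.
#'
#' @param ts Region surface temperature, degC.
#' @param ta Ambient temperature, degC.
#' @param area_mm2 Region surface area in mm^2.
#' @param d Characteristic dimension, m (see [characteristic_dimension()]).
#' @param params Region convection constants from
#'   [region_convection_params()].
#' @param constants [physical_constants()].
#' @param conductivity_at Evaluate air conductivity at the "film"
#'   (surface-ambient mean, default) or "ambient" temperature.
#' @return List with \code{q_radiative}, \code{q_convective}, \code{q} (W).
#' @export
region_heat_loss <- function(ts, ta, area_mm2, d, params,
                             constants = physical_constants(),
                             conductivity_at = c("film", "ambient")) {
  conductivity_at <- match.arg(conductivity_at)
  area_m2 <- mm2_to_m2(check_positive(area_mm2, "area_mm2"))
  t_k_eval <- if (conductivity_at == "film") film_temperature(ts, ta) else ta
  k <- air_thermal_conductivity(t_k_eval)
  nu_visc <- air_kinematic_viscosity(ta)
  re <- reynolds(constants$air_velocity, d, nu_visc)
  nu_num <- nusselt(re, params$c, params$n)
  hc <- convective_coefficient(nu_num, k, d)
  q_r <- radiative_heat(ts, ta, area_m2, constants$emissivity,
                        constants$stefan_boltzmann)
  q_c <- convective_heat(hc, area_m2, ts, ta)
  list(q_radiative = q_r, q_convective = q_c, q = q_r + q_c)
}

#' Full per-observation heat budget
#'
#' Computes dry heat loss through bill, legs and body for one observation,
#' their total, and the percent of total heat lost through the bill. The
#' bill uses the total bill area and the whole-bill surface temperature.
#' Negative regional values (surface colder than air) are retained;
#' \code{percent_q_bill} is NA when total heat loss is not positive.
#'
#' @param areas A [region_areas()] object (mm^2 areas, cm^3 volume).
#' @param temps List with \code{bill}, \code{legs}, \code{body} surface
#'   temperatures in degC.
#' @param ta Ambient temperature, degC.
#' @param dims List with \code{bill_depth_base} and \code{tarsus_length}
#'   in mm.
#' @param constants [physical_constants()].
#' @param conductivity_at See [region_heat_loss()].
#' @return List of class \code{heat_budget}: per-region radiative/convective
#'   components, \code{q_bill}, \code{q_legs}, \code{q_body}, \code{q_total}
#'   (W) and \code{percent_q_bill}.
#' @export
full_budget <- function(areas, temps, ta, dims,
                        constants = physical_constants(),
                        conductivity_at = c("film", "ambient")) {
  conductivity_at <- match.arg(conductivity_at)
  plaus <- unlist(temps[c("bill", "legs", "body")])
  if (any(plaus < ta - 5 | plaus > 45))
    warning("surface temperature outside plausibility band [ta - 5, 45] degC")
  region_area <- c(bill = areas$bill_total_area, legs = areas$legs_area,
                   body = areas$body_area)
  d <- c(bill = characteristic_dimension("bill",
                  bill_depth_base = dims$bill_depth_base),
         legs = characteristic_dimension("legs",
                  tarsus_length = dims$tarsus_length),
         body = characteristic_dimension("body",
                  body_volume = areas$body_volume))
  per_region <- lapply(c(bill = "bill", legs = "legs", body = "body"),
    function(r) region_heat_loss(temps[[r]], ta, region_area[[r]], d[[r]],
                                 region_convection_params(r), constants,
                                 conductivity_at))
  q <- vapply(per_region, `[[`, numeric(1), "q")
  q_total <- sum(q)
  structure(list(regions = per_region,
                 q_bill = q[["bill"]], q_legs = q[["legs"]],
                 q_body = q[["body"]], q_total = q_total,
                 percent_q_bill = if (q_total > 0) 100 * q[["bill"]] / q_total
                                  else NA_real_),
            class = "heat_budget")
}

#' Heat budgets for an observation table
#'
#' Applies [full_budget()] to every row of an observation table joined with
#' per-bird morphometrics, returning a per-observation heat-budget table.
#' The default analysis unit is the per-(bird x ambient step) mean of the
#' frames, mirroring how repeated frames are typically averaged before
#' modelling; set \code{average_frames = FALSE} to keep frame-level rows.
#'
#' @param observations Data.frame with columns \code{bird_id},
#'   \code{subspecies}, \code{ta}, \code{t_bill}, \code{t_legs},
#'   \code{t_body} (degC) and optionally \code{frame}, \code{activity},
#'   \code{relative_humidity}.
#' @param morphometrics Data.frame with per-bird \code{bird_id},
#'   \code{bill_total_area}, \code{legs_area}, \code{body_area},
#'   \code{body_volume}, \code{bill_depth_base}, \code{tarsus_length}.
#' @param constants [physical_constants()].
#' @param average_frames Average frames within each (bird, ta) step before
#'   computing heat loss (default TRUE).
#' @param conductivity_at See [region_heat_loss()].
#' @return Data.frame with q_bill, q_legs, q_body, q_total (W, columns also
#'   provided in mW) and percent_q_bill per row.
#' @export
heat_budget_table <- function(observations, morphometrics,
                              constants = physical_constants(),
                              average_frames = TRUE,
                              conductivity_at = c("film", "ambient")) {
  conductivity_at <- match.arg(conductivity_at)
  obs <- observations
  if (average_frames) {
    num_cols <- intersect(c("t_bill", "t_base", "t_cone", "t_legs", "t_body",
                            "activity", "relative_humidity"), names(obs))
    obs <- stats::aggregate(obs[num_cols],
                            by = obs[c("bird_id", "subspecies", "ta")],
                            FUN = mean)
  }
  idx <- match(obs$bird_id, morphometrics$bird_id)
  if (any(is.na(idx)))
    stop("observations reference bird_id values absent from morphometrics",
         call. = FALSE)
  m <- morphometrics[idx, ]
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    areas <- region_areas(
      bill_cone_area = if (!is.null(m$bill_cone_area)) m$bill_cone_area[i]
                       else m$bill_total_area[i],
      bill_total_area = m$bill_total_area[i],
      legs_area = m$legs_area[i],
      body_area = m$body_area[i],
      body_volume = m$body_volume[i])
    hb <- suppressWarnings(full_budget(
      areas,
      temps = list(bill = obs$t_bill[i], legs = obs$t_legs[i],
                   body = obs$t_body[i]),
      ta = obs$ta[i],
      dims = list(bill_depth_base = m$bill_depth_base[i],
                  tarsus_length = m$tarsus_length[i]),
      constants = constants, conductivity_at = conductivity_at))
    data.frame(q_bill = hb$q_bill, q_legs = hb$q_legs, q_body = hb$q_body,
               q_total = hb$q_total, percent_q_bill = hb$percent_q_bill)
  })
  out <- cbind(obs, do.call(rbind, rows))
  for (col in c("q_bill", "q_legs", "q_body", "q_total"))
    out[[paste0(col, "_mw")]] <- out[[col]] * 1000
  out
}

#' Water-savings equivalent of a heat-loss difference
#'
#' Converts a difference in dry heat loss into the mass of water whose
#' evaporation would shed the same heat:
#' \eqn{\dot m = \Delta Q \cdot 3600 / L \cdot 1000} mg/h, with \eqn{L} the
#' latent heat of vaporization in J/g.
#'
#' @param delta_q Heat-loss difference in W.
#' @param latent_heat Latent heat of vaporization, J/g (default 2418).
#' @return Water savings in mg/h.
#' @export
#' @examples
#' water_savings(0.0065) # ~9.7 mg/h
water_savings <- function(delta_q, latent_heat = 2418) {
  check_positive(latent_heat, "latent_heat")
  delta_q * 3600 / latent_heat * 1000
}
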
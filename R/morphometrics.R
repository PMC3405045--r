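#' Physical constants for the heat-budget model
#'
#' Bundles the physical constants used throughout the dry heat-loss
#' calculations. Defaults are the values standard for small passerines:
#' biological-tissue emissivity 0.96, still-chamber air velocity 0.1 m/s,
#' sparrow body density 0.913 g/cm^3, and the latent heat of vaporization of
#' water 2418 J/g used to express heat-loss differences as water savings.
#'
#' @param emissivity Surface emissivity (dimensionless, in (0, 1]).
#' @param stefan_boltzmann Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param air_velocity Air speed over the surfaces, m/s.
#' @param bird_density Whole-body density, g/cm^3.
#' @param latent_heat_vaporization Latent heat of vaporization of water, J/g.
#' @return A list of class \code{physical_constants}.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(emissivity = 0.96,
                               stefan_boltzmann = 5.6703e-8,
                               air_velocity = 0.1,
                               bird_density = 0.913,
                               latent_heat_vaporization = 2418) {
  if (!is.numeric(emissivity) || emissivity <= 0 || emissivity > 1)
    stop("emissivity must be in (0, 1]", call. = FALSE)
  vals <- c(stefan_boltzmann = stefan_boltzmann, air_velocity = air_velocity,
            bird_density = bird_density,
            latent_heat_vaporization = latent_heat_vaporization)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop("physical constants must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(emissivity = emissivity,
                 stefan_boltzmann = stefan_boltzmann,
                 air_velocity = air_velocity,
                 bird_density = bird_density,
                 latent_heat_vaporization = latent_heat_vaporization),
            class = "physical_constants")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive and finite", name),
         call. = FALSE)
  invisible(x)
}

#' Lateral surface area of the bill cone
#'
#' Area of the exposed (distal) portion of the bill, modelled as a nearly
#' circular elliptical cone: \eqn{((W + D)/4) \cdot L \cdot \pi}, with width
#' \eqn{W}, depth \eqn{D} and length \eqn{L} measured at the anterior edge of
#' the nares. The printed cone length is used as-is (no slant-height
#' correction), matching how field morphometrics are converted in practice.
#'
#' @param width,depth,length Bill width, depth and length in mm.
#' @return Lateral surface area in mm^2.
#' @export
#' @examples
#' bill_cone_area(width = 6, depth = 4, length = 8) # 62.83 mm^2
bill_cone_area <- function(width, depth, length) {
  check_positive(width, "width")
  check_positive(depth, "depth")
  check_positive(length, "length")
  (width + depth) / 4 * length * pi
}

#' Total bill surface area
#'
#' Same elliptical-cone formula as [bill_cone_area()] but applied to
#' measurements taken at the base of the bill, where the bill is embedded in
#' the face, giving a more complete estimate of the heat-exchanging surface.
#'
#' @param width_base,depth_base,length_base Bill dimensions at the base, mm.
#' @return Lateral surface area in mm^2.
#' @export
bill_total_area <- function(width_base, depth_base, length_base) {
  check_positive(width_base, "width_base")
  check_positive(depth_base, "depth_base")
  check_positive(length_base, "length_base")
  bill_cone_area(width_base, depth_base, length_base)
}

#' Surface area of both tarsi
#'
#' Lateral surface area of the two tarsi modelled as elliptical cylinders:
#' \eqn{\pi \sqrt{2((w/2)^2 + (d/2)^2) - (w - d)^2 / 2} \cdot l \cdot 2}.
#' Toes are excluded (not resolvable in thermal images) and the feathered
#' tibia is counted as body surface.
#'
#' @param width,depth,length Tarsus width, depth and length in mm.
#' @return Combined lateral area of both tarsi in mm^2.
#' @export
#' @examples
#' legs_area(width = 2, depth = 2, length = 20) # circular limit: 2 * 2*pi*1*20
legs_area <- function(width, depth, length) {
  check_positive(width, "width")
  check_positive(depth, "depth")
  check_positive(length, "length")
  radicand <- 2 * ((width / 2)^2 + (depth / 2)^2) - 0.5 * (width - depth)^2
  if (any(radicand <= 0))
    stop("elliptical-cylinder radicand must be positive; ",
         "check tarsus width/depth", call. = FALSE)
  pi * sqrt(radicand) * length * 2
}

#' Allometric body surface area
#'
#' Body surface area from mass by the passerine allometry
#' \eqn{A = 8.11 m^{0.67}} (A in cm^2, m in g), returned in mm^2 to match the
#' other region areas. Per-cohort mean areas should be computed as means of
#' per-bird areas, never as the area at the mean mass (the allometry is
#' concave).
#'
#' @param mass Body mass in g.
#' @return Surface area in mm^2.
#' @export
#' @examples
#' body_area(1)     # 811 mm^2
#' body_area(18.89) # ~5810 mm^2
body_area <- function(mass) {
  check_positive(mass, "mass")
  8.11 * mass^0.67 * 100
}

#' Body volume from mass and density
#'
#' @param mass Body mass in g.
#' @param density Whole-body density in g/cm^3 (default: sparrow, 0.913).
#' @return Volume in cm^3.
#' @export
body_volume <- function(mass, density = 0.913) {
  check_positive(mass, "mass")
  check_positive(density, "density")
  mass / density
}

#' Region areas for one bird
#'
#' Assembles the per-region surface areas the heat-budget model consumes.
#' Areas are stored in mm^2; conversion to m^2 happens at exactly one point,
#' inside the heat-budget module.
#'
#' @param bill_cone_area,bill_total_area,legs_area,body_area Areas in mm^2.
#' @param body_volume Body volume in cm^3.
#' @return A list of class \code{region_areas} with the four region areas,
#'   their total, and body volume.
#' @export
region_areas <- function(bill_cone_area, bill_total_area, legs_area,
                         body_area, body_volume) {
  for (nm in c("bill_cone_area", "bill_total_area", "legs_area", "body_area",
               "body_volume"))
    check_positive(get(nm), nm)
  if (bill_total_area < bill_cone_area)
    warning("bill_total_area < bill_cone_area: base dimensions should be ",
            "at least the nares dimensions")
  structure(list(bill_cone_area = bill_cone_area,
                 bill_total_area = bill_total_area,
                 legs_area = legs_area,
                 body_area = body_area,
                 total_area = bill_total_area + legs_area + body_area,
                 body_volume = body_volume),
            class = "region_areas")
}

#' Relative region areas
#'
#' Expresses bill, leg and body areas as percentages of the whole-body
#' surface (total bill + both tarsi + body). The three percentages sum to
#' 100.
#'
#' @param areas A \code{region_areas} object, or a list with elements
#'   \code{bill_total_area}, \code{legs_area}, \code{body_area}.
#' @return Named numeric vector \code{c(bill, legs, body)} in percent.
#' @export
#' @examples
#' a <- region_areas(88.19, 127.46, 240.07, 5846.04, 20.69)
#' relative_areas(a) # bill 2.05, legs 3.86, body 94.09
relative_areas <- function(areas) {
  parts <- c(bill = areas$bill_total_area, legs = areas$legs_area,
             body = areas$body_area)
  total <- sum(parts)
  check_positive(total, "total_area")
  100 * parts / total
}

#' Percent increase of a larger mean over a smaller mean
#'
#' \eqn{100 (larger - smaller) / smaller}, the convention used when reporting
#' how much larger one cohort's mean is than another's.
#'
#' @param larger_mean,smaller_mean Group means; \code{smaller_mean} must be
#'   positive.
#' @return Percent increase.
#' @export
#' @examples
#' percent_increase(148.70, 127.46) # 16.7
percent_increase <- function(larger_mean, smaller_mean) {
  check_positive(smaller_mean, "smaller_mean")
  100 * (larger_mean - smaller_mean) / smaller_mean
}

#' Read per-bird morphometrics from delimited text
#'
#' Expects a header with columns \code{bird_id}, \code{subspecies},
#' \code{mass} and either precomputed area columns (\code{bill_cone_area},
#' \code{bill_total_area}, \code{legs_area} in mm^2) or the linear
#' measurements to derive them (\code{bill_width_nares}, \code{bill_depth_nares},
#' \code{bill_length_nares}, \code{bill_width_base}, \code{bill_depth_base},
#' \code{bill_length_base}, \code{tarsus_width}, \code{tarsus_depth},
#' \code{tarsus_length}, all mm). Derived columns (areas, total area, body
#' volume) are appended.
#'
#' @param path Path to a CSV (or TSV with \code{sep = "\t"}) file.
#' @param sep Field separator.
#' @param constants \code{physical_constants} (for body density).
#' @return A data.frame with one row per bird including derived areas.
#' @export
read_morphometrics <- function(path, sep = ",",
                               constants = physical_constants()) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("bird_id", "subspecies", "mass")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("morphometrics file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  derive_areas(df, constants)
}

#' Derive region areas for a morphometrics table
#'
#' Fills in \code{bill_cone_area}, \code{bill_total_area}, \code{legs_area}
#' (from linear measurements, if absent), \code{body_area},
#' \code{total_area} and \code{body_volume}.
#'
#' @param df Morphometrics data.frame (see [read_morphometrics()]).
#' @param constants \code{physical_constants}.
#' @return The data.frame with derived columns appended.
#' @export
derive_areas <- function(df, constants = physical_constants()) {
  if (is.null(df$bill_cone_area) &&
      all(c("bill_width_nares", "bill_depth_nares", "bill_length_nares")
          %in% names(df)))
    df$bill_cone_area <- bill_cone_area(df$bill_width_nares,
                                        df$bill_depth_nares,
                                        df$bill_length_nares)
  if (is.null(df$bill_total_area) &&
      all(c("bill_width_base", "bill_depth_base", "bill_length_base")
          %in% names(df)))
    df$bill_total_area <- bill_total_area(df$bill_width_base,
                                          df$bill_depth_base,
                                          df$bill_length_base)
  if (is.null(df$legs_area) &&
      all(c("tarsus_width", "tarsus_depth", "tarsus_length") %in% names(df)))
    df$legs_area <- legs_area(df$tarsus_width, df$tarsus_depth,
                              df$tarsus_length)
  df$body_area <- body_area(df$mass)
  needed <- c("bill_cone_area", "bill_total_area", "legs_area")
  missing <- needed[!needed %in% names(df)]
  if (length(missing))
    stop("cannot derive ", paste(missing, collapse = ", "),
         ": supply areas or linear measurements", call. = FALSE)
  df$total_area <- df$bill_total_area + df$legs_area + df$body_area
  df$body_volume <- body_volume(df$mass, constants$bird_density)
  df
}

#' Cohort morphometric comparison table
#'
#' Per-measurement group means and SDs with pooled-variance t-tests
#' (Bonferroni-corrected over the number of rows) and the percent increase of
#' the larger group mean over the smaller, in the layout conventional for
#' two-cohort morphometric comparisons.
#'
#' @param df Morphometrics data.frame with a \code{subspecies} column and the
#'   numeric columns to compare.
#' @param measures Character vector of columns to summarise. Defaults to the
#'   standard set present in \code{df}.
#' @param group Column defining the two groups.
#' @return A data.frame with columns measurement, group means/SDs,
#'   \code{p_bonferroni} and \code{percent_increase}, at full precision.
#' @export
morphometric_summary <- function(df, measures = NULL, group = "subspecies") {
  g <- factor(df[[group]])
  if (nlevels(g) != 2)
    stop("morphometric_summary needs exactly two groups", call. = FALSE)
  if (is.null(measures)) {
    std <- c("wing_chord", "mass", "tarsus_length", "bill_cone_area",
             "bill_total_area", "legs_area", "body_area")
    measures <- intersect(std, names(df))
  }
  lv <- levels(g)
  n_tests <- length(measures)
  rows <- lapply(measures, function(m) {
    a <- df[[m]][g == lv[1]]
    b <- df[[m]][g == lv[2]]
    tt <- pooled_t_bonferroni(a, b, n_tests = n_tests)
    mns <- c(mean(a), mean(b))
    data.frame(measurement = m,
               mean_1 = mns[1], sd_1 = stats::sd(a),
               mean_2 = mns[2], sd_2 = stats::sd(b),
               p_bonferroni = tt$p_adjusted,
               percent_increase = percent_increase(max(mns), min(mns)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", lv[1]), paste0("sd_", lv[1]),
                                 paste0("mean_", lv[2]), paste0("sd_", lv[2]))
  out
}
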
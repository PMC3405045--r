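# Seeded synthetic thermography experiments.
#
# The generator emulates a step-wise temperature-chamber protocol: a cohort
# of birds from two subspecies, each exposed to 2 degC ambient steps from 15
# to 37 degC, with five thermal-image frames retained per step. Surface
# temperatures follow the qualitative structure seen in such experiments:
# bill and body elevations above ambient that shrink linearly as ambient
# rises, a subspecies-by-ambient interaction at the bill base, a logistic
# vasodilation threshold in the legs, quadratic activity, and relative
# humidity anticorrelated with ambient temperature. Individual birds get
# random intercepts; frames get i.i.d. noise.

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# truncated-normal draw by rejection; truncation at +/- trunc_sd keeps
# morphometrics physical (no negative areas)
rnorm_trunc <- function(n, mean, sd, trunc_sd = 3) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- abs(out - mean) > trunc_sd * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(out - mean) > trunc_sd * sd
  }
  out
}

#' Cohort configuration for the synthetic generator
#'
#' Morphometric means and SDs per subspecies. Defaults reproduce a
#' two-subspecies song-sparrow cohort: nine birds per subspecies, the
#' coastal (atlantica) birds carrying ~17% more bill surface area than the
#' inland (melodia) birds at near-identical mass, tarsus and body area.
#' Region areas are drawn directly from truncated normals (3 SD) at these
#' means; bill depth at the base and tarsus length are drawn as linear
#' measurements because the convection model needs characteristic
#' dimensions.
#'
#' @param n_per_subspecies Birds per subspecies (>= 2).
#' @param means,sds Named lists (one element per subspecies) of named
#'   numeric vectors with entries \code{mass} (g), \code{wing_chord},
#'   \code{tarsus_length}, \code{bill_depth_base} (mm),
#'   \code{bill_cone_area}, \code{bill_total_area}, \code{legs_area},
#'   \code{body_area} (mm^2).
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_subspecies = 9, means = NULL, sds = NULL) {
  if (!is.numeric(n_per_subspecies) || n_per_subspecies < 2)
    stop("n_per_subspecies must be >= 2", call. = FALSE)
  default_means <- list(
    melodia = c(mass = 18.89, wing_chord = 65.89, tarsus_length = 20.01,
                bill_depth_base = 6.0, bill_cone_area = 88.19,
                bill_total_area = 127.46, legs_area = 240.07,
                body_area = 5846.04),
    atlantica = c(mass = 19.97, wing_chord = 63.92, tarsus_length = 19.85,
                  bill_depth_base = 6.3, bill_cone_area = 99.89,
                  bill_total_area = 148.70, legs_area = 241.94,
                  body_area = 5852.78))
  default_sds <- list(
    melodia = c(mass = 1.27, wing_chord = 1.19, tarsus_length = 0.74,
                bill_depth_base = 0.3, bill_cone_area = 4.21,
                bill_total_area = 10.41, legs_area = 20.87,
                body_area = 149.26),
    atlantica = c(mass = 1.05, wing_chord = 1.44, tarsus_length = 0.89,
                  bill_depth_base = 0.3, bill_cone_area = 19.81,
                  bill_total_area = 12.12, legs_area = 20.61,
                  body_area = 226.03))
  means <- if (is.null(means)) default_means else means
  sds <- if (is.null(sds)) default_sds else sds
  if (any(unlist(sds) < 0)) stop("SDs must be >= 0", call. = FALSE)
  structure(list(n_per_subspecies = as.integer(n_per_subspecies),
                 means = means, sds = sds),
            class = "cohort_config")
}

#' Chamber protocol configuration
#'
#' The step-wise ambient-temperature protocol: 2 degC increments from 15 to
#' 37 degC, 15 min per step, five analysed frames per step.
#'
#' @param ta_start,ta_end,ta_step Ambient range and increment, degC.
#' @param frames_per_step Frames retained per step.
#' @param step_duration Minutes per step (metadata only).
#' @return List of class \code{protocol_config}.
#' @export
protocol_config <- function(ta_start = 15, ta_end = 37, ta_step = 2,
                            frames_per_step = 5, step_duration = 15) {
  if (ta_end <= ta_start) stop("ta_end must exceed ta_start", call. = FALSE)
  if ((ta_end - ta_start) %% ta_step != 0)
    stop("ta_step must divide the ambient range", call. = FALSE)
  structure(list(ta_start = ta_start, ta_end = ta_end, ta_step = ta_step,
                 frames_per_step = as.integer(frames_per_step),
                 step_duration = step_duration),
            class = "protocol_config")
}

#' Surface-temperature response configuration
#'
#' Parameters of the generating model for region surface temperatures and
#' covariates. Bill and body elevations above ambient interpolate linearly
#' between their endpoint values at the protocol's first and last ambient
#' temperatures (defaults 9.8 -> 4.7 degC for the bill, 4.4 -> 2.6 degC for
#' the body). The bill base carries a subspecies-by-ambient interaction:
#' coastal birds run warmer at the base, most strongly at cold ambients
#' (default extra elevation 1.2 degC at the cold end shrinking to 0.2 degC
#' at the warm end). Legs follow a logistic vasodilation threshold. The
#' whole-bill subspecies offset defaults to a small constant 0.3 degC,
#' reflecting a weakly supported effect; set it to 0 for null simulations.
#' Variance components (individual-intercept SD 0.5 degC, frame SD 0.4
#' degC) are stated assumptions, not literature values.
#'
#' @param bill_elev_start,bill_elev_end Bill elevation over ambient at the
#'   protocol endpoints, degC.
#' @param body_elev_start,body_elev_end Body elevation endpoints, degC.
#' @param base_elev_start,base_elev_end Bill-base elevation endpoints for
#'   the inland subspecies, degC.
#' @param base_ssp_start,base_ssp_end Extra bill-base elevation of the
#'   coastal subspecies at the protocol endpoints (the subspecies x ambient
#'   interaction), degC.
#' @param bill_ssp_offset Constant whole-bill offset of the coastal
#'   subspecies, degC.
#' @param cone_offset Bill-cone elevation relative to whole-bill, degC.
#' @param leg_threshold,leg_scale Logistic midpoint and width for leg
#'   vasodilation, degC.
#' @param leg_elev_pre,leg_elev_post Leg elevation below/above threshold,
#'   degC.
#' @param ranef_sd Individual random-intercept SD, degC.
#' @param frame_sd Frame-level residual SD, degC.
#' @param activity_coef Quadratic coefficients \code{c(a0, a1, a2)} giving
#'   mean hops/min as \code{a0 + a1 ta + a2 ta^2}.
#' @param activity_sd Activity noise SD, hops/min (draws truncated at 0).
#' @param rh_start,rh_end Mean relative humidity at the protocol endpoints,
#'   percent.
#' @param rh_sd Humidity noise SD, percent.
#' @return List of class \code{response_config}.
#' @export
response_config <- function(bill_elev_start = 9.8, bill_elev_end = 4.7,
                            body_elev_start = 4.4, body_elev_end = 2.6,
                            base_elev_start = 9.8, base_elev_end = 4.7,
                            base_ssp_start = 1.2, base_ssp_end = 0.2,
                            bill_ssp_offset = 0.3, cone_offset = -1.0,
                            leg_threshold = 29, leg_scale = 1.5,
                            leg_elev_pre = 1.0, leg_elev_post = 4.0,
                            ranef_sd = 0.5, frame_sd = 0.4,
                            activity_coef = c(30, -1.8, 0.035),
                            activity_sd = 2,
                            rh_start = 70, rh_end = 30, rh_sd = 3) {
  if (ranef_sd < 0 || frame_sd < 0 || activity_sd < 0 || rh_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (bill_elev_start <= 0 || bill_elev_end <= 0 ||
      body_elev_start <= 0 || body_elev_end <= 0)
    stop("bill and body elevation endpoints must be positive", call. = FALSE)
  structure(mget(names(formals())), class = "response_config")
}

#' Generate a synthetic cohort
#'
#' Draws per-bird morphometrics from truncated normals (3 SD) at the
#' configured subspecies means and SDs, and derives total area and body
#' volume. Deterministic given the seed.
#'
#' @param config [cohort_config()].
#' @param seed Integer seed.
#' @param constants [physical_constants()] (for body density).
#' @return Data.frame with one row per bird: identifiers, linear
#'   measurements, region areas (mm^2), total area and body volume (cm^3).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            constants = physical_constants()) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config", call. = FALSE)
  with_preserved_seed(seed, {
    ssp_names <- names(config$means)
    rows <- lapply(ssp_names, function(ssp) {
      n <- config$n_per_subspecies
      mu <- config$means[[ssp]]
      sd <- config$sds[[ssp]]
      draws <- vapply(names(mu),
                      function(v) rnorm_trunc(n, mu[[v]], sd[[v]]),
                      numeric(n))
      draws <- as.data.frame(draws)
      cbind(data.frame(bird_id = paste0(substr(ssp, 1, 3), "_",
                                        seq_len(n)),
                       subspecies = ssp, stringsAsFactors = FALSE),
            draws)
    })
    out <- do.call(rbind, rows)
    out$total_area <- out$bill_total_area + out$legs_area + out$body_area
    out$body_volume <- body_volume(out$mass, constants$bird_density)
    rownames(out) <- NULL
    out
  })
}

interp_elev <- function(ta, protocol, start, end) {
  start + (end - start) * (ta - protocol$ta_start) /
    (protocol$ta_end - protocol$ta_start)
}

#' Generate a synthetic thermography experiment
#'
#' For every bird x ambient step x frame, draws region surface temperatures,
#' activity and relative humidity from the configured response model.
#' Activity and humidity vary by (bird, step); frame noise is i.i.d. per
#' region and frame. Deterministic given the seed.
#'
#' @param cohort Data.frame from [generate_cohort()].
#' @param protocol [protocol_config()].
#' @param response [response_config()].
#' @param seed Integer seed.
#' @return Data.frame of observations: \code{bird_id}, \code{subspecies},
#'   \code{ta}, \code{frame}, \code{t_bill}, \code{t_base}, \code{t_cone},
#'   \code{t_legs}, \code{t_body} (degC), \code{activity} (hops/min),
#'   \code{relative_humidity} (percent).
#' @export
generate_experiment <- function(cohort, protocol = protocol_config(),
                                response = response_config(), seed = 1) {
  if (!inherits(protocol, "protocol_config"))
    stop("protocol must be a protocol_config", call. = FALSE)
  if (!inherits(response, "response_config"))
    stop("response must be a response_config", call. = FALSE)
  with_preserved_seed(seed, {
    ta_levels <- seq(protocol$ta_start, protocol$ta_end, by = protocol$ta_step)
    n_birds <- nrow(cohort)
    u <- list(bill = stats::rnorm(n_birds, 0, response$ranef_sd),
              base = stats::rnorm(n_birds, 0, response$ranef_sd),
              body = stats::rnorm(n_birds, 0, response$ranef_sd),
              legs = stats::rnorm(n_birds, 0, response$ranef_sd))
    grid <- expand.grid(frame = seq_len(protocol$frames_per_step),
                        ta = ta_levels, bird = seq_len(n_birds),
                        KEEP.OUT.ATTRS = FALSE)
    # step-level covariates shared across frames within a (bird, step)
    step_grid <- expand.grid(ta = ta_levels, bird = seq_len(n_birds),
                             KEEP.OUT.ATTRS = FALSE)
    ac <- response$activity_coef
    step_grid$activity <- pmax(0, ac[1] + ac[2] * step_grid$ta +
                                  ac[3] * step_grid$ta^2 +
                                  stats::rnorm(nrow(step_grid), 0,
                                               response$activity_sd))
    rh_mean <- interp_elev(step_grid$ta, protocol, response$rh_start,
                           response$rh_end)
    step_grid$relative_humidity <-
      pmin(100, pmax(5, rh_mean + stats::rnorm(nrow(step_grid), 0,
                                               response$rh_sd)))
    key <- match(paste(grid$bird, grid$ta), paste(step_grid$bird,
                                                  step_grid$ta))
    is_coastal <- cohort$subspecies[grid$bird] == "atlantica"
    n_obs <- nrow(grid)
    eps <- function() stats::rnorm(n_obs, 0, response$frame_sd)
    bill_elev <- interp_elev(grid$ta, protocol, response$bill_elev_start,
                             response$bill_elev_end)
    base_elev <- interp_elev(grid$ta, protocol, response$base_elev_start,
                             response$base_elev_end) +
      is_coastal * interp_elev(grid$ta, protocol, response$base_ssp_start,
                               response$base_ssp_end)
    body_elev <- interp_elev(grid$ta, protocol, response$body_elev_start,
                             response$body_elev_end)
    leg_elev <- response$leg_elev_pre +
      (response$leg_elev_post - response$leg_elev_pre) *
      stats::plogis((grid$ta - response$leg_threshold) / response$leg_scale)
    t_bill <- grid$ta + bill_elev + is_coastal * response$bill_ssp_offset +
      u$bill[grid$bird] + eps()
    t_base <- grid$ta + base_elev + u$base[grid$bird] + eps()
    t_cone <- t_bill + response$cone_offset
    t_body <- grid$ta + body_elev + u$body[grid$bird] + eps()
    t_legs <- grid$ta + leg_elev + u$legs[grid$bird] + eps()
    out <- data.frame(bird_id = cohort$bird_id[grid$bird],
                      subspecies = cohort$subspecies[grid$bird],
                      ta = grid$ta, frame = grid$frame,
                      t_bill = t_bill, t_base = t_base, t_cone = t_cone,
                      t_legs = t_legs, t_body = t_body,
                      activity = step_grid$activity[key],
                      relative_humidity = step_grid$relative_humidity[key],
                      stringsAsFactors = FALSE)
    out <- out[order(out$bird_id, out$ta, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Mean temperature over a region of interest
#'
#' Arithmetic mean of a gridded radiometric temperature field under a
#' logical mask, as produced when a region of interest is drawn on a
#' thermal image.
#'
#' @param grid Numeric matrix of temperatures, degC.
#' @param mask Logical matrix of the same dimensions.
#' @return Mean temperature in degC.
#' @export
roi_mean_temperature <- function(grid, mask) {
  if (!is.matrix(grid) || !is.matrix(mask) ||
      !all(dim(grid) == dim(mask)))
    stop("grid and mask must be matrices of identical dimensions",
         call. = FALSE)
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  mean(grid[mask])
}

#' Select analysis frames from a video's frame times
#'
#' Picks one frame per minute: the last frame within each minute interval,
#' unless that frame is flagged bad, in which case the temporally closest
#' good frame within the same minute is used (ties broken toward the
#' earlier frame). A minute with no usable frame yields NA.
#'
#' @param frame_times Numeric vector of frame timestamps, minutes.
#' @param quality_flags Logical vector, TRUE where the frame is usable.
#'   Defaults to all good.
#' @param n_minutes Number of minute intervals to sample (default 5).
#' @return Integer vector of length \code{n_minutes} of frame indices (NA
#'   where a minute has no good frame).
#' @export
select_frames <- function(frame_times, quality_flags = NULL, n_minutes = 5) {
  if (is.null(quality_flags)) quality_flags <- rep(TRUE, length(frame_times))
  if (length(quality_flags) != length(frame_times))
    stop("quality_flags must match frame_times in length", call. = FALSE)
  if (max(frame_times) < n_minutes)
    stop("video shorter than ", n_minutes, " minutes", call. = FALSE)
  tol <- 1e-8  # absorb float error in times built by seq()
  vapply(seq_len(n_minutes), function(m) {
    in_minute <- which(frame_times > m - 1 + tol & frame_times <= m + tol)
    if (!length(in_minute)) return(NA_integer_)
    last <- in_minute[which.max(frame_times[in_minute])]
    if (quality_flags[last]) return(last)
    good <- in_minute[quality_flags[in_minute]]
    if (!length(good)) return(NA_integer_)
    dist <- abs(frame_times[good] - m)
    # ties go to the earlier frame
    good[order(dist, frame_times[good])][1]
  }, integer(1))
}
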
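# Independent step-by-step re-evaluation of the heat-loss formula chain,
# written as flat arithmetic so it shares no code path with the package's
# region_heat_loss()/full_budget().

oracle_region_q <- function(ts, ta, area_mm2, d_m, c_coef, n_exp,
                            emissivity = 0.96, sigma = 5.6703e-8,
                            velocity = 0.1, conductivity_at = "film") {
  area_m2 <- area_mm2 * 1e-6
  qr <- emissivity * sigma * area_m2 *
    ((ts + 273.15)^4 - (ta + 273.15)^4)
  t_eval <- if (conductivity_at == "film") (ts + ta) / 2 else ta
  k <- 0.02624 * ((t_eval + 273.15) / 300)^0.8646
  mu <- 1.458e-6 * (ta + 273.15)^1.5 / (ta + 273.15 + 110.4)
  rho <- 101325 / (287.05 * (ta + 273.15))
  re <- velocity * d_m / (mu / rho)
  hc <- c_coef * re^n_exp * k / d_m
  qc <- hc * area_m2 * (ts - ta)
  qr + qc
}

oracle_full_budget <- function(areas, temps, ta, dims,
                               conductivity_at = "film") {
  q_bill <- oracle_region_q(temps$bill, ta, areas$bill_total_area,
                            dims$bill_depth_base / 2 / 1000, 0.174, 0.618,
                            conductivity_at = conductivity_at)
  q_legs <- oracle_region_q(temps$legs, ta, areas$legs_area,
                            dims$tarsus_length / 1000, 0.174, 0.618,
                            conductivity_at = conductivity_at)
  q_body <- oracle_region_q(temps$body, ta, areas$body_area,
                            areas$body_volume^(1 / 3) / 100, 0.34, 0.6,
                            conductivity_at = conductivity_at)
  list(q_bill = q_bill, q_legs = q_legs, q_body = q_body,
       q_total = q_bill + q_legs + q_body)
}

# small random-but-valid heat-budget input, for property tests
random_budget_input <- function() {
  list(areas = region_areas(
         bill_cone_area = runif(1, 60, 120),
         bill_total_area = runif(1, 120, 180),
         legs_area = runif(1, 180, 300),
         body_area = runif(1, 5000, 6500),
         body_volume = runif(1, 18, 24)),
       temps = list(bill = runif(1, 16, 44), legs = runif(1, 16, 44),
                    body = runif(1, 16, 44)),
       ta = runif(1, 15, 37),
       dims = list(bill_depth_base = runif(1, 5, 7),
                   tarsus_length = runif(1, 18, 22)))
}

default_heat_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(seed = 101)
      obs <- generate_experiment(cohort, seed = 102)
      cache <<- suppressWarnings(heat_budget_table(obs, cohort))
    }
    cache
  }
})
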
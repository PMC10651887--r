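#' Incubation schedule
#'
#' Timing of the bottle experiment: a daytime census some hours after
#' deployment and a final census the following morning. Day-interval rates
#' apply before `t_day_census`, night rates after.
#'
#' @param t_day_census Hours after deployment of the end-of-day census
#'   (default 6).
#' @param t_night_census Hours after deployment of the end-of-night
#'   census (default 20).
#' @param dt Integration step in hours (default 0.05, must be <= 0.25).
#' @return A `sim_schedule` list.
#' @export
sim_schedule <- function(t_day_census = 6, t_night_census = 20, dt = 0.05) {
  if (!(t_day_census > 0 && t_night_census > t_day_census)) {
    stop("need 0 < t_day_census < t_night_census.", call. = FALSE)
  }
  if (!(dt > 0 && dt <= 0.25)) {
    stop("`dt` must lie in (0, 0.25] hours.", call. = FALSE)
  }
  structure(list(t_day_census = t_day_census,
                 t_night_census = t_night_census,
                 dt = dt),
            class = "sim_schedule")
}

#' Parameters of one incubation bottle
#'
#' Describes one bottle of the 2 site x 2 treatment design: the bottle
#' volume, the plant it holds (if any), and the true process rates the
#' forward model integrates. Rates are zero by default so that tests can
#' switch on one process at a time.
#'
#' @param site `"control"` (ambient pH) or `"vent"` (CO2 seep).
#' @param treatment `"seagrass"` or `"seawater_only"`.
#' @param volume Bottle volume, L.
#' @param plant_dry_mass Plant dry mass, g (0 for seawater-only bottles).
#' @param percent_n Tissue nitrogen content, percent of dry mass.
#' @param dfaa_conc Background dissolved free amino-acid N, µM.
#' @param nh4_conc Background ammonium, µM.
#' @param pom_n_conc Particulate organic N, µM.
#' @param don_conc Background dissolved organic N available to
#'   regeneration, µM.
#' @param ammonification_day,ammonification_night Amino-acid
#'   mineralisation rate, nmol N per hour per bottle.
#' @param plant_nh4_uptake_day,plant_nh4_uptake_night Plant ammonium
#'   uptake, µmol N per g dry mass per hour.
#' @param pom_nh4_uptake_day,pom_nh4_uptake_night Ammonium uptake by
#'   particulate organic matter, µmol N per L per hour.
#' @param pom_aa_uptake Direct amino-acid uptake by particulate organic
#'   matter, µmol N per L per hour.
#' @param background_regeneration Ammonium regeneration from unlabelled
#'   organic matter, nmol N per hour per bottle (at natural abundance).
#' @param o2_npp_day Net O2 production during the day, µmol O2 per hour
#'   per bottle.
#' @param o2_resp_night O2 consumption at night, µmol O2 per hour per
#'   bottle (positive number).
#' @param o2_conc Initial O2 concentration, µmol/L.
#' @param no3_conc,no2_conc,po4_conc,si_conc,doc_conc Ancillary nutrient
#'   and organic-carbon concentrations, µM (carried through unchanged).
#' @return A one-row tibble of class parameters.
#' @export
bottle_params <- function(site = c("control", "vent"),
                          treatment = c("seagrass", "seawater_only"),
                          volume = 0.66,
                          plant_dry_mass = if (treatment == "seagrass") 0.25 else 0,
                          percent_n = 2.1,
                          dfaa_conc = 1.0,
                          nh4_conc = 0.5,
                          pom_n_conc = 1.0,
                          don_conc = 5.0,
                          ammonification_day = 0,
                          ammonification_night = 0,
                          plant_nh4_uptake_day = 0,
                          plant_nh4_uptake_night = 0,
                          pom_nh4_uptake_day = 0,
                          pom_nh4_uptake_night = 0,
                          pom_aa_uptake = 0,
                          background_regeneration = 0,
                          o2_npp_day = 0,
                          o2_resp_night = 0,
                          o2_conc = 230,
                          no3_conc = 0.5,
                          no2_conc = 0.05,
                          po4_conc = 0.05,
                          si_conc = 1.0,
                          doc_conc = 80) {
  site <- match.arg(site)
  treatment <- match.arg(treatment)
  force(plant_dry_mass)
  rates <- c(volume, plant_dry_mass, percent_n, dfaa_conc, nh4_conc,
             pom_n_conc, don_conc, ammonification_day, ammonification_night,
             plant_nh4_uptake_day, plant_nh4_uptake_night,
             pom_nh4_uptake_day, pom_nh4_uptake_night, pom_aa_uptake,
             background_regeneration, o2_npp_day, o2_resp_night, o2_conc)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates and concentrations must be finite and >= 0.",
         call. = FALSE)
  }
  if (volume <= 0) stop("`volume` must be positive.", call. = FALSE)
  if (treatment == "seawater_only" &&
      (plant_dry_mass > 0 || plant_nh4_uptake_day > 0 ||
       plant_nh4_uptake_night > 0)) {
    stop("seawater_only bottles cannot carry plant mass or plant uptake.",
         call. = FALSE)
  }
  tibble::tibble(
    site = site, treatment = treatment, volume = volume,
    plant_dry_mass = plant_dry_mass, percent_n = percent_n,
    dfaa_conc = dfaa_conc, nh4_conc = nh4_conc, pom_n_conc = pom_n_conc,
    don_conc = don_conc,
    ammonification_day = ammonification_day,
    ammonification_night = ammonification_night,
    plant_nh4_uptake_day = plant_nh4_uptake_day,
    plant_nh4_uptake_night = plant_nh4_uptake_night,
    pom_nh4_uptake_day = pom_nh4_uptake_day,
    pom_nh4_uptake_night = pom_nh4_uptake_night,
    pom_aa_uptake = pom_aa_uptake,
    background_regeneration = background_regeneration,
    o2_npp_day = o2_npp_day, o2_resp_night = o2_resp_night,
    o2_conc = o2_conc, no3_conc = no3_conc, no2_conc = no2_conc,
    po4_conc = po4_conc, si_conc = si_conc, doc_conc = doc_conc
  )
}

#' Default tracer spikes
#'
#' The amino-acid tracer (50 µL of a 0.05 M solution at 98 atom% 15N, one
#' N per molecule) and the ammonium carrier (77.6 µL of 0.05 M NH4Cl at a
#' known delta value, here natural abundance) added to every bottle.
#'
#' @param aa_atom_fraction 15N atom fraction of the amino-acid spike.
#' @param nh4_atom_fraction 15N atom fraction of the ammonium carrier.
#' @return A named list of [spike_definition()] objects with elements
#'   `aa` and `nh4`.
#' @export
default_spikes <- function(aa_atom_fraction = 0.98,
                           nh4_atom_fraction = natural_abundance_15n()) {
  list(
    aa  = spike_definition(50e-6, 0.05, aa_atom_fraction, 1),
    nh4 = spike_definition(77.6e-6, 0.05, nh4_atom_fraction, 1)
  )
}

#' The default experiment design
#'
#' Two sites (ambient-pH control and CO2 vent), and per site 8 bottles
#' holding a seagrass shoot plus unfiltered seawater and 4 bottles of
#' seawater only. Process rates are set to values in the ranges the
#' incubation literature reports for Mediterranean seagrass meadows:
#' ammonification of a few nmol per hour (roughly 4x greater at the
#' control site and 2.5x greater with the plant), plant ammonium uptake
#' of order 1 µmol per g dry mass per hour, and O2 metabolism giving
#' daytime carbon fixation near 0.7 mg C per g dry mass per hour.
#'
#' @return A tibble with one row per site x treatment cell and an
#'   `n_bottles` column (8 seagrass, 4 seawater-only).
#' @export
default_design <- function() {
  cell <- function(site, treatment, n) {
    sw <- treatment == "seawater_only"
    base_amm <- if (site == "control") c(4, 3) else c(1, 0.75)
    amm <- if (sw) base_amm else base_amm * 2.5
    pom_mult <- if (sw) 1 else if (site == "control") 1.6 else 2.5
    p <- bottle_params(
      site = site, treatment = treatment,
      ammonification_day = amm[1], ammonification_night = amm[2],
      plant_nh4_uptake_day = if (sw) 0 else 1.2,
      plant_nh4_uptake_night = if (sw) 0 else 0.4,
      pom_nh4_uptake_day = 0.02 * pom_mult,
      pom_nh4_uptake_night = 0.01 * pom_mult,
      pom_aa_uptake = 0.005 * pom_mult,
      background_regeneration = 2,
      o2_npp_day = if (sw) 2 else 15,
      o2_resp_night = if (sw) 1 else 3
    )
    p$n_bottles <- n
    p
  }
  dplyr::bind_rows(
    cell("control", "seagrass", 8L),
    cell("control", "seawater_only", 4L),
    cell("vent", "seagrass", 8L),
    cell("vent", "seawater_only", 4L)
  )
}

# Initial pool state for one bottle: amounts in umol N, 15N tracked as
# mass so that conservation is exact by construction.
.init_pools <- function(p, spikes) {
  f_nat <- natural_abundance_15n()
  pool <- function(amount, f) list(amount = amount, n15 = amount * f)
  st <- list(
    aa  = pool(p$dfaa_conc * p$volume, f_nat),
    nh4 = pool(p$nh4_conc * p$volume, f_nat),
    don = pool(p$don_conc * p$volume, f_nat),
    pom = pool(p$pom_n_conc * p$volume, f_nat),
    plant = pool(if (p$treatment == "seagrass") {
      p$plant_dry_mass * p$percent_n / 100 / 14.0067 * 1e6
    } else 0, f_nat)
  )
  for (target in names(spikes)) {
    if (!target %in% c("aa", "nh4")) {
      stop("spike targets must be 'aa' or 'nh4'.", call. = FALSE)
    }
    sp <- spikes[[target]]
    add <- spike_n_amount(sp)
    st[[target]]$amount <- st[[target]]$amount + add
    st[[target]]$n15 <- st[[target]]$n15 + add * sp$spike_atom_fraction
  }
  st
}

.pool_fraction <- function(pool) {
  if (pool$amount == 0) natural_abundance_15n() else pool$n15 / pool$amount
}

# One explicit Euler step of length h under the given interval's rates.
# Fluxes in umol N / h. Transfers carry the source pool's current atom
# fraction, so total N and 15N are conserved exactly.
.step_pools <- function(st, p, h, interval) {
  day <- interval == "day"
  amm  <- (if (day) p$ammonification_day else p$ammonification_night) / 1000
  regen <- p$background_regeneration / 1000
  u_plant <- (if (day) p$plant_nh4_uptake_day else p$plant_nh4_uptake_night) *
    p$plant_dry_mass
  u_pom_nh4 <- (if (day) p$pom_nh4_uptake_day else p$pom_nh4_uptake_night) *
    p$volume
  u_pom_aa <- p$pom_aa_uptake * p$volume

  out_aa  <- (amm + u_pom_aa) * h
  out_nh4 <- (u_plant + u_pom_nh4) * h
  out_don <- regen * h
  for (nm in c("aa", "nh4", "don")) {
    need <- switch(nm, aa = out_aa, nh4 = out_nh4, don = out_don)
    if (st[[nm]]$amount - need < -1e-12) {
      stop(sprintf("integration step drove pool '%s' below zero; reduce rates or dt.",
                   nm), call. = FALSE)
    }
  }
  f_aa  <- .pool_fraction(st$aa)
  f_don <- .pool_fraction(st$don)
  # The amino-acid and organic pools only lose nitrogen, so their atom
  # fractions are constant within a step; the ammonium pool both gains
  # and loses, so its outflow fraction is evaluated at the midpoint
  # state (explicit midpoint rule) for second-order accuracy.
  f_nh4_0 <- .pool_fraction(st$nh4)
  half <- h / 2
  nh4_amt_mid <- st$nh4$amount +
    (amm + regen - u_plant - u_pom_nh4) * half
  nh4_n15_mid <- st$nh4$n15 +
    (amm * f_aa + regen * f_don - (u_plant + u_pom_nh4) * f_nh4_0) * half
  f_nh4 <- if (nh4_amt_mid > 0) nh4_n15_mid / nh4_amt_mid else f_nh4_0

  mv <- function(st, from, to, amount, f) {
    st[[from]]$amount <- st[[from]]$amount - amount
    st[[from]]$n15 <- st[[from]]$n15 - amount * f
    st[[to]]$amount <- st[[to]]$amount + amount
    st[[to]]$n15 <- st[[to]]$n15 + amount * f
    st
  }
  st <- mv(st, "aa", "nh4", amm * h, f_aa)
  st <- mv(st, "aa", "pom", u_pom_aa * h, f_aa)
  st <- mv(st, "don", "nh4", regen * h, f_don)
  st <- mv(st, "nh4", "plant", u_plant * h, f_nh4)
  st <- mv(st, "nh4", "pom", u_pom_nh4 * h, f_nh4)
  st
}

.census_record <- function(st, p, o2, census, time_h, bottle_id) {
  sg <- p$treatment == "seagrass"
  tibble::tibble(
    bottle_id = bottle_id,
    site = p$site, treatment = p$treatment,
    census = census, time_h = time_h,
    volume = p$volume,
    plant_dry_mass = p$plant_dry_mass,
    percent_n = p$percent_n,
    aa_atom_fraction = .pool_fraction(st$aa),
    nh4_conc = st$nh4$amount / p$volume,
    nh4_atom_fraction = .pool_fraction(st$nh4),
    tissue_atom_fraction = if (sg) .pool_fraction(st$plant) else NA_real_,
    tissue_n_umol = if (sg) st$plant$amount else NA_real_,
    pom_atom_fraction = .pool_fraction(st$pom),
    pom_n = st$pom$amount,
    o2_conc = o2,
    no3_conc = p$no3_conc, no2_conc = p$no2_conc,
    po4_conc = p$po4_conc, si_conc = p$si_conc,
    doc_conc = p$doc_conc,
    don_conc = st$don$amount / p$volume
  )
}

.pool_snapshot <- function(st, census) {
  tibble::tibble(
    census = census,
    pool = names(st),
    amount = vapply(st, function(x) x$amount, numeric(1)),
    n15 = vapply(st, function(x) x$n15, numeric(1))
  )
}

#' Simulate one incubation bottle (noiseless)
#'
#' Forward model of the labelled-nitrogen transfer system: the spiked
#' amino-acid pool feeds ammonium through ammonification, ammonium feeds
#' plant tissue and particulate organic matter through uptake, particles
#' also take amino acids up directly, and an unlabelled organic pool
#' regenerates ammonium at natural abundance. Integration is explicit
#' fixed-step Euler; transfers carry the source pool's current atom
#' fraction, so nitrogen and 15N are conserved exactly. Dissolved O2
#' changes linearly (+NPP by day, -respiration by night).
#'
#' @param params A one-row tibble from [bottle_params()].
#' @param schedule A [sim_schedule()].
#' @param spikes Named list of [spike_definition()]s (`aa` and/or `nh4`);
#'   see [default_spikes()].
#' @param bottle_id Identifier carried into the records.
#' @param seed Accepted for interface symmetry; the bottle model itself
#'   is deterministic.
#' @return A tibble of noiseless records at the t0, day and night
#'   censuses, with the per-census pool states in `attr(, "pools")`.
#' @export
simulate_bottle <- function(params, schedule = sim_schedule(),
                            spikes = default_spikes(),
                            bottle_id = "bottle_1", seed = NULL) {
  p <- as.list(params)
  st <- .init_pools(p, spikes)
  o2_amount <- p$o2_conc * p$volume  # umol O2 in the bottle

  records <- list(.census_record(st, p, p$o2_conc, "t0", 0, bottle_id))
  pools <- list(.pool_snapshot(st, "t0"))

  segments <- list(
    list(from = 0, to = schedule$t_day_census, interval = "day",
         census = "day"),
    list(from = schedule$t_day_census, to = schedule$t_night_census,
         interval = "night", census = "night")
  )
  for (seg in segments) {
    len <- seg$to - seg$from
    n_steps <- ceiling(len / schedule$dt - 1e-9)
    h <- len / n_steps
    for (i in seq_len(n_steps)) {
      st <- .step_pools(st, p, h, seg$interval)
    }
    d_o2 <- if (seg$interval == "day") p$o2_npp_day else -p$o2_resp_night
    o2_amount <- o2_amount + d_o2 * len
    if (o2_amount < 0) {
      stop("O2 driven below zero; reduce respiration or shorten the night window.",
           call. = FALSE)
    }
    records[[length(records) + 1L]] <-
      .census_record(st, p, o2_amount / p$volume, seg$census, seg$to,
                     bottle_id)
    pools[[length(pools) + 1L]] <- .pool_snapshot(st, seg$census)
  }
  out <- dplyr::bind_rows(records)
  attr(out, "pools") <- dplyr::bind_rows(pools)
  out
}

#' Measurement-noise specification
#'
#' Gaussian noise on the measured fields. Isotope enrichments are
#' perturbed in delta (per-mil) space — 2 per mil for ammonium delta-15N
#' (chemical conversion methods) and 0.5 per mil for particulate and
#' tissue material (elemental-analyser IRMS); concentrations in µM.
#'
#' @param sd_delta_nh4 s.d. of ammonium delta-15N, per mil.
#' @param sd_delta_particulate s.d. of tissue/POM delta-15N, per mil.
#' @param sd_conc s.d. of nutrient concentrations, µM.
#' @param sd_o2 s.d. of O2 concentration, µmol/L.
#' @param sd_pom_n s.d. of the POM filter N amount, µmol.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sd_delta_nh4 = 2, sd_delta_particulate = 0.5,
                       sd_conc = 0.05, sd_o2 = 2, sd_pom_n = 0.02) {
  vals <- c(sd_delta_nh4, sd_delta_particulate, sd_conc, sd_o2, sd_pom_n)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise standard deviations must be finite and >= 0.", call. = FALSE)
  }
  structure(list(sd_delta_nh4 = sd_delta_nh4,
                 sd_delta_particulate = sd_delta_particulate,
                 sd_conc = sd_conc, sd_o2 = sd_o2, sd_pom_n = sd_pom_n),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
zero_noise <- function() {
  noise_spec(0, 0, 0, 0, 0)
}

#' Apply measurement noise to bottle records
#'
#' Adds Gaussian noise to the measured fields of a record table, drawing
#' from the current RNG state. Delta-space noise is applied to
#' enrichments (convert to per mil, perturb, convert back); plain
#' Gaussian noise to concentrations. Concentrations are truncated at 0
#' and atom fractions to `[0, 1]`; the number of truncated values is
#' reported in `attr(, "n_truncated")` and via a message.
#'
#' @param records A bottle-record tibble.
#' @param noise A [noise_spec()].
#' @param quiet Suppress the truncation message? Default `FALSE`.
#' @return The perturbed records.
#' @export
observe <- function(records, noise = noise_spec(), quiet = FALSE) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- nrow(records)
  n_trunc <- 0L
  jitter_delta <- function(f, sd) {
    if (sd == 0) return(f)
    d <- atom_fraction_to_delta(f) + stats::rnorm(length(f), 0, sd)
    d <- pmax(d, -999.999)
    delta_to_atom_fraction(d)
  }
  clamp01 <- function(f) {
    bad <- !is.na(f) & (f < 0 | f > 1)
    n_trunc <<- n_trunc + sum(bad)
    pmin(pmax(f, 0), 1)
  }
  clamp0 <- function(x) {
    bad <- !is.na(x) & x < 0
    n_trunc <<- n_trunc + sum(bad)
    pmax(x, 0)
  }
  jitter_abs <- function(x, sd) {
    if (sd == 0) return(x)
    out <- x + stats::rnorm(length(x), 0, sd)
    out[is.na(x)] <- NA_real_
    out
  }
  ok <- !is.na(records$nh4_atom_fraction)
  records$nh4_atom_fraction[ok] <-
    clamp01(jitter_delta(records$nh4_atom_fraction[ok], noise$sd_delta_nh4))
  for (col in c("tissue_atom_fraction", "pom_atom_fraction")) {
    ok <- !is.na(records[[col]])
    records[[col]][ok] <-
      clamp01(jitter_delta(records[[col]][ok], noise$sd_delta_particulate))
  }
  for (col in c("nh4_conc", "no3_conc", "no2_conc", "po4_conc", "si_conc",
                "doc_conc", "don_conc")) {
    records[[col]] <- clamp0(jitter_abs(records[[col]], noise$sd_conc))
  }
  records$o2_conc <- clamp0(jitter_abs(records$o2_conc, noise$sd_o2))
  records$pom_n <- clamp0(jitter_abs(records$pom_n, noise$sd_pom_n))
  if (n_trunc > 0 && !quiet) {
    message(sprintf("observe(): truncated %d out-of-range value(s).", n_trunc))
  }
  attr(records, "n_truncated") <- n_trunc
  records
}

#' Simulate the full bottle experiment
#'
#' Replicates bottles over every row of a design table, applies the
#' split-census scheme (alternate bottles are harvested at the end of the
#' day, the rest run through the night), adds measurement noise, and
#' returns one tidy record table. Fully reproducible for a fixed seed.
#'
#' @param design Tibble of [bottle_params()] rows, optionally with an
#'   `n_bottles` column (as in [default_design()]).
#' @param schedule A [sim_schedule()].
#' @param spikes Named spike list, see [default_spikes()].
#' @param n_replicates Bottles per design row when the row carries no
#'   `n_bottles` column.
#' @param noise A [noise_spec()]; use [zero_noise()] for noiseless output.
#' @param seed Integer seed governing all randomness.
#' @return A tidy tibble, one row per bottle x census, with columns
#'   `harvest` (`"day"` or `"night"`) and the measured fields. Day-harvest
#'   bottles carry t0 and day rows; night-harvest bottles carry all three
#'   censuses. The seed is stored in `attr(, "seed")`.
#' @export
simulate_experiment <- function(design = default_design(),
                                schedule = sim_schedule(),
                                spikes = default_spikes(),
                                n_replicates = 1,
                                noise = noise_spec(),
                                seed = 1L) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    p <- design[i, , drop = FALSE]
    n <- if ("n_bottles" %in% names(p) && !is.na(p$n_bottles)) {
      p$n_bottles
    } else {
      n_replicates
    }
    harvest <- rep(c("night", "day"), length.out = n)
    for (b in seq_len(n)) {
      id <- sprintf("%s_%s_%02d", p$site,
                    if (p$treatment == "seagrass") "sg" else "sw", b)
      rec <- simulate_bottle(p[, setdiff(names(p), "n_bottles")],
                             schedule, spikes, bottle_id = id)
      rec$harvest <- harvest[b]
      if (harvest[b] == "day") {
        rec <- rec[rec$census != "night", , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- observe(out, noise, quiet = TRUE)
  out <- out[, c("bottle_id", "harvest",
                 setdiff(names(out), c("bottle_id", "harvest")))]
  attr(out, "seed") <- as.integer(seed)
  out
}
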
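#' Molar masses used in rate conversions
#'
#' Grams per mole of nitrogen and carbon.
#' @return A length-one numeric.
#' @export
molar_mass_n <- function() 14.0067

#' @rdname molar_mass_n
#' @export
molar_mass_c <- function() 12.011

#' Construct a rate estimate row
#'
#' Rate estimates are tidy tibble rows: a value with units, the diel
#' interval it covers, and the attribution of the activity (whole bottle,
#' seawater only, or host after subtraction of the seawater signal).
#'
#' @param value Numeric rate.
#' @param units One of `"nmol_h"`, `"umol_gDM_h"`, `"umol_L_h"`,
#'   `"mgC_gDM_h"`, `"mgC_L_h"`.
#' @param interval `"day"`, `"night"` or `"full"`.
#' @param attribution `"bottle_total"`, `"seawater_only"` or
#'   `"host_attributed"`.
#' @param bottle_id Identifier (may be `NA`).
#' @param site,treatment Design factors (may be `NA`).
#' @param flag `NA` or a short string (e.g. `"negative"`).
#' @return A one-row tibble.
#' @export
rate_estimate <- function(value,
                          units = c("nmol_h", "umol_gDM_h", "umol_L_h",
                                    "mgC_gDM_h", "mgC_L_h"),
                          interval = c("day", "night", "full"),
                          attribution = c("bottle_total", "seawater_only",
                                          "host_attributed"),
                          bottle_id = NA_character_,
                          site = NA_character_,
                          treatment = NA_character_,
                          flag = NA_character_) {
  units <- match.arg(units)
  interval <- match.arg(interval)
  attribution <- match.arg(attribution)
  tibble::tibble(bottle_id = bottle_id, site = site, treatment = treatment,
                 interval = interval, attribution = attribution,
                 value = as.numeric(value), units = units, flag = flag)
}

#' Ammonification rate from the source-sink tracer model
#'
#' Infers the transfer rate from a labelled source pool (the spiked amino
#' acids, at constant enrichment `r_source`) into a sink pool (seawater
#' ammonium) from the sink's enrichment trajectory:
#' \deqn{rate = \frac{R(t)_{sink} - R(0)_{sink}}
#'              {(R_{source} - R(0)_{sink}) \; t} \; \overline{NH_4}}
#' where \eqn{\overline{NH_4}} is the average amount of ammonium over the
#' incubation (µmol). The numerator uses the sink's gain in enrichment;
#' `printed_form = TRUE` switches to the variant with
#' \eqn{R(t)_{sink} - R_{source}} in the numerator, kept for audit
#' only — it is negative whenever the sink stays below the source and is
#' not the source-sink dilution model.
#'
#' @param r_source Source-pool atom fraction (constant over the window).
#' @param r_sink_t0,r_sink_t Sink atom fraction at the start and end of
#'   the window.
#' @param t Window length, hours.
#' @param mean_nh4 Average ammonium amount over the window, µmol.
#' @param printed_form Use the literal published numerator? Default
#'   `FALSE`.
#' @param ... Metadata columns passed to [rate_estimate()].
#' @return A one-row tibble in nmol N per hour; negative rates are
#'   flagged `"negative"`, never truncated.
#' @examples
#' ammonification_rate(0.776, 0.003663, 0.01, t = 7, mean_nh4 = 4)
#' @export
ammonification_rate <- function(r_source, r_sink_t0, r_sink_t, t, mean_nh4,
                                printed_form = FALSE, ...) {
  fr <- c(r_source, r_sink_t0, r_sink_t)
  if (any(fr < 0 | fr > 1)) {
    stop("atom fractions must lie in [0, 1].", call. = FALSE)
  }
  if (t <= 0) stop("`t` must be positive (hours).", call. = FALSE)
  if (mean_nh4 <= 0) stop("`mean_nh4` must be positive (µmol).", call. = FALSE)
  if (r_source == r_sink_t0) {
    stop("degenerate gradient: r_source equals r_sink_t0.", call. = FALSE)
  }
  num <- if (printed_form) r_sink_t - r_source else r_sink_t - r_sink_t0
  rate_umol_h <- num / ((r_source - r_sink_t0) * t) * mean_nh4
  value <- rate_umol_h * 1000  # umol/h -> nmol/h
  rate_estimate(value, units = "nmol_h",
                flag = if (value < 0) "negative" else NA_character_, ...)
}

#' Night-only ammonification by diel partitioning
#'
#' The overnight rate re-applies the source-sink model with the sink's
#' starting enrichment taken as the mean end-of-day value across the
#' day-harvested bottles of the same site x treatment cell.
#'
#' @param day_end_sink_fractions Nonempty numeric vector of end-of-day
#'   sink atom fractions in the cell.
#' @param morning_sink_fraction Sink atom fraction at the morning census.
#' @param r_source Source atom fraction.
#' @param t_night Night window length, hours.
#' @param mean_nh4 Average ammonium amount over the night window, µmol.
#' @inheritParams ammonification_rate
#' @return A one-row tibble in nmol N per hour with `interval = "night"`.
#' @export
night_rate_partition <- function(day_end_sink_fractions,
                                 morning_sink_fraction,
                                 r_source, t_night, mean_nh4,
                                 printed_form = FALSE, ...) {
  if (length(day_end_sink_fractions) == 0) {
    stop("`day_end_sink_fractions` must be nonempty.", call. = FALSE)
  }
  ammonification_rate(r_source,
                      r_sink_t0 = mean(day_end_sink_fractions),
                      r_sink_t = morning_sink_fraction,
                      t = t_night, mean_nh4 = mean_nh4,
                      printed_form = printed_form,
                      interval = "night", ...)
}

#' Attribute bottle rates to the host
#'
#' For every seagrass bottle, the host-attributed rate is the bottle rate
#' minus the mean seawater-only rate of the same site x interval cell;
#' seawater-only rows pass through unchanged. Negative attributions are
#' flagged, never removed.
#'
#' @param rates A rate-estimate tibble with columns `site`, `treatment`,
#'   `interval`, `value` (as produced by [estimate_ammonification()]).
#' @return The input with one extra `host_attributed` row per seagrass
#'   bottle.
#' @export
attribute_host_rate <- function(rates) {
  needed <- c("site", "treatment", "interval", "value", "units")
  missing <- setdiff(needed, names(rates))
  if (length(missing)) {
    stop("rate table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sw <- rates[rates$treatment == "seawater_only", , drop = FALSE]
  sg <- rates[rates$treatment == "seagrass", , drop = FALSE]
  if (nrow(sg) == 0) return(rates)
  sw_means <- dplyr::summarise(
    dplyr::group_by(sw, .data$site, .data$interval),
    sw_mean = mean(.data$value), .groups = "drop")
  joined <- dplyr::left_join(sg, sw_means, by = c("site", "interval"))
  if (any(is.na(joined$sw_mean))) {
    bad <- unique(paste(joined$site[is.na(joined$sw_mean)],
                        joined$interval[is.na(joined$sw_mean)], sep = " x "))
    stop("no seawater_only bottles in cell(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  host <- joined
  host$value <- host$value - host$sw_mean
  host$attribution <- "host_attributed"
  host$flag <- ifelse(host$value < 0, "negative", NA_character_)
  host$sw_mean <- NULL
  dplyr::bind_rows(rates, host)
}

#' A tissue or particulate sample for uptake estimation
#'
#' @param tissue One of `"meristem"`, `"midblade"`,
#'   `"blade_under_epiphytes"`, `"rhizome"`, `"pom_filter"`.
#' @param dry_mass Dry mass, g (required unless `n_umol` is given).
#' @param percent_n Nitrogen content, percent of dry mass.
#' @param atom_fraction_15n Measured 15N atom fraction after incubation.
#' @param baseline_atom_fraction_15n Pre-incubation atom fraction.
#' @param percent_c Optional carbon content, percent.
#' @param n_umol Total sample nitrogen in µmol, overriding the
#'   `dry_mass * percent_n` computation (used for filter samples whose N
#'   is measured directly).
#' @return A `tissue_sample` list.
#' @export
tissue_sample <- function(tissue = c("meristem", "midblade",
                                     "blade_under_epiphytes", "rhizome",
                                     "pom_filter"),
                          dry_mass = NA_real_, percent_n = NA_real_,
                          atom_fraction_15n, baseline_atom_fraction_15n,
                          percent_c = NA_real_, n_umol = NA_real_) {
  tissue <- match.arg(tissue)
  if (is.na(n_umol)) {
    if (is.na(dry_mass) || is.na(percent_n)) {
      stop("give either `n_umol` or both `dry_mass` and `percent_n`.",
           call. = FALSE)
    }
    if (dry_mass <= 0) stop("`dry_mass` must be positive.", call. = FALSE)
    if (percent_n < 0 || percent_n > 100) {
      stop("`percent_n` must lie in [0, 100].", call. = FALSE)
    }
    n_umol <- dry_mass * percent_n / 100 / molar_mass_n() * 1e6
  }
  fr <- c(atom_fraction_15n, baseline_atom_fraction_15n)
  if (any(fr < 0 | fr > 1)) {
    stop("atom fractions must lie in [0, 1].", call. = FALSE)
  }
  structure(list(tissue = tissue, dry_mass = dry_mass,
                 percent_n = percent_n, percent_c = percent_c,
                 atom_fraction_15n = atom_fraction_15n,
                 baseline_atom_fraction_15n = baseline_atom_fraction_15n,
                 n_umol = n_umol),
            class = "tissue_sample")
}

#' Nitrogen uptake rate from atom-percent excess
#'
#' The tracer-uptake estimator
#' \deqn{uptake = \frac{excess}{R \; t} \; N_T}
#' where `excess` is the sample's 15N atom-fraction gain over its
#' baseline, `R` the mean enrichment of the ammonium pool over the
#' incubation (as excess above natural abundance by default, or as
#' absolute atom fraction with `r_mode = "absolute"`), `t` the duration,
#' and \eqn{N_T} the sample's total nitrogen in µmol. Tissue rates are
#' normalised per g dry mass; filter (POM) samples per litre filtered.
#'
#' @param sample A [tissue_sample()].
#' @param mean_pool_enrichment `R`: mean ammonium-pool enrichment.
#' @param t Incubation length, hours.
#' @param filtered_volume Litres of seawater filtered (required for
#'   `pom_filter` samples).
#' @param ... Metadata passed to [rate_estimate()].
#' @return A one-row tibble, µmol N per g dry mass per hour for tissue or
#'   µmol N per litre per hour for POM. Negative excesses yield a flagged
#'   negative rate.
#' @examples
#' s <- tissue_sample("meristem", dry_mass = 0.5, percent_n = 2.1,
#'                    atom_fraction_15n = 0.0041630,
#'                    baseline_atom_fraction_15n = 0.0036630)
#' nitrogen_uptake_rate(s, mean_pool_enrichment = 0.05, t = 7)
#' @export
nitrogen_uptake_rate <- function(sample, mean_pool_enrichment, t,
                                 filtered_volume = NULL, ...) {
  stopifnot(inherits(sample, "tissue_sample"))
  if (t <= 0) stop("`t` must be positive (hours).", call. = FALSE)
  if (mean_pool_enrichment <= 0) {
    stop("`mean_pool_enrichment` must be positive.", call. = FALSE)
  }
  excess <- atom_excess(sample$atom_fraction_15n,
                        sample$baseline_atom_fraction_15n, warn = FALSE)
  uptake_umol_h <- excess / (mean_pool_enrichment * t) * sample$n_umol
  if (sample$tissue == "pom_filter") {
    if (is.null(filtered_volume) || filtered_volume <= 0) {
      stop("POM samples need a positive `filtered_volume` (L).",
           call. = FALSE)
    }
    value <- uptake_umol_h / filtered_volume
    units <- "umol_L_h"
  } else {
    value <- uptake_umol_h / sample$dry_mass
    units <- "umol_gDM_h"
  }
  rate_estimate(value, units = units,
                flag = if (excess < 0) "negative" else NA_character_, ...)
}

#' Convert an oxygen change to a carbon rate
#'
#' Net O2 evolution, after subtraction of the water-column rate, is
#' converted to carbon fixed (or respired) through a photosynthetic
#' quotient (PQ, mol O2 per mol CO2; default 1.0) and the molar mass of
#' carbon. Positive values are carbon fixation, negative respiration.
#'
#' @param delta_o2 O2 change over the window, µmol per bottle (or µmol/L
#'   for water-column-only use with `volume = 1`).
#' @param t Window length, hours.
#' @param dry_mass Normaliser for plant rates, g dry mass.
#' @param volume Normaliser for water-column rates, L.
#' @param water_column_rate Water-column O2 rate to subtract, µmol O2 per
#'   hour (same basis as `delta_o2`). Default 0.
#' @param pq Photosynthetic quotient. Default 1.0.
#' @param ... Metadata passed to [rate_estimate()].
#' @return A one-row tibble in mg C per g dry mass per hour (if
#'   `dry_mass` is given) or mg C per litre per hour (if `volume`).
#' @examples
#' oxygen_to_carbon_rate(100, t = 7, dry_mass = 0.5,
#'                       water_column_rate = 10 / 7)
#' @export
oxygen_to_carbon_rate <- function(delta_o2, t, dry_mass = NULL,
                                  volume = NULL, water_column_rate = 0,
                                  pq = 1.0, ...) {
  if (t <= 0) stop("`t` must be positive (hours).", call. = FALSE)
  if (pq <= 0) stop("`pq` must be positive.", call. = FALSE)
  if (is.null(dry_mass) == is.null(volume)) {
    stop("give exactly one of `dry_mass` or `volume` as the normaliser.",
         call. = FALSE)
  }
  o2_rate <- delta_o2 / t - water_column_rate       # umol O2 / h
  c_rate_mg_h <- o2_rate / pq * molar_mass_c() / 1000  # mg C / h
  if (!is.null(dry_mass)) {
    if (dry_mass <= 0) stop("`dry_mass` must be positive.", call. = FALSE)
    value <- c_rate_mg_h / dry_mass
    units <- "mgC_gDM_h"
  } else {
    if (volume <= 0) stop("`volume` must be positive.", call. = FALSE)
    value <- c_rate_mg_h / volume
    units <- "mgC_L_h"
  }
  rate_estimate(value, units = units,
                flag = if (value < 0) "negative" else NA_character_, ...)
}

#' Benthic-pelagic amplification factor
#'
#' How much the plant's presence amplifies water-column carbon uptake:
#' the fold increase in particulate nitrogen uptake with the plant
#' (day + night integrated) multiplied by the particulate C:N molar
#' ratio, assuming the particles' C:N uptake stoichiometry is constant.
#'
#' @param pom_uptake_with_plant Integrated POM N uptake with the plant,
#'   µmol.
#' @param pom_uptake_seawater_only Same for seawater-only bottles, µmol.
#' @param pom_cn_ratio Molar C:N ratio of the particulate matter.
#' @return A list with `fold_n` (the nitrogen fold increase) and
#'   `amplification` (the carbon amplification factor).
#' @examples
#' amplification_factor(1.6, 1.0, 5.09)
#' @export
amplification_factor <- function(pom_uptake_with_plant,
                                 pom_uptake_seawater_only,
                                 pom_cn_ratio) {
  vals <- c(pom_uptake_with_plant, pom_uptake_seawater_only, pom_cn_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all amplification inputs must be positive.", call. = FALSE)
  }
  fold_n <- pom_uptake_with_plant / pom_uptake_seawater_only
  list(fold_n = fold_n, amplification = fold_n * pom_cn_ratio)
}

#' Net concentration flux
#'
#' Linear net change of a dissolved constituent: positive is net
#' production, negative net uptake.
#'
#' @param conc_t0,conc_t Concentrations at the window ends, µM.
#' @param t Window length, hours.
#' @return µmol per litre per hour.
#' @export
net_flux <- function(conc_t0, conc_t, t) {
  if (any(t <= 0)) stop("`t` must be positive (hours).", call. = FALSE)
  (conc_t - conc_t0) / t
}

#' Fixed-effects factorial ANOVA of rate estimates
#'
#' Standard least-squares factorial decomposition (main effects and all
#' interactions) of a response over up to three crossed factors, with an
#' optional log transform for variance stabilisation of strictly
#' positive rates.
#'
#' @param data A data frame of observations.
#' @param response Name of the response column (string).
#' @param factors Character vector of 1-3 factor column names.
#' @param log_transform Log the response first? Requires all values
#'   positive.
#' @return A tibble with one row per term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic` (F) and `p_value`.
#' @export
factorial_anova <- function(data, response, factors, log_transform = FALSE) {
  if (length(factors) < 1 || length(factors) > 3) {
    stop("`factors` must name 1 to 3 columns.", call. = FALSE)
  }
  missing <- setdiff(c(response, factors), names(data))
  if (length(missing)) {
    stop("data lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)[, c(response, factors)]
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2) {
      stop(sprintf("factor '%s' has fewer than 2 levels.", f), call. = FALSE)
    }
  }
  if (length(factors) > 1) {
    cells <- table(df[factors])
    if (any(cells == 0)) {
      stop("empty design cells: interactions are not estimable.",
           call. = FALSE)
    }
  }
  y <- df[[response]]
  if (log_transform) {
    if (any(y <= 0)) {
      stop("log transform requires a strictly positive response.",
           call. = FALSE)
    }
    df[[response]] <- log(y)
  }
  fml <- stats::as.formula(
    paste0("`", response, "` ~ ", paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  tibble::tibble(
    term = terms,
    df = tab[["Df"]],
    sumsq = tab[["Sum Sq"]],
    meansq = tab[["Mean Sq"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
}
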
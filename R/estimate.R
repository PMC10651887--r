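#' Estimate ammonification rates from a bottle-record table
#'
#' Applies the source-sink estimator per bottle: a day rate for bottles
#' harvested at the end-of-day census (t0 to day), a full-window rate for
#' night-harvested bottles (t0 to night), and a night-only rate obtained
#' by re-anchoring the sink at the mean end-of-day enrichment of the
#' day-harvested bottles in the same site x treatment cell. The average
#' ammonium amount is the mean of the window's endpoint amounts
#' (concentration times bottle volume).
#'
#' @param records A tidy bottle-record tibble (see
#'   [simulate_experiment()] / [read_bottle_table()]).
#' @param r_source Source atom fraction; defaults to each bottle's t0
#'   `aa_atom_fraction` column.
#' @param intervals Which intervals to estimate, subset of
#'   `c("day", "full", "night")`.
#' @param printed_form Passed to [ammonification_rate()].
#' @return A rate-estimate tibble in nmol N per hour per bottle.
#' @export
estimate_ammonification <- function(records, r_source = NULL,
                                    intervals = c("day", "full", "night"),
                                    printed_form = FALSE) {
  intervals <- match.arg(intervals, several.ok = TRUE)
  out <- list()
  wide <- .census_wide(records)
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    rs <- if (is.null(r_source)) w$aa_f_t0 else r_source
    attribution <- if (w$treatment == "seagrass") "bottle_total" else "seawater_only"
    meta <- list(bottle_id = w$bottle_id, site = w$site,
                 treatment = w$treatment, attribution = attribution,
                 printed_form = printed_form)
    if ("day" %in% intervals && w$harvest == "day") {
      out[[length(out) + 1L]] <- do.call(ammonification_rate, c(list(
        r_source = rs, r_sink_t0 = w$nh4_f_t0, r_sink_t = w$nh4_f_day,
        t = w$t_day, mean_nh4 = mean(c(w$nh4_t0, w$nh4_day)) * w$volume,
        interval = "day"), meta))
    }
    if ("full" %in% intervals && w$harvest == "night") {
      out[[length(out) + 1L]] <- do.call(ammonification_rate, c(list(
        r_source = rs, r_sink_t0 = w$nh4_f_t0, r_sink_t = w$nh4_f_night,
        t = w$t_night, mean_nh4 = mean(c(w$nh4_t0, w$nh4_night)) * w$volume,
        interval = "full"), meta))
    }
  }
  if ("night" %in% intervals) {
    day_end <- wide[wide$harvest == "day", ]
    night_b <- wide[wide$harvest == "night", ]
    for (i in seq_len(nrow(night_b))) {
      w <- night_b[i, ]
      anchor <- day_end[day_end$site == w$site &
                          day_end$treatment == w$treatment, ]
      if (nrow(anchor) == 0) next
      rs <- if (is.null(r_source)) w$aa_f_t0 else r_source
      attribution <- if (w$treatment == "seagrass") "bottle_total" else "seawater_only"
      mean_amt <- mean(c(mean(anchor$nh4_day), w$nh4_night)) * w$volume
      out[[length(out) + 1L]] <- night_rate_partition(
        day_end_sink_fractions = anchor$nh4_f_day,
        morning_sink_fraction = w$nh4_f_night,
        r_source = rs, t_night = w$t_night - w$t_day,
        mean_nh4 = mean_amt, printed_form = printed_form,
        bottle_id = w$bottle_id, site = w$site, treatment = w$treatment,
        attribution = attribution)
    }
  }
  dplyr::bind_rows(out)
}

# Pivot a record table to one row per bottle with the census measurements
# needed by the estimators.
.census_wide <- function(records) {
  needed <- c("bottle_id", "site", "treatment", "census", "time_h",
              "volume", "nh4_conc", "nh4_atom_fraction")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("record table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"harvest" %in% names(records)) {
    records$harvest <- ifelse(
      records$bottle_id %in% records$bottle_id[records$census == "night"],
      "night", "day")
  }
  grab <- function(ids, census, col) {
    sub <- records[records$census == census, ]
    sub[[col]][match(ids, sub$bottle_id)]
  }
  ids <- unique(records$bottle_id)
  first <- records[match(ids, records$bottle_id), ]
  tibble::tibble(
    bottle_id = ids,
    site = first$site, treatment = first$treatment,
    harvest = first$harvest, volume = first$volume,
    plant_dry_mass = if ("plant_dry_mass" %in% names(records)) {
      first$plant_dry_mass
    } else NA_real_,
    t_day = grab(ids, "day", "time_h"),
    t_night = grab(ids, "night", "time_h"),
    aa_f_t0 = if ("aa_atom_fraction" %in% names(records)) {
      grab(ids, "t0", "aa_atom_fraction")
    } else NA_real_,
    nh4_t0 = grab(ids, "t0", "nh4_conc"),
    nh4_day = grab(ids, "day", "nh4_conc"),
    nh4_night = grab(ids, "night", "nh4_conc"),
    nh4_f_t0 = grab(ids, "t0", "nh4_atom_fraction"),
    nh4_f_day = grab(ids, "day", "nh4_atom_fraction"),
    nh4_f_night = grab(ids, "night", "nh4_atom_fraction"),
    tissue_f_t0 = .opt_col(records, ids, "t0", "tissue_atom_fraction"),
    tissue_f_day = .opt_col(records, ids, "day", "tissue_atom_fraction"),
    tissue_f_night = .opt_col(records, ids, "night", "tissue_atom_fraction"),
    tissue_n_day = .opt_col(records, ids, "day", "tissue_n_umol"),
    tissue_n_night = .opt_col(records, ids, "night", "tissue_n_umol"),
    pom_f_t0 = .opt_col(records, ids, "t0", "pom_atom_fraction"),
    pom_f_day = .opt_col(records, ids, "day", "pom_atom_fraction"),
    pom_f_night = .opt_col(records, ids, "night", "pom_atom_fraction"),
    pom_n_day = .opt_col(records, ids, "day", "pom_n"),
    pom_n_night = .opt_col(records, ids, "night", "pom_n")
  )
}

.opt_col <- function(records, ids, census, col) {
  if (!col %in% names(records)) return(rep(NA_real_, length(ids)))
  sub <- records[records$census == census, ]
  sub[[col]][match(ids, sub$bottle_id)]
}

#' Estimate nitrogen uptake rates from a bottle-record table
#'
#' Applies the atom-percent-excess estimator per bottle to plant tissue
#' (µmol N per g dry mass per hour) and to the particulate organic
#' matter (µmol N per L per hour). The pool enrichment `R` is the mean
#' of the ammonium pool's enrichment at the window endpoints, as excess
#' above natural abundance (`r_mode = "excess"`, the default) or as
#' absolute atom fraction (`r_mode = "absolute"`).
#'
#' @inheritParams estimate_ammonification
#' @param what `"tissue"`, `"pom"` or both.
#' @param r_mode Enrichment convention for `R`.
#' @return A rate-estimate tibble with `interval` `"day"` (day-harvest
#'   bottles) or `"full"` (night-harvest bottles, t0 to morning).
#' @export
estimate_uptake <- function(records, what = c("tissue", "pom"),
                            r_mode = c("excess", "absolute")) {
  what <- match.arg(what, several.ok = TRUE)
  r_mode <- match.arg(r_mode)
  wide <- .census_wide(records)
  f_nat <- natural_abundance_15n()
  pool_r <- function(f0, ft) {
    if (r_mode == "excess") mean(c(f0, ft)) - f_nat else mean(c(f0, ft))
  }
  out <- list()
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    end <- w$harvest  # "day" or "night"
    t_end <- if (end == "day") w$t_day else w$t_night
    interval <- if (end == "day") "day" else "full"
    f_end <- if (end == "day") w$nh4_f_day else w$nh4_f_night
    r_pool <- pool_r(w$nh4_f_t0, f_end)
    attribution <- if (w$treatment == "seagrass") "bottle_total" else "seawater_only"
    if ("tissue" %in% what && w$treatment == "seagrass") {
      f_tis <- if (end == "day") w$tissue_f_day else w$tissue_f_night
      n_tis <- if (end == "day") w$tissue_n_day else w$tissue_n_night
      if (!is.na(f_tis) && !is.na(n_tis)) {
        s <- tissue_sample("meristem", dry_mass = w$plant_dry_mass,
                           atom_fraction_15n = f_tis,
                           baseline_atom_fraction_15n = w$tissue_f_t0,
                           n_umol = n_tis)
        out[[length(out) + 1L]] <- nitrogen_uptake_rate(
          s, mean_pool_enrichment = r_pool, t = t_end,
          bottle_id = w$bottle_id, site = w$site, treatment = w$treatment,
          interval = interval, attribution = attribution)
      }
    }
    if ("pom" %in% what) {
      f_pom <- if (end == "day") w$pom_f_day else w$pom_f_night
      n_pom <- if (end == "day") w$pom_n_day else w$pom_n_night
      if (!is.na(f_pom) && !is.na(n_pom)) {
        s <- tissue_sample("pom_filter",
                           atom_fraction_15n = f_pom,
                           baseline_atom_fraction_15n = w$pom_f_t0,
                           n_umol = n_pom)
        out[[length(out) + 1L]] <- nitrogen_uptake_rate(
          s, mean_pool_enrichment = r_pool, t = t_end,
          filtered_volume = w$volume,
          bottle_id = w$bottle_id, site = w$site, treatment = w$treatment,
          interval = interval, attribution = attribution)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Amplification of water-column carbon uptake, per site
#'
#' Integrates particulate nitrogen uptake over the full day + night
#' window (the full-interval POM uptake of night-harvested bottles),
#' takes the fold increase of bottles with the plant over seawater-only
#' bottles, and multiplies by the particulate C:N ratio.
#'
#' @param pom_uptake A rate tibble from
#'   `estimate_uptake(records, what = "pom")`.
#' @param cn_ratio Named numeric of C:N molar ratios per site, e.g.
#'   `c(control = 5.09, vent = 5.97)`.
#' @return A tibble with one row per site: `site`, `fold_n`,
#'   `cn_ratio`, `amplification`.
#' @export
estimate_amplification <- function(pom_uptake,
                                   cn_ratio = c(control = 5.09,
                                                vent = 5.97)) {
  full <- pom_uptake[pom_uptake$interval == "full", , drop = FALSE]
  if (nrow(full) == 0) {
    stop("no full-interval POM uptake rows; need night-harvested bottles.",
         call. = FALSE)
  }
  cells <- dplyr::summarise(
    dplyr::group_by(full, .data$site, .data$treatment),
    mean_uptake = mean(.data$value), .groups = "drop")
  out <- list()
  for (site in unique(cells$site)) {
    with_plant <- cells$mean_uptake[cells$site == site &
                                      cells$treatment == "seagrass"]
    sw_only <- cells$mean_uptake[cells$site == site &
                                   cells$treatment == "seawater_only"]
    if (length(with_plant) == 0 || length(sw_only) == 0) next
    cn <- if (site %in% names(cn_ratio)) cn_ratio[[site]] else cn_ratio[[1]]
    amp <- amplification_factor(with_plant, sw_only, cn)
    out[[length(out) + 1L]] <- tibble::tibble(
      site = site, fold_n = amp$fold_n, cn_ratio = cn,
      amplification = amp$amplification)
  }
  dplyr::bind_rows(out)
}

#' Carbon rates from the O2 record of a bottle table
#'
#' Converts each bottle's O2 change over its harvest window to a carbon
#' rate, subtracting the mean seawater-only O2 rate of the same site x
#' interval (for seagrass bottles) and normalising per g plant dry mass;
#' seawater-only bottles are reported per litre without subtraction.
#'
#' @inheritParams estimate_ammonification
#' @param pq Photosynthetic quotient.
#' @return A rate-estimate tibble (mg C per g dry mass per hour for
#'   seagrass bottles; mg C per litre per hour for seawater-only).
#' @export
estimate_carbon <- function(records, pq = 1.0) {
  if (!"o2_conc" %in% names(records)) {
    stop("record table lacks column: o2_conc", call. = FALSE)
  }
  wide <- .census_wide(records)
  o2 <- function(ids, census) {
    sub <- records[records$census == census, ]
    sub$o2_conc[match(ids, sub$bottle_id)]
  }
  wide$o2_t0 <- o2(wide$bottle_id, "t0")
  wide$o2_end <- ifelse(wide$harvest == "day",
                        o2(wide$bottle_id, "day"),
                        o2(wide$bottle_id, "night"))
  wide$t_end <- ifelse(wide$harvest == "day", wide$t_day, wide$t_night)
  wide$interval <- ifelse(wide$harvest == "day", "day", "full")
  # per-bottle O2 change in umol
  wide$delta_o2 <- (wide$o2_end - wide$o2_t0) * wide$volume
  sw <- wide[wide$treatment == "seawater_only", ]
  sw_rates <- dplyr::summarise(
    dplyr::group_by(sw, .data$site, .data$interval),
    wc_rate = mean(.data$delta_o2 / .data$t_end), .groups = "drop")
  out <- list()
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    if (w$treatment == "seagrass") {
      wc <- sw_rates$wc_rate[sw_rates$site == w$site &
                               sw_rates$interval == w$interval]
      if (length(wc) == 0) {
        stop(sprintf("no seawater_only bottles in cell %s x %s.",
                     w$site, w$interval), call. = FALSE)
      }
      out[[length(out) + 1L]] <- oxygen_to_carbon_rate(
        w$delta_o2, t = w$t_end, dry_mass = w$plant_dry_mass,
        water_column_rate = wc, pq = pq,
        bottle_id = w$bottle_id, site = w$site, treatment = w$treatment,
        interval = w$interval, attribution = "host_attributed")
    } else {
      out[[length(out) + 1L]] <- oxygen_to_carbon_rate(
        w$delta_o2, t = w$t_end, volume = w$volume, pq = pq,
        bottle_id = w$bottle_id, site = w$site, treatment = w$treatment,
        interval = w$interval, attribution = "seawater_only")
    }
  }
  dplyr::bind_rows(out)
}
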
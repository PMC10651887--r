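# Independent oracles and fixture builders used across the suite.

# Brute-force two-term mass balance for a spiked pool, written against
# the definition directly (mol-level arithmetic, no package types).
brute_force_spike <- function(bg_umol, bg_f, spike_vol_l, spike_mol_l,
                              spike_f, n_atoms = 1) {
  spike_umol <- spike_vol_l * spike_mol_l * n_atoms * 1e6
  n15 <- bg_umol * bg_f + spike_umol * spike_f
  total <- bg_umol + spike_umol
  list(amount = total, atom_fraction = n15 / total)
}

# Brute-force EC wildcard matcher: split both strings and compare field
# by field with explicit loops (independent of the package's vapply
# implementation).
brute_force_ec_match <- function(ec, pattern) {
  split_fields <- function(s) strsplit(s, ".", fixed = TRUE)[[1]]
  pat <- sub("\\*$", "", pattern)
  pf <- split_fields(pat)
  pf <- pf[pf != ""]
  ef <- split_fields(ec)
  ok <- TRUE
  i <- 1
  while (i <= length(pf)) {
    if (i <= length(ef) && ef[i] != "-" && ef[i] != pf[i]) ok <- FALSE
    i <- i + 1
  }
  ok
}

# Random well-formed EC strings and patterns for the equivalence check.
random_ec <- function(n) {
  f1 <- sample(1:7, n, replace = TRUE)
  f2 <- sample(c(1:20, "-"), n, replace = TRUE)
  f3 <- sample(c(1:30, "-"), n, replace = TRUE)
  f4 <- sample(c(1:120, "-"), n, replace = TRUE)
  paste(f1, f2, f3, f4, sep = ".")
}

random_ec_pattern <- function(n) {
  depth <- sample(1:3, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    fields <- c(sample(1:7, 1), sample(1:20, 1), sample(1:30, 1))
    paste0(paste(fields[seq_len(depth[i])], collapse = "."),
           if (depth[i] < 3) ".*" else "*")
  }, character(1))
}

# Records constructed to satisfy the source-sink model exactly: constant
# source enrichment, constant ammonium pool, sink starting at natural
# abundance and rising linearly per the model's forward relation.
eq1_forward_records <- function(rate_nmol_h, r_source = 0.776,
                                nh4_umol = 4, volume = 0.66,
                                t_day = 6, t_night = 20,
                                site = "control",
                                treatment = "seawater_only",
                                bottle_id = "fix_01",
                                harvest = "night") {
  f0 <- seagrassN15::natural_abundance_15n()
  sink_f <- function(t) {
    f0 + (rate_nmol_h / 1000) * t * (r_source - f0) / nh4_umol
  }
  tibble::tibble(
    bottle_id = bottle_id, harvest = harvest,
    site = site, treatment = treatment,
    census = c("t0", "day", "night"),
    time_h = c(0, t_day, t_night),
    volume = volume,
    aa_atom_fraction = r_source,
    nh4_conc = nh4_umol / volume,
    nh4_atom_fraction = sink_f(c(0, t_day, t_night))
  )
}

# Simulator configuration under which the source-sink assumptions
# approximately hold: seawater only, ammonification the only process.
recovery_amm_params <- function(rate_nmol_h = 5, site = "control") {
  seagrassN15::bottle_params(
    site = site, treatment = "seawater_only",
    ammonification_day = rate_nmol_h,
    ammonification_night = rate_nmol_h)
}

# Seagrass bottle taking up ammonium from a pre-enriched, otherwise
# untouched pool: the atom-percent-excess estimator's home ground.
recovery_uptake_params <- function(uptake_day = 1.2, uptake_night = 0.4) {
  seagrassN15::bottle_params(
    site = "control", treatment = "seagrass",
    plant_nh4_uptake_day = uptake_day,
    plant_nh4_uptake_night = uptake_night)
}

recovery_uptake_spikes <- function(nh4_f = 0.05) {
  seagrassN15::default_spikes(nh4_atom_fraction = nh4_f)
}

# Total N and 15N per census from a simulated bottle's pool snapshots.
pool_totals <- function(records) {
  pools <- attr(records, "pools")
  stats::aggregate(cbind(amount, n15) ~ census, data = pools, FUN = sum)
}
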
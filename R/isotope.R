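#' Isotope constants
#'
#' `r_ref_air()` returns the 15N/14N isotope ratio of atmospheric N2, the
#' reference for delta notation. `natural_abundance_15n()` is the
#' corresponding natural-abundance 15N atom fraction,
#' \eqn{F = R/(1+R)}.
#'
#' @return A length-one numeric.
#' @export
r_ref_air <- function() 0.0036765

#' @rdname r_ref_air
#' @export
natural_abundance_15n <- function() {
  r <- r_ref_air()
  r / (1 + r)
}

#' Create a nitrogen isotope pool
#'
#' An isotope pool is a quantity of nitrogen characterised by its total
#' amount (µmol N), its 15N atom fraction, and optionally the volume of
#' water it is dissolved in (L), from which a concentration (µmol/L)
#' follows.
#'
#' @param amount Total nitrogen, µmol.
#' @param atom_fraction 15N atom fraction, in `[0, 1]`.
#' @param volume Optional volume in litres; `NA` for particulate or tissue
#'   pools that have no meaningful solute volume.
#' @return An object of class `isotope_pool`: a list with elements
#'   `amount`, `atom_fraction` and `volume`.
#' @examples
#' isotope_pool(0.66, natural_abundance_15n(), volume = 0.66)
#' @export
isotope_pool <- function(amount, atom_fraction, volume = NA_real_) {
  stopifnot(is.numeric(amount), length(amount) == 1L,
            is.numeric(atom_fraction), length(atom_fraction) == 1L)
  if (is.na(amount) || amount < 0) {
    stop("`amount` must be a non-negative number of µmol N.", call. = FALSE)
  }
  if (is.na(atom_fraction) || atom_fraction < 0 || atom_fraction > 1) {
    stop("`atom_fraction` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.na(volume) && volume <= 0) {
    stop("`volume`, when given, must be positive (litres).", call. = FALSE)
  }
  structure(
    list(amount = as.numeric(amount),
         atom_fraction = as.numeric(atom_fraction),
         volume = as.numeric(volume)),
    class = "isotope_pool"
  )
}

#' @rdname isotope_pool
#' @param x,pool An `isotope_pool`.
#' @export
is_isotope_pool <- function(x) inherits(x, "isotope_pool")

#' @rdname isotope_pool
#' @export
pool_concentration <- function(pool) {
  stopifnot(is_isotope_pool(pool))
  if (is.na(pool$volume)) {
    stop("pool has no volume; concentration is undefined.", call. = FALSE)
  }
  pool$amount / pool$volume
}

#' @export
print.isotope_pool <- function(x, ...) {
  cat(sprintf("<isotope_pool> %.6g µmol N @ %.6g atom fraction 15N",
              x$amount, x$atom_fraction))
  if (!is.na(x$volume)) {
    cat(sprintf(" in %.4g L (%.6g µM)", x$volume, x$amount / x$volume))
  }
  cat("\n")
  invisible(x)
}

#' Convert between delta notation and atom fraction
#'
#' Isotope ratio mass spectrometers report 15N enrichment as
#' \eqn{\delta^{15}N} per mil versus atmospheric N2, while tracer mass
#' balances need the atom fraction \eqn{F}. The two are related through the
#' isotope ratio \eqn{R = {}^{15}N/{}^{14}N}:
#' \deqn{R = R_{ref} (1 + \delta/1000), \quad F = R / (1 + R)}
#' and inversely \eqn{R = F/(1-F)}, \eqn{\delta = (R/R_{ref} - 1) \times 1000}.
#'
#' @param delta Per-mil delta value(s); must exceed −1000.
#' @param atom_fraction Atom fraction(s), strictly inside (0, 1).
#' @return `delta_to_atom_fraction()` returns atom fractions;
#'   `atom_fraction_to_delta()` returns per-mil values.
#' @examples
#' delta_to_atom_fraction(0)       # natural abundance, 0.003663
#' atom_fraction_to_delta(0.98)    # a 98 atom% tracer, ~1.33e7 per mil
#' @export
delta_to_atom_fraction <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(delta <= -1000)) {
    stop("delta values must exceed -1000 ‰ (atom fraction must stay positive).",
         call. = FALSE)
  }
  r <- r_ref_air() * (1 + delta / 1000)
  r / (1 + r)
}

#' @rdname delta_to_atom_fraction
#' @export
atom_fraction_to_delta <- function(atom_fraction) {
  stopifnot(is.numeric(atom_fraction))
  if (any(atom_fraction <= 0 | atom_fraction >= 1)) {
    stop("atom fractions must lie strictly inside (0, 1).", call. = FALSE)
  }
  r <- atom_fraction / (1 - atom_fraction)
  (r / r_ref_air() - 1) * 1000
}

#' Mix two isotope pools
#'
#' Exact two-pool mass balance: amounts add, and the mixture's atom
#' fraction is the amount-weighted mean of the inputs, so both total N and
#' total 15N are conserved.
#'
#' @param a,b `isotope_pool` objects; at least one must have positive
#'   amount.
#' @param volume Volume assigned to the mixture (L); defaults to `a`'s
#'   volume (tracer additions are negligible in volume).
#' @return An `isotope_pool`.
#' @examples
#' dfaa  <- isotope_pool(0.66, natural_abundance_15n(), volume = 0.66)
#' spike <- isotope_pool(2.5, 0.98)
#' mix_pools(dfaa, spike)
#' @export
mix_pools <- function(a, b, volume = a$volume) {
  stopifnot(is_isotope_pool(a), is_isotope_pool(b))
  total <- a$amount + b$amount
  if (total == 0) {
    stop("cannot mix two empty pools.", call. = FALSE)
  }
  f <- (a$amount * a$atom_fraction + b$amount * b$atom_fraction) / total
  isotope_pool(total, f, volume = volume)
}

#' Define a tracer spike
#'
#' A spike is a small volume of concentrated solution at a known 15N atom
#' fraction. `n_atoms_per_molecule` converts moles of compound to moles of
#' N (1 for NH4Cl and for an amino-acid mixture treated as one N per
#' molecule).
#'
#' @param spike_volume Volume added, litres.
#' @param spike_concentration Solution concentration, mol/L.
#' @param spike_atom_fraction 15N atom fraction of the spike N.
#' @param n_atoms_per_molecule N atoms per molecule of solute.
#' @return An object of class `spike_definition`.
#' @examples
#' spike_definition(50e-6, 0.05, 0.98)
#' @export
spike_definition <- function(spike_volume, spike_concentration,
                             spike_atom_fraction,
                             n_atoms_per_molecule = 1) {
  vals <- c(spike_volume, spike_concentration, spike_atom_fraction,
            n_atoms_per_molecule)
  if (any(!is.finite(vals)) || spike_volume < 0 ||
      spike_concentration <= 0 || spike_atom_fraction <= 0 ||
      n_atoms_per_molecule <= 0) {
    # spike_volume == 0 is allowed as an explicit no-op spike
    stop("spike fields must be positive (spike_volume may be 0 for a no-op).",
         call. = FALSE)
  }
  if (spike_atom_fraction > 1) {
    stop("`spike_atom_fraction` cannot exceed 1.", call. = FALSE)
  }
  structure(
    list(spike_volume = spike_volume,
         spike_concentration = spike_concentration,
         spike_atom_fraction = spike_atom_fraction,
         n_atoms_per_molecule = n_atoms_per_molecule),
    class = "spike_definition"
  )
}

#' @rdname spike_definition
#' @param spike A `spike_definition`.
#' @return `spike_n_amount()` gives the µmol N the spike delivers;
#'   `spike_as_pool()` wraps it as an `isotope_pool`.
#' @export
spike_n_amount <- function(spike) {
  stopifnot(inherits(spike, "spike_definition"))
  # L * mol/L * atoms/molecule -> mol N; report in umol
  spike$spike_volume * spike$spike_concentration *
    spike$n_atoms_per_molecule * 1e6
}

#' @rdname spike_definition
#' @export
spike_as_pool <- function(spike) {
  isotope_pool(spike_n_amount(spike), spike$spike_atom_fraction)
}

#' Enrich a background pool with a tracer spike
#'
#' Applies the two-pool mass balance between a dissolved background pool
#' and a tracer spike. The spike volume is ignored in the diluted volume
#' (tens of µL against hundreds of mL); set `include_spike_volume = TRUE`
#' to add it.
#'
#' @param background An `isotope_pool` with a volume (a dissolved pool).
#' @param spike A `spike_definition`.
#' @param include_spike_volume Add the spike's volume to the mixture
#'   volume? Default `FALSE`.
#' @return An `isotope_pool` at the post-spike enrichment.
#' @examples
#' # 660 mL of seawater with 1 uM dissolved free amino acids at natural
#' # abundance, spiked with 50 uL of a 0.05 M, 98 atom% solution:
#' dfaa <- isotope_pool(0.66, natural_abundance_15n(), volume = 0.66)
#' spike_pool(dfaa, spike_definition(50e-6, 0.05, 0.98))
#' @export
spike_pool <- function(background, spike, include_spike_volume = FALSE) {
  stopifnot(is_isotope_pool(background), inherits(spike, "spike_definition"))
  if (is.na(background$volume)) {
    stop("`background` must have a volume to be spiked.", call. = FALSE)
  }
  if (spike$spike_volume == 0) {
    return(background)
  }
  vol <- background$volume +
    if (include_spike_volume) spike$spike_volume else 0
  mix_pools(background, spike_as_pool(spike), volume = vol)
}

#' Atom-percent excess
#'
#' The enrichment of a sample above its baseline: final atom fraction
#' minus initial atom fraction. Negative excesses (sample below baseline,
#' possible under measurement noise) are returned as-is with a warning,
#' never clamped.
#'
#' @param sample_fraction,baseline_fraction Atom fractions in `[0, 1]`.
#' @param warn Warn on negative excess? Default `TRUE`.
#' @return Numeric excess (same length as the inputs).
#' @export
atom_excess <- function(sample_fraction, baseline_fraction, warn = TRUE) {
  stopifnot(is.numeric(sample_fraction), is.numeric(baseline_fraction))
  if (any(sample_fraction < 0 | sample_fraction > 1) ||
      any(baseline_fraction < 0 | baseline_fraction > 1)) {
    stop("atom fractions must lie in [0, 1].", call. = FALSE)
  }
  excess <- sample_fraction - baseline_fraction
  if (warn && any(excess < 0)) {
    warning(sprintf("%d negative atom-percent excess value(s); returned unclamped.",
                    sum(excess < 0)), call. = FALSE)
  }
  excess
}

#' Parse atom-percent / atom-fraction dialects
#'
#' Field data report 15N enrichment either as atom percent ("at%", 0–100)
#' or as a decimal atom fraction (0–1). Internally everything is a decimal
#' fraction; this helper normalises a vector given its declared unit.
#'
#' @param x Numeric vector.
#' @param unit `"fraction"` or `"percent"`.
#' @return Numeric vector of atom fractions.
#' @export
as_atom_fraction <- function(x, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (unit == "percent") x / 100 else x
}
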
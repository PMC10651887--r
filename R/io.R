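#' Write a bottle-record table
#'
#' Tab-delimited text with a header row; atom fractions are written as
#' decimal fractions. A `# seed:` comment line is emitted when the table
#' carries a seed attribute, and restored on read, so
#' write-read-write round trips are byte identical.
#'
#' @param records A bottle-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bottle_table <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed <- attr(records, "seed")
  if (!is.null(seed)) {
    writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  }
  utils::write.table(as.data.frame(records), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# Columns every bottle table must carry.
.mandatory_columns <- function() {
  c("bottle_id", "site", "treatment", "census", "time_h", "volume",
    "nh4_conc", "nh4_atom_fraction")
}

#' Read a bottle-record table
#'
#' Reads the tab-delimited interchange format back into a validated
#' tibble. Enrichment columns may be in atom percent rather than decimal
#' fractions: either pass `atom_unit = "percent"` or include an
#' `atom_unit` column (values `"fraction"` or `"percent"`, applied per
#' row and dropped). Validation problems are collected and reported
#' together, with row indices.
#'
#' @param path Input file path.
#' @param atom_unit Unit of `*_atom_fraction` columns when the file has
#'   no `atom_unit` column.
#' @return A bottle-record tibble; any `# seed:` header is restored as
#'   the `seed` attribute.
#' @export
read_bottle_table <- function(path, atom_unit = c("fraction", "percent")) {
  atom_unit <- match.arg(atom_unit)
  header <- readLines(path, n = 5)
  seed <- NULL
  m <- grep("^# seed:", header, value = TRUE)
  if (length(m)) seed <- as.integer(sub("^# seed:\\s*", "", m[1]))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  df <- tibble::as_tibble(df)
  missing <- setdiff(.mandatory_columns(), names(df))
  if (length(missing)) {
    stop("bottle table schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frac_cols <- grep("_atom_fraction$", names(df), value = TRUE)
  if ("atom_unit" %in% names(df)) {
    pct <- df$atom_unit == "percent"
    for (col in frac_cols) {
      df[[col]][pct] <- df[[col]][pct] / 100
    }
    df$atom_unit <- NULL
  } else if (atom_unit == "percent") {
    for (col in frac_cols) df[[col]] <- df[[col]] / 100
  }
  problems <- character(0)
  conc_cols <- intersect(c("nh4_conc", "o2_conc", "no3_conc", "no2_conc",
                           "po4_conc", "si_conc", "doc_conc", "don_conc",
                           "pom_n", "volume"), names(df))
  for (col in conc_cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s negative (%g)",
                                      bad, col, df[[col]][bad]))
    }
  }
  for (col in frac_cols) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s outside [0, 1] (%g)",
                                      bad, col, df[[col]][bad]))
    }
  }
  bad_census <- which(!df$census %in% c("t0", "day", "night"))
  if (length(bad_census)) {
    problems <- c(problems, sprintf("row %d: unknown census '%s'",
                                    bad_census, df$census[bad_census]))
  }
  if (length(problems)) {
    stop("bottle table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  if (!is.null(seed)) attr(df, "seed") <- seed
  df
}

#' Default analysis configuration
#'
#' One named list gathering every tunable of the pipeline: schedule,
#' spikes, physical constants, estimator switches and the noise model.
#' All randomness flows from the single `seed` entry.
#'
#' @param seed Integer seed.
#' @return A `config_profile` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    schedule = sim_schedule(),
    spikes = default_spikes(),
    noise = noise_spec(),
    constants = list(r_ref = r_ref_air(),
                     natural_abundance = natural_abundance_15n(),
                     molar_mass_n = molar_mass_n(),
                     molar_mass_c = molar_mass_c(),
                     pq = 1.0),
    estimators = list(printed_eq1 = FALSE,
                      r_mode = "excess",
                      log_transform = TRUE),
    cn_ratio = c(control = 5.09, vent = 5.97),
    medium_floor = 50
  ), class = "config_profile")
}

#' Run manifest
#'
#' A small text file recording what produced a set of outputs: package
#' version, seed, a hash of the configuration, input/output paths,
#' timestamp and warning count. Written alongside every pipeline run.
#'
#' @param path File to write.
#' @param config A `config_profile`.
#' @param inputs,outputs Character vectors of paths.
#' @param n_warnings Count of warnings raised during the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           outputs = character(0), n_warnings = 0L) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  lines <- c(
    sprintf("tool_version: %s",
            as.character(utils::packageVersion("seagrassN15"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_md5: %s", hash),
    sprintf("inputs: %s", paste(inputs, collapse = ", ")),
    sprintf("outputs: %s", paste(outputs, collapse = ", ")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("warnings: %d", n_warnings)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the modules end to end on synthetic data: simulate the bottle
#' experiment, estimate ammonification (with host attribution), nitrogen
#' uptake and carbon rates, compute per-site amplification factors, run
#' the MAG ammonification screen on a synthetic cohort, and write every
#' table plus a run manifest to `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [default_config()] list; `config$seed` drives all
#'   randomness.
#' @param n_mags Size of the synthetic MAG cohort.
#' @return Named list of output paths, invisibly.
#' @export
run_report <- function(out_dir, config = default_config(), n_mags = 67) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    bottles = file.path(out_dir, "bottles.tsv"),
    rates = file.path(out_dir, "ammonification_rates.tsv"),
    uptake = file.path(out_dir, "uptake_rates.tsv"),
    carbon = file.path(out_dir, "carbon_rates.tsv"),
    amplification = file.path(out_dir, "amplification.tsv"),
    mag_flags = file.path(out_dir, "mag_screen_flags.tsv"),
    mag_counts = file.path(out_dir, "mag_screen_counts.tsv"),
    function_matrix = file.path(out_dir, "function_matrix.tsv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  n_warn <- 0L
  wh <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  }
  records <- simulate_experiment(design = default_design(),
                                 schedule = config$schedule,
                                 spikes = config$spikes,
                                 noise = config$noise,
                                 seed = config$seed)
  write_bottle_table(records, paths$bottles)

  amm <- wh(estimate_ammonification(
    records, printed_form = config$estimators$printed_eq1))
  amm <- wh(attribute_host_rate(amm))
  .write_tsv(amm, paths$rates)

  uptake <- wh(estimate_uptake(records, r_mode = config$estimators$r_mode))
  .write_tsv(uptake, paths$uptake)

  carbon <- wh(estimate_carbon(records, pq = config$constants$pq))
  .write_tsv(carbon, paths$carbon)

  amp <- estimate_amplification(uptake[uptake$units == "umol_L_h", ],
                                cn_ratio = config$cn_ratio)
  .write_tsv(amp, paths$amplification)

  synth <- synth_annotations(
    n_mags,
    class_prevalences = c(has_ec_1_4 = 1, has_ec_3_5 = 1,
                          has_ec_4_3_1 = round(0.9 * n_mags) / n_mags),
    module_completion_targets = c(M_nif = 0.75, M_urease = 1,
                                  M_denit = 0.5),
    seed = config$seed)
  flags <- ammonification_screen(synth$annotations)
  .write_tsv(flags, paths$mag_flags)
  .write_tsv(screen_counts(flags), paths$mag_counts)
  fm <- wh(function_matrix(synth$mags, synth$annotations,
                           toy_modules(), medium_floor = config$medium_floor))
  .write_tsv(fm, paths$function_matrix)

  write_manifest(paths$manifest, config,
                 outputs = unlist(paths[names(paths) != "manifest"]),
                 n_warnings = n_warn)
  invisible(paths)
}

.write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Command-line entry point
#'
#' A thin dispatcher over the package functions with the subcommands
#' `simulate`, `rates`, `amplify`, `screen` and `report`. Returns an
#' exit code rather than quitting, so it is testable in-process: 0 on
#' success, 1 on a validation error, 2 on a usage error. Messages go to
#' standard error.
#'
#' @param args Character vector of arguments, e.g.
#'   `c("simulate", "--seed", "7", "--out", "bottles.tsv")`.
#' @return Integer exit code, invisibly.
#' @export
sgn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: seagrassN15 <simulate|rates|amplify|screen|report> [options]",
    "  simulate --seed S --out FILE        write a synthetic bottle table",
    "  rates    --in FILE --out FILE       source-sink + host-attributed rates",
    "  amplify  --in FILE --out FILE       per-site amplification factors",
    "  screen   --seed S --n-mags N --out-dir DIR   synthetic MAG screen",
    "  report   --seed S --out-dir DIR     full synthetic pipeline",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) return(default)
    if (i == length(args)) stop("usage", call. = FALSE)
    args[i + 1]
  }
  if (length(args) < 1 ||
      !args[1] %in% c("simulate", "rates", "amplify", "screen", "report")) {
    message(usage)
    return(invisible(2L))
  }
  code <- tryCatch({
    cmd <- args[1]
    seed <- as.integer(opt("--seed", "1"))
    if (cmd == "simulate") {
      out <- opt("--out") %||% stop("usage", call. = FALSE)
      records <- simulate_experiment(seed = seed)
      write_bottle_table(records, out)
    } else if (cmd == "rates") {
      infile <- opt("--in") %||% stop("usage", call. = FALSE)
      out <- opt("--out") %||% stop("usage", call. = FALSE)
      records <- read_bottle_table(infile)
      rates <- attribute_host_rate(estimate_ammonification(records))
      .write_tsv(rates, out)
    } else if (cmd == "amplify") {
      infile <- opt("--in") %||% stop("usage", call. = FALSE)
      out <- opt("--out") %||% stop("usage", call. = FALSE)
      records <- read_bottle_table(infile)
      uptake <- estimate_uptake(records, what = "pom")
      .write_tsv(estimate_amplification(uptake), out)
    } else if (cmd == "screen") {
      out_dir <- opt("--out-dir") %||% stop("usage", call. = FALSE)
      n_mags <- as.integer(opt("--n-mags", "67"))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      synth <- synth_annotations(n_mags, seed = seed)
      flags <- ammonification_screen(synth$annotations)
      .write_tsv(flags, file.path(out_dir, "mag_screen_flags.tsv"))
      .write_tsv(screen_counts(flags),
                 file.path(out_dir, "mag_screen_counts.tsv"))
    } else if (cmd == "report") {
      out_dir <- opt("--out-dir") %||% stop("usage", call. = FALSE)
      run_report(out_dir, config = default_config(seed = seed))
    }
    0L
  }, error = function(e) {
    if (identical(conditionMessage(e), "usage")) {
      message(usage)
      return(2L)
    }
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
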
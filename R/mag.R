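#' MAG quality tier
#'
#' Assigns each metagenome-assembled genome to a quality tier from its
#' single-copy-gene completeness and redundancy estimates: `high` needs
#' completeness strictly above 90% and redundancy strictly below 10%;
#' `medium` needs completeness between `medium_floor` and 90%
#' (inclusive at both ends) with redundancy below 10%; everything else
#' is `below_medium`.
#'
#' @param completeness Percent completeness, 0-100 (vectorised).
#' @param redundancy Percent redundancy/contamination, >= 0.
#' @param medium_floor Lower completeness bound for the medium tier
#'   (default 50, the usual manual-refinement floor; set 42 to match a
#'   cohort whose observed medium range starts lower).
#' @return Character vector: `"high"`, `"medium"` or `"below_medium"`.
#' @examples
#' quality_tier(c(95, 90, 45), c(5, 5, 8), medium_floor = 42)
#' @export
quality_tier <- function(completeness, redundancy, medium_floor = 50) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("`completeness` must lie in [0, 100].", call. = FALSE)
  }
  if (any(redundancy < 0)) {
    stop("`redundancy` must be >= 0.", call. = FALSE)
  }
  ifelse(completeness > 90 & redundancy < 10, "high",
         ifelse(completeness >= medium_floor & completeness <= 90 &
                  redundancy < 10, "medium", "below_medium"))
}

# Split a dotted EC string into fields, validating shape. Returns a
# character vector of 1-4 fields; "-" marks an unannotated field.
.ec_fields <- function(ec) {
  if (!is.character(ec) || length(ec) != 1L || is.na(ec) || ec == "") {
    stop("malformed EC string: ", deparse(ec), call. = FALSE)
  }
  fields <- strsplit(sub("^EC:", "", ec), ".", fixed = TRUE)[[1]]
  if (length(fields) < 1 || length(fields) > 4 || any(fields == "")) {
    stop("malformed EC string: ", ec, call. = FALSE)
  }
  if (!grepl("^[0-9]+$", fields[1])) {
    stop("malformed EC string (first field must be numeric): ", ec,
         call. = FALSE)
  }
  fields
}

#' Wildcard EC-number matching
#'
#' Field-wise comparison of an EC annotation against a class pattern.
#' A pattern either names a full EC number or ends in `*`; all pattern
#' fields before the `*` must equal the corresponding EC fields exactly,
#' so `"1.4.*"` matches `1.4.1.2` but not `1.14.13.1` (fields, not
#' string prefixes). A trailing `"1*"` constrains its own field too, so
#' `"4.3.1*"` matches `4.3.1.19` but not `4.3.2.1`. Unannotated EC
#' fields (`"-"`, or absent) are treated as compatible with any
#' constraint, so partial annotations match on their known fields.
#'
#' @param ec Character vector of dotted EC strings (an optional `EC:`
#'   prefix is stripped).
#' @param pattern A single wildcard pattern, e.g. `"1.4.*"`, `"4.3.1*"`,
#'   or a full EC number.
#' @return Logical vector, one element per `ec`.
#' @examples
#' ec_matches(c("1.4.1.2", "1.14.13.1"), "1.4.*")
#' @export
ec_matches <- function(ec, pattern) {
  pf <- .ec_fields(sub("\\*$", "", pattern))
  had_star <- grepl("\\*$", pattern)
  if (!had_star && length(.ec_fields(pattern)) < 4) {
    # a bare partial pattern without "*" is ambiguous; require 4 fields
    stop("pattern must end in '*' or be a full 4-field EC number: ",
         pattern, call. = FALSE)
  }
  vapply(ec, function(e) {
    ef <- .ec_fields(e)
    for (i in seq_along(pf)) {
      if (i > length(ef) || ef[i] == "-") next  # unknown field: compatible
      if (ef[i] != pf[i]) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# The three ammonification enzyme classes screened for.
.ammonification_patterns <- function() {
  c(has_ec_1_4 = "1.4.*",      # oxidoreductases acting on CH-NH2 bonds
    has_ec_3_5 = "3.5.*",      # hydrolases of non-peptide C-N bonds
    has_ec_4_3_1 = "4.3.1*")   # ammonia lyases
}

# Normalise a ";"-separated or list column to a list of character vectors.
.split_multi <- function(x) {
  if (is.list(x)) {
    lapply(x, function(v) v[nzchar(v)])
  } else {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
}

#' Screen MAGs for ammonification enzyme classes
#'
#' Flags, per MAG, whether at least one annotated gene falls in each of
#' the three ammonification enzyme classes: oxidoreductases acting on
#' CH-NH2 bonds (EC 1.4.*), hydrolases acting on carbon-nitrogen bonds
#' other than peptide bonds (EC 3.5.*, e.g. ureases), and ammonia
#' lyases (EC 4.3.1*).
#'
#' @param annotations Tibble with columns `mag_id`, `gene_id` and
#'   `ec_numbers` (`;`-separated string or list column of dotted EC
#'   strings).
#' @return A tibble with one row per MAG and logical columns
#'   `has_ec_1_4`, `has_ec_3_5`, `has_ec_4_3_1`; cohort counts per class
#'   are in `attr(, "counts")` and via [screen_counts()].
#' @export
ammonification_screen <- function(annotations) {
  needed <- c("mag_id", "ec_numbers")
  missing <- setdiff(needed, names(annotations))
  if (length(missing)) {
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(annotations) == 0) {
    stop("annotation table is empty.", call. = FALSE)
  }
  ecs <- .split_multi(annotations$ec_numbers)
  pats <- .ammonification_patterns()
  mags <- sort(unique(annotations$mag_id))
  flags <- tibble::tibble(mag_id = mags)
  for (cls in names(pats)) {
    gene_hit <- vapply(ecs, function(e) {
      length(e) > 0 && any(ec_matches(e, pats[[cls]]))
    }, logical(1))
    hit_mags <- unique(annotations$mag_id[gene_hit])
    flags[[cls]] <- flags$mag_id %in% hit_mags
  }
  counts <- vapply(names(pats), function(cls) sum(flags[[cls]]), integer(1))
  attr(flags, "counts") <- counts
  flags
}

#' @rdname ammonification_screen
#' @param flags Output of `ammonification_screen()`.
#' @export
screen_counts <- function(flags) {
  cls <- intersect(names(.ammonification_patterns()), names(flags))
  tibble::tibble(class = cls,
                 n_mags = unname(vapply(cls, function(k) sum(flags[[k]]),
                                        integer(1))))
}

#' Define a metabolic module
#'
#' A module is a named set of ortholog identifiers that together
#' constitute a metabolic capability.
#'
#' @param module_id Identifier string.
#' @param required_ortholog_ids Nonempty character vector.
#' @return A `module_definition` list.
#' @export
module_definition <- function(module_id, required_ortholog_ids) {
  required_ortholog_ids <- unique(as.character(required_ortholog_ids))
  if (length(required_ortholog_ids) == 0) {
    stop("a module needs at least one ortholog.", call. = FALSE)
  }
  structure(list(module_id = module_id,
                 required_ortholog_ids = required_ortholog_ids),
            class = "module_definition")
}

#' Module completion of a MAG
#'
#' The fraction of a module's required orthologs present in the MAG's
#' annotations; a module counts as complete when the fraction reaches
#' the threshold (75% by default, inclusive).
#'
#' @param present_orthologs Character vector of ortholog ids annotated
#'   in the MAG.
#' @param module A [module_definition()].
#' @param threshold Completion threshold in `[0, 1]`, compared with
#'   `>=`.
#' @return A list with `fraction` and `complete`.
#' @examples
#' m <- module_definition("M1", paste0("K", 1:8))
#' module_completion(paste0("K", 1:6), m)  # 0.75, complete
#' @export
module_completion <- function(present_orthologs, module, threshold = 0.75) {
  stopifnot(inherits(module, "module_definition"))
  req <- module$required_ortholog_ids
  fraction <- length(intersect(unique(present_orthologs), req)) / length(req)
  list(fraction = fraction, complete = fraction >= threshold)
}

#' MAG x module function matrix
#'
#' Completion fractions for every quality-tiered MAG (medium tier or
#' better) against a list of module definitions, in deterministic
#' lexicographic row (mag_id) and column (module_id) order, with tier
#' and taxonomy carried alongside — the tabular form of a
#' presence/completion heatmap.
#'
#' @param mags Tibble with columns `mag_id`, `completeness`,
#'   `redundancy`, and optionally `taxonomy` and `sample`.
#' @param annotations Tibble with `mag_id` and `ortholog_ids`
#'   (`;`-separated or list column).
#' @param modules List of [module_definition()]s.
#' @param medium_floor Passed to [quality_tier()].
#' @param threshold Completion threshold (recorded as attribute; the
#'   matrix stores fractions).
#' @return A tibble: `mag_id`, `tier`, `taxonomy`, one numeric column
#'   per module. Annotation rows for unknown MAGs are skipped with a
#'   warning; the skip count is in `attr(, "n_skipped")`.
#' @export
function_matrix <- function(mags, annotations, modules,
                            medium_floor = 50, threshold = 0.75) {
  stopifnot(all(c("mag_id", "completeness", "redundancy") %in% names(mags)))
  unknown <- !annotations$mag_id %in% mags$mag_id
  if (any(unknown)) {
    warning(sprintf("skipping %d annotation row(s) for unknown MAGs.",
                    sum(unknown)), call. = FALSE)
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  mags$tier <- quality_tier(mags$completeness, mags$redundancy,
                            medium_floor = medium_floor)
  keep <- mags[mags$tier %in% c("high", "medium"), , drop = FALSE]
  keep <- keep[order(keep$mag_id), , drop = FALSE]
  module_ids <- vapply(modules, function(m) m$module_id, character(1))
  ord <- order(module_ids)
  modules <- modules[ord]
  module_ids <- module_ids[ord]
  split_orthos <- .split_multi(annotations$ortholog_ids)
  mag_orthos <- split(unlist(split_orthos, use.names = FALSE),
                      rep(annotations$mag_id,
                          lengths(split_orthos)))
  out <- tibble::tibble(
    mag_id = keep$mag_id,
    tier = keep$tier,
    taxonomy = if ("taxonomy" %in% names(keep)) keep$taxonomy else NA_character_
  )
  for (j in seq_along(modules)) {
    out[[module_ids[j]]] <- vapply(keep$mag_id, function(id) {
      module_completion(mag_orthos[[id]] %||% character(0),
                        modules[[j]], threshold)$fraction
    }, numeric(1), USE.NAMES = FALSE)
  }
  attr(out, "n_skipped") <- sum(unknown)
  attr(out, "threshold") <- threshold
  out
}

#' A small built-in module map for tests and examples
#'
#' Toy stand-ins for curated metabolic modules (nitrogen fixation,
#' urea degradation, denitrification), each a handful of ortholog ids.
#' Real module definitions can be supplied in the same shape.
#'
#' @return Named list of [module_definition()]s.
#' @export
toy_modules <- function() {
  list(
    nitrogen_fixation = module_definition(
      "M_nif", c("K02588", "K02586", "K02591", "K00531",
                 "K02585", "K02587", "K02592", "K02589")),
    urea_degradation = module_definition(
      "M_urease", c("K01428", "K01429", "K01430", "K03190")),
    denitrification = module_definition(
      "M_denit", c("K00368", "K00370", "K00376", "K02305", "K04561",
                   "K15864"))
  )
}

#' Generate a synthetic MAG cohort with planted screen outcomes
#'
#' Builds MAG summary and gene-annotation tables whose ammonification
#' class prevalences, module completion fractions and quality-tier
#' counts are planted constructively: when a target times the cohort or
#' module size is an integer the realised count matches it exactly,
#' otherwise the nearest achievable count is used with a warning.
#'
#' @param n_mags Cohort size.
#' @param class_prevalences Named numeric in `[0, 1]` for
#'   `has_ec_1_4`, `has_ec_3_5`, `has_ec_4_3_1`.
#' @param module_completion_targets Named numeric in `[0, 1]`, one per
#'   module of `modules`, applied to every MAG.
#' @param modules Module definitions the targets refer to.
#' @param tier_counts Named integer vector
#'   (`high`, `medium`, `below_medium`) summing to `n_mags`; default
#'   splits the cohort roughly 1/3, 5/8, remainder.
#' @param seed Integer seed (assignment of which MAGs carry which class
#'   is a seeded permutation).
#' @return A list with tibbles `mags` and `annotations`.
#' @export
synth_annotations <- function(n_mags,
                              class_prevalences = c(has_ec_1_4 = 1,
                                                    has_ec_3_5 = 1,
                                                    has_ec_4_3_1 = 0.9),
                              module_completion_targets = NULL,
                              modules = toy_modules(),
                              tier_counts = NULL,
                              seed = 1L) {
  if (any(class_prevalences < 0 | class_prevalences > 1)) {
    stop("class prevalences must lie in [0, 1].", call. = FALSE)
  }
  set.seed(seed)
  mag_ids <- sprintf("MAG%03d", seq_len(n_mags))
  samples <- rep(c("blade_control", "blade_vent", "rhizome_control",
                   "rhizome_vent"), length.out = n_mags)
  if (is.null(tier_counts)) {
    n_high <- round(n_mags / 3)
    n_medium <- round(n_mags * 5 / 8)
    tier_counts <- c(high = n_high, medium = n_medium,
                     below_medium = n_mags - n_high - n_medium)
  }
  if (sum(tier_counts) != n_mags || any(tier_counts < 0)) {
    stop("`tier_counts` must be non-negative and sum to `n_mags`.",
         call. = FALSE)
  }
  completeness <- c(
    stats::runif(tier_counts[["high"]], 91, 99),
    stats::runif(tier_counts[["medium"]], 55, 90),
    stats::runif(tier_counts[["below_medium"]], 20, 45))
  redundancy <- c(
    stats::runif(tier_counts[["high"]] + tier_counts[["medium"]], 0, 9),
    stats::runif(tier_counts[["below_medium"]], 0, 9))
  taxonomy <- sprintf("Bacteria;Phylum%02d;Class%02d;Genus%02d",
                      (seq_len(n_mags) %% 5) + 1,
                      (seq_len(n_mags) %% 9) + 1,
                      seq_len(n_mags))
  taxonomy[seq_len(min(3, n_mags))] <- ""  # a few unresolved genomes
  mags <- tibble::tibble(mag_id = mag_ids, sample = samples,
                         completeness = completeness,
                         redundancy = redundancy,
                         taxonomy = taxonomy)

  class_ecs <- c(has_ec_1_4 = "1.4.1.2",    # glutamate dehydrogenase
                 has_ec_3_5 = "3.5.1.5",    # urease
                 has_ec_4_3_1 = "4.3.1.19") # threonine ammonia-lyase
  ann <- list()
  gene_counter <- 0L
  add_gene <- function(mag_id, ec, ko) {
    gene_counter <<- gene_counter + 1L
    tibble::tibble(mag_id = mag_id,
                   gene_id = sprintf("gene_%05d", gene_counter),
                   ec_numbers = ec, ortholog_ids = ko)
  }
  for (cls in names(class_prevalences)) {
    target <- class_prevalences[[cls]] * n_mags
    k <- round(target)
    if (abs(k - target) > 1e-9) {
      warning(sprintf("class %s: target %.3f not achievable with %d MAGs; using %d.",
                      cls, class_prevalences[[cls]], n_mags, k),
              call. = FALSE)
    }
    carriers <- sample(mag_ids, k)
    for (id in carriers) {
      ann[[length(ann) + 1L]] <- add_gene(id, class_ecs[[cls]], "")
    }
  }
  if (!is.null(module_completion_targets)) {
    module_ids <- vapply(modules, function(m) m$module_id, character(1))
    for (mid in names(module_completion_targets)) {
      m <- modules[[match(mid, module_ids)]]
      if (is.na(match(mid, module_ids))) {
        stop("unknown module in targets: ", mid, call. = FALSE)
      }
      size <- length(m$required_ortholog_ids)
      target <- module_completion_targets[[mid]] * size
      k <- round(target)
      if (abs(k - target) > 1e-9) {
        warning(sprintf("module %s: fraction %.3f of %d genes not achievable; using %d/%d.",
                        mid, module_completion_targets[[mid]], size, k, size),
                call. = FALSE)
      }
      kos <- m$required_ortholog_ids[seq_len(k)]
      for (id in mag_ids) {
        for (ko in kos) {
          ann[[length(ann) + 1L]] <- add_gene(id, "", ko)
        }
      }
    }
  }
  # unlabelled background genes so tables never look degenerate
  for (id in mag_ids) {
    ann[[length(ann) + 1L]] <- add_gene(id, "2.7.1.1", "K00844")
  }
  list(mags = mags, annotations = dplyr::bind_rows(ann))
}
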
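# CSV/Newick/YAML interfaces, the packaged results fixture, and the
# end-to-end pipeline. All tables are comma-separated UTF-8 with a header
# row and "." as the decimal mark, fixed to avoid locale drift.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    tc_stop("missing_file", sprintf("%s file not found: %s", what, path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) tc_stop("malformed_csv",
                                sprintf("cannot parse %s (%s): %s", what, path,
                                        conditionMessage(e)))
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    tc_stop("malformed_csv", sprintf("%s (%s) lacks columns: %s", what, path,
                                     paste(missing, collapse = ", ")))
  }
  df
}

#' Read increment transects from CSV
#'
#' `transects.csv` has one row per boundary (`tooth_id`, `plane`,
#' `position_um`); the optional companion `gaps.csv` has one row per
#' unreadable interval (`tooth_id`, `gap_start_um`, `gap_end_um`).
#'
#' @param transects_path Path to `transects.csv`.
#' @param gaps_path Optional path to `gaps.csv`.
#' @return Named list of [increment_transect()] objects, keyed by tooth id.
#' @export
read_transects <- function(transects_path, gaps_path = NULL) {
  df <- read_csv_checked(transects_path, c("tooth_id", "plane", "position_um"),
                         "transects")
  gaps <- if (!is.null(gaps_path)) {
    read_csv_checked(gaps_path, c("tooth_id", "gap_start_um", "gap_end_um"), "gaps")
  } else {
    data.frame(tooth_id = character(0), gap_start_um = numeric(0),
               gap_end_um = numeric(0))
  }
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  out <- list()
  for (id in unique(df$tooth_id)) {
    sub <- df[df$tooth_id == id, , drop = FALSE]
    plane <- unique(sub$plane)
    if (length(plane) != 1L) {
      tc_stop("malformed_csv",
              sprintf("tooth %s has inconsistent section planes (rows %s)",
                      id, paste(which(df$tooth_id == id), collapse = ",")))
    }
    g <- gaps[gaps$tooth_id == id, c("gap_start_um", "gap_end_um"), drop = FALSE]
    out[[id]] <- increment_transect(
      id, plane, sort(sub$position_um),
      gaps = if (nrow(g) > 0L) g else NULL
    )
  }
  out
}

#' Read tooth records from CSV
#'
#' `teeth.csv` columns: `tooth_id`, `taxon`, `specimen_id`, `element`,
#' `position_label`, `age_days`, `age_is_minimum`, `crown_height_um`,
#' `rp_height_um`, `ankylosed`, `shed`. Empty cells in the optional
#' measurement columns are treated as absent.
#'
#' @param path Path to `teeth.csv`.
#' @return Named list of [tooth_record()] objects, keyed by tooth id.
#' @export
read_teeth <- function(path) {
  df <- read_csv_checked(path, c("tooth_id", "taxon", "specimen_id", "element",
                                 "position_label", "age_days"), "teeth")
  if (anyDuplicated(df$tooth_id)) {
    tc_stop("duplicate_id", sprintf("duplicate tooth ids in %s: %s", path,
      paste(unique(df$tooth_id[duplicated(df$tooth_id)]), collapse = ", ")))
  }
  opt_num <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]][row]
    if (is.na(v) || (is.character(v) && !nzchar(v))) NULL else as.numeric(v)
  }
  opt_flag <- function(row, col) {
    if (!col %in% names(df)) return(FALSE)
    v <- as.logical(df[[col]][row])
    !is.na(v) && v
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[df$tooth_id[i]]] <- withCallingHandlers(
      tooth_record(
        taxon = df$taxon[i], specimen_id = df$specimen_id[i],
        element = df$element[i], position_label = df$position_label[i],
        age_days = df$age_days[i],
        age_is_minimum = opt_flag(i, "age_is_minimum"),
        crown_height = opt_num(i, "crown_height_um"),
        rp_height = opt_num(i, "rp_height_um"),
        ankylosed = opt_flag(i, "ankylosed"),
        shed = opt_flag(i, "shed")
      ),
      toothchron_error = function(e) {
        tc_stop(class(e)[1L], sprintf("%s (row %d of %s)", conditionMessage(e), i, path))
      }
    )
  }
  out
}

#' Read tooth families from CSV
#'
#' `families.csv` columns: `family_id`, `functional_tooth_id`,
#' `replacement_tooth_ids` (semicolon-separated, oldest first; may be
#' empty).
#'
#' @param path Path to `families.csv`.
#' @param teeth Named list of [tooth_record()]s (from [read_teeth()]).
#' @return Named list of [tooth_family()] objects.
#' @export
read_families <- function(path, teeth) {
  df <- read_csv_checked(path, c("family_id", "functional_tooth_id",
                                 "replacement_tooth_ids"), "families")
  out <- list()
  for (i in seq_len(nrow(df))) {
    fid <- df$family_id[i]
    fun_id <- df$functional_tooth_id[i]
    if (!fun_id %in% names(teeth)) {
      tc_stop("dangling_reference",
              sprintf("family %s (row %d) references unknown tooth %s", fid, i, fun_id))
    }
    rep_ids <- df$replacement_tooth_ids[i]
    rep_ids <- if (is.na(rep_ids) || !nzchar(rep_ids)) character(0) else
      trimws(strsplit(rep_ids, ";", fixed = TRUE)[[1L]])
    unknown <- setdiff(rep_ids, names(teeth))
    if (length(unknown) > 0L) {
      tc_stop("dangling_reference",
              sprintf("family %s (row %d) references unknown teeth: %s",
                      fid, i, paste(unknown, collapse = ", ")))
    }
    fam <- tooth_family(teeth[[fun_id]], teeth[rep_ids], family_id = fid)
    fam$functional_tooth_id <- fun_id
    out[[fid]] <- fam
  }
  out
}

#' Read apex profiles from CSV
#'
#' `profiles.csv` columns: `tooth_id`, `line_index_from_apex`,
#' `cumulative_height_um`.
#'
#' @param path Path to `profiles.csv`.
#' @return Named list of [apex_profile()] objects, keyed by tooth id.
#' @export
read_profiles <- function(path) {
  df <- read_csv_checked(path, c("tooth_id", "line_index_from_apex",
                                 "cumulative_height_um"), "profiles")
  out <- list()
  for (id in unique(df$tooth_id)) {
    sub <- df[df$tooth_id == id, , drop = FALSE]
    sub <- sub[order(sub$line_index_from_apex), , drop = FALSE]
    out[[id]] <- apex_profile(sub$cumulative_height_um, tooth_id = id)
  }
  out
}

#' Read a per-taxon trait table from CSV
#'
#' `traits.csv` columns: `taxon`, `diet`, `body_mass_kg`, `longevity_days`,
#' `longevity_is_min`, `rate_days`, `rate_is_min`.
#'
#' @param path Path to `traits.csv`.
#' @return Validated data frame.
#' @export
read_traits <- function(path) {
  df <- read_csv_checked(path, c("taxon", "diet"), "traits")
  validate_traits(df)
  df
}

#' Load and cross-validate a full set of input tables
#'
#' @param teeth_path,families_path Paths to `teeth.csv` and `families.csv`.
#' @param profiles_path,transects_path,gaps_path,traits_path,tree_path
#'   Optional paths to the remaining tables.
#' @return List with components `teeth`, `families`, and (when supplied)
#'   `profiles`, `transects`, `traits`, `tree`.
#' @export
load_tables <- function(teeth_path, families_path, profiles_path = NULL,
                        transects_path = NULL, gaps_path = NULL,
                        traits_path = NULL, tree_path = NULL) {
  teeth <- read_teeth(teeth_path)
  out <- list(teeth = teeth, families = read_families(families_path, teeth))
  if (!is.null(profiles_path)) out$profiles <- read_profiles(profiles_path)
  if (!is.null(transects_path)) out$transects <- read_transects(transects_path, gaps_path)
  if (!is.null(traits_path)) out$traits <- read_traits(traits_path)
  if (!is.null(tree_path)) {
    out$tree <- ape::read.tree(tree_path)
    if (is.null(out$tree)) tc_stop("malformed_tree", paste("cannot parse", tree_path))
  }
  out
}

# --- packaged fixtures ------------------------------------------------------

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "toothchron")
  if (!nzchar(p)) tc_stop("missing_file", paste("packaged fixture not found:", file))
  p
}

#' The packaged table of published line counts and rates
#'
#' Every per-tooth line count, estimated replacement count, and replacement
#' rate reported for the thirteen fossil taxa and two extant varanids in
#' the study this package models, one row per tooth, with a provenance
#' note per row. `expected_discrepancy` marks rows whose printed rate is
#' inconsistent with the printed counts (or whose family attribution is
#' ambiguous in the source); regression tests assert the recomputed and
#' printed values separately for those rows.
#'
#' @return Data frame with columns `taxon`, `specimen`, `element`,
#'   `position`, `functional_lines`, `replacement_lines`,
#'   `estimated_lines`, `printed_rate`, `method`, `is_minimum`,
#'   `expected_discrepancy`, `note`.
#' @export
paper_fixture <- function() {
  df <- read_csv_checked(fixture_path("printed_counts.csv"),
                         c("taxon", "specimen", "element", "position",
                           "functional_lines", "replacement_lines",
                           "estimated_lines", "printed_rate", "method",
                           "is_minimum", "expected_discrepancy", "note"),
                         "printed counts fixture")
  df$is_minimum <- isTRUE_vec(df$is_minimum)
  df$expected_discrepancy <- isTRUE_vec(df$expected_discrepancy)
  df
}

#' Packaged per-taxon trait table
#'
#' Diet categories, tooth longevities and replacement rates as published;
#' body masses are package-estimated order-of-magnitude values (the source
#' prints none), so mass-based results on this table are indicative only.
#'
#' @return Data frame in the `traits.csv` schema.
#' @export
trait_fixture <- function() {
  read_traits(fixture_path("traits_synthetic_mass.csv"))
}

#' Packaged time-calibrated phylogeny
#'
#' A topology-faithful reconstruction of the study taxa's phylogeny with
#' plausible branch lengths in millions of years; synthetic in the sense
#' that branch lengths are not asserted against any published calibration.
#'
#' @return An `ape` `phylo` object with 14 tips.
#' @export
tree_fixture <- function() {
  ape::read.tree(fixture_path("tree_synthetic.nwk"))
}

#' Recompute replacement rates from the packaged fixture counts
#'
#' Applies the package's estimators to the published counts: direct
#' subtraction where the replacement tooth's count is printed, subtraction
#' of the published pit-estimated count for the resorption-pit rows, and
#' the minimum rule where neither replacement tooth nor pit is present.
#' Rows without a usable functional count are skipped.
#'
#' @param fixture Fixture table; defaults to [paper_fixture()].
#' @return Data frame with `taxon`, `position`, `method`,
#'   `recomputed_rate`, `printed_rate`, `matches_printed`, `is_minimum`,
#'   `expected_discrepancy`.
#' @export
recompute_fixture_rates <- function(fixture = paper_fixture()) {
  rows <- fixture[!is.na(fixture$functional_lines) & fixture$method != "none", ,
                  drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    rate <- switch(
      r$method,
      direct = replacement_rate_direct(r$functional_lines,
                                       r$replacement_lines)$rate_days,
      rp_height = r$functional_lines - r$estimated_lines,
      dentine_extent = if (!is.na(r$estimated_lines))
        r$functional_lines - r$estimated_lines else NA_integer_,
      minimum = r$functional_lines,
      NA_integer_
    )
    data.frame(
      taxon = r$taxon, position = r$position, method = r$method,
      recomputed_rate = as.integer(rate), printed_rate = r$printed_rate,
      matches_printed = !is.na(rate) && !is.na(r$printed_rate) &&
        rate == r$printed_rate,
      is_minimum = r$is_minimum,
      expected_discrepancy = r$expected_discrepancy,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# --- pipeline ---------------------------------------------------------------

#' Run configuration
#'
#' Builds (or reads from YAML) the configuration for [run_pipeline()].
#'
#' @param teeth,families Paths to the required tables.
#' @param profiles,transects,gaps,traits,tree Optional table paths.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed, required because the association test may be
#'   Monte-Carlo.
#' @param n_permutations Permutation count for the association test.
#' @param yaml_path If given, all other arguments are read from this YAML
#'   file (keys as above).
#' @return A `run_config` list.
#' @export
run_config <- function(teeth = NULL, families = NULL, profiles = NULL,
                       transects = NULL, gaps = NULL, traits = NULL,
                       tree = NULL, out_dir = tempdir(), seed = 1L,
                       n_permutations = 9999L, yaml_path = NULL) {
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    return(do.call(run_config, y[setdiff(names(y), "yaml_path")]))
  }
  if (is.null(teeth) || is.null(families)) {
    tc_stop("configuration_error", "teeth and families paths are required")
  }
  if (!is_scalar_number(seed)) {
    tc_stop("configuration_error", "a numeric seed is required")
  }
  structure(
    list(teeth = teeth, families = families, profiles = profiles,
         transects = transects, gaps = gaps, traits = traits, tree = tree,
         out_dir = out_dir, seed = as.integer(seed),
         n_permutations = as.integer(n_permutations)),
    class = "run_config"
  )
}

#' Run the full dental-chronology pipeline
#'
#' Loads the configured tables, computes a replacement-rate estimate and
#' longevity for every tooth family (`rates.csv`), and, when trait/tree
#' inputs are configured, the diet-group summary (`summary.csv`), the
#' body-mass association, and Brownian-motion ancestral states for
#' longevity and replacement rate (`asr_longevity.csv`,
#' `asr_rate.csv`, with branch gradients alongside). Taxa whose rate is
#' only a minimum are excluded from the rate reconstruction and the
#' exclusion is logged. A structured log (also written to `run.log`)
#' records every warning: out-of-band widths, minimum flags, exclusions.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed tables, the association
#'   result (if any), and the log; files are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("seed=%d", config$seed)

  tabs <- load_tables(config$teeth, config$families,
                      profiles_path = config$profiles,
                      transects_path = config$transects,
                      gaps_path = config$gaps,
                      traits_path = config$traits, tree_path = config$tree)
  note("loaded %d teeth, %d families", length(tabs$teeth), length(tabs$families))

  if (!is.null(tabs$transects)) {
    for (id in names(tabs$transects)) {
      st <- count_total_increments(tabs$transects[[id]])
      if (st$out_of_range_fraction > 0) {
        note("warning: transect %s has %.1f%% widths outside [%g,%g] um",
             id, 100 * st$out_of_range_fraction,
             WIDTH_PLAUSIBILITY_UM[1L], WIDTH_PLAUSIBILITY_UM[2L])
      }
      if (st$n_lines_extrapolated > 0) {
        note("flag: transect %s age includes %d extrapolated lines",
             id, st$n_lines_extrapolated)
      }
    }
  }

  rates <- lapply(names(tabs$families), function(fid) {
    fam <- tabs$families[[fid]]
    prof <- NULL
    if (!is.null(tabs$profiles) && !is.null(fam$functional_tooth_id) &&
        fam$functional_tooth_id %in% names(tabs$profiles)) {
      prof <- tabs$profiles[[fam$functional_tooth_id]]
    }
    est <- replacement_rate_for_family(fam, prof)
    lon <- tooth_longevity(fam)
    if (est$is_minimum) note("flag: family %s rate is a minimum (%d days)", fid,
                             est$rate_days)
    data.frame(family_id = fid, taxon = fam$functional$taxon,
               rate_days = est$rate_days, method = est$method,
               is_minimum = est$is_minimum,
               longevity_days = lon$days, longevity_is_minimum = lon$is_minimum,
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rates)
  utils::write.csv(rates, file.path(config$out_dir, "rates.csv"), row.names = FALSE)

  result <- list(rates = rates)

  if (!is.null(tabs$traits)) {
    summary_df <- group_summary(tabs$traits)
    utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    result$summary <- summary_df
    assoc <- tryCatch(
      mass_rate_association(tabs$traits, n_permutations = config$n_permutations,
                            seed = config$seed),
      toothchron_error = function(e) {
        note("association skipped: %s", conditionMessage(e)); NULL
      }
    )
    if (!is.null(assoc)) {
      note("mass-rate association: r=%.3f, p_perm=%.4f (n=%d, %s)",
           assoc$r, assoc$p_perm, assoc$n,
           if (assoc$exhaustive) "exhaustive" else "monte-carlo")
      result$association <- assoc
    }
  }

  if (!is.null(tabs$tree) && !is.null(tabs$traits)) {
    for (trait in c("longevity", "rate")) {
      col <- paste0(trait, "_days")
      flag <- paste0(trait, "_is_min")
      tr <- tabs$traits
      keep <- !is.na(tr[[col]])
      if (trait == "rate" && flag %in% names(tr)) {
        excl <- tr$taxon[keep & isTRUE_vec(tr[[flag]])]
        if (length(excl) > 0L) {
          note("asr(rate): excluded minimum-only taxa: %s",
               paste(excl, collapse = ", "))
        }
        keep <- keep & !isTRUE_vec(tr[[flag]])
      }
      vals <- stats::setNames(tr[[col]][keep], tr$taxon[keep])
      tips <- intersect(tabs$tree$tip.label, names(vals))
      if (length(tips) < 3L) {
        note("asr(%s): skipped, fewer than 3 tips with data", trait)
        next
      }
      sub <- ape::keep.tip(tabs$tree, tips)
      asr <- bm_ancestral_states(sub, vals[tips])
      utils::write.csv(
        data.frame(node_id = names(asr$node_states), state = asr$node_states,
                   row.names = NULL),
        file.path(config$out_dir, sprintf("asr_%s.csv", trait)),
        row.names = FALSE)
      utils::write.csv(
        branch_gradient(asr, samples_per_branch = 10L),
        file.path(config$out_dir, sprintf("asr_%s_gradient.csv", trait)),
        row.names = FALSE)
      note("asr(%s): %d tips, root state %.1f", trait, length(tips),
           asr$node_states[[1L]])
      result[[paste0("asr_", trait)]] <- asr
    }
  }

  writeLines(log, file.path(config$out_dir, "run.log"))
  result$log <- log
  invisible(result)
}
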
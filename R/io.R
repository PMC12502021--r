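# Strict CSV readers/writers for the four input schemas plus result output.
# CSV (RFC 4180, "." decimal separator) is the single interchange format;
# the generators emit exactly these schemas, so synthetic and field data are
# interchangeable.

.read_csv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  attr(df, "extra_columns") <- setdiff(names(df), c(required, optional))
  df
}

.report_violations <- function(df, bad, what, mode) {
  if (!any(bad)) return(df)
  lines <- which(bad) + 1L  # +1 for the header line
  msg <- sprintf("%d row(s) violate %s (file line%s %s)",
                 sum(bad), what, if (sum(bad) > 1) "s" else "",
                 paste(utils::head(lines, 10), collapse = ", "))
  if (mode == "strict") stop(msg) else {
    message("dropping ", msg)
    df[!bad, , drop = FALSE]
  }
}

#' Read a leaf-level fluorescence table
#'
#' Required columns: `species`, `site`, `leaf_id`, `temperature` (measured
#' leaf temperature, C), `fvfm`, `control_fvfm`. Optional: `tree_id`,
#' `target_temperature`, `control_temperature`, `protocol`
#' (`direct`/`recovered`), `recovery_hours`. Unrecognised columns are kept
#' and noted. Invariants: `0 <= fvfm <= 1`, `0 < control_fvfm <= 1`,
#' temperature inside the 10-70 C sanity window.
#'
#' @param path CSV file path.
#' @param mode `"strict"` (default) aborts on any violating row, citing file
#'   line numbers; `"lenient"` drops violators with a message.
#' @return validated data frame of observations.
#' @export
read_fluorescence_table <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- .read_csv_checked(path, c("species", "site", "leaf_id",
                                  "temperature", "fvfm", "control_fvfm"),
                          optional = c("tree_id", "target_temperature",
                                       "control_temperature", "protocol",
                                       "recovery_hours"))
  if (length(attr(df, "extra_columns")))
    message("ignoring unrecognised column(s): ",
            paste(attr(df, "extra_columns"), collapse = ", "))
  df <- .report_violations(
    df, !is.finite(df$fvfm) | df$fvfm < 0 | df$fvfm > 1,
    "0 <= fvfm <= 1", mode)
  df <- .report_violations(
    df, !is.finite(df$control_fvfm) | df$control_fvfm <= 0 |
      df$control_fvfm > 1, "0 < control_fvfm <= 1", mode)
  df <- .report_violations(
    df, !is.finite(df$temperature) | df$temperature < 10 |
      df$temperature > 70, "temperature in [10, 70] C", mode)
  if (!"protocol" %in% names(df)) df$protocol <- "direct"
  df
}

#' Read a midday leaf-temperature survey table
#'
#' Required columns: `species`, `site`, `leaf_temperature` (C, sanity window
#' 0-70). Optional: `campaign`.
#' @inheritParams read_fluorescence_table
#' @return validated data frame.
#' @export
read_leaf_temperature_table <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- .read_csv_checked(path, c("species", "site", "leaf_temperature"),
                          optional = "campaign")
  df <- .report_violations(
    df, !is.finite(df$leaf_temperature) | df$leaf_temperature < 0 |
      df$leaf_temperature > 70, "leaf_temperature in [0, 70] C", mode)
  if (!"campaign" %in% names(df)) df$campaign <- "C1"
  df
}

#' Read a lipid molecular-species table
#'
#' Required columns: `species`, `site`, `lipid_class` (one of MGDG, DGDG,
#' PG, SQDG) and either (`acyl_carbons`, `double_bonds`) or a combined
#' `lipid_species` column in "carbons:double_bonds" form (e.g. "34:3"),
#' plus `abundance` (non-negative, any consistent unit).
#' @inheritParams read_fluorescence_table
#' @return validated data frame with `acyl_carbons`/`double_bonds` resolved.
#' @export
read_lipid_table <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- .read_csv_checked(path, c("species", "site", "lipid_class",
                                  "abundance"),
                          optional = c("acyl_carbons", "double_bonds",
                                       "lipid_species"))
  if (!all(c("acyl_carbons", "double_bonds") %in% names(df))) {
    if (!"lipid_species" %in% names(df))
      stop("need either acyl_carbons + double_bonds or a lipid_species ",
           "column in carbons:double_bonds form")
    parts <- strsplit(as.character(df$lipid_species), ":", fixed = TRUE)
    ok <- lengths(parts) == 2
    df <- .report_violations(df, !ok,
                             "lipid_species parseable as carbons:bonds", mode)
    parts <- parts[ok | rep(mode == "strict", length(ok))]
    parts <- strsplit(as.character(df$lipid_species), ":", fixed = TRUE)
    df$acyl_carbons <- as.integer(vapply(parts, `[`, "", 1))
    df$double_bonds <- as.integer(vapply(parts, `[`, "", 2))
  }
  allowed <- c("MGDG", "DGDG", "PG", "SQDG")
  if (any(!df$lipid_class %in% allowed))
    stop("unknown lipid class ",
         paste(unique(setdiff(df$lipid_class, allowed)), collapse = ", "),
         "; allowed classes: ", paste(allowed, collapse = ", "))
  df <- .report_violations(
    df, !is.finite(df$double_bonds) | df$double_bonds < 0,
    "double_bonds >= 0", mode)
  .report_violations(df, !is.finite(df$abundance) | df$abundance < 0,
                     "abundance >= 0", mode)
}

#' Read a species-site trait table
#'
#' Required columns: `species`, `site`. Recognised trait columns:
#' `leaf_area` (cm2), `gs` (mol m-2 s-1), `lma` (g m-2),
#' `growth_temperature` (C), `max_air_temperature` (C), `osmolality`
#' (mmol kg-1); any may be absent, and downstream analyses report the
#' corresponding regression as not available. Present trait values must be
#' strictly positive (missing values permitted).
#' @inheritParams read_fluorescence_table
#' @return validated data frame.
#' @export
read_trait_table <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- .read_csv_checked(path, c("species", "site"),
                          optional = c("leaf_area", "gs", "lma",
                                       "growth_temperature",
                                       "max_air_temperature", "osmolality"))
  traits <- intersect(c("leaf_area", "gs", "lma", "growth_temperature",
                        "max_air_temperature", "osmolality"), names(df))
  for (tr in traits)
    df <- .report_violations(
      df, !is.na(df[[tr]]) & df[[tr]] <= 0,
      sprintf("%s > 0 where present", tr), mode)
  attr(df, "available_traits") <- traits
  df
}

#' Write pipeline results with a provenance sidecar
#'
#' Writes each data frame in `results` as `<name>.csv` under `dir` and a
#' `run_metadata.json` sidecar recording the seed, package version,
#' timestamp and any scalar configuration passed in `config_summary`.
#'
#' @param results named list of data frames (non-data-frame entries are
#'   stored in the sidecar).
#' @param dir output directory, created if needed.
#' @param seed seed the run used.
#' @param config_summary list of scalar settings to record.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, dir, seed = NA_integer_,
                          config_summary = list()) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  is_df <- vapply(results, is.data.frame, TRUE)
  paths <- character(0)
  for (nm in names(results)[is_df]) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, "run_metadata.json")
  meta <- list(
    seed = seed,
    package = "leafheat",
    version = as.character(utils::packageVersion("leafheat")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config_summary,
    scalars = results[!is_df])
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, sidecar))
}
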
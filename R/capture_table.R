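#' @keywords internal
"_PACKAGE"

CAPTURE_COLUMNS <- c("ring_id", "species", "scheme", "site", "year", "visit",
                     "age_class")
AGE_LEVELS <- c("A", "J")

#' Construct and validate a capture table
#'
#' A capture table is the universal interchange record of the package: one row
#' per capture event of an individually ringed bird, with columns `ring_id`,
#' `species`, `scheme`, `site`, `year` (calendar year), `visit` (within-season
#' visit index, 1-based) and `age_class` (`"A"` adult = older than first
#' calendar year, `"J"` juvenile = first calendar-year bird).
#'
#' Validation enforces the record invariants: `visit >= 1`, `age_class` one of
#' `A`/`J`, every site belonging to exactly one scheme, and at most one record
#' per `(ring_id, species, year, visit)`. Violations are reported with the
#' offending row numbers.
#'
#' @param x data frame with the seven capture columns.
#' @param provenance character scalar recording where the records came from
#'   (a file path or a simulation seed tag).
#' @return An object of class `capture_table` (a validated data frame).
#' @export
capture_table <- function(x, provenance = "in-memory") {
  if (!is.data.frame(x)) stop("capture table input must be a data frame")
  missing_cols <- setdiff(CAPTURE_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("capture table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[CAPTURE_COLUMNS]
  for (col in c("ring_id", "species", "scheme", "site", "age_class")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$year <- as.integer(x$year)
  x$visit <- as.integer(x$visit)

  if (nrow(x) > 0) {
    bad_age <- which(!(x$age_class %in% AGE_LEVELS))
    if (length(bad_age) > 0) {
      stop("value error: unknown age_class ",
           paste(unique(x$age_class[bad_age]), collapse = ", "),
           " in row(s) ", paste(utils::head(bad_age, 5), collapse = ", "))
    }
    bad_visit <- which(is.na(x$visit) | x$visit < 1L)
    if (length(bad_visit) > 0) {
      stop("value error: visit must be an integer >= 1 in row(s) ",
           paste(utils::head(bad_visit, 5), collapse = ", "))
    }
    bad_year <- which(is.na(x$year))
    if (length(bad_year) > 0) {
      stop("value error: missing year in row(s) ",
           paste(utils::head(bad_year, 5), collapse = ", "))
    }
    site_scheme <- unique(x[c("site", "scheme")])
    dup_site <- site_scheme$site[duplicated(site_scheme$site)]
    if (length(dup_site) > 0) {
      stop("invariant violation: site(s) ",
           paste(unique(dup_site), collapse = ", "),
           " assigned to more than one scheme")
    }
    key <- paste(x$ring_id, x$species, x$year, x$visit, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      stop("invariant violation: duplicate (ring_id, species, year, visit) ",
           "record(s) in row(s) ", paste(utils::head(dup, 5), collapse = ", "))
    }
  } else {
    warning("capture table is empty")
  }

  structure(x, class = c("capture_table", "data.frame"),
            provenance = provenance)
}

#' Read a capture table from CSV
#'
#' Expects a comma-separated, UTF-8 file whose header names the seven capture
#' columns (`ring_id,species,scheme,site,year,visit,age_class`); `age_class`
#' uses the levels `A` (adult) and `J` (juvenile).
#'
#' @param path path to an existing CSV file.
#' @return A validated [capture_table()].
#' @export
read_capture_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  capture_table(df, provenance = path)
}

#' Write a capture table to CSV
#'
#' @param x a [capture_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_capture_table <- function(x, path) {
  stopifnot(inherits(x, "capture_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.capture_table <- function(x, ...) {
  cat("<capture_table> ", nrow(x), " capture events, ",
      length(unique(x$scheme)), " scheme(s), ",
      length(unique(x$species)), " species\n", sep = "")
  cat("provenance:", attr(x, "provenance"), "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Data-selection criteria for CES sites and species
#'
#' Thresholds governing which site-years, species-site-years and species enter
#' the analysis. Defaults follow standard constant-effort-site practice:
#' sites running at least five years; site-years visited at least 2/3 of the
#' scheme's maximum (modal) visit number, with at least 1/4 of the maximum in
#' each half of the breeding season; species-site-years with at least two
#' adults and two juveniles; and species averaging at least 50 distinct
#' individuals captured per year within a scheme.
#'
#' @param min_site_years minimum number of retained years for a site.
#' @param visit_fraction fraction of the scheme maximum visit number a
#'   site-year must reach overall.
#' @param half_season_fraction fraction of the maximum visit number required
#'   in each of the first and second halves of the season.
#' @param min_adults_per_species_year minimum adults per species-site-year.
#' @param min_young_per_species_year minimum juveniles per species-site-year.
#' @param min_mean_individuals_per_year minimum mean distinct individuals per
#'   year for a (scheme, species) pair.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_site_years = 5L,
                               visit_fraction = 2 / 3,
                               half_season_fraction = 1 / 4,
                               min_adults_per_species_year = 2L,
                               min_young_per_species_year = 2L,
                               min_mean_individuals_per_year = 50) {
  stopifnot(min_site_years > 0, min_adults_per_species_year > 0,
            min_young_per_species_year > 0,
            min_mean_individuals_per_year > 0)
  if (visit_fraction <= 0 || visit_fraction > 1 ||
      half_season_fraction <= 0 || half_season_fraction > 1) {
    stop("visit fractions must lie in (0, 1]")
  }
  structure(list(min_site_years = as.integer(min_site_years),
                 visit_fraction = visit_fraction,
                 half_season_fraction = half_season_fraction,
                 min_adults_per_species_year =
                   as.integer(min_adults_per_species_year),
                 min_young_per_species_year =
                   as.integer(min_young_per_species_year),
                 min_mean_individuals_per_year =
                   min_mean_individuals_per_year),
            class = "selection_criteria")
}
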
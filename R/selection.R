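# Site-, species-site-year- and species-level selection filters.
# All fractional thresholds are rounded UP to whole visits (2/3 of 10 -> 7).

# distinct visit indices per (scheme, site, year)
site_year_visit_table <- function(table) {
  sy <- unique(as.data.frame(table)[c("scheme", "site", "year", "visit")])
  sy
}

#' Modal maximum visit number of a scheme
#'
#' The scheme's maximum visit number is defined as the mode, across all the
#' scheme's site-years, of the number of distinct visits made in a site-year.
#' A tie between modal counts is broken towards the larger count (the stricter
#' inclusion rule).
#'
#' @param table a [capture_table()].
#' @param scheme scheme code present in `table`.
#' @return Integer modal visit count.
#' @export
modal_max_visits <- function(table, scheme) {
  df <- as.data.frame(table)
  if (!scheme %in% df$scheme) stop("scheme not present in table: ", scheme)
  sy <- site_year_visit_table(df[df$scheme == scheme, , drop = FALSE])
  counts <- stats::aggregate(visit ~ site + year, data = sy,
                             FUN = function(v) length(unique(v)))$visit
  tab <- base::table(counts)
  modes <- as.integer(names(tab)[tab == max(tab)])
  max(modes)
}

new_selection_report <- function() {
  data.frame(level = character(), identifier = character(),
             rule = character(), stringsAsFactors = FALSE)
}

report_row <- function(level, identifier, rule) {
  data.frame(level = level, identifier = identifier, rule = rule,
             stringsAsFactors = FALSE)
}

#' Retain site-years meeting the visit-coverage rules, then well-covered sites
#'
#' A site-year is retained when its number of distinct visits reaches
#' `ceiling(visit_fraction * V)` where `V` is the scheme's modal maximum visit
#' number, and when each half of the breeding season contains at least
#' `ceiling(half_season_fraction * V)` distinct visits. The first half is
#' visits `1..ceiling(V/2)`; later visit indices fall in the second half.
#' Sites are then retained only if they keep at least `min_site_years` years.
#'
#' @param table a [capture_table()].
#' @param criteria a [selection_criteria()].
#' @return A list with `table` (filtered [capture_table()]) and `report`
#'   (one row per exclusion: level, identifier, triggering rule).
#' @export
select_site_years <- function(table, criteria = selection_criteria()) {
  df <- as.data.frame(table)
  report <- new_selection_report()
  if (nrow(df) == 0) {
    warning("empty capture table: nothing to select")
    return(list(table = table, report = report))
  }
  keep <- rep(FALSE, nrow(df))
  for (scheme in unique(df$scheme)) {
    v_max <- modal_max_visits(table, scheme)
    need_total <- ceiling(criteria$visit_fraction * v_max)
    need_half <- ceiling(criteria$half_season_fraction * v_max)
    half_cut <- ceiling(v_max / 2)
    sdf <- df[df$scheme == scheme, , drop = FALSE]
    sy <- site_year_visit_table(sdf)
    sy_key <- paste(sy$site, sy$year)
    n_total <- tapply(sy$visit, sy_key, function(v) length(unique(v)))
    n_first <- tapply(sy$visit, sy_key,
                      function(v) length(unique(v[v <= half_cut])))
    n_second <- tapply(sy$visit, sy_key,
                       function(v) length(unique(v[v > half_cut])))
    ok <- n_total >= need_total & n_first >= need_half & n_second >= need_half
    for (k in names(ok)[!ok]) {
      rule <- if (n_total[k] < need_total) {
        sprintf("visits %d < %d (%.2f of modal max %d)", n_total[k],
                need_total, criteria$visit_fraction, v_max)
      } else {
        sprintf("half-season visits (%d, %d) < %d", n_first[k], n_second[k],
                need_half)
      }
      report <- rbind(report,
                      report_row("site_year", paste(scheme, k), rule))
    }
    retained_key <- names(ok)[ok]
    years_per_site <- base::table(sub(" [^ ]+$", "", retained_key))
    good_sites <- names(years_per_site)[years_per_site >=
                                          criteria$min_site_years]
    for (s in setdiff(names(years_per_site), good_sites)) {
      report <- rbind(report, report_row(
        "site", paste(scheme, s),
        sprintf("retained years %d < %d", years_per_site[s],
                criteria$min_site_years)))
    }
    final_key <- retained_key[sub(" [^ ]+$", "", retained_key) %in% good_sites]
    row_key <- paste(df$site, df$year)
    keep <- keep | (df$scheme == scheme & row_key %in% final_key)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("site-year selection removed all records")
  tbl <- if (nrow(out) == 0) {
    suppressWarnings(capture_table(out, provenance = attr(table, "provenance")))
  } else {
    capture_table(out, provenance = attr(table, "provenance"))
  }
  list(table = tbl, report = report)
}

#' Drop species-site-years with too few adults or juveniles
#'
#' For each species independently, drops site-years where fewer than the
#' required numbers of distinct adults and distinct juveniles were captured.
#' Other species at the same site-year are unaffected.
#'
#' @inheritParams select_site_years
#' @return A list with `table` and `report`, as [select_site_years()].
#' @export
select_species_site_years <- function(table, criteria = selection_criteria()) {
  df <- as.data.frame(table)
  report <- new_selection_report()
  if (nrow(df) == 0) return(list(table = table, report = report))
  key <- paste(df$scheme, df$species, df$site, df$year, sep = "\r")
  n_ad <- tapply(ifelse(df$age_class == "A", df$ring_id, NA), key,
                 function(v) length(unique(v[!is.na(v)])))
  n_juv <- tapply(ifelse(df$age_class == "J", df$ring_id, NA), key,
                  function(v) length(unique(v[!is.na(v)])))
  ok <- n_ad >= criteria$min_adults_per_species_year &
    n_juv >= criteria$min_young_per_species_year
  for (k in names(ok)[!ok]) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    report <- rbind(report, report_row(
      "species_site_year", paste(parts, collapse = " "),
      sprintf("adults %d < %d or juveniles %d < %d", n_ad[k],
              criteria$min_adults_per_species_year, n_juv[k],
              criteria$min_young_per_species_year)))
  }
  out <- df[key %in% names(ok)[ok], , drop = FALSE]
  rownames(out) <- NULL
  tbl <- if (nrow(out) == 0) {
    suppressWarnings(capture_table(out, provenance = attr(table, "provenance")))
  } else {
    capture_table(out, provenance = attr(table, "provenance"))
  }
  list(table = tbl, report = report)
}

#' Retain (scheme, species) pairs by mean individuals captured per year
#'
#' The mean is taken over distinct ring numbers (adults plus juveniles) per
#' year across the scheme's selected sites, averaged over all years in which
#' the scheme was active (years with no captures of the species count as
#' zero).
#'
#' @inheritParams select_site_years
#' @return A data frame with one row per (scheme, species):
#'   `mean_individuals` and logical `retained`.
#' @export
select_species <- function(table, criteria = selection_criteria()) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) {
    return(data.frame(scheme = character(), species = character(),
                      mean_individuals = numeric(), retained = logical()))
  }
  out <- NULL
  for (scheme in unique(df$scheme)) {
    sdf <- df[df$scheme == scheme, , drop = FALSE]
    active_years <- length(unique(sdf$year))
    for (sp in unique(sdf$species)) {
      spd <- sdf[sdf$species == sp, , drop = FALSE]
      per_year <- tapply(spd$ring_id, spd$year,
                         function(v) length(unique(v)))
      mean_ind <- sum(per_year) / active_years
      out <- rbind(out, data.frame(
        scheme = scheme, species = sp, mean_individuals = mean_ind,
        retained = mean_ind >= criteria$min_mean_individuals_per_year,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Apply all data-selection filters in sequence
#'
#' Runs [select_site_years()], [select_species_site_years()] and
#' [select_species()] and returns the fully filtered table together with the
#' combined exclusion report and the species-selection table.
#'
#' @inheritParams select_site_years
#' @return list with `table`, `report`, `species`.
#' @export
select_captures <- function(table, criteria = selection_criteria()) {
  s1 <- select_site_years(table, criteria)
  s2 <- select_species_site_years(s1$table, criteria)
  sp <- select_species(s2$table, criteria)
  df <- as.data.frame(s2$table)
  report <- rbind(s1$report, s2$report)
  if (nrow(df) > 0) {
    kept <- sp[sp$retained, c("scheme", "species"), drop = FALSE]
    key <- paste(df$scheme, df$species)
    keep_key <- paste(kept$scheme, kept$species)
    dropped <- sp[!sp$retained, , drop = FALSE]
    if (nrow(dropped) > 0) {
      report <- rbind(report, report_row(
        "scheme_species", paste(dropped$scheme, dropped$species),
        sprintf("mean individuals/year %.1f < %s", dropped$mean_individuals,
                format(criteria$min_mean_individuals_per_year))))
    }
    df <- df[key %in% keep_key, , drop = FALSE]
    rownames(df) <- NULL
  }
  tbl <- if (nrow(df) == 0) {
    suppressWarnings(capture_table(df, provenance = attr(table, "provenance")))
  } else {
    capture_table(df, provenance = attr(table, "provenance"))
  }
  list(table = tbl, report = report, species = sp)
}

#' Write a selection report to CSV
#'
#' @param report selection report data frame (level, identifier, rule).
#' @param path output path.
#' @export
write_selection_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
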
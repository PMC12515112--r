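#' Build annual adult capture histories for one species within a scheme
#'
#' Collapses within-year repeat captures to a single annual detection,
#' excludes juvenile captures (a bird ringed as a juvenile enters the history
#' in its first adult-capture year), and assigns each individual to the site
#' of its first adult capture. Individuals captured as adults at more than one
#' site keep the first site and are flagged.
#'
#' Occasions are the ordered distinct years in which the scheme's selected
#' sites were operated (so an individual not caught in an operated year is a
#' genuine miss).
#'
#' @param table a [capture_table()] after selection filtering.
#' @param species species code.
#' @param scheme scheme code.
#' @return An object of class `capture_history_set`: list with `species`,
#'   `scheme`, `years` (length `T`), `det` (individuals x `T` 0/1 matrix,
#'   ring IDs as rownames), `first` (first-capture occasion index),
#'   `site` (site of first adult capture) and `multi_site` (logical flag).
#' @export
build_histories <- function(table, species, scheme) {
  df <- as.data.frame(table)
  sdf <- df[df$scheme == scheme, , drop = FALSE]
  if (nrow(sdf) == 0) stop("no records for scheme ", scheme)
  years <- sort(unique(sdf$year))
  if (length(years) < 3) {
    stop("insufficient data: fewer than 3 study years for scheme ", scheme)
  }
  ad <- sdf[sdf$species == species & sdf$age_class == "A", , drop = FALSE]
  if (nrow(ad) == 0) stop("no adult records for species ", species,
                          " in scheme ", scheme)
  # order by year then visit so the first row per ring is the first capture
  ad <- ad[order(ad$ring_id, ad$year, ad$visit), , drop = FALSE]
  ids <- unique(ad$ring_id)
  T_n <- length(years)
  det <- matrix(0L, nrow = length(ids), ncol = T_n,
                dimnames = list(ids, years))
  yr_idx <- match(ad$year, years)
  det[cbind(match(ad$ring_id, ids), yr_idx)] <- 1L
  first_rows <- ad[!duplicated(ad$ring_id), , drop = FALSE]
  first <- match(first_rows$year, years)
  names(first) <- first_rows$ring_id
  site <- first_rows$site
  names(site) <- first_rows$ring_id
  n_sites_per_id <- tapply(ad$site, ad$ring_id, function(s) length(unique(s)))
  multi_site <- as.vector(n_sites_per_id[ids] > 1)
  names(multi_site) <- ids
  first <- first[ids]
  site <- site[ids]
  structure(list(species = species, scheme = scheme, years = years,
                 det = det, first = first, site = site,
                 multi_site = multi_site),
            class = "capture_history_set")
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat("<capture_history_set> ", x$species, " / ", x$scheme, ": ",
      nrow(x$det), " adults over ", length(x$years), " years (",
      min(x$years), "-", max(x$years), "), ",
      sum(x$multi_site), " multi-site individual(s)\n", sep = "")
  invisible(x)
}
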
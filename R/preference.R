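#' Thin camera-trap records to independent detections
#'
#' Within each station x species series (time-sorted), a photograph counts
#' as an independent record iff it is the first, or falls more than
#' `window_min` minutes after the previously *retained* record (the chained
#' convention; `chained = FALSE` instead measures the gap from the previous
#' raw photograph). Animals sharing one frame were already collapsed to one
#' record upstream; different species never suppress each other.
#'
#' @param records camera data frame with `station_id`, `species`,
#'   `timestamp` (POSIXct or parseable character).
#' @param window_min independence window in minutes (default 30).
#' @param chained measure the gap from the last retained record (default)
#'   rather than the last raw photo.
#' @return the retained subset of `records`.
#' @export
independent_records <- function(records, window_min = 30, chained = TRUE) {
  if (nrow(records) == 0) return(records)
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamp(s)")
  key <- paste(records$station_id, records$species, sep = "\r")
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), key)) {
    idx <- idx[order(ts[idx])]
    last <- -Inf
    for (i in idx) {
      t_i <- as.numeric(ts[i])
      ref <- last
      if (t_i - ref > window_min * 60 || ref == -Inf) {
        keep[i] <- TRUE
        last <- t_i
      } else if (!chained) {
        last <- t_i  # unchained: window restarts at every raw photo
      }
    }
  }
  records[keep, , drop = FALSE]
}

#' Camera-trap relative abundance index
#'
#' RAI = independent records / trap days. Computed per survey sector
#' (records at the sector's stations divided by the sector's summed trap
#' days) and, for `level = "area"`, averaged unweighted over the area's
#' sectors.
#'
#' @param records *independent* camera records (see [independent_records()])
#'   with `station_id`, `sector`, `area`, `species`.
#' @param effort data frame with `station_id`, `trap_days`, and optionally
#'   `sector`/`area` (else derived from `records`; stations appearing in
#'   neither cannot be placed and raise an error).
#' @param level `"sector"` or `"area"`.
#' @return data frame with `species`, the level column, and `rai`.
#' @export
rai <- function(records, effort, level = c("area", "sector")) {
  level <- match.arg(level)
  no_eff <- setdiff(unique(records$station_id), effort$station_id)
  if (length(no_eff))
    stop("station(s) with records but no effort: ",
         paste(no_eff, collapse = ", "))
  if (is.null(effort$sector)) {
    map <- unique(records[, c("station_id", "sector", "area")])
    m <- match(effort$station_id, map$station_id)
    if (anyNA(m))
      stop("effort station(s) not mappable to a sector: ",
           paste(effort$station_id[is.na(m)], collapse = ", "))
    effort$sector <- map$sector[m]
    effort$area <- map$area[m]
  }
  sec_days <- tapply(effort$trap_days, effort$sector, sum)
  species <- sort(unique(records$species))
  sectors <- sort(unique(effort$sector))
  n_rec <- table(factor(records$species, levels = species),
                 factor(records$sector, levels = sectors))
  sec_tab <- expand.grid(species = species, sector = sectors,
                         stringsAsFactors = FALSE)
  sec_tab$rai <- mapply(function(sp, se) {
    n_rec[sp, se] / sec_days[[se]]
  }, sec_tab$species, sec_tab$sector)
  if (level == "sector") return(sec_tab)
  sec_area <- unique(effort[, c("sector", "area")])
  sec_tab$area <- sec_area$area[match(sec_tab$sector, sec_area$sector)]
  out <- stats::aggregate(rai ~ species + area, data = sec_tab, FUN = mean)
  out[order(out$area, out$species), c("species", "area", "rai")]
}

#' Jacobs' selectivity index
#'
#' D = (r - p) / (r + p - 2 r p), contrasting a prey's proportion in the
#' diet (r) with its proportional availability (p). D = -1 is maximum
#' avoidance, 0 use in proportion to availability, +1 maximum preference.
#' At r = p = 1 (a single shared prey) the index is 0 by continuity; at
#' r = p = 0 it is undefined.
#'
#' @param r proportion of the prey in the diet, in \[0, 1\] (vectorised).
#' @param p proportion of the prey available, in \[0, 1\].
#' @return selectivity in \[-1, 1\].
#' @export
jacobs_index <- function(r, p) {
  if (any(r < 0 | r > 1 | p < 0 | p > 1)) stop("r and p must lie in [0, 1]")
  if (any(r == 0 & p == 0)) stop("Jacobs' index undefined at r = p = 0")
  ifelse(r == 1 & p == 1, 0, (r - p) / (r + p - 2 * r * p))
}

#' Prey preference table for one predator and stratum
#'
#' Joins a predator's diet proportions to an availability table (camera-trap
#' RAI or densities), renormalises both over their shared prey species, and
#' computes Jacobs' index per species. Diet species absent from the
#' availability table are kept with `D = NA` and a warning rather than
#' silently dropped.
#'
#' @param fo named diet-proportion vector (item-convention frequency of
#'   occurrence).
#' @param availability data frame with `species` and an abundance column
#'   (`rai` or `density`); rows for one stratum.
#' @param predator,stratum labels copied to the output.
#' @param source availability source label (`"rai"` or `"density"`).
#' @return data frame: predator, stratum, species, r, p_avail, D,
#'   availability_source.
#' @export
preference_table <- function(fo, availability, predator = NA,
                             stratum = "All", source = "rai") {
  if (nrow(availability) == 0) stop("empty availability table")
  abun_col <- intersect(c("rai", "density"), names(availability))[1]
  if (is.na(abun_col)) stop("availability needs an 'rai' or 'density' column")
  avail <- stats::setNames(availability[[abun_col]], availability$species)
  avail <- avail[avail > 0]
  shared <- intersect(names(fo), names(avail))
  missing <- setdiff(names(fo), names(avail))
  if (length(shared) == 0) stop("no prey shared between diet and availability")
  r <- fo[shared] / sum(fo[shared])
  p <- avail[shared] / sum(avail[shared])
  out <- data.frame(predator = predator, stratum = stratum,
                    species = shared, r = unname(r), p_avail = unname(p),
                    D = unname(jacobs_index(r, p)),
                    availability_source = source, stringsAsFactors = FALSE)
  if (length(missing)) {
    warning("prey absent from availability, D undefined: ",
            paste(missing, collapse = ", "))
    out <- rbind(out, data.frame(predator = predator, stratum = stratum,
                                 species = missing, r = unname(fo[missing]),
                                 p_avail = NA_real_, D = NA_real_,
                                 availability_source = source,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
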
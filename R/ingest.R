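#' @keywords internal
"_PACKAGE"

PREDATORS <- c("wild_dog", "cheetah", "leopard", "lion", "hyaena")
AREAS <- c("NE", "NW", "SW")
WATER_LEVELS <- c("high", "medium", "low")
FEEDING_GUILDS <- c("mixed_feeder", "browser", "grassland_grazer",
                    "woodland_grazer", "omnivore", "carnivore", "other")
SIZE_CLASSES <- c("XS", "S", "M", "L", "XL")

#' Read a scat-content table
#'
#' Reads a long-format CSV with one row per prey item found in a scat.
#' Scat-level fields (predator, date, coordinates, area, pack) are repeated
#' on every row of the same scat. Expected columns: `scat_id`, `predator`,
#' `date` (ISO-8601), `x_m`, `y_m`, `area`, `pack_id` (may be empty except
#' for wild dogs), `prey_species`.
#'
#' @param path path to the CSV file.
#' @return A list with two data frames: `scats` (one row per scat: scat_id,
#'   predator, date, x_m, y_m, area, pack_id, year) and `items` (scat_id,
#'   prey_species).
#' @export
read_scat_table <- function(path) {
  if (!file.exists(path)) stop("scat table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("scat_id", "predator", "date", "x_m", "y_m", "area",
                "pack_id", "prey_species")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("scat table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    scats <- data.frame(scat_id = character(), predator = character(),
                        date = as.Date(character()), x_m = numeric(),
                        y_m = numeric(), area = character(),
                        pack_id = character(), year = integer(),
                        stringsAsFactors = FALSE)
    items <- data.frame(scat_id = character(), prey_species = character(),
                        stringsAsFactors = FALSE)
    return(list(scats = scats, items = items))
  }
  raw$x_m <- as.numeric(raw$x_m)
  raw$y_m <- as.numeric(raw$y_m)
  raw$date <- as.Date(raw$date)
  if (anyNA(raw$date))
    stop("unparseable date(s) in rows: ",
         paste(utils::head(which(is.na(raw$date)), 10), collapse = ", "))
  bad_pred <- !(raw$predator %in% PREDATORS)
  if (any(bad_pred))
    stop("unknown predator label(s) ",
         paste(unique(raw$predator[bad_pred]), collapse = ", "),
         " in rows: ", paste(utils::head(which(bad_pred), 10),
                             collapse = ", "))
  bad_area <- !(raw$area %in% AREAS)
  if (any(bad_area))
    stop("unknown area label(s) ",
         paste(unique(raw$area[bad_area]), collapse = ", "))
  raw$pack_id[!nzchar(raw$pack_id)] <- NA_character_
  items <- raw[, c("scat_id", "prey_species")]
  first <- !duplicated(raw$scat_id)
  scats <- raw[first, c("scat_id", "predator", "date", "x_m", "y_m",
                        "area", "pack_id")]
  # scat-level fields must agree across a scat's item rows
  for (col in c("predator", "area")) {
    n_per <- tapply(raw[[col]], raw$scat_id, function(v) length(unique(v)))
    if (any(n_per > 1))
      stop("inconsistent ", col, " within scat_id(s): ",
           paste(names(n_per)[n_per > 1], collapse = ", "))
  }
  no_pack <- scats$predator == "wild_dog" & is.na(scats$pack_id)
  if (any(no_pack))
    stop("wild dog scat(s) lacking pack_id: ",
         paste(scats$scat_id[no_pack], collapse = ", "))
  scats$year <- as.integer(format(scats$date, "%Y"))
  rownames(scats) <- NULL
  rownames(items) <- NULL
  list(scats = scats, items = items)
}

#' Read a prey-trait table
#'
#' Columns: `species`, `mean_female_mass_kg`, `water_dependency`
#' (high/medium/low), `feeding_guild`. A `size_class` column is derived from
#' the mass via [assign_size_class()].
#'
#' @param path path to the CSV file.
#' @return data frame with a derived `size_class` column.
#' @export
read_prey_traits <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "mean_female_mass_kg", "water_dependency",
                "feeding_guild")
  missing <- setdiff(required, names(tr))
  if (length(missing))
    stop("trait table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(duplicated(tr$species)))
    stop("duplicated species in trait table: ",
         paste(unique(tr$species[duplicated(tr$species)]), collapse = ", "))
  if (any(tr$mean_female_mass_kg <= 0))
    stop("non-positive mass for species: ",
         paste(tr$species[tr$mean_female_mass_kg <= 0], collapse = ", "))
  bad <- !(tr$water_dependency %in% WATER_LEVELS)
  if (any(bad))
    stop("unknown water_dependency level(s): ",
         paste(unique(tr$water_dependency[bad]), collapse = ", "))
  bad <- !(tr$feeding_guild %in% FEEDING_GUILDS)
  if (any(bad))
    stop("unknown feeding_guild level(s): ",
         paste(unique(tr$feeding_guild[bad]), collapse = ", "))
  tr$size_class <- assign_size_class(tr$mean_female_mass_kg)
  tr
}

#' Filter pseudo-replicated scat records
#'
#' Removes likely repeat samples of the same defecation cluster. For lions
#' and hyaenas, only one sample per 24 h per location is retained, where two
#' locations count as the same if they are at most 1 km apart (Euclidean on
#' projected metre coordinates). For wild dogs, only one sample per 24 h per
#' pack is retained, regardless of location. No rule applies to cheetah and
#' leopard scats, which pass through unchanged.
#'
#' Records are scanned earliest-first (ties by input order); a scat is
#' retained iff it conflicts with no already-retained scat. Dates without
#' time-of-day conflict when they fall on the same calendar day; POSIXct
#' timestamps conflict when strictly less than 24 h apart.
#'
#' @param scats scat data frame as returned by [read_scat_table()].
#' @return list with `retained` (filtered scat data frame) and `log`
#'   (data frame of dropped scat_ids with the rule applied).
#' @export
filter_pseudoreplicates <- function(scats) {
  if (nrow(scats) == 0)
    return(list(retained = scats,
                log = data.frame(scat_id = character(), rule = character(),
                                 conflicts_with = character(),
                                 stringsAsFactors = FALSE)))
  wd <- scats$predator == "wild_dog"
  if (any(wd & is.na(scats$pack_id)))
    stop("wild dog scat(s) lacking pack_id: ",
         paste(scats$scat_id[wd & is.na(scats$pack_id)], collapse = ", "))
  ord <- order(scats$date)
  s <- scats[ord, , drop = FALSE]
  keep <- logical(nrow(s))
  drop_id <- character(0); drop_rule <- character(0); drop_conf <- character(0)
  same_window <- function(d1, d2) {
    if (inherits(d1, "POSIXct")) {
      abs(as.numeric(difftime(d1, d2, units = "hours"))) < 24
    } else {
      d1 == d2
    }
  }
  for (i in seq_len(nrow(s))) {
    pred <- s$predator[i]
    if (pred %in% c("cheetah", "leopard")) { keep[i] <- TRUE; next }
    prev <- which(keep & s$predator == pred)
    conflict <- 0L
    for (j in prev) {
      if (!same_window(s$date[i], s$date[j])) next
      if (pred == "wild_dog") {
        if (identical(s$pack_id[i], s$pack_id[j])) { conflict <- j; break }
      } else {
        dist <- sqrt((s$x_m[i] - s$x_m[j])^2 + (s$y_m[i] - s$y_m[j])^2)
        if (dist <= 1000) { conflict <- j; break }
      }
    }
    if (conflict > 0L) {
      drop_id <- c(drop_id, s$scat_id[i])
      drop_rule <- c(drop_rule,
                     if (pred == "wild_dog") "24h_same_pack" else "24h_1km")
      drop_conf <- c(drop_conf, s$scat_id[conflict])
    } else keep[i] <- TRUE
  }
  retained <- s[keep, , drop = FALSE]
  retained <- retained[order(match(retained$scat_id, scats$scat_id)), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       log = data.frame(scat_id = drop_id, rule = drop_rule,
                        conflicts_with = drop_conf, stringsAsFactors = FALSE))
}

#' Assign a season label to a date
#'
#' Two schemes are supported. `"weather"`: the wet-early dry season runs
#' November-June and the late dry season July-October. `"behavioural"`
#' (wild dog life history): nomadic September-April, breeding (denning)
#' May-August.
#'
#' @param date a `Date` (or date-time) vector.
#' @param scheme `"weather"` or `"behavioural"`.
#' @return character vector of season labels.
#' @export
assign_season <- function(date, scheme = c("weather", "behavioural")) {
  scheme <- match.arg(scheme)
  m <- as.integer(format(as.Date(date), "%m"))
  if (scheme == "weather") {
    ifelse(m %in% c(11, 12, 1:6), "wet_early_dry", "late_dry")
  } else {
    ifelse(m %in% c(9:12, 1:4), "nomadic", "breeding")
  }
}

#' Assign a prey body-size class
#'
#' Classes follow the mean-female-mass bounds XS < 5 kg, S 5-24 kg,
#' M 25-99 kg, L 100-349 kg, XL >= 350 kg, implemented as half-open
#' intervals \[0,5), \[5,25), \[25,100), \[100,350), \[350,Inf) so every
#' positive mass is assigned.
#'
#' @param mass_kg positive numeric vector of mean female masses in kg.
#' @return character vector in `c("XS","S","M","L","XL")`.
#' @export
assign_size_class <- function(mass_kg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    stop("mass_kg must be positive and finite")
  as.character(cut(mass_kg, breaks = c(0, 5, 25, 100, 350, Inf),
                   labels = SIZE_CLASSES, right = FALSE))
}

#' Flag analysis cells with enough scats
#'
#' An analysis cell (predator x stratum) enters statistical comparisons only
#' when it holds at least `threshold` scats; smaller cells are excluded and
#' logged.
#'
#' @param counts named integer vector of scat counts per cell.
#' @param threshold minimum scat count (default 21).
#' @return list with `included` (named logical) and `log` (data frame of
#'   excluded cells with counts).
#' @export
enforce_min_samples <- function(counts, threshold = 21) {
  if (any(counts < 0)) stop("counts must be non-negative")
  inc <- counts >= threshold
  excl <- data.frame(cell = names(counts)[!inc],
                     n_scats = unname(counts[!inc]),
                     reason = rep(sprintf("fewer than %d scats", threshold),
                                  sum(!inc)),
                     stringsAsFactors = FALSE)
  list(included = inc, log = excl)
}
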
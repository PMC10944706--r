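# ---- default study conditions -------------------------------------------
# Prey pool and predator diets emulate a semi-arid African savanna guild:
# five sympatric carnivores sharing a pool of ~20 ungulate and small-mammal
# prey across three park areas with contrasting waterhole density (NE
# maximum, NW high, SW low). Masses are mean female body mass in kg.

.default_prey_pool <- function() {
  data.frame(
    species = c("impala", "kudu", "duiker", "bushbuck", "steenbok",
                "buffalo", "sable", "wildebeest", "waterbuck", "warthog",
                "eland", "reedbuck", "giraffe", "elephant", "zebra",
                "scrub_hare", "bushpig", "baboon", "gemsbok", "squirrel",
                "jackal"),
    mean_female_mass_kg = c(40, 157, 17, 30, 11, 520, 220, 180, 160, 57,
                            460, 48, 828, 2744, 220, 2, 62, 15, 210, 0.6,
                            8),
    water_dependency = c("high", "medium", "low", "low", "low", "high",
                         "medium", "high", "high", "high", "low", "high",
                         "low", "high", "high", "low", "medium", "medium",
                         "low", "low", "low"),
    feeding_guild = c("mixed_feeder", "browser", "browser", "browser",
                      "browser", "grassland_grazer", "grassland_grazer",
                      "grassland_grazer", "grassland_grazer",
                      "grassland_grazer", "mixed_feeder",
                      "grassland_grazer", "browser", "mixed_feeder",
                      "grassland_grazer", "browser", "omnivore",
                      "omnivore", "grassland_grazer", "other", "carnivore"),
    stringsAsFactors = FALSE)
}

.default_base_diets <- function() {
  list(
    wild_dog = c(impala = 0.33, kudu = 0.33, duiker = 0.15, bushbuck = 0.12,
                 steenbok = 0.03, waterbuck = 0.02, scrub_hare = 0.01,
                 warthog = 0.01),
    cheetah = c(scrub_hare = 0.25, impala = 0.22, duiker = 0.18,
                bushbuck = 0.15, steenbok = 0.10, kudu = 0.05,
                baboon = 0.05),
    leopard = c(duiker = 0.20, bushbuck = 0.17, steenbok = 0.14,
                impala = 0.13, kudu = 0.08, scrub_hare = 0.07,
                squirrel = 0.06, baboon = 0.05, warthog = 0.04,
                jackal = 0.03, bushpig = 0.03),
    lion = c(impala = 0.14, kudu = 0.12, buffalo = 0.12, sable = 0.10,
             zebra = 0.09, wildebeest = 0.08, waterbuck = 0.08,
             eland = 0.06, elephant = 0.05, giraffe = 0.05, warthog = 0.05,
             bushpig = 0.03, duiker = 0.03),
    hyaena = c(impala = 0.16, kudu = 0.14, sable = 0.12, buffalo = 0.09,
               wildebeest = 0.09, waterbuck = 0.07, zebra = 0.07,
               duiker = 0.06, warthog = 0.05, eland = 0.04, giraffe = 0.04,
               bushpig = 0.03, steenbok = 0.02, reedbuck = 0.02))
}

# multiplicative area tilts on the base diets (then renormalised): impala
# and waterbuck favoured near maximum waterhole density, kudu in the high
# area, small browsers in the dry SW
.default_area_tilts <- function() {
  list(NE = c(impala = 1.5, waterbuck = 1.5),
       NW = c(kudu = 1.5, impala = 1.2),
       SW = c(duiker = 1.8, steenbok = 1.8, kudu = 1.2))
}

.default_n_scats <- function() {
  list(wild_dog = c(NE = 14, NW = 26, SW = 13),
       cheetah = c(NW = 26),
       leopard = c(NW = 26, SW = 25),
       lion = c(NE = 30, NW = 28, SW = 27),
       hyaena = c(NE = 26, NW = 32, SW = 21))
}

# true density (animals / km2) by species, scaled per area below
.default_densities <- function() {
  c(impala = 8, kudu = 3, duiker = 2.5, bushbuck = 1.5, steenbok = 1.2,
    buffalo = 2, sable = 1, wildebeest = 1.2, waterbuck = 0.8,
    warthog = 1.5, eland = 0.5, reedbuck = 0.4, giraffe = 0.6,
    elephant = 3, zebra = 1.5, scrub_hare = 4, bushpig = 0.7, baboon = 5,
    gemsbok = 0.3, squirrel = 6, jackal = 0.8)
}

#' Configuration for a synthetic scat-and-camera study
#'
#' Bundles every generating parameter of [generate_study()] with defaults
#' emulating a three-area savanna carnivore guild at roughly one quarter of
#' a full field campaign (50-90 scats per predator, 21 prey species, nine
#' camera sectors). All defaults can be overridden.
#'
#' @param prey_pool prey trait data frame (species, mass, categories).
#' @param base_diets named list of per-predator diet proportion vectors.
#' @param area_tilts named list (by area) of multiplicative diet tilts.
#' @param n_scats named list: per predator, named vector of scat counts per
#'   area (configured counts are exact, before duplicate injection).
#' @param items_lambda Poisson rate of extra items per scat; items per scat
#'   are 1 + Poisson(lambda). Default 0.1, giving ~1.1 items/scat as seen
#'   in field scat studies.
#' @param dup_rate fraction of scats duplicated nearby in space and time to
#'   exercise the pseudo-replication filter (default 0.05).
#' @param densities named vector of true densities per km2 (base, per
#'   species).
#' @param area_density_mult named multiplier per area (default NE 1.2,
#'   NW 1.0, SW 0.6).
#' @param n_stations_per_sector camera stations in each of the nine sectors.
#' @param trap_days trap days per station.
#' @param detect_rate expected independent detections per trap day per unit
#'   density.
#' @param burst_rate probability a detection spawns a same-half-hour photo
#'   burst (exercises the 30-min independence filter).
#' @param years calendar years scats span.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(prey_pool = .default_prey_pool(),
                             base_diets = .default_base_diets(),
                             area_tilts = .default_area_tilts(),
                             n_scats = .default_n_scats(),
                             items_lambda = 0.1,
                             dup_rate = 0.05,
                             densities = .default_densities(),
                             area_density_mult = c(NE = 1.2, NW = 1.0,
                                                   SW = 0.6),
                             n_stations_per_sector = 5,
                             trap_days = 50,
                             detect_rate = 0.01,
                             burst_rate = 0.3,
                             years = 2012:2015) {
  for (pred in names(base_diets)) {
    d <- base_diets[[pred]]
    if (abs(sum(d) - 1) > 1e-8)
      stop("diet of ", pred, " does not sum to 1")
    unknown <- setdiff(names(d), prey_pool$species)
    if (length(unknown))
      stop("diet species not in prey pool: ", paste(unknown, collapse = ", "))
  }
  if (any(unlist(n_scats) <= 0)) stop("scat counts must be positive")
  cfg <- list(prey_pool = prey_pool, base_diets = base_diets,
              area_tilts = area_tilts, n_scats = n_scats,
              items_lambda = items_lambda, dup_rate = dup_rate,
              densities = densities, area_density_mult = area_density_mult,
              n_stations_per_sector = n_stations_per_sector,
              trap_days = trap_days, detect_rate = detect_rate,
              burst_rate = burst_rate, years = years)
  class(cfg) <- "synthetic_config"
  cfg
}

# tilted, renormalised true diet of a predator in an area
.true_diet <- function(cfg, predator, area) {
  d <- cfg$base_diets[[predator]]
  tilt <- cfg$area_tilts[[area]]
  f <- rep(1, length(d)); names(f) <- names(d)
  common <- intersect(names(tilt), names(d))
  f[common] <- tilt[common]
  d <- d * f
  d / sum(d)
}

#' Generate a complete synthetic study with known ground truth
#'
#' Draws dated, located scat records (prey items multinomial from the
#' configured true diets; wild dog scats carry pack ids; a configurable
#' fraction of duplicate scats violates the 24-h/1-km and same-pack rules),
#' a prey-trait table, and camera-trap records (Poisson detections with
#' rate proportional to true density, plus short photo bursts) with
#' per-station effort. The returned `truth` element records every
#' generating parameter, the per-area true diet vectors, the true pairwise
#' Pianka overlaps and Levins breadths, and true densities, so pipeline
#' estimates can be scored against them.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; fixed seed gives identical output.
#' @param dir optional directory; when given, writes `scats.csv`,
#'   `prey_traits.csv`, `cameras.csv`, `effort.csv` and `truth.json`.
#' @return list with `scats` (scat-level data frame), `items`, `scats_long`
#'   (the CSV layout: one row per prey item), `traits`, `cameras`,
#'   `effort`, `truth`.
#' @export
generate_study <- function(config = synthetic_config(), seed = 1,
                           dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  boxes <- list(NE = c(60000, 90000, 60000, 90000),
                NW = c(0, 30000, 60000, 90000),
                SW = c(0, 30000, 0, 30000))
  date_lo <- as.Date(sprintf("%d-01-01", min(config$years)))
  date_hi <- as.Date(sprintf("%d-12-31", max(config$years)))
  n_days <- as.integer(date_hi - date_lo) + 1L

  scat_rows <- list(); item_rows <- list(); truth_diets <- list()
  sid <- 0L
  for (pred in names(config$n_scats)) {
    for (area in names(config$n_scats[[pred]])) {
      n <- config$n_scats[[pred]][[area]]
      diet <- .true_diet(config, pred, area)
      truth_diets[[pred]][[area]] <- diet
      box <- boxes[[area]]
      packs <- if (pred == "wild_dog")
        paste0(area, "_pack", 1:2) else NA_character_
      for (i in seq_len(n)) {
        sid <- sid + 1L
        id <- sprintf("S%05d", sid)
        date <- date_lo + sample.int(n_days, 1) - 1L
        x <- stats::runif(1, box[1], box[2])
        y <- stats::runif(1, box[3], box[4])
        pack <- if (pred == "wild_dog") sample(packs, 1) else NA_character_
        scat_rows[[sid]] <- data.frame(
          scat_id = id, predator = pred, date = date, x_m = x, y_m = y,
          area = area, pack_id = pack, stringsAsFactors = FALSE)
        n_items <- 1L + stats::rpois(1, config$items_lambda)
        sp <- sample(names(diet), n_items, replace = TRUE, prob = diet)
        item_rows[[sid]] <- data.frame(scat_id = id, prey_species = sp,
                                       stringsAsFactors = FALSE)
      }
    }
  }
  scats <- do.call(rbind, scat_rows)
  items <- do.call(rbind, item_rows)

  # duplicate injection: near-copies that the pseudo-replication filter
  # must drop (same day; <1 km for lion/hyaena, same pack for wild dog)
  dup_pool <- which(scats$predator %in% c("wild_dog", "lion", "hyaena"))
  n_dup <- round(config$dup_rate * length(dup_pool))
  if (n_dup > 0) {
    src <- sample(dup_pool, n_dup)
    for (i in src) {
      sid <- sid + 1L
      id <- sprintf("S%05d", sid)
      row <- scats[i, ]
      row$scat_id <- id
      row$x_m <- row$x_m + stats::runif(1, -300, 300)
      row$y_m <- row$y_m + stats::runif(1, -300, 300)
      scats <- rbind(scats, row)
      diet <- truth_diets[[row$predator]][[row$area]]
      items <- rbind(items, data.frame(
        scat_id = id, prey_species = sample(names(diet), 1, prob = diet),
        stringsAsFactors = FALSE))
    }
  }
  scats$year <- as.integer(format(scats$date, "%Y"))
  rownames(scats) <- NULL; rownames(items) <- NULL

  # cameras: 9 sectors, Poisson detections proportional to true density
  sectors <- paste0(rep(names(boxes), each = 3), "_", 1:3)
  stations <- data.frame(
    station_id = sprintf("CT%03d", seq_len(9 * config$n_stations_per_sector)),
    sector = rep(sectors, each = config$n_stations_per_sector),
    stringsAsFactors = FALSE)
  stations$area <- sub("_.*", "", stations$sector)
  effort <- data.frame(station_id = stations$station_id,
                       sector = stations$sector, area = stations$area,
                       trap_days = config$trap_days,
                       stringsAsFactors = FALSE)
  cam_rows <- list()
  t0 <- as.POSIXct("2013-01-01 00:00:00", tz = "UTC")
  for (s in seq_len(nrow(stations))) {
    area <- stations$area[s]
    dens <- config$densities * config$area_density_mult[[area]]
    for (sp in names(dens)) {
      lam <- config$detect_rate * dens[[sp]] * config$trap_days
      n_det <- stats::rpois(1, lam)
      if (n_det == 0) next
      times <- t0 + stats::runif(n_det, 0, config$trap_days * 86400)
      burst <- stats::runif(n_det) < config$burst_rate
      extra <- lapply(which(burst), function(b)
        times[b] + stats::runif(sample(1:3, 1), 60, 25 * 60))
      all_t <- c(times, do.call(c, extra) %||% times[0])
      cam_rows[[length(cam_rows) + 1]] <- data.frame(
        station_id = stations$station_id[s], sector = stations$sector[s],
        area = area, species = sp, timestamp = all_t,
        n_individuals = sample(1:4, length(all_t), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  cameras <- do.call(rbind, cam_rows)
  cameras <- cameras[order(cameras$station_id, cameras$species,
                           cameras$timestamp), ]
  rownames(cameras) <- NULL

  truth <- list(seed = seed, diets = truth_diets,
                n_scats = config$n_scats,
                densities = lapply(names(boxes), function(a)
                  config$densities * config$area_density_mult[[a]]),
                items_lambda = config$items_lambda,
                dup_rate = config$dup_rate,
                detect_rate = config$detect_rate)
  names(truth$densities) <- names(boxes)

  scats_long <- merge(items, scats, by = "scat_id", sort = FALSE)
  scats_long <- scats_long[, c("scat_id", "predator", "date", "x_m", "y_m",
                               "area", "pack_id", "prey_species")]
  out <- list(scats = scats, items = items, scats_long = scats_long,
              traits = {
                tr <- config$prey_pool
                tr$size_class <- assign_size_class(tr$mean_female_mass_kg)
                tr
              },
              cameras = cameras, effort = effort, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    long <- out$scats_long
    long$pack_id[is.na(long$pack_id)] <- ""
    utils::write.csv(long, file.path(dir, "scats.csv"), row.names = FALSE)
    utils::write.csv(config$prey_pool, file.path(dir, "prey_traits.csv"),
                     row.names = FALSE)
    cams <- out$cameras
    cams$timestamp <- format(cams$timestamp, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(cams, file.path(dir, "cameras.csv"), row.names = FALSE)
    utils::write.csv(effort, file.path(dir, "effort.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Score pipeline estimates against generating truth
#'
#' Compares a [run_study()] result with the `truth` element of the
#' [generate_study()] call that produced its inputs: per-predator overall
#' diet proportions, pairwise Pianka overlaps, standardised Levins
#' breadths, the Spearman rank agreement of camera-trap RAI with true
#' densities per area, and the sign of Jacobs' index for strongly
#' preferred/avoided species (true diet share at least twice, or at most
#' half, the true availability share).
#'
#' @param truth the `truth` list from [generate_study()].
#' @param run a [run_study()] result from the same study.
#' @return data frame with columns quantity, true, estimated, abs_error.
#' @export
recovery_report <- function(truth, run) {
  run_preds <- unique(run$composition$predator)
  if (!all(run_preds %in% names(truth$diets)))
    stop("truth and run come from different studies: predators ",
         paste(setdiff(run_preds, names(truth$diets)), collapse = ", "),
         " not in truth")
  rows <- list()
  add <- function(q, tr, est) rows[[length(rows) + 1]] <<-
    data.frame(quantity = q, true = tr, estimated = est,
               abs_error = abs(tr - est), stringsAsFactors = FALSE)

  # overall true diets: mix of area diets weighted by configured scat counts
  preds <- names(truth$diets)
  all_prey <- sort(unique(unlist(lapply(truth$diets, function(x)
    unlist(lapply(x, names))))))
  true_all <- list()
  for (pred in preds) {
    w <- truth$n_scats[[pred]]
    v <- rep(0, length(all_prey)); names(v) <- all_prey
    for (a in names(w)) {
      d <- truth$diets[[pred]][[a]]
      v[names(d)] <- v[names(d)] + w[[a]] * d
    }
    true_all[[pred]] <- v / sum(v)
  }
  for (pred in preds) {
    est_fo <- run$composition$fo_items[run$composition$predator == pred &
                                         run$composition$stratum == "All"]
    names(est_fo) <- run$composition$species[
      run$composition$predator == pred & run$composition$stratum == "All"]
    for (sp in names(true_all[[pred]])[true_all[[pred]] > 0.05])
      add(paste0("fo:", pred, ":", sp), true_all[[pred]][[sp]],
          if (sp %in% names(est_fo)) est_fo[[sp]] else 0)
  }
  # true pairwise Pianka on the overall diets
  U_true <- do.call(rbind, true_all)
  ov <- run$overlap[["All"]]
  if (!is.null(ov)) {
    for (r in seq_len(nrow(ov))) {
      j <- ov$predator_j[r]; k <- ov$predator_k[r]
      add(paste0("pianka:", j, ":", k),
          pianka_overlap(U_true[j, ], U_true[k, ]), ov$observed[r])
    }
  }
  br <- run$breadth[run$breadth$stratum == "All", ]
  for (r in seq_len(nrow(br))) {
    p <- true_all[[br$predator[r]]]
    n_true <- sum(colSums(U_true) > 0)
    add(paste0("levins_Bs:", br$predator[r]),
        levins_breadth(p, n_true)$Bs, br$Bs[r])
  }
  # RAI rank agreement with true density, per area (rank corr; true = 1)
  if (!is.null(run$rai)) {
    for (a in unique(run$rai$area)) {
      est <- run$rai[run$rai$area == a, ]
      tr <- truth$densities[[a]][est$species]
      add(paste0("rai_rank_corr:", a), 1,
          stats::cor(est$rai, unlist(tr), method = "spearman"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
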
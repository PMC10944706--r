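#' Run the full dietary-competition analysis
#'
#' Orchestrates the pipeline on parsed tables: pseudo-replication
#' filtering, minimum-sample screening of predator x stratum cells, diet
#' composition (frequency of occurrence, biomass proportions, category
#' aggregation), utilization matrices with Pianka overlap null tests and
#' Levins breadth per stratum, between-predator and between-area PERMANOVA
#' comparisons stratified by year, camera-trap RAI and Jacobs' preference,
#' and species accumulation curves. Every excluded cell and dropped scat is
#' recorded in the run log.
#'
#' Strata analysed: `"All"` plus each area; seasonal strata (weather
#' scheme) restricted to the northern areas (NE, NW), where sampling covers
#' both seasons.
#'
#' @param scats,items,traits parsed tables ([read_scat_table()],
#'   [read_prey_traits()]).
#' @param cameras,effort optional camera tables; preference and RAI are
#'   skipped when absent.
#' @param densities optional density table (`species`, `area`,
#'   `density_per_km2`) used as a second availability source.
#' @param min_scats minimum scats per analysis cell (default 21).
#' @param n_perm PERMANOVA permutations (default 1000).
#' @param n_iter overlap null iterations (default 10000).
#' @param seed master seed for all permutation draws.
#' @param accumulation_perm permutations for accumulation curves.
#' @return object of class `scatcomp_run`; a list with elements
#'   `composition`, `overlap` (per stratum), `breadth`, `permanova`,
#'   `preference`, `rai`, `accumulation`, `filter_log`, `excluded_cells`,
#'   `included`.
#' @export
run_study <- function(scats, items, traits, cameras = NULL, effort = NULL,
                      densities = NULL, min_scats = 21, n_perm = 1000,
                      n_iter = 10000, seed = 1, accumulation_perm = 100) {
  flt <- filter_pseudoreplicates(scats)
  scats <- flt$retained
  scats$season_weather <- assign_season(scats$date, "weather")
  scats$season_behav <- assign_season(scats$date, "behavioural")

  strata_of <- function(s) {
    # list of (stratum label, row filter)
    north <- s$area %in% c("NE", "NW")
    c(list(All = rep(TRUE, nrow(s))),
      stats::setNames(lapply(AREAS, function(a) s$area == a), AREAS),
      list(wet_early_dry = north & s$season_weather == "wet_early_dry",
           late_dry = north & s$season_weather == "late_dry"))
  }
  strata <- strata_of(scats)

  # which predator x stratum cells have enough scats
  cell_counts <- integer(0)
  for (st in names(strata)) for (pred in unique(scats$predator)) {
    n <- sum(strata[[st]] & scats$predator == pred)
    cell_counts[paste(pred, st, sep = ":")] <- n
  }
  screen <- enforce_min_samples(cell_counts, threshold = min_scats)

  cell_ok <- function(pred, st)
    isTRUE(screen$included[[paste(pred, st, sep = ":")]])

  comp_rows <- list(); overlap <- list(); breadth_rows <- list()
  for (st in names(strata)) {
    sub <- scats[strata[[st]], , drop = FALSE]
    diets <- list()
    for (pred in sort(unique(sub$predator))) {
      if (!cell_ok(pred, st)) next
      d <- diet_counts(sub, items, predator = pred, stratum = st)
      diets[[pred]] <- d
      fo_i <- frequency_of_occurrence(d, "items")
      fo_s <- frequency_of_occurrence(d, "scats")
      bio <- relative_biomass(d, traits)
      comp_rows[[length(comp_rows) + 1]] <- data.frame(
        predator = pred, stratum = st, species = names(fo_i),
        n_items = unname(d$counts), fo_items = unname(fo_i),
        fo_scats = unname(fo_s[names(fo_i)]), biomass_prop = unname(bio),
        stringsAsFactors = FALSE)
    }
    if (length(diets) >= 2) {
      U <- utilization_matrix(diets)
      overlap[[st]] <- overlap_null_test(U, n_iter = n_iter, seed = seed)
      for (pred in rownames(U)) {
        b <- levins_breadth(U[pred, ], ncol(U))
        breadth_rows[[length(breadth_rows) + 1]] <- data.frame(
          predator = pred, stratum = st, B = b$B, Bs = b$Bs, n = b$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  composition <- do.call(rbind, comp_rows)

  # PERMANOVA: wild dog vs each other predator within each area (species
  # composition, Jaccard), and each predator between areas; year strata
  perm_rows <- list()
  run_perm <- function(sub_scats, label) {
    res <- permanova(scat_distance_matrix(sub_scats, items,
                                          "species_presence"),
                     groups = sub_scats$.grp, strata = sub_scats$year,
                     n_perm = n_perm, seed = seed)
    data.frame(comparison = label, pseudo_F = res$pseudo_F,
               df_between = res$df_between, df_within = res$df_within,
               r2 = res$r2, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }
  for (a in AREAS) {
    sub <- scats[scats$area == a, , drop = FALSE]
    others <- setdiff(unique(sub$predator), "wild_dog")
    for (pred in others) {
      if (!cell_ok("wild_dog", a) || !cell_ok(pred, a)) next
      pair <- sub[sub$predator %in% c("wild_dog", pred), , drop = FALSE]
      pair$.grp <- pair$predator
      perm_rows[[length(perm_rows) + 1]] <-
        run_perm(pair, paste0("wild_dog_vs_", pred, ":", a))
    }
  }
  for (pred in unique(scats$predator)) {
    ok_areas <- AREAS[vapply(AREAS, function(a) cell_ok(pred, a),
                             logical(1))]
    if (length(ok_areas) >= 2) {
      for (i in seq_len(length(ok_areas) - 1))
        for (j in (i + 1):length(ok_areas)) {
          sub <- scats[scats$predator == pred &
                         scats$area %in% ok_areas[c(i, j)], , drop = FALSE]
          sub$.grp <- sub$area
          perm_rows[[length(perm_rows) + 1]] <-
            run_perm(sub, paste0(pred, ":", ok_areas[i], "_vs_",
                                 ok_areas[j]))
        }
    }
  }
  permanova_tab <- if (length(perm_rows)) do.call(rbind, perm_rows) else NULL

  # preference: RAI availability per area, Jacobs per predator x area
  rai_tab <- NULL; pref_rows <- list()
  if (!is.null(cameras) && !is.null(effort)) {
    ind <- independent_records(cameras)
    rai_tab <- rai(ind, effort, level = "area")
    avail_sources <- list(rai = rai_tab)
    if (!is.null(densities)) {
      d <- densities
      names(d)[names(d) == "density_per_km2"] <- "density"
      avail_sources$density <- d
    }
    for (src in names(avail_sources)) {
      av <- avail_sources[[src]]
      for (a in AREAS) {
        av_a <- av[av$area == a, , drop = FALSE]
        if (nrow(av_a) == 0) next
        sub <- scats[scats$area == a, , drop = FALSE]
        for (pred in sort(unique(sub$predator))) {
          if (!cell_ok(pred, a)) next
          fo <- frequency_of_occurrence(
            diet_counts(sub, items, predator = pred, stratum = a))
          pref_rows[[length(pref_rows) + 1]] <- withCallingHandlers(
            preference_table(fo, av_a, predator = pred, stratum = a,
                             source = src),
            warning = function(w) invokeRestart("muffleWarning"))
        }
      }
    }
  }
  preference <- if (length(pref_rows)) do.call(rbind, pref_rows) else NULL

  accum <- list()
  for (pred in sort(unique(scats$predator))) {
    sub <- scats[scats$predator == pred, , drop = FALSE]
    accum[[pred]] <- species_accumulation(incidence_matrix(sub, items),
                                          n_perm = accumulation_perm,
                                          seed = seed)
  }

  out <- list(composition = composition, overlap = overlap,
              breadth = do.call(rbind, breadth_rows),
              permanova = permanova_tab, preference = preference,
              rai = rai_tab, accumulation = accum,
              filter_log = flt$log, excluded_cells = screen$log,
              included = screen$included, min_scats = min_scats,
              seed = seed)
  class(out) <- "scatcomp_run"
  out
}

#' @export
print.scatcomp_run <- function(x, ...) {
  cat("Dietary-competition analysis\n")
  cat(sprintf("  %d scats dropped by pseudo-replication filter\n",
              nrow(x$filter_log)))
  cat(sprintf("  %d analysis cells excluded (< %d scats)\n",
              nrow(x$excluded_cells), x$min_scats))
  cat(sprintf("  composition rows: %d; PERMANOVA comparisons: %d\n",
              nrow(x$composition) %||% 0L,
              if (is.null(x$permanova)) 0L else nrow(x$permanova)))
  if (!is.null(x$overlap[["All"]])) {
    cat("  overall Pianka overlaps:\n")
    ov <- x$overlap[["All"]]
    for (r in seq_len(nrow(ov)))
      cat(sprintf("    %s - %s: %.2f (p = %.3g)\n", ov$predator_j[r],
                  ov$predator_k[r], ov$observed[r], ov$p_value[r]))
  }
  invisible(x)
}

#' Headline wild-dog overlap summary
#'
#' Recomputes the study's headline quantities from a scat dataset: overall
#' Pianka overlap of wild dogs with each other predator, the same per area,
#' and the number of prey species in the wild dog diet. Scats are
#' pseudo-replication-filtered first; utilization rows use item-convention
#' frequency of occurrence over the union of all consumed prey.
#'
#' @param scats,items parsed scat tables.
#' @param min_scats minimum scats for a predator cell to enter the per-area
#'   table (default 21; the overall row always includes all predators).
#' @return list with `overall` (named vector of wild dog x predator
#'   overlaps), `by_area` (data frame area/predator/overlap), and
#'   `wild_dog_richness`.
#' @export
headline_overlaps <- function(scats, items, min_scats = 21) {
  scats <- filter_pseudoreplicates(scats)$retained
  others <- setdiff(unique(scats$predator), "wild_dog")
  if (!"wild_dog" %in% scats$predator) stop("no wild dog scats")
  diets <- lapply(sort(unique(scats$predator)), function(p)
    diet_counts(scats, items, predator = p, stratum = "All"))
  U <- utilization_matrix(diets)
  overall <- vapply(others, function(p)
    pianka_overlap(U["wild_dog", ], U[p, ]), numeric(1))
  rows <- list()
  for (a in intersect(AREAS, unique(scats$area))) {
    sub <- scats[scats$area == a, , drop = FALSE]
    n_by <- table(sub$predator)
    preds <- names(n_by)[n_by >= min_scats]
    if (!"wild_dog" %in% preds || length(preds) < 2) next
    diets_a <- lapply(preds, function(p)
      diet_counts(sub, items, predator = p, stratum = a))
    Ua <- utilization_matrix(diets_a)
    for (p in setdiff(preds, "wild_dog"))
      rows[[length(rows) + 1]] <- data.frame(
        area = a, predator = p,
        overlap = pianka_overlap(Ua["wild_dog", ], Ua[p, ]),
        stringsAsFactors = FALSE)
  }
  wd_items <- items[items$scat_id %in%
                      scats$scat_id[scats$predator == "wild_dog"], ]
  list(overall = overall,
       by_area = if (length(rows)) do.call(rbind, rows) else NULL,
       wild_dog_richness = length(unique(wd_items$prey_species)))
}
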
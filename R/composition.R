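#' Tally a predator's diet within a stratum
#'
#' Counts prey-item occurrences over a set of scats, giving the raw material
#' for frequency-of-occurrence and biomass proportions.
#'
#' @param scats scat data frame (already filtered).
#' @param items prey-item data frame (`scat_id`, `prey_species`).
#' @param predator predator label; `NULL` keeps all.
#' @param stratum label recorded on the result (e.g. `"All"`, an area, a
#'   season); purely descriptive — subset `scats` before calling.
#' @return object of class `diet_counts`: list with `predator`, `stratum`,
#'   `counts` (named integer, items per prey species), `scat_counts` (named
#'   integer, number of scats containing each species), `n_scats`, `n_items`.
#' @export
diet_counts <- function(scats, items, predator = NULL, stratum = "All") {
  if (!is.null(predator)) scats <- scats[scats$predator == predator, ,
                                         drop = FALSE]
  it <- items[items$scat_id %in% scats$scat_id, , drop = FALSE]
  if (nrow(it) == 0)
    stop("no prey items for predator ", predator %||% "<all>",
         " in stratum ", stratum)
  counts <- table(it$prey_species)
  per_scat <- table(unique(it)[, "prey_species"])
  out <- list(predator = predator %||% "all", stratum = stratum,
              counts = stats::setNames(as.integer(counts), names(counts)),
              scat_counts = stats::setNames(as.integer(per_scat),
                                            names(per_scat)),
              n_scats = length(unique(it$scat_id)), n_items = nrow(it))
  class(out) <- "diet_counts"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.diet_counts <- function(x, ...) {
  cat(sprintf("Diet of %s [%s]: %d items in %d scats, %d prey species\n",
              x$predator, x$stratum, x$n_items, x$n_scats, length(x$counts)))
  invisible(x)
}

#' Frequency of occurrence of prey species
#'
#' The primary (item) convention divides each species' occurrence count by
#' the total number of prey items, so proportions sum to 1 and can feed
#' utilization matrices directly. The scat convention divides the number of
#' scats containing the species by the total number of scats; it need not
#' sum to 1 when scats hold several items.
#'
#' @param diet a [diet_counts()] object.
#' @param convention `"items"` (default) or `"scats"`.
#' @return named numeric vector of proportions.
#' @export
frequency_of_occurrence <- function(diet, convention = c("items", "scats")) {
  convention <- match.arg(convention)
  stopifnot(inherits(diet, "diet_counts"))
  if (diet$n_items <= 0) stop("empty diet")
  if (convention == "items") diet$counts / diet$n_items
  else diet$scat_counts / diet$n_scats
}

# intercept/slope: prey mass (kg) represented by one scat as a linear
# function of the prey's mean female mass; cap = predator stomach capacity
BIOMASS_MODELS <- list(
  wild_dog = list(intercept = 0.439, slope = 0.008, cap = NULL),
  cheetah  = list(intercept = 1.980, slope = 0.035, cap = NULL),
  leopard  = list(intercept = 1.980, slope = 0.035, cap = 10),
  hyaena   = list(intercept = 1.980, slope = 0.035, cap = 24),
  lion     = list(intercept = 1.980, slope = 0.035, cap = 50)
)

#' Prey biomass represented by one scat
#'
#' Linear regressions convert a prey species' mean female mass into the kg
#' of that prey represented by one scat: the Weaver grey-wolf equation
#' (0.439 + 0.008 x mass) for wild dogs and the Ackerman puma equation
#' (1.980 + 0.035 x mass) for the other predators. The per-scat value is
#' truncated at the predator's maximum stomach capacity (10 kg leopard,
#' 24 kg hyaena, 50 kg lion); wild dog and cheetah values never approach
#' their capacity, so no cap applies. The resulting biomass proportions are
#' indicative, not absolute intake.
#'
#' @param predator predator label.
#' @param mass_kg mean female mass of the prey in kg (vectorised);
#'   `mass_kg = 0` is allowed to read off the intercept.
#' @return numeric vector of kg per scat.
#' @export
biomass_per_scat <- function(predator, mass_kg) {
  m <- BIOMASS_MODELS[[predator]]
  if (is.null(m)) stop("unknown predator: ", predator)
  if (any(mass_kg < 0)) stop("mass_kg must be non-negative")
  v <- m$intercept + m$slope * mass_kg
  if (!is.null(m$cap)) v <- pmin(v, m$cap)
  v
}

#' Relative biomass contribution of each prey species
#'
#' Weights occurrence counts by the per-scat biomass of each species and
#' renormalises, giving the proportion of consumed biomass attributable to
#' each prey.
#'
#' @param diet a [diet_counts()] object.
#' @param traits prey-trait data frame with `species` and
#'   `mean_female_mass_kg`.
#' @param predator predator label for the biomass model; defaults to
#'   `diet$predator`.
#' @return named numeric vector of biomass proportions summing to 1.
#' @export
relative_biomass <- function(diet, traits, predator = diet$predator) {
  stopifnot(inherits(diet, "diet_counts"))
  sp <- names(diet$counts)
  miss <- setdiff(sp, traits$species)
  if (length(miss))
    stop("species missing from trait table: ", paste(miss, collapse = ", "))
  mass <- traits$mean_female_mass_kg[match(sp, traits$species)]
  w <- diet$counts * biomass_per_scat(predator, mass)
  w / sum(w)
}

#' Aggregate diet counts by a prey trait category
#'
#' Sums occurrence counts over prey species sharing a trait level (water
#' dependency, feeding guild or size class). Total item count is preserved;
#' levels no species maps to are omitted.
#'
#' @param diet a [diet_counts()] object.
#' @param traits prey-trait data frame (with derived `size_class`).
#' @param category one of `"water_dependency"`, `"feeding_guild"`,
#'   `"size_class"`.
#' @return named integer vector of counts per category level.
#' @export
aggregate_by_category <- function(diet, traits,
                                  category = c("water_dependency",
                                               "feeding_guild",
                                               "size_class")) {
  category <- match.arg(category)
  stopifnot(inherits(diet, "diet_counts"))
  sp <- names(diet$counts)
  idx <- match(sp, traits$species)
  if (anyNA(idx))
    stop("species missing from trait table: ",
         paste(sp[is.na(idx)], collapse = ", "))
  lev <- traits[[category]][idx]
  if (anyNA(lev))
    stop("species with missing ", category, ": ",
         paste(sp[is.na(lev)], collapse = ", "))
  agg <- tapply(diet$counts, lev, sum)
  stats::setNames(as.integer(agg), names(agg))
}

#' Build a predator x prey utilization matrix
#'
#' Rows are predators, columns the union of all prey consumed by any of
#' them; entries are item-convention frequencies of occurrence, so every row
#' sums to 1. This matrix feeds Pianka overlap and Levins breadth.
#'
#' @param diets list of [diet_counts()] objects (one per predator).
#' @return numeric matrix with predator rownames and prey colnames.
#' @export
utilization_matrix <- function(diets) {
  stopifnot(length(diets) >= 1,
            all(vapply(diets, inherits, logical(1), "diet_counts")))
  prey <- sort(unique(unlist(lapply(diets, function(d) names(d$counts)))))
  preds <- vapply(diets, function(d) d$predator, character(1))
  if (any(duplicated(preds))) stop("duplicate predators in diet list")
  U <- matrix(0, nrow = length(diets), ncol = length(prey),
              dimnames = list(preds, prey))
  for (d in diets) {
    fo <- frequency_of_occurrence(d)
    U[d$predator, names(fo)] <- fo
  }
  U
}
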
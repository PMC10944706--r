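#' Jaccard dissimilarity between two species sets
#'
#' For presence/absence comparison of two scats: with A and B the species
#' richness of each scat and J the number shared, the dissimilarity is
#' (A + B - 2J) / (A + B - J). 0 for identical sets, 1 for disjoint sets.
#'
#' @param a,b character vectors of species (duplicates ignored).
#' @return dissimilarity in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  A <- length(a); B <- length(b)
  if (A + B == 0) stop("both species sets are empty")
  J <- length(intersect(a, b))
  (A + B - 2 * J) / (A + B - J)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' For abundance comparison of per-scat category counts:
#' sum|x_i - y_i| / sum(x_i + y_i), on a shared category index.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must share the category index")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both count vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Scat-level dissimilarity matrix
#'
#' Builds the pairwise dissimilarity matrix feeding PERMANOVA: Jaccard on
#' per-scat prey species presence (`mode = "species_presence"`), or
#' Bray-Curtis on per-scat counts of prey in a trait category
#' (`mode = "category_counts"`, requires `traits` and `category`).
#'
#' @param scats scat data frame.
#' @param items prey-item data frame.
#' @param mode `"species_presence"` or `"category_counts"`.
#' @param traits prey-trait table (category mode only).
#' @param category trait column to count over (category mode only).
#' @return a `dist`-like square matrix with scat_id dimnames and a
#'   `"metric"` attribute.
#' @export
scat_distance_matrix <- function(scats, items,
                                 mode = c("species_presence",
                                          "category_counts"),
                                 traits = NULL, category = NULL) {
  mode <- match.arg(mode)
  ids <- scats$scat_id
  if (length(ids) < 2) stop("need at least 2 scats")
  it <- items[items$scat_id %in% ids, , drop = FALSE]
  if (mode == "species_presence") {
    sets <- split(it$prey_species, factor(it$scat_id, levels = ids))
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- jaccard_distance(sets[[i]], sets[[j]])
    attr(d, "metric") <- "jaccard"
  } else {
    if (is.null(traits) || is.null(category))
      stop("category_counts mode requires traits and category")
    idx <- match(it$prey_species, traits$species)
    if (anyNA(idx))
      stop("species missing from trait table: ",
           paste(unique(it$prey_species[is.na(idx)]), collapse = ", "))
    lev <- traits[[category]][idx]
    tab <- table(factor(it$scat_id, levels = ids), lev)
    X <- matrix(as.numeric(tab), nrow = length(ids),
                dimnames = list(ids, colnames(tab)))
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- bray_curtis(X[i, ], X[j, ])
    attr(d, "metric") <- "bray_curtis"
  }
  d
}

# within/among sum-of-squares partition of a squared-distance matrix for a
# grouping vector (integer codes); returns c(SS_within, F) pieces needed hot
.permanova_stats <- function(d2, groups) {
  N <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (N - a))
  c(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among, f = f)
}

# all distinct assignments of group labels (multiset permutations); feasible
# only for small N. Returns a matrix with one assignment per column.
.enumerate_assignments <- function(groups) {
  uniq <- unique(groups)
  n <- length(groups)
  rec <- function(remaining) {
    if (length(remaining) == 1) return(matrix(remaining, nrow = 1))
    out <- NULL
    for (g in unique(remaining)) {
      rest <- rec(remaining[-match(g, remaining)])
      out <- cbind(out, rbind(g, rest))
    }
    out
  }
  rec(groups)
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' One-factor PERMANOVA: partitions the sum of squared dissimilarities into
#' among- and within-group components, forms the pseudo-F statistic
#' (SS_among / (a-1)) / (SS_within / (N-a)), and assesses it by permuting
#' group labels. Permutations are restricted within strata (here, calendar
#' year) so that year effects cannot masquerade as group differences. The
#' p-value uses the (b + 1) / (m + 1) convention. With
#' `permutations = "exhaustive"` all distinct label assignments are
#' enumerated (small N only) and p = #\{F* >= F\} / n_assignments, the
#' identity assignment included.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param groups group label per observation.
#' @param strata stratum label per observation (default: one stratum).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation RNG.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return object of class `scat_permanova` with fields `pseudo_F`,
#'   `df_between`, `df_within`, `r2`, `p_value`, `ss` (total/among/within),
#'   `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 1000, seed = 1,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  d <- as.matrix(d)
  N <- nrow(d)
  stopifnot(length(groups) == N)
  if (is.null(strata)) strata <- rep(1L, N)
  stopifnot(length(strata) == N)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 members")
  d2 <- d^2
  obs <- .permanova_stats(d2, groups)
  degenerate <- obs[["ss_within"]] <= .Machine$double.eps * obs[["ss_total"]]
  str_idx <- split(seq_len(N), strata)
  if (permutations == "exhaustive") {
    # enumerate within-stratum label assignments; cartesian over strata
    per_str <- lapply(str_idx, function(ix) .enumerate_assignments(groups[ix]))
    counts <- vapply(per_str, ncol, integer(1))
    combos <- expand.grid(lapply(counts, seq_len))
    fs <- apply(combos, 1, function(sel) {
      g <- groups
      for (k in seq_along(str_idx))
        g[str_idx[[k]]] <- per_str[[k]][, sel[k]]
      .permanova_stats(d2, g)[["f"]]
    })
    n_used <- length(fs)
    p <- sum(fs >= obs[["f"]] - 1e-12) / n_used
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      g <- groups
      for (ix in str_idx) g[ix] <- g[ix][sample.int(length(ix))]
      if (.permanova_stats(d2, g)[["f"]] >= obs[["f"]] - 1e-12)
        exceed <- exceed + 1L
    }
    n_used <- n_perm
    p <- (exceed + 1) / (n_perm + 1)
  }
  a <- length(tab)
  out <- list(pseudo_F = unname(obs[["f"]]), df_between = a - 1L,
              df_within = N - a,
              r2 = unname(obs[["ss_among"]] / obs[["ss_total"]]),
              p_value = p,
              ss = c(total = unname(obs[["ss_total"]]),
                     among = unname(obs[["ss_among"]]),
                     within = unname(obs[["ss_within"]])),
              n_perm = n_used, seed = seed, degenerate = degenerate,
              metric = attr(d, "metric") %||% "unknown")
  class(out) <- "scat_permanova"
  out
}

#' @export
print.scat_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F[%d,%d] = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$metric, x$df_between, x$df_within, x$pseudo_F, x$r2,
              x$p_value, x$n_perm))
  if (x$degenerate)
    cat("  note: within-group sum of squares ~ 0; F is unstable\n")
  invisible(x)
}
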
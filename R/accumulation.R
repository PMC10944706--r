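#' Prey species accumulation curve
#'
#' Assesses whether enough scats were collected to characterise a diet:
#' the expected number of distinct prey species found in the first n scats,
#' as n grows to the full sample. `method = "random"` averages cumulative
#' richness over random permutations of scat order; `method = "exact"` uses
#' the closed-form hypergeometric expectation
#' E\[S(n)\] = sum_s (1 - C(N - m_s, n) / C(N, n)), with m_s the number of
#' scats containing species s — the limit of the permutation average.
#'
#' @param incidence logical/0-1 matrix, scats in rows, species in columns;
#'   or a list as returned by [read_scat_table()] via `scats`/`items`.
#' @param n_perm permutations for `method = "random"` (default 100).
#' @param seed integer seed for the permutation RNG.
#' @param method `"random"` or `"exact"`.
#' @return object of class `accum_curve`: list with `n_scats` (1..N),
#'   `mean_richness`, `sd_richness` (NA for exact), `method`, `n_perm`,
#'   `seed`.
#' @export
species_accumulation <- function(incidence, n_perm = 100, seed = 1,
                                 method = c("random", "exact")) {
  method <- match.arg(method)
  X <- as.matrix(incidence) > 0
  if (nrow(X) == 0) stop("empty incidence table")
  N <- nrow(X)
  if (method == "exact") {
    m_s <- colSums(X)
    mean_rich <- vapply(seq_len(N), function(n) {
      sum(1 - exp(lchoose(N - m_s, n) - lchoose(N, n)))
    }, numeric(1))
    sd_rich <- rep(NA_real_, N)
    n_perm <- NA_integer_
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    rich <- matrix(0, n_perm, N)
    for (b in seq_len(n_perm)) {
      ord <- sample.int(N)
      seen <- rep(FALSE, ncol(X))
      for (i in seq_len(N)) {
        seen <- seen | X[ord[i], ]
        rich[b, i] <- sum(seen)
      }
    }
    mean_rich <- colMeans(rich)
    sd_rich <- apply(rich, 2, stats::sd)
  }
  out <- list(n_scats = seq_len(N), mean_richness = mean_rich,
              sd_richness = sd_rich, method = method, n_perm = n_perm,
              seed = seed, total_richness = sum(colSums(X) > 0))
  class(out) <- "accum_curve"
  out
}

#' Build a scat x species incidence matrix
#'
#' @param scats scat data frame (rows define the scats included).
#' @param items prey-item data frame.
#' @return logical matrix, one row per scat, one column per species.
#' @export
incidence_matrix <- function(scats, items) {
  ids <- scats$scat_id
  it <- items[items$scat_id %in% ids, , drop = FALSE]
  sp <- sort(unique(it$prey_species))
  X <- matrix(FALSE, length(ids), length(sp), dimnames = list(ids, sp))
  if (nrow(it)) X[cbind(it$scat_id, it$prey_species)] <- TRUE
  X
}

#' @export
print.accum_curve <- function(x, ...) {
  cat(sprintf("Species accumulation (%s): %d scats, %d species total\n",
              x$method, length(x$n_scats), x$total_richness))
  invisible(x)
}

#' @export
plot.accum_curve <- function(x, ...) {
  graphics::plot(x$n_scats, x$mean_richness, type = "l",
                 xlab = "Number of scats", ylab = "Prey species", ...)
  if (!all(is.na(x$sd_richness))) {
    graphics::lines(x$n_scats, x$mean_richness + x$sd_richness, lty = 2)
    graphics::lines(x$n_scats,
                    pmax(0, x$mean_richness - x$sd_richness), lty = 2)
  }
  invisible(x)
}
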
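test_that("Jaccard and Bray-Curtis match hand-derived values and axioms", {
  expect_equal(jaccard_distance(c("kudu", "impala"),
                                c("kudu", "duiker", "steenbok")), 0.75)
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b", "c")), 1)
  expect_error(jaccard_distance(character(0), character(0)), "empty")

  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(3, 2), c(3, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(5)
  pool <- letters[1:8]
  for (i in 1:50) {
    a <- sample(pool, sample(1:5, 1))
    b <- sample(pool, sample(1:5, 1))
    c_ <- sample(pool, sample(1:5, 1))
    dab <- jaccard_distance(a, b)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, jaccard_distance(b, a))
    # Jaccard distance is a metric: triangle inequality on random triples
    expect_lte(jaccard_distance(a, c_),
               dab + jaccard_distance(b, c_) + 1e-12)
    x <- rpois(4, 2); y <- rpois(4, 2)
    if (sum(x + y) > 0) {
      expect_equal(bray_curtis(x, y), bray_curtis(y, x))
      expect_gte(bray_curtis(x, y), 0)
      expect_lte(bray_curtis(x, y), 1)
    }
  }
})

test_that("scat distance matrices compose the pairwise metrics", {
  s <- make_scats(paste0("s", 1:4), "lion", "2013-01-01")
  it <- make_items(c("s1", "s1", "s2", "s3", "s3", "s4"),
                   c("kudu", "impala", "kudu", "duiker", "impala",
                     "buffalo"))
  d <- scat_distance_matrix(s, it, "species_presence")
  expect_equal(attr(d, "metric"), "jaccard")
  expect_true(isSymmetric(unname(d)))
  expect_equal(unname(diag(d)), rep(0, 4))
  sets <- split(it$prey_species, it$scat_id)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], jaccard_distance(sets[[i]], sets[[j]]))

  # identical single-species scats at distance 0; disjoint at 1
  s2 <- make_scats(c("a", "b"), "lion", "2013-01-01")
  d2 <- scat_distance_matrix(s2, make_items(c("a", "b"), c("kudu", "kudu")),
                             "species_presence")
  expect_equal(d2["a", "b"], 0)

  dc <- scat_distance_matrix(s, it, "category_counts",
                             traits = toy_traits(),
                             category = "water_dependency")
  expect_equal(attr(dc, "metric"), "bray_curtis")
  # s1 = {medium:1, high:1}, s2 = {medium:1} -> |0|+|1|+... / 3
  expect_equal(dc["s1", "s2"], 1 / 3)
  expect_error(scat_distance_matrix(s, it, "category_counts"),
               "traits and category")

  # cross-check against vegan's binary Jaccard on the incidence matrix
  X <- incidence_matrix(s, it)
  dv <- as.matrix(vegan::vegdist(X * 1, method = "jaccard", binary = TRUE))
  expect_equal(matrix(d, nrow(d)), matrix(dv, nrow(dv)), tolerance = 1e-12)
})

test_that("PERMANOVA decomposes sums of squares and matches adonis2", {
  set.seed(8)
  n <- 16
  s <- make_scats(sprintf("s%02d", 1:n), rep(c("lion", "hyaena"), each = 8),
                  as.Date("2013-01-01") + sample(0:700, n))
  it <- make_items(rep(s$scat_id, times = 2),
                   sample(c("kudu", "impala", "duiker", "buffalo"),
                          2 * n, replace = TRUE))
  d <- scat_distance_matrix(s, it, "species_presence")
  res <- permanova(d, groups = s$predator, n_perm = 500, seed = 3)
  expect_equal(res$ss[["among"]] + res$ss[["within"]], res$ss[["total"]],
               tolerance = 1e-9)
  expect_equal(res$r2, res$ss[["among"]] / res$ss[["total"]])
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, n - 2L)

  # independent implementation: vegan::adonis2 on the same matrix
  ad <- vegan::adonis2(stats::as.dist(d) ~ grp,
                       data = data.frame(grp = s$predator),
                       permutations = 999)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$p_value, ad$`Pr(>F)`[1], tolerance = 0.12)

  # invariant to observation order
  ord <- sample(n)
  res2 <- permanova(d[ord, ord], groups = s$predator[ord],
                    n_perm = 500, seed = 3)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  expect_equal(res2$r2, res$r2)
})

test_that("stratified permutations respect year blocks", {
  # each scat its own stratum: no permutation moves anything -> p = 1
  set.seed(2)
  n <- 10
  s <- make_scats(sprintf("s%02d", 1:n), rep(c("lion", "hyaena"), 5),
                  "2013-01-01")
  it <- make_items(s$scat_id,
                   sample(c("kudu", "impala", "duiker"), n, replace = TRUE))
  d <- scat_distance_matrix(s, it, "species_presence")
  res <- permanova(d, groups = s$predator, strata = seq_len(n),
                   n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1)

  # two groups with non-overlapping species pools: the observed split is
  # the most separated assignment, so only the identity assignment and its
  # label swap reach the observed F: exhaustive p = 2 / C(8,4)
  s2 <- make_scats(sprintf("t%02d", 1:8), rep(c("lion", "hyaena"), each = 4),
                   "2013-01-01")
  it2 <- make_items(c(s2$scat_id, "t02", "t04", "t06", "t08"),
                    c("kudu", "kudu", "kudu", "kudu",
                      "duiker", "duiker", "duiker", "duiker",
                      "impala", "impala", "steenbok", "steenbok"))
  d2 <- scat_distance_matrix(s2, it2, "species_presence")
  res2 <- permanova(d2, groups = s2$predator, permutations = "exhaustive")
  expect_equal(res2$p_value, 2 / 70)
  # random permutations put the same F in the far upper tail
  res3 <- permanova(d2, groups = s2$predator, n_perm = 300, seed = 4)
  expect_lt(res3$p_value, 0.06)
})

test_that("small-sample permutation p equals exhaustive enumeration", {
  set.seed(21)
  s <- make_scats(paste0("s", 1:6), rep(c("lion", "hyaena"), each = 3),
                  "2013-01-01")
  it <- make_items(c("s1", "s1", "s2", "s3", "s4", "s5", "s6"),
                   c("kudu", "impala", "kudu", "duiker", "impala",
                     "buffalo", "duiker"))
  d <- scat_distance_matrix(s, it, "species_presence")

  # oracle: enumerate all C(6,3) = 20 label assignments from first
  # principles and compute pseudo-F directly from the SS definitions
  f_of <- function(g) {
    d2 <- d^2; N <- 6
    sst <- sum(d2[upper.tri(d2)]) / N
    ssw <- 0
    for (lev in unique(g)) {
      ix <- which(g == lev)
      ssw <- ssw + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  obs <- f_of(s$predator)
  fs <- apply(utils::combn(6, 3), 2, function(ix) {
    g <- rep("B", 6); g[ix] <- "A"; f_of(g)
  })
  p_oracle <- mean(fs >= obs - 1e-12)

  res <- permanova(d, groups = s$predator, permutations = "exhaustive")
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$n_perm, 20L)  # distinct assignments of 3 + 3 labels
  # random permutations converge to the same p
  res_r <- permanova(d, groups = s$predator, n_perm = 4000, seed = 9)
  expect_equal(res_r$p_value, p_oracle, tolerance = 0.05)
})
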
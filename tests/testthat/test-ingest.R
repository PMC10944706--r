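test_that("read_scat_table groups item rows into scats and validates labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(
    scat_csv_row("s1", "lion", "2013-05-02", 100, 200, "NE", "", "kudu"),
    scat_csv_row("s1", "lion", "2013-05-02", 100, 200, "NE", "", "impala"),
    scat_csv_row("s2", "hyaena", "2013-06-10", 500, 900, "NW", "", "duiker"))
  write_scat_csv(df, f)
  out <- read_scat_table(f)
  expect_equal(nrow(out$scats), 2)
  expect_equal(nrow(out$items), 3)
  expect_equal(out$scats$year, c(2013L, 2013L))

  df$predator[3] <- "tiger"
  write_scat_csv(df, f)
  expect_error(read_scat_table(f), "tiger")

  # wild dog rows must carry a pack id
  df <- scat_csv_row("s9", "wild_dog", "2013-05-02", 1, 1, "NE", "", "kudu")
  write_scat_csv(df, f)
  expect_error(read_scat_table(f), "pack_id")

  # empty file with valid header parses to empty tables
  writeLines(paste("scat_id", "predator", "date", "x_m", "y_m", "area",
                   "pack_id", "prey_species", sep = ","), f)
  out <- read_scat_table(f)
  expect_equal(nrow(out$scats), 0)
  expect_equal(nrow(out$items), 0)

  # missing column is named in the error
  writeLines("scat_id,predator,date", f)
  expect_error(read_scat_table(f), "x_m")
})

test_that("pseudo-replication filter applies the 24 h / 1 km and pack rules", {
  # two lion scats, same point, same day -> 1 retained
  s <- make_scats(c("a", "b"), "lion", c("2013-01-01", "2013-01-01"))
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 1)
  expect_equal(filter_pseudoreplicates(s)$retained$scat_id, "a")
  expect_equal(filter_pseudoreplicates(s)$log$rule, "24h_1km")

  # two hyaena scats, 2000 m apart, same day -> both retained
  s <- make_scats(c("a", "b"), "hyaena", "2013-01-01", x = c(0, 2000))
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 2)

  # exactly 1000 m is "the same location" (<= 1 km inclusive)
  s <- make_scats(c("a", "b"), "hyaena", "2013-01-01", x = c(0, 1000))
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 1)

  # wild dog: same pack, same day, 5 km apart -> 1 retained
  s <- make_scats(c("a", "b"), "wild_dog", "2013-01-01",
                  x = c(0, 5000), pack_id = "p1")
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 1)

  # different packs never conflict
  s <- make_scats(c("a", "b"), "wild_dog", "2013-01-01",
                  pack_id = c("p1", "p2"))
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 2)

  # cheetah and leopard pass through unchanged
  s <- make_scats(c("a", "b", "c"), c("cheetah", "cheetah", "leopard"),
                  "2013-01-01")
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 3)

  # wild dog scat without a pack id is a validation error
  s <- make_scats("a", "wild_dog", "2013-01-01")
  expect_error(filter_pseudoreplicates(s), "pack_id")

  # different predators never suppress each other
  s <- make_scats(c("a", "b"), c("lion", "hyaena"), "2013-01-01")
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 2)
})

test_that("pseudo-replication filter is idempotent and earliest-first", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 15
    s <- make_scats(sprintf("s%02d", 1:n),
                    sample(c("lion", "hyaena"), n, replace = TRUE),
                    as.Date("2013-01-01") + sample(0:5, n, replace = TRUE),
                    x = runif(n, 0, 3000), y = runif(n, 0, 3000))
    once <- filter_pseudoreplicates(s)$retained
    twice <- filter_pseudoreplicates(once)$retained
    expect_equal(twice, once)
    expect_lte(nrow(once), n)
  }
  # all scats > 24 h apart: nothing dropped
  s <- make_scats(c("a", "b", "c"), "lion",
                  as.Date("2013-01-01") + c(0, 2, 4))
  expect_equal(nrow(filter_pseudoreplicates(s)$retained), 3)
})

test_that("season schemes partition the calendar with the stated windows", {
  dates <- as.Date(sprintf("2014-%02d-15", 1:12))
  weather <- assign_season(dates, "weather")
  behav <- assign_season(dates, "behavioural")
  expect_true(all(weather %in% c("wet_early_dry", "late_dry")))
  expect_true(all(behav %in% c("nomadic", "breeding")))
  expect_equal(sum(weather == "late_dry"), 4)    # July-October
  expect_equal(sum(behav == "breeding"), 4)      # May-August
  expect_equal(assign_season(as.Date("2014-07-15"), "weather"), "late_dry")
  expect_equal(assign_season(as.Date("2014-05-01"), "behavioural"),
               "breeding")
  expect_equal(assign_season(as.Date("2014-11-30"), "weather"),
               "wet_early_dry")
  expect_equal(assign_season(as.Date("2014-06-30"), "weather"),
               "wet_early_dry")
})

test_that("size classes follow the mass bounds and partition (0, Inf)", {
  expect_equal(assign_size_class(4), "XS")
  expect_equal(assign_size_class(150), "L")
  expect_equal(assign_size_class(400), "XL")
  expect_equal(assign_size_class(c(5, 25, 100, 350)), c("S", "M", "L", "XL"))
  # gap masses between printed bounds are still assigned
  expect_equal(assign_size_class(c(5.4, 24.5, 99.5, 349.5)),
               c("S", "S", "M", "L"))
  set.seed(3)
  m <- exp(runif(200, log(0.1), log(5000)))
  expect_false(anyNA(assign_size_class(m)))
  expect_error(assign_size_class(0), "positive")
})

test_that("minimum-sample screening excludes cells under the threshold", {
  counts <- c(cheetah_NW = 26, leopard_NE = 20, lion_SW = 27, empty = 0)
  res <- enforce_min_samples(counts)
  expect_true(res$included[["cheetah_NW"]])
  expect_false(res$included[["leopard_NE"]])
  expect_equal(sort(res$log$cell), c("empty", "leopard_NE"))
  # degenerate threshold: any non-empty cell passes
  expect_true(all(enforce_min_samples(c(a = 1, b = 5),
                                      threshold = 1)$included))
  expect_error(enforce_min_samples(c(a = -1)), "non-negative")
})
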
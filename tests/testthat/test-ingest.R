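test_that("record tables parse, reject malformed rows, and deduplicate", {
  path <- write_temp_records(c(
    "group,species,year,authors",
    "Tardigrada, Milnesium tardigradum, 1834, Doyère",
    "Tardigrada, Macrobiotus hufelandi, 1834, Schultze",
    "Tardigrada, Echiniscus testudo, 1740, Doyère",
    "Tardigrada, Milnesium tardigradum, 1900, Someone"
  ))
  expect_warning(
    expect_warning(rec <- read_description_table(path), "malformed"),
    "duplicated"
  )
  expect_equal(nrow(rec), 2L)
  expect_identical(rec$species[1], "Milnesium tardigradum")
  expect_identical(rec$year[1], 1834L) # first occurrence kept
  expect_error(
    read_description_table(write_temp_records("group,species,year,authors")),
    class = "descurves_error_ingest"
  )
})

test_that("parse -> write -> re-parse is idempotent", {
  rec <- simulate_description_records(
    sim_spec("gx", 400, k = 1, a = 40, b = 1900, noise_sd = 0.01, seed = 2)
  )
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_description_table(rec, f1)
  r1 <- read_description_table(f1)
  write_description_table(r1, f2)
  r2 <- read_description_table(f2)
  expect_identical(r1, r2)
})

test_that("yearly series accumulate and scale correctly", {
  rec <- tibble::tibble(
    group = "g",
    species = paste0("s", 1:4),
    year = c(1800L, 1800L, 1800L, 1900L),
    authors = "x"
  )
  ys <- build_yearly_series(rec, "g")
  expect_equal(ys$cumulative[ys$year == 1899], 3L)
  expect_equal(ys$cumulative[ys$year == 2017], 4L)
  expect_equal(tail(ys$scaled, 1), 1)
  expect_equal(nrow(ys), 265L)
  ## step function when everything is described in one year
  one <- tibble::tibble(group = "g", species = "s", year = 1900L, authors = "x")
  step <- build_yearly_series(one, "g")
  expect_true(all(step$scaled[step$year < 1900] == 0))
  expect_true(all(step$scaled[step$year >= 1900] == 1))
  expect_error(
    build_yearly_series(rec, "nope"),
    class = "descurves_error_unknown_group"
  )
  ## scaling is invariant to multiplying all counts
  rec10 <- rec[rep(seq_len(nrow(rec)), 10), ]
  rec10$species <- paste0("s", seq_len(nrow(rec10)))
  expect_equal(build_yearly_series(rec10, "g")$scaled, ys$scaled)
})

test_that("simulated histories round-trip through record expansion and ingest", {
  sp <- sim_spec("gr", 800, k = 0.5, a = 35, b = 1930, noise_sd = 0.01, seed = 4)
  direct <- simulate_description_history(sp)
  via_records <- build_yearly_series(simulate_description_records(sp), "gr")
  expect_identical(direct$count, via_records$count)
  expect_equal(direct$scaled, via_records$scaled)
})

test_that("mean authors per year matches a brute-force set count", {
  base <- tibble::tibble(
    group = "g", species = paste0("s", 1:6),
    year = c(1800L, 1800L, 1801L, 1801L, 1801L, 1950L),
    authors = c("A;B", "b", "C", "c ;D", "d", "E")
  )
  ## brute force: explode, normalise, count distinct names per grid year
  years <- 1753:2017
  sets <- lapply(years, function(y) {
    nm <- unlist(strsplit(base$authors[base$year == y], ";"))
    unique(tolower(trimws(nm)))
  })
  expect_equal(
    mean_authors_per_year(base, "g"),
    mean(lengths(sets))
  )
  ## trivial anchors
  every_year <- tibble::tibble(
    group = "g", species = paste0("s", seq_along(years)),
    year = years, authors = "Same Author"
  )
  expect_equal(mean_authors_per_year(every_year, "g"), 1)
  two_once <- tibble::tibble(
    group = "g", species = c("s1", "s2"), year = 1900L,
    authors = c("A", "B")
  )
  expect_equal(mean_authors_per_year(two_once, "g"), 2 / 265)
  ## pooled reading divides the overall distinct count by the grid length
  expect_equal(mean_authors_per_year(base, "g", method = "pooled"), 5 / 265)
})

test_that("group aggregation commutes with series building", {
  specs <- list(
    sim_spec("Coleoptera", 300, k = 1, a = 30, b = 1940, noise_sd = 0.01, seed = 5),
    sim_spec("Diptera", 200, k = 1, a = 45, b = 1960, noise_sd = 0.01, seed = 6),
    sim_spec("Araneae", 150, k = 1, a = 50, b = 1900, noise_sd = 0.01, seed = 7)
  )
  rec <- dplyr::bind_rows(lapply(specs, simulate_description_records))
  mapping <- c(Coleoptera = "Insecta", Diptera = "Insecta")
  agg <- aggregate_groups(rec, mapping)
  expect_setequal(unique(agg$group), c("Insecta", "Araneae"))
  summed <- build_yearly_series(rec, "Coleoptera")$count +
    build_yearly_series(rec, "Diptera")$count
  expect_equal(build_yearly_series(agg, "Insecta")$count, summed)
  ## identity mapping is a no-op; chained mappings are rejected
  expect_identical(aggregate_groups(rec, c(Araneae = "Araneae")), rec)
  expect_error(
    aggregate_groups(rec, c(Coleoptera = "Insecta", Insecta = "Hexapoda")),
    class = "descurves_error_mapping"
  )
})

test_that("unit-interval scaling is invertible and rejects constant columns", {
  tab <- tibble::tibble(a = c(1, 3, 5), b = c(0, 0.5, 1), g = c("x", "y", "z"))
  sc <- scale_unit_interval(tab)
  expect_equal(sc$a, c(0, 0.5, 1))
  expect_equal(sc$b, tab$b) # already [0,1] with min 0, max 1
  back <- unscale_unit_interval(sc)
  expect_equal(back$a, tab$a)
  expect_equal(back$b, tab$b)
  expect_error(
    scale_unit_interval(tibble::tibble(a = c(2, 2, 2))),
    regexp = "a",
    class = "descurves_error_constant_column"
  )
})

test_that("the packaged 47-group fixture is complete and plausible", {
  fx <- description_curve_fixture()
  expect_equal(nrow(fx), 47L)
  expect_true(all(fx$future_ratio >= 1))
  expect_true(all(fx$initial_time > 0 & fx$initial_time < 265))
  expect_true(all(fx$region_fraction >= 0 & fx$region_fraction <= 1))
  expect_true(all(fx$soil_endo %in% 1:5) && all(fx$aquatic %in% 1:5))
  expect_true(all(fx$body_size %in% -3:2))
})
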
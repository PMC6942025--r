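test_that("read_occurrences parses, filters and labels records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,year,x,y",
               "aj,2011,1.5,2.5",
               "aj,2012,bad,2.0",
               "av,2015,3.0,1.0"), f)
  expect_message(occ <- read_occurrences(f), "dropped 1 of 3")
  expect_equal(nrow(occ), 2)
  expect_identical(occ$species, c("aj", "av"))

  occ15 <- suppressMessages(read_occurrences(f, years = 2015))
  expect_equal(occ15$year, 2015L)

  occ_r <- suppressMessages(
    read_occurrences(f, roles = c(aj = "invasive", av = "native")))
  expect_identical(occ_r$role, c("invasive", "native"))
  expect_error(suppressMessages(read_occurrences(f, roles = c(aj = "invasive"))),
               "av")

  # missing required column is named in the error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,x,y", "aj,1,2"), f2)
  expect_error(read_occurrences(f2), "'year'")

  # empty file: empty tibble with a warning
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,year,x,y", f3)
  expect_warning(empty <- read_occurrences(f3), "no records")
  expect_equal(nrow(empty), 0)

  # species implied by filename-style single-species export
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,x,y", "2011,1,2"), f4)
  expect_identical(read_occurrences(f4, species = "aj")$species, "aj")
})

test_that("attach_features does nearest-cell, year-matched extraction", {
  m1 <- matrix(as.numeric(1:12), 3, 4)  # value = cell index, column-major
  m2 <- m1 * 10
  st11 <- tiny_stack(list(T13 = m1), year = 2011)
  st12 <- tiny_stack(list(T13 = m2), year = 2012)

  # exact centre of cell (row 2, col 3) -> that cell's stored value
  rec <- tibble::tibble(species = "aj", year = 2011L, x = 2.5, y = 1.5)
  got <- attach_features(rec, list(`2011` = st11))
  expect_equal(got$T13, m1[2, 3])

  # a whisker outside the extent is excluded and counted
  out <- tibble::tibble(species = "aj", year = 2011L,
                        x = c(2.5, 4.000001), y = c(1.5, 1))
  expect_message(got2 <- attach_features(out, list(`2011` = st11)), "excluded 1")
  expect_equal(nrow(got2), 1)
  expect_equal(attr(got2, "exclusions")[["outside"]], 1L)

  # same cell, different years -> year-matched values
  two <- tibble::tibble(species = "aj", year = c(2011L, 2012L),
                        x = 2.5, y = 1.5)
  got3 <- attach_features(two, list(`2011` = st11, `2012` = st12))
  expect_equal(got3$T13, c(m1[2, 3], m2[2, 3]))

  # nodata cells are excluded and counted
  m_na <- m1; m_na[2, 3] <- NA
  st_na <- tiny_stack(list(T13 = m_na), year = 2011)
  expect_message(got4 <- attach_features(rec, list(`2011` = st_na)), "1 on nodata")
  expect_equal(nrow(got4), 0)

  # missing year's stack is an error listing the year
  expect_error(attach_features(two, list(`2011` = st11)), "2012")

  # constant raster: every attached value equals the constant
  stc <- tiny_stack(list(T13 = matrix(7.25, 3, 4)), year = 2011)
  pts <- tibble::tibble(species = "aj", year = 2011L,
                        x = runif(50, 0, 4), y = runif(50, 0, 3))
  expect_true(all(attach_features(pts, list(`2011` = stc))$T13 == 7.25))
})

test_that("attach_features is idempotent in value and order-preserving", {
  cfg <- small_world(seed = 9)
  st <- generate_climate_stack(cfg, 2011)
  niche <- niche_spec("s", tibble::tibble(
    variable = "T13", optimum = 9, breadth = 2, weight = 0.5), abundance = 80)
  occ <- generate_occurrences(cfg, niche, st, seed = 2)
  f1 <- attach_features(occ, list(`2011` = st))
  f2 <- attach_features(f1[names(occ)], list(`2011` = st))
  expect_equal(f1$T13, f2$T13)
  expect_identical(f1$x, occ$x)

  # joining synthetic occurrences back reproduces the generator's cell values
  cell <- nichesvm:::point_to_cell(st$geometry, occ$x, occ$y)
  expect_identical(f1$T13, st$layers$T13[cbind(cell$row, cell$col)])
})

test_that("feature tables round-trip through CSV", {
  tab <- two_cloud_table(5, vars = c("T13", "D15"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  expect_error(read_feature_table(f, variables = c("T13", "D15", "P02")),
               "P02")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,role,year,x,y,T13", "aj,invasive,2011,1,2,oops"), f2)
  expect_error(read_feature_table(f2), "row 1")
})

test_that("different CSV dialects of one table load identically", {
  # dialect-independent parsing: our writer's output vs a re-encoded copy
  # with full quoting must yield the same feature table
  tab <- two_cloud_table(4, vars = "T13")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f1)
  utils::write.csv(as.data.frame(tab), f2, row.names = FALSE, quote = TRUE)
  expect_equal(read_feature_table(f1), read_feature_table(f2))
})

test_that("climate stacks round-trip through ESRI ASCII + manifest", {
  cfg <- small_world(seed = 5, rows = 7, cols = 9)
  st <- generate_climate_stack(cfg, 2011)
  st$layers$T13[3, 4] <- NA  # nodata survives the round trip
  dir <- withr::local_tempdir()
  manifest <- write_climate_stack(st, dir)
  expect_setequal(manifest$variable, cfg$variables)
  back <- read_climate_stack(dir)
  expect_equal(back$geometry, st$geometry)
  for (v in names(st$layers)) {
    expect_equal(back$layers[[v]], st$layers[[v]], tolerance = 1e-12)
  }
  expect_true(is.na(back$layers$T13[3, 4]))
})
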
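test_that("trait table reading validates labels, duplicates and missing values", {
  tbl <- make_table(list(c(A = "a"), c(A = "b"), c(A = "c")))
  expect_s3_class(tbl, "trait_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$species, sprintf("sp_%02d", 1:3))  # row order preserved

  df <- as.data.frame(tbl)
  df$B[2] <- "6"
  path <- records_csv(df)
  expect_error(read_trait_table(path), "trait B")

  df2 <- as.data.frame(tbl)[, setdiff(names(tbl), "J")]
  expect_error(read_trait_table(records_csv(df2)), "missing column.*J")

  df3 <- as.data.frame(tbl)
  df3$species[2] <- df3$species[1]
  expect_error(read_trait_table(records_csv(df3)), "duplicate species")

  df4 <- as.data.frame(tbl)
  df4$E[3] <- ""
  expect_error(read_trait_table(records_csv(df4)), "missing trait values")
})

test_that("trait tables round-trip through CSV unchanged", {
  tbl <- random_table(25, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_trait_table(tbl, path)
  back <- read_trait_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("severity classes partition the 10% steps with closed moderate bounds", {
  expect_equal(classify_severity(20), "low")
  expect_equal(classify_severity(50), "moderate")
  expect_equal(classify_severity(80), "severe")
  expect_equal(classify_severity(c(30, 60)), c("moderate", "moderate"))
  steps <- seq(10, 100, 10)
  cls <- classify_severity(steps)
  expect_true(all(cls %in% c("low", "moderate", "severe")))
  expect_equal(length(cls), length(steps))       # exactly one class each
  expect_error(classify_severity(55), "multiple of 10")
  expect_error(classify_severity(0), "multiple of 10")
})

test_that("functional entities group identical signatures deterministically", {
  tbl <- make_table(list(c(A = "b"), c(A = "b"), c(A = "c")))
  fes <- build_functional_entities(tbl)
  expect_equal(nrow(fes$fe), 2)
  expect_setequal(fes$fe$n_species, c(2, 1))
  expect_equal(sort(unname(unlist(fes$members))), sort(tbl$species))

  distinct <- make_table(lapply(1:5, function(i) c(A = letters[i])))
  expect_equal(nrow(build_functional_entities(distinct)$fe), 5)

  # permutation invariance: shuffled rows give identical signatures/sizes
  tbl2 <- random_table(60, seed = 9)
  shuffled <- as_trait_table(as.data.frame(tbl2)[sample(60), ])
  f1 <- build_functional_entities(tbl2)
  f2 <- build_functional_entities(shuffled)
  expect_equal(f1$fe[, !(names(f1$fe) %in% "n_species")],
               f2$fe[, !(names(f2$fe) %in% "n_species")])
  expect_equal(f1$fe$n_species, f2$fe$n_species)
  expect_equal(lapply(f1$members, sort), lapply(f2$members, sort))
})

test_that("redundancy summary reports exact counts and full-precision means", {
  # sizes {12, 1, 1}: 12 + 2 singletons
  sigs <- c(lapply(1:12, function(i) c(A = "a")),
            list(c(A = "b"), c(A = "c")))
  fes <- build_functional_entities(make_table(sigs))
  rs <- summarize_redundancy(fes)
  expect_equal(rs$n_fes, 3)
  expect_equal(rs$max_species_per_fe, 12)
  expect_equal(rs$mean_species_per_fe, 14 / 3)
  expect_equal(rs$n_singletons, 2)

  singles <- build_functional_entities(
    make_table(lapply(1:4, function(i) c(D = letters[i]))))
  rs2 <- summarize_redundancy(singles)
  expect_equal(rs2$mean_species_per_fe, 1)
  expect_equal(rs2$singleton_share, 1)

  # invariant: singleton count + multi-FE sizes = species count
  tblr <- random_table(120, seed = 2)
  rsr <- summarize_redundancy(build_functional_entities(tblr))
  expect_equal(rsr$n_singletons +
                 sum(build_functional_entities(tblr)$fe$n_species[
                   build_functional_entities(tblr)$fe$n_species > 1]),
               rsr$n_species)
})

test_that("a single impacted member species marks its whole FE as impacted", {
  tbl <- make_table(list(c(A = "b"), c(A = "b"), c(A = "c")))
  fes <- build_functional_entities(tbl)
  rec <- make_records("sp_01", 80)          # one of the two species in its FE
  ids <- impacted_fe_ids(rec, fes)
  expect_equal(ids, unname(fes$species_fe["sp_01"]))
  expect_equal(length(ids), 1)

  expect_equal(impacted_fe_ids(make_records(character(0), numeric(0)), fes),
               character(0))
  all_rec <- make_records(tbl$species, 50)
  expect_setequal(impacted_fe_ids(all_rec, fes), fes$fe$fe_id)
  expect_error(impacted_fe_ids(make_records("ghost", 50), fes), "ghost")
})

test_that("mortality records parse, count unquantified rows and flag bad input", {
  rows <- data.frame(
    species = paste0("sp", 1:5), phylum = "Cnidaria", year = 2001:2005,
    longitude = c(3, 8, 15, 25, 30), latitude = 40,
    depth_range = "0-10 m", habitat = "reef",
    drivers = c("temperature anomaly", "disease",
                "temperature anomaly;disease", "storm;pollution",
                "disease;mucilage coverage"),
    percent_mortality = c("10", "40", "90", "", "100"),
    stringsAsFactors = FALSE
  )
  got <- read_mortality_records(records_csv(rows))
  expect_equal(nrow(got$records), 4)
  expect_equal(got$unquantified_count, 1)
  expect_equal(got$records$severity, c("low", "moderate", "severe", "severe"))
  expect_equal(got$records$driver_class[3], "abiotic-biotic combination")
  expect_equal(got$records$driver_class[4], "biotic combination")

  rows$percent_mortality[1] <- "55"
  expect_error(read_mortality_records(records_csv(rows)), "multiple of 10")

  rows$percent_mortality[1] <- "10"
  rows$drivers[2] <- "asteroid impact"
  expect_error(read_mortality_records(records_csv(rows)), "asteroid impact")
})

test_that("driver classes distinguish same-class and mixed combinations", {
  expect_equal(classify_driver(list("storm")), "storm")
  expect_equal(classify_driver(list(c("storm", "pollution"))),
               "abiotic combination")
  expect_equal(classify_driver(list(c("disease", "predator outbreak"))),
               "biotic combination")
  expect_equal(classify_driver(list(c("storm", "disease"))),
               "abiotic-biotic combination")
  expect_length(driver_classes(), 12)
})
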
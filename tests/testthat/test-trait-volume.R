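test_that("hull volumes are exact on known polytopes", {
  square <- as.matrix(expand.grid(x = 0:1, y = 0:1))
  expect_equal(hull_volume(square)$volume, 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(hull_volume(tri)$volume, 0.5)
  cube4 <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  expect_equal(hull_volume(cube4)$volume, 1)
  simplex4 <- rbind(0, diag(4))             # volume 1/4!
  expect_equal(hull_volume(simplex4)$volume, 1 / 24)

  # degenerate inputs: too few points, or affinely dependent
  expect_true(hull_volume(rbind(c(0, 0), c(1, 1)))$degenerate)
  flat <- cbind(runif(10), runif(10), 0.5)
  expect_true(hull_volume(flat)$degenerate)
  expect_error(hull_volume(rbind(c(0, NA), c(1, 1), c(0, 1))), "finite")
})

test_that("hull volume agrees with the Monte-Carlo rejection oracle", {
  set.seed(17)
  for (m in c(2, 4)) {
    pts <- matrix(runif(12 * m), 12, m)
    v <- hull_volume(pts)$volume
    vmc <- mc_hull_volume(pts, ndraw = 2e5, seed = m)
    expect_lt(abs(v - vmc) / vmc, 0.03)
  }
})

test_that("impacted fractions are normalized, monotone and handle degeneracy", {
  tbl <- random_table(40, seed = 10)
  fes <- build_functional_entities(tbl)
  space <- select_dimension(gower_distance(fes), 2:3)
  ids <- space$labels

  all_fr <- impacted_fraction(space, ids)
  expect_equal(all_fr$fraction, 1)
  none <- impacted_fraction(space, character(0))
  expect_equal(none$fraction, 0)
  expect_true(none$degenerate)

  m <- space$m_selected
  small <- impacted_fraction(space, ids[seq_len(m)])   # < m+1 points
  expect_true(small$degenerate)
  expect_equal(small$fraction, 0)

  # monotonicity: growing the impacted set never shrinks the volume
  set.seed(3)
  start <- sample(ids, m + 2)
  rest <- setdiff(ids, start)
  sets <- Reduce(function(acc, id) c(acc, id), rest[1:10],
                 accumulate = TRUE, init = start)
  fr <- impacted_fractions(space, sets)
  expect_true(all(diff(fr$fraction) >= -1e-12))
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))

  # interior subset scores strictly between 0 and 1
  interior <- fr$fraction[1]
  if (!fr$degenerate[1]) expect_gt(interior, 0)
  expect_lt(interior, 1)

  expect_error(impacted_fractions(space, list("FE_999")), "unknown fe_id")
})

test_that("record filters compose correctly", {
  rec <- make_records(paste0("s", 1:6), c(20, 50, 80, 90, 100, 30),
                      year = c(1990, 1995, 2000, 2005, 2010, 2015),
                      longitude = c(5, 5, 15, 15, 30, 30))
  expect_equal(nrow(subset_records(rec, min_percent = 90)), 2)
  expect_equal(nrow(subset_records(rec, min_percent = 100)), 1)  # >90% bin
  expect_equal(nrow(subset_records(rec, severity = "severe")), 3)
  expect_equal(nrow(subset_records(rec, region = "western")), 2)
  expect_equal(nrow(subset_records(rec, region = "eastern",
                                   years = c(2010, 2020))), 2)
  expect_equal(nrow(subset_records(rec, region = "western",
                                   years = c(2005, 2020))), 0)
  expect_error(subset_records(rec, years = c(2010, 2000)), "contradictory")
})

test_that("regions band by configured longitudes", {
  expect_equal(assign_region(c(5, 15, 30)), c("western", "central", "eastern"))
  expect_equal(assign_region(5, boundaries = c(2, 4)), "eastern")
  expect_error(assign_region(NaN), "non-finite")
})

test_that("balanced resampling is seed-stable and exact at full group size", {
  tbl <- random_table(50, seed = 20)
  fes <- build_functional_entities(tbl)
  space <- select_dimension(gower_distance(fes), 2:3)
  set.seed(99)
  rec <- make_records(sample(tbl$species, 120, replace = TRUE),
                      sample(seq(10, 100, 10), 120, replace = TRUE))

  # n = group size: every repetition sees the whole group
  rs_full <- resample_volume(rec, space, fes, n = nrow(rec), R = 5, seed = 1)
  expect_equal(rs_full$sd_fraction, 0)
  full_fr <- impacted_fraction(space, impacted_fe_ids(rec, fes))$fraction
  expect_equal(unique(rs_full$fractions), full_fr)

  # fixed seed reproduces the whole repetition vector
  rs1 <- resample_volume(rec, space, fes, n = 40, R = 25, seed = 7)
  rs2 <- resample_volume(rec, space, fes, n = 40, R = 25, seed = 7)
  expect_identical(rs1$fractions, rs2$fractions)
  expect_identical(rs1$n_fes, rs2$n_fes)
  expect_false(identical(
    rs1$fractions,
    resample_volume(rec, space, fes, n = 40, R = 25, seed = 8)$fractions))

  expect_error(resample_volume(rec[1:10, ], space, fes, n = 40, R = 2),
               "fewer than n")
})

test_that("regional resampling orders regions by their generating impact", {
  # western records drawn from many FEs, eastern from few: the resampled
  # impacted volume must rank west > east
  tbl <- random_table(60, seed = 30)
  fes <- build_functional_entities(tbl)
  space <- select_dimension(gower_distance(fes), 2:3)
  set.seed(41)
  west_sp <- sample(tbl$species, 40)
  east_sp <- sample(tbl$species, 8)
  rec <- rbind(
    make_records(sample(west_sp, 150, TRUE), 80, longitude = 5),
    make_records(sample(east_sp, 150, TRUE), 80, longitude = 30)
  )
  class(rec) <- c("mortality_records", "data.frame")
  rw <- resample_volume(subset_records(rec, region = "western"), space, fes,
                        n = 60, R = 40, seed = 2)
  re <- resample_volume(subset_records(rec, region = "eastern"), space, fes,
                        n = 60, R = 40, seed = 2)
  expect_gt(rw$mean_fraction, re$mean_fraction)
  expect_gt(rw$mean_n_fes, re$mean_n_fes)
})

test_that("driver-year heatmap covers the full grid and isolates cells", {
  tbl <- random_table(30, seed = 50)
  fes <- build_functional_entities(tbl)
  space <- select_dimension(gower_distance(fes), 2:3)
  rec <- make_records(tbl$species[1:10], 80, year = 1999,
                      drivers = "disease")
  hm <- driver_year_heatmap(rec, space, fes, years = 1986:2020)
  expect_equal(nrow(hm), 12 * 35)
  nz <- hm[hm$n_records > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$driver_class, "disease")
  expect_equal(nz$year, 1999)
  expect_true(all(hm$fraction[hm$n_records == 0] == 0))
})

test_that("decade and five-year summaries average calendar windows", {
  annual <- data.frame(year = 1986:1995, fraction = 0.1,
                       n_fes_impacted = 5)
  ds <- decade_summary(annual, window = 10)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$mean_fraction, 0.1)

  one <- data.frame(year = 1986:1995, fraction = c(0.4, rep(0, 9)),
                    n_fes_impacted = c(8, rep(0, 9)))
  expect_equal(decade_summary(one, window = 10)$mean_fraction, 0.04)

  # activity concentrated late in the decade: its 5-year mean exceeds the
  # decade mean
  late <- data.frame(year = 1986:1995,
                     fraction = c(rep(0, 5), rep(0.2, 5)),
                     n_fes_impacted = c(rep(0, 5), rep(4, 5)))
  d10 <- decade_summary(late, window = 10)
  d5 <- decade_summary(late, window = 5)
  expect_gte(max(d5$mean_fraction), d10$mean_fraction)
  expect_equal(d5$window_start, c(1986, 1991))
  expect_error(decade_summary(late[0, ]), "empty")
})
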
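test_that("survey tables read with typed columns and integrity checks", {
  fx <- write_survey_fixture()
  tabs <- read_survey_tables(fx$haul_path, fx$catch_path)
  expect_equal(nrow(tabs$hauls), 2L)
  expect_equal(nrow(tabs$catch), 3L)
  expect_type(tabs$hauls$depth_m, "double")

  # orphan catch row names the offending haul
  bad <- fx$catch
  bad$haul_id[1] <- "H99"
  bp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, bp, row.names = FALSE)
  expect_error(read_survey_tables(fx$haul_path, bp), "H99")

  # empty catch with header is fine
  ep <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$catch[0, ], ep, row.names = FALSE)
  empty <- read_survey_tables(fx$haul_path, ep)
  expect_equal(nrow(empty$catch), 0L)

  # missing column is fatal and names it
  mp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$hauls[, -4], mp, row.names = FALSE)
  expect_error(read_survey_tables(mp, fx$catch_path), "depth_m")
  expect_error(read_survey_tables("nope.csv", fx$catch_path), "not found")
})

make_hauls <- function(depths, rect = "R1") {
  tibble::tibble(
    haul_id = sprintf("H%02d", seq_along(depths)), year = 2000L,
    ices_rectangle = rect, depth_m = depths, duration_min = 120)
}

test_that("station pooling follows the complete-linkage 100 m rule", {
  s <- pool_stations(make_hauls(c(400, 450)))
  expect_equal(nrow(s), 1L)
  expect_equal(s$depth_m, 425)

  s2 <- pool_stations(make_hauls(c(400, 520)))
  expect_equal(nrow(s2), 2L)

  # 400 and 560 violate the pairwise bound: {400, 480} + {560}
  s3 <- pool_stations(make_hauls(c(400, 480, 560)))
  expect_equal(nrow(s3), 2L)
  expect_equal(sort(s3$depth_m), c(440, 560))
  expect_equal(s3$n_hauls[order(s3$depth_m)], c(2L, 1L))

  # hauls in different rectangles never pool
  h <- dplyr::bind_rows(make_hauls(400, "R1"), make_hauls(410, "R2"))
  h$haul_id <- c("Ha", "Hb")
  expect_equal(nrow(pool_stations(h)), 2L)
  expect_error(pool_stations(make_hauls(400), depth_tol_m = -5), "positive")
})

test_that("complete-linkage pooling is the unique maximal valid partition of 3 hauls", {
  # brute-force oracle: enumerate all 5 partitions of three hauls, keep those
  # whose blocks satisfy the pairwise <= 100 m constraint, and pick the one
  # with fewest blocks
  depths <- c(400, 480, 560)
  partitions <- list(
    list(1, 2, 3), list(c(1, 2), 3), list(c(1, 3), 2), list(c(2, 3), 1),
    list(c(1, 2, 3)))
  valid <- Filter(function(pt) all(vapply(pt, function(b)
    diff(range(depths[b])) <= 100, logical(1))), partitions)
  best <- valid[[which.min(lengths(valid))]]
  oracle <- lapply(best, function(b) sort(depths[b]))

  s <- pool_stations(make_hauls(depths))
  got <- lapply(station_members(s) |>
                  dplyr::left_join(make_hauls(depths), by = "haul_id") |>
                  dplyr::group_by(station_id) |>
                  dplyr::group_split(), function(df) sort(df$depth_m))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle, paste, collapse = ","))
})

test_that("pooling invariants hold on random haul sets", {
  set.seed(77)
  for (rep in 1:10) {
    h <- tibble::tibble(
      haul_id = sprintf("H%03d", 1:40), year = 2000L,
      ices_rectangle = sample(c("R1", "R2", "R3"), 40, replace = TRUE),
      depth_m = runif(40, 300, 2000), duration_min = 120)
    s <- pool_stations(h)
    mem <- station_members(s) |> dplyr::left_join(h, by = "haul_id")
    # union of stations is the input; no haul assigned twice
    expect_setequal(mem$haul_id, h$haul_id)
    expect_equal(anyDuplicated(mem$haul_id), 0L)
    by_st <- split(mem, mem$station_id)
    for (st in by_st) {
      expect_lte(diff(range(st$depth_m)), 100)
      expect_equal(length(unique(st$ices_rectangle)), 1L)
      expect_equal(s$depth_m[s$station_id == st$station_id[1]],
                   mean(st$depth_m))
    }
  }
})

test_that("conversion factors are means of per-pair ratios", {
  p <- tibble::tibble(species_id = "sp", length_type = "SL",
                      alt_length = c(50, 100), tl = c(55, 130))
  f <- estimate_length_conversion(p)
  expect_equal(f$factor, mean(c(1.1, 1.3)))  # 1.2: mean of ratios
  expect_equal(f$n_pairs, 2L)
  expect_equal(f$provenance, "survey")

  one <- estimate_length_conversion(
    tibble::tibble(species_id = "sp", length_type = "SL",
                   alt_length = 50, tl = 60))
  expect_equal(one$factor, 1.2)
  expect_error(estimate_length_conversion(
    tibble::tibble(species_id = "s", length_type = "SL",
                   alt_length = -1, tl = 2)), "positive")
})

test_that("length standardization walks the fallback chain", {
  catch <- tibble::tibble(
    haul_id = "H1",
    species_id = c("a", "b", "c", "d"),
    length_value = c(80, 50, 30, 40),
    length_type = c("TL", "SL", "PAFL", "PSCFL"))
  factors <- tibble::tibble(species_id = "b", length_type = "SL",
                            factor = 1.2, n_pairs = 5, provenance = "survey")
  refs <- tibble::tibble(species_id = "c", length_type = "PAFL",
                         factor = 2.5, n_pairs = NA, provenance = "reference")
  out <- standardize_total_length(catch, factors, refs, pooled_average = 1.5)
  expect_equal(out$tl_cm, c(80, 60, 75, 60))

  # with no pooled average supplied, it defaults to the mean of all known
  # factors (the cross-species average)
  out2 <- standardize_total_length(catch, factors, refs)
  expect_equal(out2$tl_cm[4], 40 * mean(c(1.2, 2.5)))

  # exhausting the chain entirely drops the row with a message
  expect_message(out3 <- standardize_total_length(catch[4, ]),
                 "no conversion factor")
  expect_equal(nrow(out3), 0L)
})

test_that("length-weight fit recovers exact and noisy allometries", {
  exact <- tibble::tibble(tl_cm = c(10, 20, 40, 80),
                          weight_g = 0.01 * c(10, 20, 40, 80)^3)
  fit <- estimate_length_weight(exact)
  expect_equal(fit$lw_a, 0.01, tolerance = 1e-10)
  expect_equal(fit$lw_b, 3, tolerance = 1e-10)

  # two points determine the line exactly
  two <- estimate_length_weight(exact[c(1, 4), ])
  expect_equal(two$lw_b, 3, tolerance = 1e-10)

  set.seed(11)
  tl <- runif(500, 10, 120)
  noisy <- tibble::tibble(tl_cm = tl,
                          weight_g = 0.008 * tl^3.1 * exp(rnorm(500, 0, 0.2)))
  nf <- estimate_length_weight(noisy)
  expect_lt(abs(nf$lw_b - 3.1), 0.05)

  expect_error(estimate_length_weight(
    tibble::tibble(tl_cm = c(5, 5, 5), weight_g = c(1, 2, 3))), "Degenerate")
})

test_that("station CPUE time-averages biomass per hour over member hauls", {
  hauls <- make_hauls(c(400, 450))
  stations <- pool_stations(hauls)
  lw <- tibble::tibble(species_id = "sp", lw_a = 2000 / 50^3, lw_b = 3)
  catch <- tibble::tibble(haul_id = c("H01", "H02", "H02"),
                          species_id = "sp",
                          length_value = c(50, 50, 50), length_type = "TL",
                          tl_cm = c(50, 50, 50))
  sc <- station_cpue(stations, hauls, catch, lw)
  # haul 1: one 2 kg fish in 2 h -> 1 kg/h; haul 2: two fish -> 2 kg/h
  expect_equal(sc$cpue$cpue_kg_per_h, mean(c(1, 2)))
  expect_equal(nrow(sc$individuals), 3L)

  # an empty station keeps a zero-CPUE row
  h2 <- make_hauls(c(400, 900)); h2$haul_id <- c("H01", "H02")
  st2 <- pool_stations(h2)
  sc2 <- station_cpue(st2, h2, catch[1, ], lw)
  expect_equal(nrow(sc2$cpue), 2L)
  empty_val <- sc2$cpue$cpue_kg_per_h[is.na(sc2$cpue$species_id)]
  expect_equal(empty_val, 0)
})

test_that("no biomass is created or destroyed by station pooling", {
  set.seed(42)
  pool <- generate_species_pool(n_species = 8, seed = 9)
  sim <- simulate_survey(pool, depth_grid = seq(500, 1500, length.out = 10),
                         seed = 10)
  factors <- dplyr::distinct(pool[pool$length_type != "TL", ],
                             species_id, length_type, factor = conv_factor)
  tl <- standardize_total_length(sim$catch, factors)
  stations <- pool_stations(sim$hauls)
  sc <- station_cpue(stations, sim$hauls, tl,
                     pool[, c("species_id", "lw_a", "lw_b")])
  # station total CPUE equals the mean over member hauls of per-haul totals
  per_haul <- sc$individuals |>
    dplyr::left_join(sim$hauls[, c("haul_id", "duration_min")], by = "haul_id") |>
    dplyr::group_by(station_id, haul_id) |>
    dplyr::summarise(tot = sum(weight_g) / 1000 / (first(duration_min) / 60),
                     .groups = "drop") |>
    dplyr::right_join(station_members(stations), by = c("station_id", "haul_id")) |>
    dplyr::mutate(tot = dplyr::coalesce(tot, 0)) |>
    dplyr::group_by(station_id) |>
    dplyr::summarise(mean_tot = mean(tot), .groups = "drop")
  st_tot <- sc$cpue |>
    dplyr::group_by(station_id) |>
    dplyr::summarise(tot = sum(cpue_kg_per_h), .groups = "drop")
  m <- dplyr::inner_join(per_haul, st_tot, by = "station_id")
  expect_equal(m$mean_tot, m$tot, tolerance = 1e-12)
  expect_true(all(sc$cpue$cpue_kg_per_h >= 0))
})

test_that("L_max resolution applies convert-then-max and the genus fallback", {
  catch <- tibble::tibble(
    species_id = c("a", "a", "b", "c"),
    tl_cm = c(120, 125, 110, 85))
  species <- tibble::tibble(
    species_id = c("a", "b", "d"),
    genus = c("g1", "g2", "g3"),
    ref_length = c(120, 100, NA), ref_type = c("TL", "SL", NA))
  factors <- tibble::tibble(species_id = "b", length_type = "SL",
                            factor = 1.2, n_pairs = 3, provenance = "survey")
  # d shares its genus with c via the genus column of the species table
  species$genus[3] <- "g3"
  catch_d <- dplyr::bind_rows(catch,
                              tibble::tibble(species_id = "e", tl_cm = 85))
  species_d <- dplyr::bind_rows(
    species[1:2, ],
    tibble::tibble(species_id = c("d", "e"), genus = "g3",
                   ref_length = c(NA, NA), ref_type = c(NA, NA)))
  out <- resolve_lmax(species_d, catch_d, factors)
  expect_equal(out$lmax_cm[out$species_id == "a"], 125)  # survey beats ref
  expect_equal(out$lmax_cm[out$species_id == "b"], 120)  # SL 100 * 1.2
  expect_equal(out$lmax_source[out$species_id == "b"], "reference")
  # d: no reference, never caught -> largest congener (e at 85)
  expect_equal(out$lmax_cm[out$species_id == "d"], 85)
  expect_equal(out$lmax_source[out$species_id == "d"], "genus")

  lonely <- tibble::tibble(species_id = "z", genus = "gz",
                           ref_length = NA_real_, ref_type = NA_character_)
  expect_error(resolve_lmax(lonely, catch, factors), "z")
})
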
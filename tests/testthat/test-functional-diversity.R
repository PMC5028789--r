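test_that("Gower dissimilarity reproduces hand-evaluated sums", {
  tr <- tibble::tibble(
    species_id = c("a", "b"),
    rel_head = c(0.2, 0.2), aspect_ratio = c(1, 1), rel_eye = c(0.05, 0.05),
    eye_position = c("Side", "Top"), mouth_angle = c(30, 30),
    rel_sam = c(0.1, 0.1), rel_gape = c(10, 10), lmax_cm = c(100, 100))
  # identical on 7 traits, categorical mismatch on 1 -> 1/8
  D <- gower_matrix(tr)
  expect_equal(D["a", "b"], 1 / 8)
  expect_equal(diag(D), c(a = 0, b = 0))

  # extremes of every continuous trait, same category -> 7/8
  tr2 <- tibble::tibble(
    species_id = c("s1", "s2"),
    rel_head = c(0.1, 0.3), aspect_ratio = c(1, 5), rel_eye = c(0.01, 0.11),
    eye_position = c("Side", "Side"), mouth_angle = c(10, 50),
    rel_sam = c(0, 1), rel_gape = c(5, 100), lmax_cm = c(30, 150))
  expect_equal(gower_matrix(tr2)["s1", "s2"], 7 / 8)

  # identical rows -> 0
  tr3 <- tr; tr3$eye_position <- c("Side", "Side")
  expect_equal(gower_matrix(tr3)["a", "b"], 0)

  # no shared observed trait -> error naming the pair
  tr4 <- tibble::tibble(
    species_id = c("a", "b"),
    rel_head = c(0.2, NA), aspect_ratio = c(NA, 1), rel_eye = c(NA, NA),
    eye_position = c(NA, NA), mouth_angle = c(NA, NA), rel_sam = c(NA, NA),
    rel_gape = c(NA, NA), lmax_cm = c(NA, NA))
  expect_error(gower_matrix(tr4), "a / b")
})

test_that("Gower matches the established mixed-type implementation", {
  skip_if_not_installed("cluster")
  tr <- load_reference_traits()
  D <- gower_matrix(tr)
  df <- as.data.frame(tr[, trait_columns()])
  df$eye_position <- factor(df$eye_position)
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(D), unname(ref), tolerance = 1e-10)
})

test_that("Gower is invariant to affine rescaling of continuous traits", {
  tr <- load_reference_traits()
  D <- gower_matrix(tr)
  tr2 <- tr
  tr2$rel_gape <- 100 + 3 * tr2$rel_gape
  tr2$lmax_cm <- tr2$lmax_cm / 7
  expect_equal(gower_matrix(tr2), D, tolerance = 1e-12)
})

test_that("principal coordinates embedding reproduces classical scaling", {
  # three collinear points with distances 1, 1, 2 -> one axis, spacing 0,1,2
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  sp <- pcoa_embed(D)
  expect_equal(sp$m, 1L)
  x <- unname(sort(sp$coordinates[, 1]))
  expect_equal(x - x[1], c(0, 1, 2), tolerance = 1e-9)

  # round trip: distances of the embedding reproduce a Euclidean input
  p <- euclid_config()
  DE <- as.matrix(dist(p))
  spE <- pcoa_embed(DE)
  back <- as.matrix(dist(spE$coordinates))
  expect_equal(back, DE, tolerance = 1e-8, ignore_attr = TRUE)

  # agreement with the base classical-scaling implementation
  cm <- stats::cmdscale(DE, k = spE$m)
  expect_equal(abs(spE$coordinates), abs(cm), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(pcoa_embed(matrix(0, 3, 3)), "[Dd]egenerate")
  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("hull volumes are exact on known polytopes", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull(sq)$volume, 1)
  expect_equal(convex_hull(rbind(c(0, 0), c(1, 0), c(0, 1)))$volume, 0.5)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull(cube)$volume, 1)
  simplex4 <- rbind(rep(0, 4), diag(4))
  expect_equal(convex_hull(simplex4)$volume, 1 / 24)
  octa <- rbind(diag(3), -diag(3))
  expect_equal(convex_hull(octa)$volume, 4 / 3)
  # degenerate: coplanar points in 3 dimensions
  flat <- cbind(matrix(rnorm(12), 6, 2), 0)
  h <- convex_hull(flat)
  expect_equal(h$volume, 0)
  expect_true(h$degenerate)
})

test_that("hull volume matches the rejection-sampling oracle", {
  set.seed(31)
  for (d in 2:4) {
    pts <- matrix(rnorm(15 * d), 15, d)
    mine <- convex_hull(pts)$volume
    orac <- rejection_volume(pts, n_samples = c(1e6, 4e6, 8e6)[d - 1],
                             seed = d)
    expect_lt(abs(mine - orac) / orac, 0.01)
  }
})

test_that("interior points are not hull vertices", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1), c(0, 0))
  h <- convex_hull(sq)
  expect_setequal(h$vertices, 1:4)
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)), c(0.5, 0.5, 0.5))
  expect_setequal(convex_hull(cube)$vertices, 1:8)
})

test_that("functional richness grows monotonically as species are added", {
  tr <- load_reference_traits()
  space <- pcoa_embed(gower_matrix(tr), max_axes = 3)
  set.seed(8)
  ids <- sample(tr$species_id)
  vols <- vapply(5:15, function(k)
    functional_richness(space, ids[1:k], axes = 3), numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  # too few species for the dimensionality -> missing
  expect_true(is.na(functional_richness(space, ids[1:3], axes = 3)))
})

test_that("functional divergence obeys its forced cases", {
  # equilateral triangle: all species equidistant from the vertex centroid
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  tri <- cbind(cos(ang), sin(ang))
  rownames(tri) <- c("a", "b", "c")
  space <- structure(list(species_ids = rownames(tri), coordinates = tri,
                          eigenvalues = c(1, 1), m = 2L),
                     class = "trait_space")
  for (w in list(c(1, 1, 1), c(5, 1, 0.2), c(0.01, 1, 10))) {
    expect_equal(functional_divergence(space, weights = w), 1)
  }

  # square plus centre, all weight on the centre -> 0
  pts <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1), c(0, 0))
  rownames(pts) <- letters[1:5]
  sp2 <- structure(list(species_ids = rownames(pts), coordinates = pts,
                        eigenvalues = c(1, 1), m = 2L),
                   class = "trait_space")
  expect_equal(functional_divergence(sp2, weights = c(0, 0, 0, 0, 1)), 0)

  # moving weight from the centre to a vertex strictly increases fdiv
  fr <- vapply(seq(0, 1, by = 0.1), function(a)
    functional_divergence(sp2, weights = c(a, 0, 0, 0, 1 - a)), numeric(1))
  expect_true(all(diff(fr) > 0))

  # invariant to rescaling all weights
  expect_equal(functional_divergence(sp2, weights = c(2, 1, 1, 1, 3)),
               functional_divergence(sp2, weights = 10 * c(2, 1, 1, 1, 3)))
})

test_that("fdiv stays within [0, 1] on random configurations", {
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    d <- sample(2:3, 1)
    pts <- matrix(rnorm(n * d), n, d)
    rownames(pts) <- paste0("s", 1:n)
    sp <- structure(list(species_ids = rownames(pts), coordinates = pts,
                         eigenvalues = rep(1, d), m = as.integer(d)),
                    class = "trait_space")
    f <- functional_divergence(sp, weights = runif(n))
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("station-level functional diversity is deterministic and normalized", {
  tr <- toy_traits()
  cpue <- tibble::tibble(
    station_id = rep(c("st1", "st2", "st3"), each = 4),
    species_id = rep(tr$species_id, 3),
    cpue_kg_per_h = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 5, 1, 0.5))
  res <- assemblage_fd(tr, cpue, max_axes = 2)
  # a station holding the full pool has normalized richness 1
  expect_equal(res$fric_norm, rep(1, 3), tolerance = 1e-9)
  # identical stations give identical results
  expect_equal(res$fdiv[1], res$fdiv[2])
  expect_true(all(res$s_used == 4))

  # stations below the species floor get missing metrics, with a message
  cpue2 <- dplyr::bind_rows(
    cpue, tibble::tibble(station_id = "st4", species_id = c("s1", "s2"),
                         cpue_kg_per_h = c(1, 1)))
  expect_message(res2 <- assemblage_fd(tr, cpue2, max_axes = 2),
                 "fewer than")
  expect_true(is.na(res2$fric_raw[res2$station_id == "st4"]))
})
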
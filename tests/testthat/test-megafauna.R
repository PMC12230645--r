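test_that("rasterize_range applies the cell-center rule", {
  g <- wl_grid(4, 4, cell_size = 1)
  # rectangle covering exactly the 4 centers of the top-left 2x2 block
  rect <- cbind(c(0.2, 2.2, 2.2, 0.2), c(0.2, 0.2, 2.2, 2.2))
  r <- rasterize_range(rect, g, "sp1")
  expect_equal(sum(r$presence), 4)
  expect_true(all(r$presence[1:2, 1:2]))
  # whole-grid polygon saturates
  whole <- cbind(c(-1, 5, 5, -1), c(-1, -1, 5, 5))
  expect_true(all(rasterize_range(whole, g, "sp2")$presence))
  # empty intersection names the species
  far <- cbind(c(100, 101, 101, 100), c(100, 100, 101, 101))
  expect_error(rasterize_range(far, g, "ghost"), "ghost")
})

test_that("polygon rasterization matches a half-plane oracle on convex polygons", {
  g <- wl_grid(10, 10, cell_size = 1)
  ctr <- grid_centers(g)
  set.seed(31)
  for (rep in 1:5) {
    # random convex polygon: points sorted by angle around their centroid
    k <- sample(3:7, 1)
    px <- runif(k, 0, 10); py <- runif(k, 0, 10)
    hull <- grDevices::chull(px, py)
    poly <- cbind(px[hull], py[hull])
    r <- try(rasterize_range(poly, g, "x"), silent = TRUE)
    inside_hp <- function(x, y) {
      n <- nrow(poly); ok <- TRUE
      for (i in seq_len(n)) {
        j <- i %% n + 1
        cr <- (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) -
              (poly[j, 2] - poly[i, 2]) * (x - poly[i, 1])
        ok <- ok && cr <= 1e-12  # chull returns clockwise order
      }
      ok
    }
    oracle <- outer(seq_len(g$n_rows), seq_len(g$n_cols),
                    Vectorize(function(rr, cc) inside_hp(ctr$x[cc], ctr$y[rr])))
    if (inherits(r, "try-error")) expect_false(any(oracle))
    else expect_equal(r$presence, oracle)
  }
})

test_that("fine-mask rasterization supports center and any-overlap rules", {
  fine <- wl_grid(8, 8, cell_size = 0.5)
  coarse <- wl_grid(4, 4, cell_size = 1)
  pv <- matrix(FALSE, 8, 8)
  pv[1, 2] <- TRUE  # off-center fine cell inside coarse cell (1,1)
  bm <- binary_map(fine, pv)
  any_r <- rasterize_range(bm, coarse, "sp", rule = "any_overlap")
  expect_true(any_r$presence[1, 1])
  expect_equal(sum(any_r$presence), 1)
  cen_r <- rasterize_range(binary_map(fine, matrix(TRUE, 8, 8)), coarse, "sp")
  expect_true(all(cen_r$presence))
})

test_that("richness sums presence maps and splits by threat group", {
  g <- wl_grid(3, 3)
  p1 <- matrix(FALSE, 3, 3); p1[1, ] <- TRUE
  p2 <- matrix(FALSE, 3, 3); p2[3, ] <- TRUE
  r1 <- species_range("t1", p1, TRUE, g)
  r2 <- species_range("n1", p2, FALSE, g)
  expect_equal(richness(list(r1), "all")$values, p1 * 1L, ignore_attr = TRUE)
  expect_equal(max(richness(list(r1, r2), "all")$values), 1)  # disjoint
  # 14 random masks vs elementwise sum oracle + group additivity
  set.seed(44)
  rs <- lapply(1:14, function(i)
    species_range(paste0("s", i),
                  matrix(runif(9) > 0.5, 3, 3) | diag(3) > 0, i <= 7, g))
  rall <- richness(rs, "all"); rthr <- richness(rs, "threatened")
  rnon <- richness(rs, "non_threatened")
  oracle <- Reduce(`+`, lapply(rs, function(r) r$presence * 1L))
  expect_equal(rall$values, oracle, ignore_attr = TRUE)
  expect_equal(rall$values, rthr$values + rnon$values)
  expect_error(species_range("none", matrix(FALSE, 3, 3), TRUE, g), "presence")
})

test_that("richness-cover correlation matches the textbook formula", {
  g <- wl_grid(2, 2)
  cov <- cover_map(g, matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2))
  rich <- structure(list(grid = g, values = matrix(c(4L, 3L, 2L, 1L), 2, 2),
                         group = "all", n_species = 4), class = "wl_richness")
  res <- richness_cover_correlation(rich, cov)
  expect_equal(res$r, -1)
  richp <- rich; richp$values <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  expect_equal(richness_cover_correlation(richp, cov)$r, 1)
  # 50 random pairs against the direct formula, to 1e-12
  set.seed(50)
  gg <- wl_grid(5, 10)
  x <- matrix(runif(50), 5, 10)
  y <- matrix(rpois(50, 4), 5, 10)
  rr <- structure(list(grid = gg, values = y, group = "all", n_species = 14),
                  class = "wl_richness")
  got <- richness_cover_correlation(rr, cover_map(gg, x))
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  # order invariance: permuting cells leaves r unchanged
  perm <- sample(50)
  rp <- structure(list(grid = gg, values = matrix(y[perm], 5, 10), group = "all",
                       n_species = 14), class = "wl_richness")
  got2 <- richness_cover_correlation(rp, cover_map(gg, matrix(x[perm], 5, 10)))
  expect_equal(got2$r, got$r, tolerance = 1e-12)
  # zero variance is an explicit error, not r = 0
  flat <- structure(list(grid = gg, values = matrix(2L, 5, 10), group = "all",
                         n_species = 14), class = "wl_richness")
  expect_error(richness_cover_correlation(flat, cover_map(gg, x)), "variance")
})

test_that("range trajectories and archetype composition match masked oracles", {
  g <- wl_grid(4, 4)
  set.seed(13)
  mats <- replicate(3, matrix(runif(16, 0.1, 0.9), 4, 4), simplify = FALSE)
  s <- mk_series(mats, 2000:2002)
  pres <- matrix(runif(16) > 0.5, 4, 4); pres[1, 1] <- TRUE
  r <- species_range("sp", pres, TRUE, g)
  tr <- range_cover_trajectory(r, s)
  for (i in 1:3)
    expect_equal(tr$mean_cover[i], mean(mats[[i]][pres]))
  # uniform cover -> constant trajectory; single cell -> that cell's series
  su <- mk_series(list(matrix(0.7, 4, 4), matrix(0.7, 4, 4)), c(2000, 2020))
  expect_true(all(range_cover_trajectory(r, su)$mean_cover == 0.7))
  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  r1 <- species_range("solo", one, FALSE, g)
  expect_equal(range_cover_trajectory(r1, s)$mean_cover,
               vapply(mats, function(m) m[2, 3], numeric(1)))
  # composition: containment, symmetry, and a counting oracle
  lab <- matrix(rep(1:2, each = 8), 4, 4)
  whole <- species_range("w", matrix(TRUE, 4, 4), TRUE, g)
  comp <- archetype_composition(whole, lab)
  expect_equal(comp$share, c(0.5, 0.5))
  in1 <- species_range("a", lab == 1, TRUE, g)
  expect_equal(archetype_composition(in1, lab)$share, c(1, 0))
  rc <- archetype_composition(r, lab)
  expect_equal(sum(rc$share), 1, tolerance = 1e-12)
  expect_equal(rc$n_cells,
               c(sum(pres & lab == 1), sum(pres & lab == 2)))
})

test_that("median richness per archetype uses sort-and-pick semantics", {
  g <- wl_grid(3, 3)
  rich <- structure(list(grid = g, values = matrix(3L, 3, 3), group = "all",
                         n_species = 5), class = "wl_richness")
  lab <- matrix(c(1, 1, 1, 2, 2, 2, 2, 2, 2), 3, 3)
  med <- median_richness_per_archetype(rich, lab)
  expect_true(all(med$median_richness == 3))
  rich2 <- rich; rich2$values <- matrix(c(1L, 2L, 9L, 5L, 5L, 5L, 5L, 5L, 4L), 3, 3)
  med2 <- median_richness_per_archetype(rich2, lab)
  expect_equal(med2$median_richness[med2$archetype == 1], 2)  # odd-count median
  # empty archetypes are reported as NA, and even counts use the midpoint
  lab3 <- matrix(c(1, 1, 3, 3, 3, 3, 3, 3, 3), 3, 3)
  rich3 <- rich; rich3$values <- matrix(c(1L, 4L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 3, 3)
  med3 <- median_richness_per_archetype(rich3, lab3)
  expect_equal(med3$median_richness[med3$archetype == 1], 2.5)
  set.seed(3)
  labs <- matrix(sample(1:3, 9, replace = TRUE), 3, 3)
  rv <- matrix(sample(0:9, 9, replace = TRUE), 3, 3)
  richr <- rich; richr$values <- rv
  medr <- median_richness_per_archetype(richr, labs)
  for (a in sort(unique(as.vector(labs)))) {
    xs <- sort(rv[labs == a]); n <- length(xs)
    want <- if (n %% 2) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(medr$median_richness[medr$archetype == a], want)
  }
})
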
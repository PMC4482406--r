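test_that("dB differences are pairwise-consistent arithmetic", {
  expect_equal(unname(db_differences(-80, -80, -80)[1, ]), c(0, 0, 0))
  expect_equal(unname(db_differences(-80, -78, -82)[1, ]), c(2, -2, -4))
  set.seed(2)
  d <- db_differences(rnorm(50, -80, 5), rnorm(50, -80, 5),
                      rnorm(50, -80, 5))
  expect_equal(d[, "d460_125"], d[, "d200_125"] + d[, "d460_200"])
})

test_that("aggregations classify to the nearest signature with an unknown cutoff", {
  sig <- cached_signatures()
  lg <- unlist(sig[sig$category == "LgCrust", c("d200_125", "d460_125",
                                                "d460_200")])
  expect_equal(classify_aggregation(lg, sig), "LgCrust")
  far <- lg + c(50, 100, 50)
  expect_equal(classify_aggregation(far, sig), "Unclass")
  expect_true(is.na(classify_aggregation(c(NA, 1, 1), sig)))
  # exact tie between two signatures resolves to the smaller size class
  a <- unlist(sig[1, c("d200_125", "d460_125", "d460_200")])
  b <- unlist(sig[2, c("d200_125", "d460_125", "d460_200")])
  mid <- (a + b) / 2
  if (sqrt(sum((mid - a)^2)) <= 12)
    expect_equal(classify_aggregation(mid, sig), sig$category[1])
  # determinism over a grid of triples
  grid <- expand.grid(d1 = seq(-5, 25, by = 5), d3 = seq(-25, 15, by = 5))
  lab1 <- apply(grid, 1, function(r)
    classify_aggregation(c(r[1], r[1] + r[2], r[2]), sig))
  lab2 <- apply(grid, 1, function(r)
    classify_aggregation(c(r[1], r[1] + r[2], r[2]), sig))
  expect_identical(lab1, lab2)
})

test_that("classification is invariant to a constant dB offset on all frequencies", {
  sig <- cached_signatures()
  set.seed(8)
  grid <- data.frame(julian_day = rep(1:10, each = 4),
                     bin_top_m = rep(c(2, 7, 12, 17), 10),
                     sv125 = rnorm(40, -80, 6))
  grid$sv200 <- grid$sv125 + rnorm(40, 3, 4)
  grid$sv460 <- grid$sv125 + rnorm(40, 8, 6)
  c0 <- composition_series(grid, sig)
  g2 <- grid
  g2[c("sv125", "sv200", "sv460")] <- g2[c("sv125", "sv200", "sv460")] + 17.3
  c1 <- composition_series(g2, sig)
  for (cc in c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson",
               "Unclass"))
    expect_equal(c1[[cc]], c0[[cc]], tolerance = 1e-9)
})

test_that("composition shares are exhaustive and respect the unknown threshold monotonically", {
  sig <- cached_signatures()
  set.seed(9)
  grid <- data.frame(julian_day = rep(1:15, each = 6),
                     bin_top_m = rep(seq(2, 27, by = 5), 15),
                     sv125 = rnorm(90, -80, 8))
  grid$sv200 <- grid$sv125 + rnorm(90, 4, 6)
  grid$sv460 <- grid$sv125 + rnorm(90, 6, 8)
  comp <- composition_series(grid, sig)
  cats <- c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson", "Unclass")
  expect_equal(rowSums(comp[cats]), rep(100, nrow(comp)), tolerance = 0.01)
  expect_true(all(as.matrix(comp[cats]) >= 0))
  loose <- composition_series(grid, sig, unknown_threshold = 20)
  expect_true(all(loose$Unclass <= comp$Unclass + 1e-9))
})

test_that("single-class days and equal splits come out exactly", {
  sig <- cached_signatures()
  md <- sig[sig$category == "MdCrust", ]
  one <- data.frame(julian_day = 1, bin_top_m = 2, sv125 = md$ts125,
                    sv200 = md$ts200, sv460 = md$ts460)
  c1 <- composition_series(one, sig)
  expect_equal(c1$MdCrust, 100)
  lg <- sig[sig$category == "LgCrust", ]
  two <- rbind(one, data.frame(julian_day = 1, bin_top_m = 7,
                               sv125 = lg$ts125 + (md$ts200 - lg$ts200),
                               sv200 = md$ts200,
                               sv460 = lg$ts460 + (md$ts200 - lg$ts200)))
  c2 <- composition_series(two, sig)
  expect_equal(c2$MdCrust, 50)
  expect_equal(c2$LgCrust, 50)
})

test_that("noise-free forward-modelled grids classify with 100% accuracy", {
  sig <- cached_signatures()
  cfg <- synthetic_year_config(seed = 12, acoustics = list(noise_db = 0))
  b <- generate_year(cfg, sig)
  comp <- composition_series(b$echo, sig)
  tr <- b$truth$composition
  mm <- merge(comp, tr, by = "julian_day", suffixes = c("", ".t"))
  for (cc in c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson",
               "Unclass"))
    expect_equal(mm[[cc]], mm[[paste0(cc, ".t")]], tolerance = 1e-9)
})
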
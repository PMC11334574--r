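test_that("count sampling respects bounds and the degenerate range", {
  cfg0 <- synth_config("grain_scatter", count = list(min = 0, max = 0))
  set.seed(1)
  expect_identical(sample_count(cfg0, 5L), rep(0L, 5L))

  cfg <- synth_config("grain_scatter",
                      count = list(mean = 40, sd = 10, min = 11, max = 68))
  set.seed(2)
  draws <- sample_count(cfg, 10000L)
  expect_true(all(draws >= 11L & draws <= 68L))
  expect_true(is.integer(draws))

  expect_error(synth_config("ear_field", count = list(min = 5, max = 1)),
               "min exceeds max")
})

test_that("empirical count mean matches the clipped-Gaussian analytic mean", {
  cfg <- synth_config("grain_scatter",
                      count = list(mean = 40, sd = 10, min = 11, max = 68))
  set.seed(3)
  draws <- sample_count(cfg, 10000L)
  mu <- oracle_clipped_mean(40, 10, 11, 68)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("rendering is a pure function of (count, config, seed)", {
  cfg <- synth_config("ear_field", image_size = 64)
  a <- render_field(7L, cfg, seed = 11)
  b <- render_field(7L, cfg, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$positions, b$positions)
  c <- render_field(7L, cfg, seed = 12)
  expect_false(identical(a$image, c$image))
})

test_that("labels equal rendered instances; zero count gives background only", {
  cfg <- synth_config("grain_scatter", image_size = 64,
                      background = list(striped = FALSE))
  s0 <- render_field(0L, cfg, seed = 1)
  expect_identical(s0$count, 0L)
  expect_identical(nrow(s0$positions), 0L)
  expect_true(all(s0$mask == 0L))

  s5 <- render_field(5L, synth_config("grain_scatter", image_size = 96,
                                      occlusion = 0), seed = 4)
  expect_identical(s5$count, 5L)
  expect_identical(nrow(s5$positions), 5L)
  expect_identical(oracle_n_components(s5$mask > 0L), 5L)
})

test_that("impossible packing raises a capacity error", {
  cfg <- synth_config("ear_field", image_size = 48)
  expect_error(render_field(5000L, cfg, seed = 1), "capacity")
})

test_that("generated datasets round-trip through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- synth_config("grain_scatter", image_size = 48,
                      count = list(mean = 6, sd = 3, min = 0, max = 12),
                      seed = 9)
  man <- generate_dataset(10L, cfg, dir)
  expect_identical(nrow(man), 10L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, man$image))))

  rt <- load_manifest(file.path(dir, "manifest.csv"))
  expect_identical(rt$image, man$image)
  expect_identical(rt$count, as.integer(man$count))

  # label exactness against the sidecar instance list
  side <- read.csv(file.path(dir, "positions.csv"))
  tab <- table(factor(side$image, levels = man$image))
  expect_identical(as.integer(tab), as.integer(man$count))

  # identical (config, seed) => byte-identical files
  dir2 <- withr::local_tempdir()
  generate_dataset(10L, cfg, dir2)
  expect_identical(readBin(file.path(dir, man$image[1]), "raw", 1e6),
                   readBin(file.path(dir2, man$image[1]), "raw", 1e6))
})

test_that("dataset count means track the truncated-Gaussian analytic mean", {
  cfg <- synth_config("ear_field", image_size = 72,
                      count = list(mean = 42, sd = 20, min = 0, max = 190),
                      seed = 21)
  smp <- synth_samples(400L, cfg)
  mu <- oracle_clipped_mean(42, 20, 0, 190)
  se <- sd(smp$count) / sqrt(length(smp$count))
  expect_lt(abs(mean(smp$count) - mu), 3 * se)
})

test_that("the ear-field emulation covers the 0-190 density range", {
  cfg <- synth_config("ear_field", image_size = 512)
  expect_identical(cfg$count$min, 0L)
  expect_identical(cfg$count$max, 190L)
  dense <- render_field(190L, cfg, seed = 5)
  expect_identical(dense$count, 190L)
  expect_identical(nrow(dense$positions), 190L)
  empty <- render_field(0L, cfg, seed = 5)
  expect_identical(empty$count, 0L)
})

test_that("manifest splitting is disjoint and seeded", {
  man <- data.frame(image = sprintf("i%03d.png", 1:100), count = 1:100)
  sp <- split_manifest(man, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(vapply(sp, nrow, 1L), c(train = 80L, val = 10L,
                                           test = 10L))
  all_rows <- c(sp$train$image, sp$val$image, sp$test$image)
  expect_identical(sort(all_rows), sort(man$image))
  sp2 <- split_manifest(man, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(sp, sp2)
})
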
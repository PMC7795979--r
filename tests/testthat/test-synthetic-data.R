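test_that("sowing density follows the mass-to-count unit chain", {
  expect_equal(sowing_density(168, 1, 42), 400)       # common triticale dose
  expect_equal(sowing_density(100, 0.5, 50), 100)
  # linear in rate and in germination
  expect_equal(sowing_density(2 * 168, 0.9, 42), 2 * sowing_density(168, 0.9, 42))
  expect_equal(sowing_density(168, 0.8, 42), 0.8 * sowing_density(168, 1, 42))
  expect_error(sowing_density(-1, 0.9, 42), "seed_rate")
  expect_error(sowing_density(168, 0.9, 0), "tkw")
  expect_error(sowing_density(168, 1.2, 42), "germination")
})

test_that("frame specs enforce their invariants", {
  expect_error(frame_spec(width = 10), ">= 32")
  expect_error(frame_spec(speed = 0), "speed")
  expect_error(frame_spec(seed_count = -1), "seed_count")
  expect_error(frame_spec(seed_class = "weeds"), "class")
  sp <- frame_spec()
  expect_equal(sp$width, 640L)
  expect_equal(sp$height, 360L)
})

test_that("identical frame specs generate bit-identical frames", {
  sp <- frame_spec(width = 128, height = 96, speed = 20, seed_count = 4,
                   seed_class = "screenings", rng_seed = 31)
  a <- generate_seed_frame(sp)
  b <- generate_seed_frame(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)
})

test_that("an empty frame is background-only and seeds clip at the border", {
  empty <- generate_seed_frame(frame_spec(width = 96, height = 96,
                                          seed_count = 0, rng_seed = 1))
  expect_equal(nrow(empty$truth), 0L)
  expect_lte(diff(range(unclass(empty$image))), 60)  # screen + ticks + noise
  # crowded small frame: geometry necessarily exceeds the frame; must clip
  crowded <- generate_seed_frame(frame_spec(width = 48, height = 48,
                                            seed_count = 8,
                                            seed_class = "select",
                                            rng_seed = 2))
  expect_equal(nrow(crowded$truth), 8L)
  expect_true(all(unclass(crowded$image) >= 0 & unclass(crowded$image) <= 255))
})

test_that("faster transport lowers the mean GLCM contrast of the frame", {
  for (seed in c(5, 6)) {
    f15 <- generate_seed_frame(frame_spec(speed = 15, rng_seed = seed))
    f25 <- generate_seed_frame(frame_spec(speed = 25, rng_seed = seed))
    expect_lte(extract_features(f25$image)["contrast"],
               extract_features(f15$image)["contrast"])
  }
})

test_that("dataset generation honours per-cell counts and is reproducible", {
  counts <- data.frame(speed = c(15, 20, 25),
                       class = c("select", "chaff", "screenings"),
                       n_frames = c(2, 3, 0))
  ds <- generate_dataset(counts, 17, width = 96, height = 96, seed_count = 2)
  expect_length(ds, 5L)
  expect_equal(sapply(ds, `[[`, "class"),
               c("select", "select", "chaff", "chaff", "chaff"))
  expect_equal(sapply(ds, `[[`, "speed"), c(15, 15, 20, 20, 20))
  ds2 <- generate_dataset(counts, 17, width = 96, height = 96, seed_count = 2)
  expect_identical(lapply(ds, function(e) unclass(e$image)),
                   lapply(ds2, function(e) unclass(e$image)))
  expect_length(generate_dataset(counts[0, ], 1), 0L)
  counts$n_frames[1] <- -1
  expect_error(generate_dataset(counts, 1), "n_frames")
})

test_that("the study set designs carry the expected frame counts", {
  expect_equal(sum(set_design("Z1")$n_frames), 600)
  expect_equal(sum(set_design("Z2")$n_frames), 150)
  expect_equal(sum(set_design("Z3")$n_frames), 300)
  expect_equal(sum(set_design("Z4")$n_frames), 1800)
  expect_setequal(unique(set_design("Z4")$speed), c(15, 20, 25))
})

test_that("datasets round-trip through PNG frames and a ground-truth CSV", {
  counts <- data.frame(speed = 15, class = "select", n_frames = 2)
  ds <- generate_dataset(counts, 23, width = 64, height = 64, seed_count = 2)
  dir <- tempfile()
  csv <- write_dataset(ds, dir)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 4L)  # 2 frames x 2 seeds
  expect_true(all(c("frame_path", "class", "speed_mps", "seed_id",
                    "cx", "cy", "area_px") %in% names(gt)))
  img <- read_image(file.path(dir, gt$frame_path[1]))
  expect_identical(unclass(img), unclass(ds[[1]]$image))
})

test_that("classes separate in edge-map descriptor space at 15 m/s", {
  counts <- data.frame(speed = 15, class = seed_classes(), n_frames = 20)
  tab <- build_table(generate_dataset(counts, 99))
  ratios <- sapply(c("asm", "entropy", "contrast", "correlation", "idm"),
                   function(f) {
    cent <- tapply(tab[[f]], tab$label, mean)
    wsd <- sqrt(mean(tapply(tab[[f]], tab$label, var)))
    pairs <- combn(names(cent), 2)
    min(abs(cent[pairs[1, ]] - cent[pairs[2, ]])) / wsd
  })
  expect_gte(sum(ratios > 1), 2)
})

test_that("between-class contrast gaps shrink as transport speed rises", {
  gaps <- sapply(c(15, 20, 25), function(s) {
    counts <- data.frame(speed = s, class = seed_classes(), n_frames = 20)
    ds <- generate_dataset(counts, 421)
    tab <- data.frame(
      contrast = sapply(ds, function(e) extract_features(crop(e$image))["contrast"]),
      label = sapply(ds, `[[`, "class"))
    cent <- tapply(tab$contrast, tab$label, mean)
    sapply(names(cent), function(c0)
      min(abs(cent[c0] - cent[setdiff(names(cent), c0)])))
  })
  # per class, non-increasing from 15 to 20 to 25 m/s
  for (k in 1:3) expect_true(all(diff(gaps[k, ]) <= 0))
})
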
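test_that("scene generation is deterministic and mask/box consistent", {
  cfg <- tiny_scene_config()
  a <- generate_scene(cfg, seed = 42)
  b <- generate_scene(cfg, seed = 42)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)
  expect_identical(a$masks, b$masks)

  W <- cfg$image_size[1]
  for (i in seq_len(nrow(a$boxes))) {
    mb <- greendet:::mask_to_box(a$masks[[i]])
    expect_lt(max(abs(unlist(mb[, -1]) - unlist(a$boxes[i, -1]))),
              1 / W + 1e-9)
  }
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
})

test_that("a single centered disc yields the expected tight box", {
  cfg <- scene_config(image_size = c(100L, 100L), n_fruit = c(1L, 1L),
                      fruit_radius = c(10, 10),
                      fruit_eccentricity = c(1, 1),
                      n_leaf_occluders = c(0L, 0L), noise_sd = 0)
  sc <- generate_scene(cfg, seed = 1,
                       fruits = data.frame(cx = 50, cy = 50, r = 10,
                                           ecc = 1, theta = 0))
  expect_equal(nrow(sc$boxes), 1)
  expect_lt(max(abs(unlist(sc$boxes[1, -1]) - c(0.5, 0.5, 0.2, 0.2))),
            1 / 100 + 1e-9)
})

test_that("empty scenes and instance extraction behave", {
  cfg <- tiny_scene_config(n_fruit = c(0L, 0L))
  sc <- generate_scene(cfg, seed = 3)
  expect_equal(nrow(sc$boxes), 0)

  full <- fixture_scene(7)
  inst <- get_instances(full)
  expect_equal(length(inst), length(full$masks))
  cats <- vapply(inst, `[[`, character(1), "category")
  expect_equal(sum(cats == "fruit"), nrow(full$boxes))
  for (i in which(cats == "fruit")) {
    mb <- greendet:::mask_to_box(inst[[i]]$mask)
    expect_lt(max(abs(unlist(mb[, -1]) - unlist(full$boxes[i, -1]))),
              1 / 96 + 1e-9)
  }

  no_masks <- labeled_image(full$pixels, full$boxes, image_id = "x")
  expect_error(get_instances(no_masks), "no instance masks")
})

test_that("fruit pixels stay within the configured hue offset of foliage", {
  cfg <- tiny_scene_config()
  sc <- fixture_scene(11, cfg)
  fruit <- Reduce(`|`, sc$masks[sc$mask_categories == "fruit"])
  bg <- !Reduce(`|`, sc$masks)
  hue <- rgb_to_hue(sc$pixels[, , 1] / 255, sc$pixels[, , 2] / 255,
                    sc$pixels[, , 3] / 255)
  delta <- abs(mean(hue[fruit]) - mean(hue[bg]))
  expect_lt(delta, cfg$hue_delta + 5)
})

test_that("render_dataset writes the full layout with a 7:3 split", {
  dir <- withr::local_tempdir()
  out <- render_dataset(tiny_scene_config(), 10, dir, ratio = 0.7, seed = 5)
  expect_equal(length(list.files(file.path(dir, "images", "train"))), 7)
  expect_equal(length(list.files(file.path(dir, "images", "test"))), 3)
  expect_true(file.exists(file.path(dir, "dataset.yaml")))
  expect_true(file.exists(file.path(dir, "masks.csv")))
  expect_equal(length(list.files(file.path(dir, "masks"))), 10)

  # labels re-read and re-validated against the generator's masks
  seeds <- greendet:::derive_seeds(5, sprintf("scene_%04d", 1:10))
  for (sub in c("train", "test")) {
    for (f in list.files(file.path(dir, "labels", sub), full.names = TRUE)) {
      stem <- sub("\\.txt$", "", basename(f))
      sc <- generate_scene(tiny_scene_config(), seeds[stem], image_id = stem)
      expect_lt(max(abs(as.matrix(read_labels(f)) - as.matrix(sc$boxes))),
                1e-6 + 1e-9)
    }
  }

  imgs <- load_dataset(dir, "train")
  expect_equal(length(imgs), 7)
  expect_equal(dim(imgs[[1]]$pixels), c(96, 96, 3))
})
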
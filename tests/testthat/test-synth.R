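# The synthetic dermoscopy generator: determinism, exact binary masks,
# category area bands, on-disk dataset layout.

test_that("the same spec and seed reproduce the pair bit for bit", {
  sp <- synthetic_spec("prominent", image_size = c(48, 48), seed = 99)
  a <- generate_synthetic_lesion(sp)
  b <- generate_synthetic_lesion(sp)
  expect_identical(a, b)
})

test_that("masks are binary with a single connected lesion", {
  for (cat in c("small", "prominent", "irregular_edge")) {
    sp <- synthetic_spec(cat, image_size = c(64, 64), seed = 7)
    out <- generate_synthetic_lesion(sp)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_gt(sum(out$mask), 0)
    labels <- EBImage::bwlabel(out$mask[, , 1])
    expect_equal(max(labels), 1)   # one connected component
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_identical(dim(out$image), c(64L, 64L, 3L))
  }
})

test_that("measured lesion area lands inside each category's band", {
  for (cat in c("small", "prominent", "irregular_edge")) {
    for (seed in 1:5) {
      sp <- synthetic_spec(cat, image_size = c(64, 64), seed = seed)
      out <- generate_synthetic_lesion(sp)
      frac <- mean(out$mask)
      expect_gte(frac, sp$area_fraction_range[1])
      expect_lte(frac, sp$area_fraction_range[2])
      expect_equal(frac, out$area_fraction)
    }
  }
  # the small band sits strictly below the prominent band
  expect_lt(synthetic_spec("small")$area_fraction_range[2],
            synthetic_spec("prominent")$area_fraction_range[1])
})

test_that("the explicit small-target band is respected", {
  sp <- synthetic_spec("small", image_size = c(96, 96),
                       area_fraction_range = c(0.005, 0.05), seed = 12)
  frac <- mean(generate_synthetic_lesion(sp)$mask)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.05)
})

test_that("infeasible area ranges are rejected", {
  expect_error(synthetic_spec("prominent", image_size = c(16, 16),
                              area_fraction_range = c(0.9, 0.95)),
               "infeasible")
})

test_that("on-disk generation writes pairs, manifest and is reproducible", {
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  split1 <- generate_dataset(10, d1, image_size = c(24, 24), seed = 3)
  expect_identical(length(list.files(file.path(d1, "images"))), 10L)
  expect_identical(length(list.files(file.path(d1, "masks"))), 10L)
  man <- utils::read.csv(file.path(d1, "manifest.csv"))
  expect_identical(nrow(man), 10L)
  # near-uniform mix over the three categories
  expect_true(all(table(man$category) >= 3))
  generate_dataset(10, d2, image_size = c(24, 24), seed = 3)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(nrow(split1$train) + nrow(split1$val) +
                     nrow(split1$test), 10L)
  expect_error(generate_dataset(2, tempfile()), ">= 3")
})

test_that("requested category mix maps to deterministic manifest counts", {
  d <- file.path(tempdir(), "gen_mix")
  unlink(d, recursive = TRUE)
  generate_dataset(8, d, category_mix = c(small = 3, prominent = 1,
                                          irregular_edge = 0),
                   image_size = c(24, 24), seed = 5)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  tab <- table(man$category)
  expect_identical(unname(tab["small"]), 6L)
  expect_identical(unname(tab["prominent"]), 2L)
  expect_false("irregular_edge" %in% names(tab))
})
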
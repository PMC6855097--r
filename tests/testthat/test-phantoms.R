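# Phantom generator: construction guarantees, determinism, the gland-area
# law, and label-conditional texture separation.

test_that("generated phantoms satisfy the construction guarantees", {
  cfg <- phantom_config(image_size = 64L)
  s <- generate_phantom(cfg, "benign", seed = 1)
  expect_equal(dim(s$image), c(64, 64))
  expect_equal(dim(s$mask), dim(s$image))
  expect_true(all(s$image >= 0 & s$image <= 255))
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_gt(sum(s$mask), 0)
  expect_identical(s$label, "benign")
  # background carries distractor structure outside the mask on some seeds
  bg_max <- vapply(1:10, function(i) {
    p <- generate_phantom(cfg, "benign", seed = i)
    max(p$image[p$mask == 0])
  }, numeric(1))
  expect_true(any(bg_max > 25))
})

test_that("identical seed and config give bit-identical phantoms", {
  cfg <- phantom_config(image_size = 48L)
  a <- generate_phantom(cfg, "malignant", seed = 7)
  b <- generate_phantom(cfg, "malignant", seed = 7)
  expect_identical(a, b)
  c <- generate_phantom(cfg, "malignant", seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("invalid labels are rejected with a clear message", {
  expect_error(generate_phantom(phantom_config(32L), "suspicious", seed = 1),
               "benign, malignant")
})

test_that("mean malignant/benign gland area ratio follows the squared
           enlargement factor", {
  cfg <- phantom_config(image_size = 64L)
  n <- 200L
  area <- function(lab, off) {
    vapply(seq_len(n), function(i) {
      sum(generate_phantom(cfg, lab, seed = 5000L + off + i)$mask)
    }, numeric(1))
  }
  ratio <- mean(area("malignant", 0L)) / mean(area("benign", 10000L))
  expect_lt(abs(ratio - cfg$malignant_enlargement_factor^2) /
              cfg$malignant_enlargement_factor^2, 0.1)
})

test_that("within-mask local intensity variance separates the classes", {
  cfg <- phantom_config(image_size = 48L)
  # local high-pass energy: squared deviation of each pixel from its
  # 4-neighbour mean, averaged over pixels whose neighbourhood lies fully
  # inside the mask (so the flat capsule rim does not dominate)
  local_var <- function(s) {
    S <- nrow(s$image); im <- s$image
    # parenchyma proper: erode past the capsule-rim band so the statistic
    # reflects internal texture, not the rim interface
    m <- EBImage::imageData(
      EBImage::erode(EBImage::Image(s$mask * 1),
                     EBImage::makeBrush(7L, "disc"))) > 0.5
    ctr <- 2:(S - 1)
    inner <- m[ctr, ctr] & m[ctr - 1, ctr] & m[ctr + 1, ctr] &
      m[ctr, ctr - 1] & m[ctr, ctr + 1]
    nb <- (im[ctr - 1, ctr] + im[ctr + 1, ctr] +
             im[ctr, ctr - 1] + im[ctr, ctr + 1]) / 4
    mean((im[ctr, ctr][inner] - nb[inner])^2)
  }
  invar <- function(lab, off) {
    vapply(1:100, function(i) {
      local_var(generate_phantom(cfg, lab, seed = 20000L + off + i))
    }, numeric(1))
  }
  v_mal <- invar("malignant", 0L)
  v_ben <- invar("benign", 50000L)
  expect_gt(mean(v_mal), mean(v_ben))
  # the separation is decisive, not marginal
  expect_lt(stats::t.test(v_ben, v_mal)$p.value, 1e-6)
})

test_that("cohorts group images by patient and round the malignant count
           half-up", {
  cfg <- phantom_config(image_size = 16L)
  co <- generate_cohort(cfg, n_patients = 10L, images_per_patient = 2L,
                        malignant_fraction = 0.3, seed = 5)
  expect_length(co$samples, 20L)
  expect_equal(nrow(co$manifest), 20L)
  lab_by_pat <- tapply(co$manifest$label, co$manifest$patient_id,
                       function(x) length(unique(x)))
  expect_true(all(lab_by_pat == 1L))  # one label per patient
  expect_equal(sum(co$manifest$label == "malignant"), 6L)  # 3 patients x 2

  co2 <- generate_cohort(cfg, 2L, 1L, 0.5, seed = 1)
  expect_equal(sort(unique(co2$manifest$label)), c("benign", "malignant"))

  # the source cohort's class ratio: 73 of 398 patients malignant
  co3 <- generate_cohort(phantom_config(image_size = 16L,
                                        background_organ_count = 0L),
                         n_patients = 398L, images_per_patient = 1L,
                         malignant_fraction = 73 / 398, seed = 2)
  pat <- !duplicated(co3$manifest$patient_id)
  expect_equal(sum(co3$manifest$label[pat] == "malignant"), 73L)
})

test_that("written cohorts round-trip through PNG and the CSV manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(image_size = 32L)
  co <- generate_cohort(cfg, 3L, 2L, 0.4, seed = 9)
  mp <- write_cohort(co, dir)
  expect_true(file.exists(mp))
  back <- load_manifest(mp)
  expect_length(back, 6L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$image, co$samples[[i]]$image)
    expect_identical(back[[i]]$mask, co$samples[[i]]$mask)
    expect_identical(back[[i]]$label, co$samples[[i]]$label)
    expect_identical(back[[i]]$patient_id, co$samples[[i]]$patient_id)
  }
})
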
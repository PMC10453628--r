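test_that("labelling is 8-connected", {
  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1
  lab <- label8(m)
  expect_equal(max(lab), 1L)  # diagonal chain is one component

  m2 <- matrix(0, 5, 5); m2[1, 1] <- 1; m2[5, 5] <- 1; m2[1, 5] <- 1
  expect_equal(max(label8(m2)), 3L)
})

test_that("largest component geometry is normalized as documented", {
  full <- matrix(1, 56, 56)
  s <- largest_component(full)
  expect_equal(s$area_px, 3136L)
  expect_equal(s$norm_area, 1)
  expect_equal(s$centroid, c(28.5, 28.5))
  expect_equal(s$norm_distance, 0)

  centre_px <- matrix(0, 57, 57); centre_px[29, 29] <- 1
  s2 <- largest_component(centre_px)
  expect_equal(s2$norm_area, 1 / 3249)
  expect_equal(s2$norm_distance, 0)

  two <- matrix(0, 20, 20)
  two[2:3, 2:6] <- 1           # 10 px
  two[10:14, 10:14] <- 1       # 25 px
  s3 <- largest_component(two)
  expect_equal(s3$area_px, 25L)
  expect_equal(s3$centroid, c(12, 12))
  expect_true(all(s3$mask_C <= two))

  s4 <- largest_component(matrix(0, 8, 8))
  expect_true(s4$empty)
  expect_equal(s4$norm_area, 0)
  expect_equal(s4$norm_distance, 1)
})

test_that("degeneracy penalty fires only on all-black or all-white masks", {
  expect_identical(mask_penalty(matrix(1, 10, 10)), Inf)
  expect_identical(mask_penalty(matrix(0, 10, 10)), Inf)
  one <- matrix(0, 10, 10); one[5, 5] <- 1
  expect_identical(mask_penalty(one), 0)
})

test_that("objective score composes area, distance and penalty", {
  # centred disc covering ~25% of a 56x56 frame
  d <- sqrt(outer((1:56 - 28.5)^2, (1:56 - 28.5)^2, `+`))
  disc <- (d <= sqrt(0.25 * 3136 / pi)) + 0
  sc <- objective_score(largest_component(disc), mask_penalty(disc))
  expect_equal(sc$value, sum(disc) / 3136, tolerance = 0.01)
  expect_lt(abs(sc$distance_term), 0.02)

  full <- matrix(1, 56, 56)
  scf <- objective_score(largest_component(full), mask_penalty(full))
  expect_identical(scf$value, -Inf)

  corner <- matrix(0, 56, 56); corner[1:28, 1:28] <- 1
  scc <- objective_score(largest_component(corner), mask_penalty(corner))
  expect_lt(scc$value, 0.25)
  expect_equal(scc$area_term, 0.25)
  # centroid (14.5, 14.5) = mean of rows/cols 1..28: hand geometry
  expect_equal(scc$distance_term,
               sqrt(2) * (28.5 - 14.5) / (sqrt(55^2 + 55^2) / 2),
               tolerance = 1e-9)
})

test_that("winner-takes-all selection returns the arg-max with fixed tie priority", {
  d <- sqrt(outer((1:56 - 28.5)^2, (1:56 - 28.5)^2, `+`))
  disc <- (d <= 15) + 0
  dec <- select_best(list(hho = matrix(1, 56, 56), acm = disc))
  expect_equal(dec$winner, "acm")  # -Inf vs positive score
  expect_equal(dec$winner, dec$scores$method[which.max(dec$scores$value)])

  tie <- select_best(list(gray = disc, kapur = disc, otsu = disc))
  expect_equal(tie$winner, "otsu")  # priority otsu > acm > kapur > hho > gray

  expect_warning(fb <- select_best(list(otsu = matrix(0, 8, 8),
                                        gray = matrix(1, 8, 8))), "degenerate")
  expect_equal(fb$winner, "otsu")
  expect_true(fb$degenerate)

  expect_error(select_best(list()), "at least one")
  expect_error(select_best(list(disc)), "named")

  # property: winner attains the max finite score on random candidate sets
  set.seed(13)
  for (i in 1:10) {
    cands <- list()
    for (m in c("otsu", "kapur", "gray")) {
      r <- matrix(0, 30, 30)
      r0 <- sample(1:20, 1); c0 <- sample(1:20, 1)
      r[r0:(r0 + sample(3:9, 1)), c0:(c0 + sample(3:9, 1))] <- 1
      cands[[m]] <- r
    }
    dec <- select_best(cands)
    expect_equal(dec$scores$value[dec$scores$method == dec$winner],
                 max(dec$scores$value))
  }
})

test_that("postprocessing shrinks, fills holes, and keeps one component", {
  d <- sqrt(outer((1:56 - 28.5)^2, (1:56 - 28.5)^2, `+`))
  disc <- (d <= 10) + 0
  post <- postprocess_mask(disc)
  expect_true(all(post <= disc))          # net erosion of a solid disc
  expect_equal(max(label8(post)), 1L)
  # erosion by the radius-1 disc: pixel survives iff its 4-neighbours are set
  er <- disc
  er[2:55, 2:55] <- disc[2:55, 2:55] * disc[1:54, 2:55] * disc[3:56, 2:55] *
    disc[2:55, 1:54] * disc[2:55, 3:56]
  er[c(1, 56), ] <- 0; er[, c(1, 56)] <- 0
  expect_equal(post, er)                  # closing is identity on the convex disc

  holey <- (d <= 12) + 0
  holey[28:29, 28:29] <- 0
  filled <- postprocess_mask(holey)
  expect_equal(filled[28:29, 28:29], matrix(1, 2, 2))

  z <- matrix(0, 10, 10)
  expect_warning(out <- postprocess_mask(z), "empty")
  expect_equal(out, z)
})

test_that("full pipeline segments a clean synthetic lesion accurately", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  res <- segment_lesion(fx$image, seed = 1)
  expect_true(res$winner %in% c("otsu", "acm", "kapur", "hho", "gray"))
  expect_gte(dice_score(res$mask, fx$mask), 0.95)
  expect_equal(nrow(res$scores), 5L)
  expect_true(all(is.finite(res$scores$value)))

  solo <- segment_lesion(fx$image, method = "otsu", seed = 1, postprocess = FALSE)
  expect_gte(dice_score(solo$mask, fx$mask), 0.98)
})
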
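test_that("component labelling matches a flood-fill oracle", {
  set.seed(10)
  for (i in 1:8) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    for (conn in c(4, 8)) {
      mine <- label_components(mask, conn)
      oracle <- flood_fill_label(mask, conn)
      expect_equal(max(mine), max(oracle))
      expect_true(same_partition(mine, oracle))
    }
  }
  # empty mask
  expect_equal(max(label_components(matrix(FALSE, 5, 5), 8)), 0)
})

test_that("8-connectivity joins diagonals, 4-connectivity does not", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(m, 8)), 1)
})

test_that("candidate extraction: areas, merging, and size filtering", {
  m <- matrix(FALSE, 20, 20)
  m[3:7, 3:4] <- TRUE                    # 10-pixel component
  cands <- extract_candidates(m, scene_id = "s1")
  expect_equal(nrow(cands), 1)
  expect_equal(cands$pixel_count, 10L)
  expect_equal(cands$guano_area, 9000)
  expect_equal(cands$guano_area, 900 * cands$pixel_count)

  # two single-pixel components one pixel apart: merged under radius 2
  m2 <- matrix(FALSE, 10, 10); m2[5, 3] <- TRUE; m2[5, 5] <- TRUE
  expect_equal(nrow(extract_candidates(m2, merge_radius = 0)), 2)
  merged <- extract_candidates(m2, merge_radius = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$pixel_count, 2L)

  # min_pixels filter drops the singleton, keeps the block
  m3 <- matrix(FALSE, 15, 15); m3[2, 2] <- TRUE; m3[8:10, 8:10] <- TRUE
  expect_equal(nrow(extract_candidates(m3, min_pixels = 2)), 1)

  # empty mask -> empty candidate list, not an error
  expect_equal(nrow(extract_candidates(matrix(FALSE, 5, 5))), 0)
})

test_that("outcome matching assigns both/omission/commission correctly", {
  reg <- make_registry(c(1000, 2000), 0.34, x = c(300, 1500), y = c(300, 1500))
  # candidate at the first colony, a stray far from any colony
  cands <- data.frame(candidate_id = c("c1", "c2"), scene_id = "s",
                      pixel_count = c(4L, 2L), guano_area = c(3600, 1800),
                      centroid_x = c(310, 5000), centroid_y = c(295, 5000))
  mo <- match_outcomes(cands, reg, max_match_distance = 3000)
  expect_equal(mo$colonies$outcome, c("both", "omission"))
  expect_equal(mo$summary$n_both, 1)
  expect_equal(mo$summary$n_omission, 1)
  expect_equal(mo$summary$n_commission, 1)
  expect_equal(mo$summary$commission_rate, 0.5)
  # extra candidate at an already-confirmed colony is absorbed
  cands3 <- rbind(cands, data.frame(candidate_id = "c3", scene_id = "s",
                                    pixel_count = 1L, guano_area = 900,
                                    centroid_x = 330, centroid_y = 300))
  mo3 <- match_outcomes(cands3, reg)
  expect_equal(mo3$summary$n_commission, 1)
  expect_equal(mo3$summary$n_both, 1)
  # the colony's matched guano area pools the absorbed candidate
  expect_equal(mo3$colonies$guano_area[1], 3600 + 900)
})

test_that("matching invariants hold on randomized configurations", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    reg <- make_registry(rep(1000, n), 0.34,
                         x = runif(n, 0, 20000), y = runif(n, 0, 20000))
    nc <- sample(1:8, 1)
    cands <- data.frame(candidate_id = sprintf("c%d", seq_len(nc)),
                        scene_id = "s", pixel_count = rep(1L, nc),
                        guano_area = rep(900, nc),
                        centroid_x = runif(nc, 0, 20000),
                        centroid_y = runif(nc, 0, 20000))
    mo <- match_outcomes(cands, reg)
    s <- mo$summary
    expect_equal(s$n_both + s$n_omission, n)
    expect_equal(s$n_both + s$n_commission, s$n_candidates_after_matching)
    expect_true(all(mo$colonies$outcome %in% c("both", "omission")))
  }
  expect_error(match_outcomes(data.frame(), make_registry(1, 1, 1, 1), -5),
               "max_match_distance")
})

test_that("a colony under full cloud is scored as an omission", {
  lib <- toy_library(sep = 10)
  reg <- make_registry(3060, 0.34, x = 450, y = 450, geometry = c(30, 30))
  sc <- render_scene(reg, lib, background_map = matrix(2L, 30, 30),
                     degradation = list(cloud_fraction = 1), seed = 12)
  clf <- fit_ellipsoid(sample_training_pixels(lib, seed = 12)$guano)
  cands <- extract_candidates(classify_pixels(sc, clf))
  mo <- match_outcomes(cands, reg)
  expect_equal(mo$colonies$outcome, "omission")
  expect_equal(mo$summary$n_both, 0)
})
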
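test_that("expand_region matches the exhaustive per-pixel distance oracle", {
  disk <- function(n, cy, cx, r) {
    g <- expand.grid(r1 = seq_len(n), c1 = seq_len(n))
    matrix((g$r1 - cy)^2 + (g$c1 - cx)^2 <= r^2, n, n)
  }
  for (case in list(list(m = disk(21, 11, 11, 3), d = 2),
                    list(m = disk(21, 11, 11, 3), d = 4),
                    list(m = bar_slice(15, 15, list(list(label = 1, rows = 7,
                                                         cols = 3:12))) == 1,
                         d = 3))) {
    expect_identical(expand_region(case$m, case$d),
                     oracle_expand(case$m, case$d))
  }
  # identity at distance 0; monotone containment in the distance
  m <- disk(15, 8, 8, 3)
  expect_identical(expand_region(m, 0), m)
  e2 <- expand_region(m, 2)
  e3 <- expand_region(m, 3)
  expect_true(all(m[e2 == FALSE] == FALSE))
  expect_true(all(e2[e3 == FALSE] == FALSE))  # e2 subset of e3
  expect_warning(expand_region(matrix(FALSE, 4, 4), 2), "CTM_EMPTY_MASK")
})

test_that("directed slice counts match the brute-force pixel-pair oracle", {
  # two 5x1 horizontal bars with one background row between, threshold 2 px
  sl <- bar_slice(9, 9, list(list(label = 1, rows = 4, cols = 3:7),
                             list(label = 2, rows = 6, cols = 3:7)))
  got <- pairwise_contact_slice(sl, 1, 2, 2L)
  want <- oracle_contact_slice(sl, 1, 2, 2L)
  expect_identical(c(got$count_ab, got$count_ba), c(want[1], want[2]))
  # mirror-symmetric geometry: the two directed counts are equal
  expect_identical(got$count_ab, got$count_ba)
  # regions separated beyond the threshold: no contact
  far <- bar_slice(9, 20, list(list(label = 1, rows = 4, cols = 1:3),
                               list(label = 2, rows = 4, cols = 15:18)))
  res <- pairwise_contact_slice(far, 1, 2, 2L)
  expect_identical(res$count_ab, 0L)
  expect_identical(res$count_ba, 0L)
  expect_false(any(res$overlap))
  expect_error(pairwise_contact_slice(sl, 1, 1, 2L), "must differ")
})

test_that("volume adjacency equals the oracle and is additive over slices", {
  vol <- three_tube_phantom(n_slices = 3)
  thr <- threshold_spec(13.5, 4.5)  # 3 px
  got <- compute_adjacency_matrix(vol, thr)
  expect_equal(got$adjacency, oracle_adjacency(vol, 3L))
  expect_equal(got$adjacency, t(got$adjacency))
  # tube 3 is far from both others
  expect_equal(got$adjacency["1", "3"], 0)
  expect_equal(got$adjacency["2", "3"], 0)
  # duplicating every slice doubles every directed count
  vol2 <- label_volume(rep(vol$slices, each = 2), vol$pixel_size,
                       vol$z_spacing)
  got2 <- compute_adjacency_matrix(vol2, thr)
  expect_equal(got2$adjacency, 2 * got$adjacency)
  rec <- got$records[["1|2"]]
  rec2 <- got2$records[["1|2"]]
  expect_equal(rec2$directed_pixels, 2 * rec$directed_pixels)
})

test_that("matrix entries are nondecreasing in the pixel threshold", {
  vol <- three_tube_phantom(n_slices = 2)
  prev <- NULL
  for (nm in c(4.5, 9, 13.5, 22.5, 45)) {
    cur <- compute_adjacency_matrix(vol, threshold_spec(nm, 4.5))$adjacency
    if (!is.null(prev)) expect_true(all(cur - prev >= 0))
    prev <- cur
  }
})

test_that("contact area is the outline-length sum times z spacing", {
  vol <- two_bar_volume(n_slices = 3)
  res <- compute_adjacency_matrix(vol, threshold_spec(27, 4.5))  # 6 px
  rec <- res$records[["1|2"]]
  expect_equal(rec$total_area_nm2,
               sum(rec$per_slice_outline_length_nm) * vol$z_spacing)
  expect_length(rec$per_slice_outline_length_nm, 3)
  # the overlap is two disjoint 11x2 rectangles (a 6 px expansion reaches
  # 2 columns into the facing bar from either side): perimeter in closed form
  ov <- rec$overlap_slices[[1]]
  expect_equal(sum(ov), 2 * 11 * 2)
  expect_equal(rec$per_slice_outline_length_nm[1],
               2 * (2 * (11 + 2)) * vol$pixel_size)
})

test_that("threshold calibration selects the smallest adequate candidate", {
  # parallel bars: facing pixel columns are 5 px apart, so a candidate of
  # c px penetrates (c - 5) * 4.5 nm into the partner at its near column
  vol <- two_bar_volume()
  cands <- c(45, 49.5, 54, 58.5)  # 10, 11, 12, 13 px
  got <- calibrate_threshold(vol, reference_expansion_nm = 45,
                             target_overlap_nm = 30, candidates_nm = cands)
  expect_equal(got$distance_nm, 54)
  expect_equal(got$mean_depth_nm, (12 - 5) * 4.5)
  # mean depth is nondecreasing in the candidate distance
  expect_true(all(diff(got$depths) >= 0))
  expect_error(
    calibrate_threshold(vol, target_overlap_nm = 30,
                        candidates_nm = c(27, 31.5)),
    "achieved depths")
  expect_error(
    calibrate_threshold(
      label_volume(list(bar_slice(20, 40,
                                  list(list(label = 1, rows = 5:8, cols = 2:5),
                                       list(label = 2, rows = 5:8, cols = 30:33)))),
                   4.5, 30),
      candidates_nm = c(45)),
    "no directly contacting pair")
})

test_that("per-contact statistics use dense ranking and match a sort oracle", {
  recs <- list(
    list(pair = c("AIML", "PVQL"), total_area_nm2 = 300),
    list(pair = c("AIML", "AVFL"), total_area_nm2 = 200),
    list(pair = c("AIML", "AVFR"), total_area_nm2 = 200),
    list(pair = c("AIML", "AIMR"), total_area_nm2 = 100))
  st <- contact_stats(recs, "AIML", neuron_surface_nm2 = 1000,
                      ring_surface_nm2 = 10000)
  expect_equal(st$rank[order(st$partner)],
               c(3L, 2L, 2L, 1L)[order(c("AIMR", "AVFL", "AVFR", "PVQL"))])
  expect_equal(sort(unique(st$rank)), 1:3)
  expect_equal(st$pct_of_neuron, 100 * st$area_nm2 / 1000)
  expect_equal(st$pct_of_ring, 100 * st$area_nm2 / 10000)
  # ranks agree with an independent sort of areas
  o <- order(-st$area_nm2)
  expect_true(all(diff(st$rank[o]) >= 0))
  one <- contact_stats(recs[1], "AIML", 1000, 10000)
  expect_equal(one$rank, 1L)
  expect_error(contact_stats(recs, "XXXX", 1000, 10000), "no contacts")
})

test_that("neuron volume uses the voxel formula and is additive", {
  one <- label_volume(list(bar_slice(9, 9, list(list(label = 1, rows = 5,
                                                     cols = 5)))),
                      pixel_size = 10, z_spacing = 30)
  expect_equal(neuron_stats(one, 1)$volume_nm3, 3000)
  # two disjoint components: volume adds
  two <- label_volume(list(bar_slice(12, 12,
                                     list(list(label = 1, rows = 2:3, cols = 2:3),
                                          list(label = 1, rows = 9:10, cols = 9:10)))),
                      pixel_size = 10, z_spacing = 30)
  expect_equal(neuron_stats(two, 1)$volume_nm3, 8 * 100 * 30)
  expect_error(neuron_stats(one, 99), "absent")
})
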
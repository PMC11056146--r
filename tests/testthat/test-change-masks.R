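# Four-class change masks, cluster filtering, resampling and volumetrics

test_that("the exhaustive 2x2x1 truth table lands each voxel correctly", {
  d <- c(2, 2, 1)
  nawm_bl <- array(c(TRUE, FALSE, FALSE, TRUE), d)
  wmh_bl <- array(c(FALSE, TRUE, TRUE, FALSE), d)
  nawm_fu <- array(c(FALSE, TRUE, FALSE, TRUE), d)
  wmh_fu <- array(c(TRUE, FALSE, TRUE, FALSE), d)
  cl <- change_classes(nawm_bl, wmh_bl, nawm_fu, wmh_fu)
  expect_identical(which(cl$progressing_wmh), 1L)  # NAWM -> WMH
  expect_identical(which(cl$regressing_wmh), 2L)   # WMH -> NAWM
  expect_identical(which(cl$stable_wmh), 3L)       # WMH -> WMH
  expect_identical(which(cl$stable_nawm), 4L)      # NAWM -> NAWM

  # identical masks at the two visits produce no change classes
  cl2 <- change_classes(nawm_bl, wmh_bl, nawm_bl, wmh_bl)
  expect_equal(sum(cl2$progressing_wmh), 0)
  expect_equal(sum(cl2$regressing_wmh), 0)

  expect_error(change_classes(nawm_bl, nawm_bl, nawm_fu, wmh_fu),
               "overlap")
})

test_that("random mask quadruples match the brute-force voxel oracle", {
  set.seed(23)
  d <- c(5, 5, 4)
  for (i in 1:60) {
    wm_bl <- random_mask(d, 0.5); wmh_bl <- random_mask(d, 0.3) & !wm_bl
    wm_fu <- random_mask(d, 0.5); wmh_fu <- random_mask(d, 0.3) & !wm_fu
    fast <- change_classes(wm_bl, wmh_bl, wm_fu, wmh_fu)
    slow <- change_classes_oracle(wm_bl, wmh_bl, wm_fu, wmh_fu)
    expect_identical(fast, slow)
    # partition: each voxel in at most one class, and every voxel in both
    # timepoints' (NAWM u WMH) belongs to exactly one
    tot <- fast$stable_nawm + fast$stable_wmh + fast$progressing_wmh +
      fast$regressing_wmh
    expect_true(all(tot <= 1))
    covered <- (wm_bl | wmh_bl) & (wm_fu | wmh_fu)
    expect_true(all(tot[covered] == 1))
  }
})

test_that("cluster filtering honors the 5-voxel threshold exactly", {
  d <- c(10, 10, 10)
  four <- array(FALSE, d); four[2:5, 2, 2] <- TRUE
  five <- array(FALSE, d); five[2:6, 5, 5] <- TRUE
  both <- four | five
  out <- filter_small_clusters(both, min_size = 5)
  expect_identical(out, five)                      # 4 removed, 5 kept
  expect_identical(filter_small_clusters(both, min_size = 1), both)
})

test_that("component labelling agrees with queue-BFS and igraph oracles", {
  set.seed(29)
  for (conn in c(6L, 26L)) {
    for (i in 1:12) {
      m <- random_mask(c(8, 8, 6), 0.25)
      lab <- label_components(m, conn)
      oracle <- label_components_oracle(m, conn)
      # same partition (labels may be permuted): compare size multisets and
      # co-membership on a voxel sample
      expect_identical(sort(tabulate(lab[lab > 0])),
                       sort(tabulate(oracle[oracle > 0])))
      vox <- which(m)
      if (length(vox) >= 2) {
        pick <- cbind(sample(vox, 30, TRUE), sample(vox, 30, TRUE))
        expect_identical(lab[pick[, 1]] == lab[pick[, 2]],
                         oracle[pick[, 1]] == oracle[pick[, 2]])
      }
      filt <- filter_small_clusters(m, 5, conn)
      if (any(filt))
        expect_true(all(tabulate(oracle[oracle > 0])[unique(oracle[filt])] >= 5))
      # removed components were all small
      removed <- unique(oracle[m & !filt])
      if (length(removed))
        expect_true(all(tabulate(oracle[oracle > 0])[removed] < 5))
    }
  }
})

test_that("nearest-neighbour resampling picks the containing source voxel", {
  d <- c(8, 8, 8)
  m <- random_mask(d, 0.4, seed = 41)
  expect_identical(resample_nn(m, c(1, 1, 1), d, c(1, 1, 1)), m)
  ones <- array(TRUE, d)
  expect_true(all(resample_nn(ones, c(1, 1, 1), c(4, 4, 4), c(2, 2, 2))))

  # 2x downsampling against an exhaustive nearest-center search
  src <- random_mask(c(12, 12, 12), 0.5, seed = 43)
  out <- resample_nn(src, c(1, 1, 1), c(6, 6, 6), c(2, 2, 2))
  src_centers <- lapply(1:3, function(a) (1:12) - 0.5)
  for (v in seq_len(6^3)) {
    ijk <- arrayInd(v, c(6, 6, 6))
    x <- (ijk - 0.5) * 2
    nearest <- vapply(1:3, function(a) {
      dist <- abs(src_centers[[a]] - x[a])
      # ties (center on a voxel boundary) resolve to the containing voxel,
      # i.e. the larger index under the half-open voxel convention
      max(which(dist < min(dist) + 1e-9))
    }, integer(1))
    expect_identical(out[v], src[nearest[1], nearest[2], nearest[3]])
  }
  expect_error(resample_nn(src, c(1, 1, 1), c(5, 5, 5), c(2, 2, 2)),
               "extent")
})

test_that("volumes are voxel counts in mL, computed pre-filter", {
  d <- c(20, 20, 20)
  m <- array(FALSE, d); m[seq_len(1000)] <- TRUE
  vols <- class_volumes(list(a = m, b = array(FALSE, d)), c(1, 1, 1))
  expect_equal(vols$volume_ml, c(1, 0))

  # sphere volume within one voxel-shell of the analytic value
  sp <- wmhtraj:::sphere_mask(d, c(1, 1, 1), c(10, 10, 10), 4)
  v_analytic <- 4 / 3 * pi * 4^3 / 1000
  v_shell <- 4 * pi * 4^2 * 1 / 1000
  expect_lt(abs(class_volumes(list(s = sp), c(1, 1, 1))$volume_ml -
                  v_analytic), v_shell)

  # volumetrics never see the cluster filter
  speck <- array(FALSE, d); speck[1:3, 1, 1] <- TRUE
  full <- sp | speck
  expect_equal(class_volumes(list(x = full), c(1, 1, 1))$volume_ml,
               sum(full) / 1000)
})
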
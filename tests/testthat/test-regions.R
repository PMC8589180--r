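test_that("decompose_regions recovers annulus classes from concentric disks", {
  A <- disk_mask(101, 30); B <- disk_mask(101, 20); C <- disk_mask(101, 10)
  rs <- decompose_regions(A, B, C, scale_mm_per_px = 1)
  ## pixel-count oracle: direct set differences of the inputs
  expect_equal(sum(rs$attn_only), sum(A) - sum(B))
  expect_equal(sum(rs$izloss_only), sum(B) - sum(C))
  expect_equal(sum(rs$C), sum(C))
  expect_equal(rs$clipped_px, c(B = 0, C = 0))
})

test_that("decompose_regions handles full coincidence and is idempotent", {
  A <- disk_mask(51, 15)
  rs <- decompose_regions(A, A, A, scale_mm_per_px = 1)
  expect_false(any(rs$attn_only))
  expect_false(any(rs$izloss_only))
  expect_identical(rs$C, A)
  rs2 <- decompose_regions(rs$A, rs$B, rs$C, scale_mm_per_px = 1)
  expect_identical(rs2$attn_only, rs$attn_only)
  expect_identical(rs2$izloss_only, rs$izloss_only)
  expect_identical(rs2$C, rs$C)
})

test_that("clip policy removes and counts nesting violations; strict errors", {
  A <- disk_mask(61, 20); B <- disk_mask(61, 14)
  C <- disk_mask(61, 7)
  out <- which(!B)[1:5]
  C[out] <- TRUE                      # 5 px of C outside B
  rs <- decompose_regions(A, B, C)
  expect_equal(unname(rs$clipped_px["C"]), 5)
  expect_false(any(rs$C & !B))
  expect_error(decompose_regions(A, B, C, policy = "strict"), "5 px of C")
})

test_that("partition conservation holds exactly for arbitrary masks", {
  for (seed in 1:10) {
    set.seed(seed)
    A <- matrix(runif(40^2) < 0.5, 40, 40)
    B <- matrix(runif(40^2) < 0.5, 40, 40)
    C <- matrix(runif(40^2) < 0.5, 40, 40)
    rs <- decompose_regions(A, B, C, scale_mm_per_px = 3 / 304)
    ## pixel counts partition exactly ...
    expect_identical(sum(rs$attn_only) + sum(rs$izloss_only) + sum(rs$C),
                     sum(rs$A))
    ## ... and so do the physical areas (up to float summation order)
    a <- region_areas(rs)
    expect_equal(area_mm2(rs$A, rs$scale_mm_per_px),
                 a[["attn_mm2"]] + a[["izloss_mm2"]] + a[["ezloss_mm2"]])
  }
})

test_that("area_mm2 converts pixel counts at the physical scale", {
  expect_identical(area_mm2(matrix(FALSE, 10, 10), 3 / 304), 0)
  full <- matrix(TRUE, 304, 304)
  expect_equal(area_mm2(full, 3 / 304), 9)
  m <- matrix(FALSE, 304, 304); m[seq_len(1000)] <- TRUE
  expect_equal(area_mm2(m, 3 / 304), 1000 * (3 / 304)^2)
  expect_equal(round(area_mm2(m, 3 / 304), 4), 0.0974)
})

test_that("percent_overlap counts shared pixels relative to telangiectasia", {
  tel <- matrix(FALSE, 30, 30); tel[1:20, 1:10] <- TRUE    # 200 px
  expect_equal(percent_overlap(tel, matrix(TRUE, 30, 30)), 100)
  expect_equal(percent_overlap(tel, !tel), 0)
  region <- matrix(FALSE, 30, 30); region[which(tel)[1:37]] <- TRUE  # 37 px inside tel
  expect_equal(percent_overlap(tel, region), 18.5)
  expect_warning(p <- percent_overlap(matrix(FALSE, 5, 5), matrix(TRUE, 5, 5)),
                 "empty telangiectasia")
  expect_true(is.na(p))
})

test_that("exclusive-class overlaps sum to at most 100", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- random_blob(40, seed); B <- A & random_blob(40, seed + 50)
    C <- B & random_blob(40, seed + 100)
    tel <- random_blob(40, seed + 200)
    if (!any(tel)) next
    rs <- decompose_regions(A, B, C, scale_mm_per_px = 1)
    s <- percent_overlap(tel, rs$attn_only) + percent_overlap(tel, rs$izloss_only) +
      percent_overlap(tel, rs$C)
    expect_lte(s, 100 + 1e-9)
  }
})

test_that("pool_stage maps 0-2/3-5/6 to early/moderate/advanced", {
  expect_identical(as.character(pool_stage(c(0, 1, 2))), rep("early", 3))
  expect_identical(as.character(pool_stage(c(3, 4, 5))), rep("moderate", 3))
  expect_identical(as.character(pool_stage(6)), "advanced")
  expect_error(pool_stage(7), "0..6")
  expect_error(pool_stage(-1), "0..6")
})

test_that("eye_record is consistent with its inputs", {
  A <- disk_mask(101, 30); B <- disk_mask(101, 20); C <- disk_mask(101, 10)
  rs <- decompose_regions(A, B, C, scale_mm_per_px = 3 / 304)
  tel <- disk_mask(101, 8)            # inside C
  rec <- eye_record("P1", "E1", "OD", 4, tel, rs)
  expect_identical(rec$pooled_group, "moderate")
  expect_equal(rec$overlap_ezloss_pct, 100)
  expect_equal(rec$tel_area_mm2, area_mm2(tel, 3 / 304))
  ## absent telangiectasia: overlaps undefined
  rec0 <- suppressWarnings(
    eye_record("P1", "E2", "OS", 6, matrix(FALSE, 101, 101), rs))
  expect_true(is.na(rec0$overlap_attn_pct))
  expect_equal(rec0$tel_area_mm2, 0)
})

test_that("polygon rasterization uses pixel centres with the even-odd rule", {
  sq <- rbind(c(0.5, 0.5), c(4.5, 0.5), c(4.5, 4.5), c(0.5, 4.5))
  m <- rasterize_polygon(sq, 8, 8)
  expect_equal(sum(m), 16)                       # centres 1..4 in both axes
  expect_true(all(which(m, arr.ind = TRUE) >= 2 & which(m, arr.ind = TRUE) <= 5))
})
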
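test_that("generated scenes nest C in B in A exactly, for every group", {
  for (g in c("early", "moderate", "advanced")) {
    for (seed in c(2, 19)) {
      tr <- generate_scene(scene_params(g, seed = seed))$truth
      expect_true(all(tr$region_combined_B[tr$region_ez_C]))
      expect_true(all(tr$region_combined_A[tr$region_combined_B]))
    }
  }
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generate_scene(scene_params("moderate", seed = 5))
  b <- generate_scene(scene_params("moderate", seed = 5))
  expect_identical(unclass(a$dcp), unclass(b$dcp))
  expect_identical(unclass(a$scp), unclass(b$scp))
  expect_identical(unclass(a$slab), unclass(b$slab))
  expect_identical(a$truth, b$truth)
  c2 <- generate_scene(scene_params("moderate", seed = 6))
  expect_false(identical(unclass(a$dcp), unclass(c2$dcp)))
})

test_that("zero target areas give empty truth and an undepressed slab", {
  sp <- scene_params("early",
                     target_areas_mm2 = list(attn = c(0, 0), izloss = c(0, 0),
                                             ezloss = c(0, 0)),
                     telangiectasia_area_mm2 = c(0, 0),
                     overlap_fractions_sd = c(attn = 0, izloss = 0, ezloss = 0),
                     noise_level = 0, seed = 1)
  sc <- generate_scene(sp)
  expect_false(any(sc$truth$telangiectasia))
  expect_false(any(sc$truth$region_combined_A))
  expect_true(all(unclass(sc$slab) == 0.7))
})

test_that("oversized targets are a parameter error", {
  expect_error(scene_params("early",
                            target_areas_mm2 = list(attn = c(10, 0))),
               "out of")
})

test_that("sampled truth areas track the configured group targets", {
  ## convergence of seed-averaged truth areas to the configured means
  n_seed <- 30
  tel <- ez <- numeric(n_seed)
  for (s in seq_len(n_seed)) {
    sc <- generate_scene(scene_params("advanced", seed = 1000 + s))
    sc_mm <- scale_mm_per_px(sc$dcp)
    tel[s] <- area_mm2(sc$truth$telangiectasia, sc_mm)
    ez[s] <- area_mm2(sc$truth$region_ez_C, sc_mm)
  }
  expect_lte(abs(mean(tel) - 0.561), 2 * sd(tel) / sqrt(n_seed))
  expect_lte(abs(mean(ez) - 1.091), 2 * sd(ez) / sqrt(n_seed))
})

test_that("rendered telangiectasia footprint matches its sampled target", {
  for (seed in c(3, 13, 23)) {
    sc <- generate_scene(scene_params("advanced", seed = seed))
    got <- area_mm2(sc$truth$telangiectasia, scale_mm_per_px(sc$dcp))
    expect_lte(abs(got / sc$sampled_areas_mm2[["tel"]] - 1), 0.10)
  }
})

test_that("truth overlap fractions realize the per-scene sampled fractions", {
  for (seed in c(7, 17)) {
    sc <- generate_scene(scene_params("moderate", seed = seed))
    tr <- sc$truth; tel <- tr$telangiectasia
    real <- c(sum(tel & tr$region_combined_A & !tr$region_combined_B),
              sum(tel & tr$region_combined_B & !tr$region_ez_C),
              sum(tel & tr$region_ez_C)) / sum(tel)
    expect_lt(max(abs(real - sc$sampled_overlap_fractions)), 0.05)
  }
})

test_that("slab reflectivity is ordered over the disruption classes", {
  sc <- generate_scene(scene_params("advanced", seed = 2))
  tr <- sc$truth; slab <- unclass(sc$slab)
  a_only <- tr$region_combined_A & !tr$region_combined_B
  i_only <- tr$region_combined_B & !tr$region_ez_C
  speckle_sd <- 0.1 * 0.7
  expect_gt(mean(slab[!tr$region_combined_A]) - mean(slab[a_only]), speckle_sd)
  expect_gt(mean(slab[a_only]) - mean(slab[i_only]), speckle_sd)
  expect_gt(mean(slab[i_only]) - mean(slab[tr$region_ez_C]), speckle_sd)
})

base_scene <- generate_scene(longitudinal_scene_params(seed = 8))

test_that("identity longitudinal parameters reproduce the baseline exactly", {
  lp <- longitudinal_params(deformation_amplitude_px = 0,
                            new_ez_area_mm2 = c(0, 0),
                            recovery_area_mm2 = c(0, 0), seed = 1)
  pair <- generate_longitudinal(base_scene, lp)
  expect_identical(pair$followup$truth$region_ez_C,
                   base_scene$truth$region_ez_C)
  expect_false(any(pair$new_ez_true))
  expect_false(any(pair$recovery_true))
  expect_true(all(pair$field$dx == 0))
})

test_that("containment_fraction = 1 places all new EZ loss inside baseline IZ loss", {
  lp <- longitudinal_params(containment_fraction = 1, seed = 4)
  pair <- generate_longitudinal(base_scene, lp)
  izonly_w <- warp_mask(base_scene$truth$region_combined_B &
                          !base_scene$truth$region_ez_C, pair$field)
  expect_true(all(izonly_w[pair$new_ez_true]))
})

test_that("follow-up truth stays nested and stores a retrievable field", {
  pair <- generate_longitudinal(base_scene, longitudinal_params(seed = 21))
  tr <- pair$followup$truth
  expect_true(all(tr$region_combined_B[tr$region_ez_C]))
  expect_true(all(tr$region_combined_A[tr$region_combined_B]))
  ## warp with the stored field then its numerical inverse: >= 99% agreement
  m <- base_scene$truth$region_combined_B
  back <- warp_mask(warp_mask(m, pair$field), pair$field_inverse)
  expect_gte(mean(back == m), 0.99)
  ## follow-up EZ equals warped baseline EZ + new - recovery
  want <- (warp_mask(base_scene$truth$region_ez_C, pair$field) |
             pair$new_ez_true) & !pair$recovery_true
  expect_identical(tr$region_ez_C, want)
})

test_that("sampled new EZ-loss areas average to the configured 0.052 mm^2", {
  n_seed <- 30
  s_mm <- scale_mm_per_px(base_scene$dcp)
  areas <- vapply(seq_len(n_seed), function(s) {
    pair <- generate_longitudinal(base_scene, longitudinal_params(seed = 3000 + s))
    area_mm2(pair$new_ez_true, s_mm)
  }, 0)
  expect_lte(abs(mean(areas) - 0.052),
             2 * sd(areas) / sqrt(n_seed) + 0.002)  # small placement quantization
})

test_that("infeasible containment is a parameter error", {
  tiny_iz <- generate_scene(scene_params(
    "early",
    target_areas_mm2 = list(attn = c(0.4, 0), izloss = c(0.005, 0),
                            ezloss = c(0, 0)),
    seed = 2))
  lp <- longitudinal_params(new_ez_area_mm2 = c(0.5, 0),
                            containment_fraction = 1, seed = 1)
  expect_error(generate_longitudinal(tiny_iz, lp), "exceeds available")
})

test_that("cohort manifests group eyes under patients with consistent stages", {
  coh1 <- generate_cohort(1, seed = 3)
  expect_equal(nrow(coh1$manifest), 3)
  expect_setequal(as.character(coh1$manifest$pooled_group),
                  c("early", "moderate", "advanced"))

  coh <- generate_cohort(10, seed = 3)
  m <- coh$manifest
  expect_true(all(table(m$patient_id) <= 2))
  expect_true(any(table(m$patient_id) == 2))   # some patients give both eyes
  expect_identical(as.character(pool_stage(m$stage)),
                   as.character(m$pooled_group))
  expect_equal(unname(table(m$pooled_group)["early"]), 10)
  ## two eyes of one patient have distinct lateralities
  for (p in unique(m$patient_id)) {
    eyes <- m[m$patient_id == p, ]
    if (nrow(eyes) == 2) expect_setequal(eyes$laterality, c("OD", "OS"))
  }
  coh_b <- generate_cohort(10, seed = 3)
  expect_identical(coh$manifest, coh_b$manifest)
})
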
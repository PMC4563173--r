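test_that("the noiseless limit yields exactly three CT and PET values", {
  spec <- small_phantom_spec(seed = 1,
                             hu_cortical = c(1200, 0), hu_trabecular = c(150, 0),
                             hu_soft_tissue = c(40, 0),
                             suv_red = c(2, 0), suv_yellow = c(0.4, 0),
                             suv_background = c(0.1, 0), blur_fwhm_mm = 0)
  ph <- generate_phantom(spec)
  expect_setequal(unique(as.vector(ph$ct$data)), c(40, 150, 1200))
  expect_setequal(unique(as.vector(ph$pet$data)), c(0.1, 0.4, 2))
})

test_that("boundary red fractions empty the other compartment", {
  f1 <- c(vertebra_thoracic = 1, vertebra_lumbar = 1, long_bone = 1,
          skull = 1, pelvis = 1)
  ph1 <- generate_phantom(small_phantom_spec(seed = 2, red_fraction = f1))
  expect_false(any(ph1$truth_yellow))
  expect_identical(ph1$truth_red, ph1$truth_trabecular)
  ph0 <- generate_phantom(small_phantom_spec(seed = 2, red_fraction = 0 * f1))
  expect_false(any(ph0$truth_red))
})

test_that("truth masks partition and ROI labels cover the skeleton", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  expect_identical(ph$truth_red | ph$truth_yellow, ph$truth_trabecular)
  expect_false(any(ph$truth_red & ph$truth_yellow))
  expect_false(any(ph$truth_cortical & ph$truth_trabecular))
  expect_identical(ph$truth_skeleton, ph$truth_cortical | ph$truth_trabecular)
  expect_true(all(ph$roi_labels[ph$truth_skeleton] > 0))
  expect_true(all(ph$roi_labels[!ph$truth_skeleton] == 0))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_phantom_spec(seed = 11))
  b <- generate_phantom(small_phantom_spec(seed = 11))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$pet$data, b$pet$data)
  c2 <- generate_phantom(small_phantom_spec(seed = 12))
  expect_false(identical(a$ct$data, c2$ct$data))
})

test_that("a wide vertebral column realises a 0.60 fraction within 0.01", {
  el <- list(bone_element("cylinder", c(48, 48, 50), c(40, 40), 4,
                          "vertebra_lumbar"))
  spec <- phantom_spec(shape = c(48, 48, 50), spacing_mm = c(2, 2, 2),
                       elements = el,
                       red_fraction = c(vertebra_lumbar = 0.60), seed = 4)
  ph <- generate_phantom(spec)
  achieved <- sum(ph$truth_red) / sum(ph$truth_trabecular)
  expect_lt(abs(achieved - 0.60), 0.01)
  expect_equal(ph$achieved_red_fraction[1], achieved)
})

test_that("the red/yellow split is spatially coherent along z", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  # within each connected trabecular core, every red voxel lies at or below
  # the lowest yellow voxel's slab (axial gradient split)
  lab <- label_components(ph$truth_trabecular, 26)
  for (comp in seq_len(max(lab))) {
    sel <- lab == comp
    zr <- arrayInd(which(sel & ph$truth_red), dim(lab))[, 3]
    zy <- arrayInd(which(sel & ph$truth_yellow), dim(lab))[, 3]
    if (length(zr) && length(zy)) expect_lte(max(zr), min(zy) + 1)
  }
})

test_that("overlapping bone elements are rejected", {
  els <- list(bone_element("box", c(40, 40, 40), c(20, 20, 20), 4, "pelvis"),
              bone_element("box", c(50, 50, 50), c(20, 20, 20), 4, "pelvis"))
  spec <- phantom_spec(shape = c(48, 48, 48), spacing_mm = c(2, 2, 2),
                       elements = els, seed = 1)
  expect_error(generate_phantom(spec), "overlaps")
})

test_that("spec invariants are enforced", {
  el <- list(bone_element("box", c(40, 40, 40), c(10, 10, 10), 2, "pelvis"))
  expect_error(phantom_spec(elements = el, hu_cortical = c(100, 10)),
               "ordered")
  expect_error(phantom_spec(elements = el, suv_red = c(0.3, 0)), "red > yellow")
  expect_error(phantom_spec(elements = el,
                            red_fraction = c(pelvis = 1.2)), "0, 1")
  expect_error(phantom_spec(elements = el, red_fraction = c(skull = 0.5)),
               "no red fraction")
  expect_error(bone_element("cylinder", c(0, 0, 0), c(5, 5), 6, "skull"),
               "shell")
})

test_that("ground-truth report counts voxels exactly and conserves volume", {
  ph <- generate_phantom(small_phantom_spec(seed = 6))
  rep0 <- ground_truth_report(ph)
  expect_equal(rep0$rbv_ml + rep0$ybv_ml, rep0$ibv_ml)
  expect_equal(rep0$rbv_ml, sum(ph$truth_red) * 8 / 1000)
  # direct-count example: 500 + 500 voxels at 1 mm^3
  fake <- ph
  fake$spec$spacing_mm <- c(1, 1, 1)
  fake$truth_red <- array(FALSE, dim(ph$roi_labels))
  fake$truth_red[seq_len(500)] <- TRUE
  fake$truth_yellow <- array(FALSE, dim(ph$roi_labels))
  fake$truth_yellow[500 + seq_len(500)] <- TRUE
  fake$truth_trabecular <- fake$truth_red | fake$truth_yellow
  r <- ground_truth_report(fake)
  expect_equal(r$rbv_ml, 0.5)
  expect_equal(r$ybv_ml, 0.5)
  expect_equal(r$red_fraction, 0.5)
})

test_that("a noiseless phantom is classified perfectly by the trained LDA", {
  spec <- small_phantom_spec(seed = 8,
                             hu_cortical = c(1200, 0), hu_trabecular = c(150, 0),
                             hu_soft_tissue = c(40, 0), blur_fwhm_mm = 0)
  ph <- generate_phantom(spec)
  # delta-distributed classes: add minimal jitter-free training via the two
  # distinct values (pooled variance must be > 0, so train on noisy labels)
  tr <- training_set(c(1200, 1200, 1199, 150, 150, 151),
                     c("C", "C", "C", "T", "T", "T"))
  bone <- extract_bone_mask(ph$ct, 100, 0)
  cm <- classify_compartments(posterior_map(train_lda(tr), ph$ct, bone))
  expect_identical(cm$cortical & ph$truth_skeleton, ph$truth_cortical)
  expect_identical(cm$trabecular & ph$truth_skeleton, ph$truth_trabecular)
})

test_that("phantom specs round-trip through YAML", {
  spec <- small_phantom_spec(seed = 21)
  y <- list(shape = spec$shape, spacing_mm = spec$spacing_mm,
            hu_cortical = spec$hu_cortical, hu_trabecular = spec$hu_trabecular,
            hu_soft_tissue = spec$hu_soft_tissue, suv_red = spec$suv_red,
            suv_yellow = spec$suv_yellow, suv_background = spec$suv_background,
            red_fraction = as.list(spec$red_fraction),
            blur_fwhm_mm = spec$blur_fwhm_mm, seed = spec$seed,
            elements = lapply(spec$elements, function(e)
              list(shape = e$shape, center_mm = e$center_mm,
                   size_mm = e$size_mm, shell_mm = e$shell_mm, tag = e$tag)))
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, f)
  spec2 <- phantom_spec_from_yaml(f)
  expect_identical(generate_phantom(spec2)$ct$data,
                   generate_phantom(spec)$ct$data)
})
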
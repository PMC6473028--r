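test_that("bundled atlas has 90 regions split 45/45 by hemisphere", {
  atlas <- aal90_atlas()
  expect_equal(nrow(atlas), 90)
  expect_equal(unname(table(atlas$hemisphere)["L"]), 45)
  expect_equal(unname(table(atlas$hemisphere)["R"]), 45)
  expect_true("MTG.R" %in% atlas$abbrev)
  expect_false(any(duplicated(atlas$roi_id)))
})

test_that("atlas validation rejects duplicates and bad hemisphere codes", {
  atlas <- aal90_atlas()
  path <- withr::local_tempfile(fileext = ".tsv")
  bad <- atlas
  bad$roi_id[2] <- bad$roi_id[1]
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_atlas(path), as.character(atlas$roi_id[1]))

  bad <- atlas
  bad$hemisphere[5] <- "X"
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_atlas(path), "X")
})

test_that("hemisphere is parsed from abbreviation suffix when absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(roi_id = 1:4, abbrev = c("A.L", "A.R", "B.L", "B.R"))
  write.csv(df, path, row.names = FALSE)
  atlas <- load_atlas(path)
  expect_equal(atlas$hemisphere, c("L", "R", "L", "R"))
})

test_that("ROI tables round-trip through disk with atlas reordering", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 6), seed = 3))
  tab <- cohort$tables$HC
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(tab, path)
  back <- read_roi_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12,
               ignore_attr = TRUE)

  # permute ROI columns: values preserved, order restored to atlas order
  atlas <- aal90_atlas()
  perm <- sample(atlas$abbrev)
  write_roi_table(tab[, c("subject_id", "group", "age", "sex", perm)], path)
  back2 <- read_roi_table(path)
  expect_equal(names(back2), names(tab))
  for (ab in atlas$abbrev) expect_equal(back2[[ab]], tab[[ab]])
})

test_that("table validation flags zero-variance ROIs and missing columns", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 6), seed = 4))
  tab <- cohort$tables$HC
  tab$PreCG.L <- 1
  expect_warning(out <- validate_roi_table(tab), "PreCG.L")
  expect_equal(attr(out, "zero_variance"), "PreCG.L")
  expect_error(validate_roi_table(tab[, -2]), "group")
})

test_that("ROI mean extraction matches an explicit voxel loop", {
  atlas <- aal90_atlas()[1:4, ]
  dims <- c(6, 5, 4)
  set.seed(9)
  labels <- array(sample(0:4, prod(dims), replace = TRUE), dims)
  for (id in atlas$roi_id) labels[id] <- id # ensure all labels present
  img <- array(rnorm(prod(dims)), dims)

  means <- extract_roi_means(img, labels, atlas)
  manual <- sapply(atlas$roi_id, function(id) {
    acc <- 0; cnt <- 0
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
      if (labels[i, j, k] == id) { acc <- acc + img[i, j, k]; cnt <- cnt + 1 }
    }
    acc / cnt
  })
  expect_equal(unname(means), manual, tolerance = 1e-12)

  # constant image -> every mean equals the constant
  expect_equal(unname(extract_roi_means(array(7, dims), labels, atlas)),
               rep(7, 4))
  # image equal to label -> mean equals roi_id
  expect_equal(unname(extract_roi_means(labels * 1.0, labels, atlas)),
               as.numeric(atlas$roi_id))
  # missing label is named in the error
  labels2 <- labels
  labels2[labels2 == 3] <- 0
  expect_error(extract_roi_means(img, labels2, atlas), "3")
  expect_error(extract_roi_means(img[1:3, , ], labels, atlas), "grids differ")
})

test_that("NIfTI volumes are read for extraction", {
  atlas <- aal90_atlas()[1:2, ]
  labels <- array(rep(c(1L, 2L), each = 12), c(4, 3, 2))
  img <- array(seq_len(24), c(4, 3, 2))
  dir <- withr::local_tempdir()
  fi <- file.path(dir, "img.nii.gz")
  fl <- file.path(dir, "lab.nii.gz")
  RNifti::writeNifti(img, fi)
  RNifti::writeNifti(labels, fl)
  means <- extract_roi_means(fi, fl, atlas)
  expect_equal(unname(means), c(mean(1:12), mean(13:24)))
})
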
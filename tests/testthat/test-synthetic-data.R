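test_that("sparse annotation geometry gives the expected unlabeled pool", {
  vol <- generate_volume(default_class_specs(4), n_slices = 21, shape = c(32, 32),
                         n_labeled = 3, neighbour_window = 3, seed = 5)
  expect_length(vol$labeled_slice_indices, 3L)
  expect_length(vol$unlabeled_slice_indices, 18L)  # 3 x 6 neighbours, disjoint
  expect_length(intersect(vol$labeled_slice_indices, vol$unlabeled_slice_indices), 0L)
  ## labeled slices are evenly spaced
  expect_true(length(unique(diff(vol$labeled_slice_indices))) == 1L)

  expect_error(generate_volume(default_class_specs(4), n_slices = 10,
                               n_labeled = 3, neighbour_window = 3),
               "infeasible")
  expect_error(texture_class_spec(0L, 0.5, "swirl"), "arg")
  expect_error(generate_volume(list(), 21), "non-empty")
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_volume(default_class_specs(4), n_slices = 14, shape = c(32, 32),
                       n_labeled = 2, seed = 17)
  b <- generate_volume(default_class_specs(4), n_slices = 14, shape = c(32, 32),
                       n_labeled = 2, seed = 17)
  expect_identical(a, b)
  c <- generate_volume(default_class_specs(4), n_slices = 14, shape = c(32, 32),
                       n_labeled = 2, seed = 18)
  expect_false(identical(a$slices, c$slices))
})

test_that("labels cover the ROI and the ignore value covers its complement", {
  vol <- generate_volume(default_class_specs(4), seed = 9)
  for (s in seq_along(vol$slices)) {
    lab <- vol$dense_labels[[s]]; roi <- vol$roi_masks[[s]]
    expect_true(all(lab[roi == 1] %in% 0:3))
    expect_true(all(lab[roi == 0] == ignore_label()))
  }
  ## every labeled slice shows at least 2 classes inside the ROI
  for (s in vol$labeled_slice_indices) {
    lab <- vol$dense_labels[[s]]
    expect_gte(length(unique(lab[lab != ignore_label()])), 2L)
  }
})

test_that("class region means stay close to the configured base intensity", {
  specs <- default_class_specs(4)
  vol <- generate_volume(specs, seed = 31)
  for (s in vol$labeled_slice_indices) {
    img <- vol$slices[[s]]; lab <- vol$dense_labels[[s]]
    for (spec in specs) {
      px <- img[lab == spec$class_id]
      if (length(px) < 30) next
      tol <- 3 * spec$noise_sd / sqrt(length(px))
      expect_lt(abs(mean(px) - spec$base_intensity), tol)
    }
  }
})

test_that("adjacent slices are strongly correlated, distant ones less so", {
  vol <- generate_volume(default_class_specs(4), seed = 12)
  lab_match <- function(i, j) {
    a <- vol$dense_labels[[i]]; b <- vol$dense_labels[[j]]
    keep <- a != ignore_label()
    mean(a[keep] == b[keep])
  }
  expect_gt(lab_match(10, 11), 0.8)
  expect_gt(lab_match(10, 11), lab_match(4, 25))
})

test_that("volume-level split keeps partitions disjoint and unlabeled larger", {
  vols <- lapply(1:5, function(k)
    generate_volume(default_class_specs(4), n_slices = 14, shape = c(32, 32),
                    n_labeled = 2, seed = 40 + k))
  st <- make_split(vols, ratios = c(3, 1, 1))
  part <- attr(st, "volume_partition")
  expect_identical(sort(unique(part)), c("test", "train", "val"))
  expect_identical(sum(part == "train"), 3L)
  ## no record id appears in two partitions
  ids <- list(names(st$labeled), names(st$unlabeled),
              vapply(st$val, `[[`, "", "id"), vapply(st$test, `[[`, "", "id"))
  all_ids <- unlist(ids)
  expect_identical(anyDuplicated(all_ids), 0L)
  ## volume prefixes never straddle partitions
  vol_of <- function(x) sub("_.*", "", x)
  train_vols <- union(vol_of(ids[[1]]), vol_of(ids[[2]]))
  expect_length(intersect(train_vols, vol_of(ids[[3]])), 0L)
  expect_length(intersect(train_vols, vol_of(ids[[4]])), 0L)
  ## more unlabeled than labeled slices (N > M)
  expect_gt(length(st$unlabeled), length(st$labeled))
  expect_error(make_split(vols[1:2]), "at least 3")
})

test_that("the default benchmark has the documented geometry", {
  data <- default_benchmark(seed = 2)
  expect_length(data$labeled, 20L)
  expect_length(data$unlabeled, 120L)
  expect_length(data$val, 8L)
  expect_length(data$test, 8L)
  expect_gt(length(data$unlabeled), length(data$labeled))
})
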
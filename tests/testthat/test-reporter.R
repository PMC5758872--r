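test_that("projection selects the in-focus window and takes elementwise maxima", {
  one <- array(runif(16), dim = c(4, 4, 1))
  p <- project(one, window = 1)
  expect_equal(unclass(p), one[, , 1], ignore_attr = TRUE)

  stack <- array(1, dim = c(4, 4, 15))
  stack[, , 7] <- 50  # dominant slice
  p <- project(stack, window = 4)
  w <- attr(p, "window")
  expect_true(w[1] <= 7 && 7 <= w[2])
  expect_equal(max(p), 50)
  expect_error(project(array(0, dim = c(2, 2, 2)), window = 4), "window")
  expect_error(project(list()), "non-empty")

  # synthetic stack: selected window equals the planted focus block
  co <- gen_embryo_cohort(n_per_cell = 1, stages = "1K", groups = "g",
                          ratio_per_group = c(g = 1), noise_cv = 0, seed = 23)
  e <- co$embryos[[1]]
  expect_equal(attr(project(e$rfp), "window")[1], co$truth$focus_start[1])
})

test_that("ROI segmentation keeps the largest suprathreshold component", {
  expect_error(segment_roi(matrix(0, 8, 8)), "no segmentable|uniform")
  plane <- matrix(10, 32, 32)
  plane[5:10, 5:10] <- 1000       # small blob
  plane[15:30, 15:30] <- 1000     # large blob
  mask <- segment_roi(plane)
  expect_true(all(mask[15:30, 15:30]))
  expect_false(any(mask[5:10, 5:10]))
  # disc recovered within tolerance on generated data
  co <- gen_embryo_cohort(n_per_cell = 1, stages = "1K", groups = "g",
                          ratio_per_group = c(g = 1.2), noise_cv = 0, seed = 23)
  e <- co$embryos[[1]]
  mask <- segment_roi(project(e$rfp))
  expect_lt(abs(sum(mask) - co$truth$roi_area[1]) / co$truth$roi_area[1], 0.02)
})

test_that("measurement arithmetic, flagging and ratio invariance hold", {
  co <- gen_embryo_cohort(n_per_cell = 1, stages = "1K",
                          groups = c("a", "b"),
                          ratio_per_group = c(a = 0.5, b = 1.5),
                          noise_cv = 0, seed = 23)
  meas <- measure_cohort(co$embryos, co$controls)
  truth <- co$truth
  expect_true(all(meas$valid))
  expect_lt(max(abs(meas$ratio - truth$ratio) / truth$ratio), 0.02)

  # multiplying both channels by a common factor leaves the ratio unchanged
  e <- co$embryos[[1]]
  e2 <- e; e2$gfp <- e$gfp * 3; e2$rfp <- e$rfp * 3
  c2 <- lapply(co$controls, function(ct) {
    ct$gfp <- ct$gfp * 3; ct$rfp <- ct$rfp * 3; ct
  })
  r1 <- measure(e, co$controls)$ratio
  r2 <- measure(e2, c2)$ratio
  expect_lt(abs(r1 - r2), 1e-9)

  # zero GFP amplitude measures a ratio of ~0
  co0 <- gen_embryo_cohort(n_per_cell = 1, stages = "1K", groups = "null",
                           ratio_per_group = c(null = 0), noise_cv = 0, seed = 5)
  m0 <- measure_cohort(co0$embryos, co0$controls)
  expect_lt(abs(m0$ratio), 1e-9)

  # background equal to signal in both channels is flagged, not dropped
  flat <- list(embryo_id = "flat", group = "g", stage = "s",
               gfp = array(400, dim = c(16, 16, 15)),
               rfp = array(400, dim = c(16, 16, 15)))
  mf <- measure(flat, co$controls)
  expect_false(mf$valid)
})

test_that("TIFF serialization round-trips through the sample-sheet pipeline", {
  co <- gen_embryo_cohort(n_per_cell = 1, stages = c("1K", "sphere"),
                          groups = "g", ratio_per_group = c(g = 1.3),
                          dim_yx = c(48L, 48L), noise_cv = 0, seed = 23)
  in_mem <- measure_cohort(co$embryos, co$controls)
  dir <- tempfile("cohort")
  sheet <- write_embryo_cohort(co, dir)
  from_disk <- quantify_cohort(sheet)
  expect_equal(sort(from_disk$ratio), sort(in_mem$ratio), tolerance = 1e-6)
})

test_that("two-way ANOVA with Bonferroni contrasts validates design and detects effects", {
  m <- gen_ratio_cohort(c(mut = 1.5, ctl = 1.0), n_per_cell = 34, cv = 0.2,
                        seed = 29)
  st <- compare_groups(m)
  expect_equal(st$anova$term, c("group", "stage", "group:stage", "Residuals"))
  expect_lt(st$anova$p[1], 0.05)
  expect_equal(nrow(st$contrasts), 3L)       # one contrast per stage
  expect_true(all(st$contrasts$p_bonferroni >= st$contrasts$p - 1e-15))
  expect_true(all(st$contrasts$significant))

  # single embryo in a cell is a validation error naming the cell
  bad <- m[!(m$group == "mut" & m$stage == "sphere" &
             seq_len(nrow(m)) %in% which(m$group == "mut" & m$stage == "sphere")[-1]), ]
  expect_error(compare_groups(bad), "fewer than 2")
  expect_error(compare_groups(m[m$group == "mut", ]), "at least 2 groups")

  # determinism: identical inputs give identical tables
  st2 <- compare_groups(m)
  expect_identical(st$anova, st2$anova)
  expect_identical(st$contrasts, st2$contrasts)
})
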
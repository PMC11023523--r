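test_that("the eight-neighbor winding number classifies canonical fields", {
  g <- field_grid(21, 21, 66)
  ctr <- c(g$xs[11] + 33, g$ys[11] + 33)
  uniform <- compose_defect_field(defect_spec(0, 0, 1)[0, ], g)
  expect_equal(winding_number(uniform, 11, 11), 0)
  vortex <- compose_defect_field(defect_spec(ctr[1], ctr[2], 1, pi / 2), g)
  expect_equal(winding_number(vortex, 11, 11), 1)
  # clockwise spin is still a +1 defect
  cw <- compose_defect_field(defect_spec(ctr[1], ctr[2], 1, -pi / 2), g)
  expect_equal(winding_number(cw, 11, 11), 1)
  saddle <- compose_defect_field(defect_spec(ctr[1], ctr[2], -1, 0), g)
  expect_equal(winding_number(saddle, 11, 11), -1)
  # a double vortex (theta = 2 atan2) is reported verbatim, not clamped;
  # the core sits exactly on a node so the surrounding ring subtends the
  # direction change in even 90-degree steps
  xy <- expand.grid(x = g$xs, y = g$ys)
  th2 <- 2 * atan2(xy$y - g$ys[11], xy$x - g$xs[11])
  double <- velocity_field(xy$x, xy$y, 35 * cos(th2), 35 * sin(th2))
  expect_equal(winding_number(double, 11, 11), 2)
  det2 <- detect_frame(double)
  expect_true(2 %in% det2$charge)
  expect_true(is.na(winding_number(vortex, 1, 1)))
})

test_that("same-charge detections merge below the 165-um radius", {
  g <- field_grid(40, 21, 66)
  y0 <- g$ys[11] + 33
  far <- compose_defect_field(
    dplyr::bind_rows(defect_spec(g$xs[8] + 33, y0, 1, pi / 2),
                     defect_spec(g$xs[8] + 33 + 1000, y0, -1, 0)), g)
  det <- detect_frame(far)
  expect_equal(nrow(det), 2)
  expect_setequal(det$charge, c(-1, 1))
  # two +1 detections 100 um apart collapse to a single defect
  pts <- tibble::tibble(x_um = c(0, 100), y_um = c(0, 0), charge = c(1L, 1L))
  lab <- defectflow:::single_linkage(pts$x_um, pts$y_um, 165)
  expect_equal(length(unique(lab)), 1)
  uniform <- compose_defect_field(defect_spec(0, 0, 1)[0, ], g)
  expect_equal(nrow(detect_frame(uniform)), 0)
})

test_that("persistence filtering keeps only corroborated defects", {
  params <- detection_params()
  rec <- function(frame, x, charge = 1L)
    tibble::tibble(frame = as.integer(frame), t_h = frame / 4, x_um = x,
                   y_um = 0, charge = as.integer(charge), cluster_size = 1L)
  # present in a single frame -> removed
  blip <- dplyr::bind_rows(rec(1, 0), rec(3, 5000))
  expect_equal(nrow(filter_persistent(blip, params, all_frames = 1:3)), 0)
  # two consecutive frames -> kept in both
  pair <- dplyr::bind_rows(rec(1, 0), rec(2, 50))
  expect_equal(nrow(filter_persistent(pair, params, all_frames = 1:3)), 2)
  # opposite charge nearby does not corroborate
  opp <- dplyr::bind_rows(rec(1, 0, 1L), rec(2, 50, -1L))
  expect_equal(nrow(filter_persistent(opp, params, all_frames = 1:2)), 0)
  # ten frames with jitter below the link radius -> all kept
  jit <- dplyr::bind_rows(lapply(1:10, function(f) rec(f, 30 * f)))
  expect_equal(nrow(filter_persistent(jit, params, all_frames = 1:10)), 10)
})

test_that("defect counts balance on far-field-uniform fields", {
  g <- field_grid(30, 30, 66)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      repeat {
        xs <- runif(4, g$xs[6], g$xs[25]); ys <- runif(4, g$ys[6], g$ys[25])
        if (min(stats::dist(cbind(xs, ys))) > 5 * g$spacing) break
      }
    })
    defs <- dplyr::bind_rows(lapply(1:4, function(i)
      defect_spec(xs[i], ys[i], c(1, -1, 1, -1)[i], if (i %% 2) pi / 2 else 0)))
    det <- detect_frame(compose_defect_field(defs, g))
    expect_equal(sum(det$charge > 0), sum(det$charge < 0))
    expect_equal(sum(det$charge), 0)
  }
})

test_that("density series counts charges per frame and per area", {
  empty <- detect_defects(
    compose_defect_field(defect_spec(0, 0, 1)[0, ], field_grid(10, 10, 66)),
    detection_params(min_persistence_frames = 1))
  dens0 <- density_series(empty, domain_area_um2 = 1e6)
  expect_equal(dens0$n_plus, 0)
  expect_equal(dens0$n_minus, 0)
  g <- field_grid(30, 30, 66)
  defs <- dplyr::bind_rows(defect_spec(g$xs[9] + 33, g$ys[9] + 33, 1, pi / 2),
                           defect_spec(g$xs[22] + 33, g$ys[22] + 33, -1, 0))
  fld <- compose_defect_field(defs, g)
  det <- detect_defects(fld, detection_params(min_persistence_frames = 1))
  dens <- density_series(det, domain_area_um2 = 2e6)
  expect_equal(dens$n_plus, 1)
  expect_equal(dens$n_minus, 1)
  expect_equal(dens$dens_total_mm2, 1)       # 2 defects over 2 mm^2
})
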
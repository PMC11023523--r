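# build a defect tibble from a list of per-track position series
toy_defects <- function(tracks) {
  dplyr::bind_rows(lapply(tracks, function(tr) {
    tibble::tibble(frame = tr$frames, t_h = tr$frames * 0.25,
                   x_um = tr$x, y_um = tr$y,
                   charge = as.integer(tr$charge), cluster_size = 1L)
  }))
}

test_that("linking follows static and well-separated moving defects", {
  d <- toy_defects(list(list(frames = 1:30, x = rep(0, 30), y = rep(0, 30),
                             charge = 1)))
  tr <- link_defect_tracks(d)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 30)
  # two defects whose paths cross but never come within the link radius
  d2 <- toy_defects(list(
    list(frames = 1:20, x = seq(0, 1900, by = 100), y = rep(0, 20), charge = 1),
    list(frames = 1:20, x = seq(1900, 0, by = -100), y = rep(300, 20), charge = 1)))
  tr2 <- link_defect_tracks(d2, link_radius = 165)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(table(tr2$track_id) == 20))
})

test_that("jittered planted tracks are relinked nearly perfectly", {
  n_tracks <- 8; n_frames <- 25
  withr::with_seed(9, {
    base_x <- runif(n_tracks, 0, 4000); base_y <- runif(n_tracks, 0, 4000)
    tracks <- lapply(seq_len(n_tracks), function(i) {
      list(frames = 1:n_frames,
           x = base_x[i] + cumsum(rnorm(n_frames, sd = 20)),
           y = base_y[i] + cumsum(rnorm(n_frames, sd = 20)),
           charge = sample(c(-1, 1), 1))
    })
  })
  truth <- rep(seq_len(n_tracks), each = n_frames)
  d <- toy_defects(tracks)
  tr <- dplyr::arrange(link_defect_tracks(d), .data$frame)
  # agreement up to a relabeling: within each true track, the modal
  # recovered id should dominate
  d_ord <- dplyr::arrange(dplyr::mutate(d, truth = truth), .data$frame)
  joined <- dplyr::left_join(d_ord, tr, by = c("frame", "x_um", "y_um"))
  acc <- mean(unlist(lapply(split(joined$track_id, joined$truth), function(ids) {
    mean(ids == as.integer(names(which.max(table(ids)))))
  })))
  expect_gte(acc, 0.95)
})

test_that("track velocity follows the path-over-time-points rule", {
  static <- toy_defects(list(list(frames = 1:25, x = rep(0, 25), y = rep(0, 25),
                                  charge = 1)))
  tv <- track_velocities(link_defect_tracks(static), frame_interval_h = 0.25)
  expect_equal(tv$velocity_umph, 0)
  # straight track, 10 um per frame, 30 points: (29 * 10) / 30 per point
  straight <- toy_defects(list(list(frames = 1:30, x = 10 * (1:30),
                                    y = rep(0, 30), charge = -1)))
  tv2 <- track_velocities(link_defect_tracks(straight), frame_interval_h = 0.25)
  expect_equal(tv2$velocity_umph, 29 * 10 / 30 / 0.25, tolerance = 1e-12)
  # a 24-point track is excluded
  short <- toy_defects(list(list(frames = 1:24, x = 10 * (1:24),
                                 y = rep(0, 24), charge = 1)))
  tv3 <- track_velocities(link_defect_tracks(short), frame_interval_h = 0.25)
  expect_equal(nrow(tv3), 0)
})

test_that("event calling distinguishes annihilation, proliferation and exits", {
  conv <- toy_defects(list(
    list(frames = 1:6, x = seq(0, 500, by = 100), y = rep(0, 6), charge = 1),
    list(frames = 1:6, x = seq(1200, 700, by = -100), y = rep(0, 6), charge = -1),
    list(frames = 1:10, x = rep(3000, 10), y = rep(3000, 10), charge = 1)))
  tr <- link_defect_tracks(conv)
  ev <- call_events(tr, event_radius = 250)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "annihilation")
  expect_equal(ev$frame, 6)
  expect_equal(ev$x_um, 600)
  # diverging newborn pair at frame 4 -> proliferation
  div <- toy_defects(list(
    list(frames = 4:10, x = seq(1000, 400, by = -100), y = rep(0, 7), charge = 1),
    list(frames = 4:10, x = seq(1100, 1700, by = 100), y = rep(0, 7), charge = -1),
    list(frames = 1:10, x = rep(4000, 10), y = rep(4000, 10), charge = 1)))
  ev2 <- call_events(link_defect_tracks(div), event_radius = 250)
  expect_equal(ev2$type, "proliferation")
  expect_equal(ev2$frame, 4)
  # a track that dies at the field border is not an annihilation partner
  border <- toy_defects(list(
    list(frames = 1:6, x = seq(500, 100, length.out = 6), y = rep(50, 6), charge = 1),
    list(frames = 1:6, x = seq(400, 60, length.out = 6), y = rep(150, 6), charge = -1),
    list(frames = 1:10, x = rep(3000, 10), y = rep(3000, 10), charge = 1)))
  ev3 <- call_events(link_defect_tracks(border), event_radius = 250,
                     bounds = c(0, 4000, 0, 4000), border_margin = 165)
  expect_equal(nrow(ev3), 0)
})

test_that("the corridor direction reverses across a planted annihilation", {
  g <- field_grid(30, 21, 66)
  y0 <- g$ys[11] + 33
  sep <- c(500, 350, 200)
  mkpair <- function(s, fr) {
    cx <- g$xs[15] + 33
    compose_defect_field(
      dplyr::bind_rows(defect_spec(cx - s / 2, y0, 1, pi / 2),
                       defect_spec(cx + s / 2, y0, -1, 0)),
      g, frame = fr, t_h = fr * 0.25)
  }
  xy <- expand.grid(x = g$xs, y = g$ys)
  frames <- dplyr::bind_rows(
    lapply(1:3, function(k) mkpair(sep[k], k)),
    # after annihilation: uniform flow along the pair's +y far field
    velocity_field(xy$x, xy$y, rep(0, nrow(xy)), rep(35, nrow(xy)),
                   frame = 4, t_h = 1))
  det <- detect_defects(frames, detection_params())
  tr <- link_defect_tracks(det)
  ev <- call_events(tr, event_radius = 250, convergence_frames = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "annihilation")
  ang <- reversal_angle(ev, tr, frames)
  expect_gt(ang, 150)
  # refuses when no post-event frames exist
  expect_error(reversal_angle(ev, tr, frames[frames$frame <= 3, ]),
               "not enough frames")
  expect_error(reversal_angle(dplyr::mutate(ev, type = "proliferation"),
                              tr, frames),
               "annihilation")
})
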
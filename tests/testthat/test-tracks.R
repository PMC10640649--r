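test_that("CSV reader builds one frame-sorted track per id", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x,y",
               "a,0,0.0,0.0",
               "a,1,1.0,0.5"), f)
  ts <- read_tracks_csv(f, dt = 0.1)
  expect_length(ts, 1L)
  expect_equal(length(ts[["a"]]$frames), 2L)
  expect_equal(ts[["a"]]$dt, 0.1)
  expect_equal(ts[["a"]]$cell_id, sub("\\.csv$", "", basename(f)))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x,y",
               "A,0,0,0", "B,0,5,5", "A,1,1,0", "B,1,6,5", "A,2,2,0"), f2)
  ts2 <- read_tracks_csv(f2, dt = 0.1)
  expect_length(ts2, 2L)
  expect_equal(ts2[["A"]]$frames, 0:2)
  expect_equal(ts2[["B"]]$x, c(5, 6))
})

test_that("rows out of frame order give the same track as a sorted file", {
  shuf <- withr::local_tempfile(fileext = ".csv")
  sorted <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("a,%d,%g,%g", 0:4, c(0, 1, 2, 3, 4), c(0, 0.5, 0, 0.5, 0))
  writeLines(c("track_id,frame,x,y", rows[c(3, 1, 5, 2, 4)]), shuf)
  writeLines(c("track_id,frame,x,y", rows), sorted)
  a <- read_tracks_csv(shuf, dt = 0.1)[["a"]]
  b <- read_tracks_csv(sorted, dt = 0.1)[["a"]]
  a$cell_id <- b$cell_id <- "c"
  expect_identical(a, b)
})

test_that("reader rejects malformed tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x", "a,0,0", "a,1,1"), f)
  expect_error(read_tracks_csv(f, 0.1), "missing column")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x,y", "a,0,0,0", "a,0,1,1"), f2)
  expect_error(read_tracks_csv(f2, 0.1), "duplicate")
})

test_that("CSV writer round-trips frames and positions bit-exactly", {
  set.seed(11)
  ts <- track_set(lapply(1:3, function(i)
    track(paste0("t", i), frames = sort(sample(0:30, 8)),
          x = rnorm(8), y = rnorm(8), dt = 0.1,
          cell_id = "c1", condition = "norm")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(ts, f)
  back <- read_tracks_csv(f, dt = 0.1)
  for (id in names(unclass(ts))) {
    expect_identical(back[[id]]$frames, ts[[id]]$frames)
    expect_identical(back[[id]]$x, ts[[id]]$x)
    expect_identical(back[[id]]$y, ts[[id]]$y)
  }
})

test_that("minimum-steps filter keeps >= min_steps and is idempotent", {
  mk <- function(n, id) straight_track(n = n, id = id)
  # 51 positions = 50 steps: retained at the 5 s / 50-step threshold
  ts <- track_set(list(mk(11, "short"), mk(51, "edge"), mk(201, "long")))
  kept <- filter_min_steps(ts, 50L)
  expect_setequal(names(unclass(kept)), c("edge", "long"))
  expect_length(filter_min_steps(track_set(), 50L), 0L)
  expect_identical(names(unclass(filter_min_steps(kept, 50L))),
                   names(unclass(kept)))
})

test_that("track invariants are enforced", {
  expect_error(track("a", 0L, 0, 0, 0.1), "at least 2")
  expect_error(track("a", c(0, 0), c(0, 1), c(0, 1), 0.1), "increasing")
  expect_error(track("a", 0:1, 0:1, 0:1, -1), "dt")
  expect_error(track_set(list(straight_track(id = "x"),
                              straight_track(id = "x"))), "duplicate")
})

test_that("grouping maps condition -> cell -> track ids", {
  ts <- track_set(list(
    track("t1", 0:2, 0:2, rep(0, 3), 0.1, cell_id = "c1", condition = "norm"),
    track("t2", 0:2, 0:2, rep(0, 3), 0.1, cell_id = "c1", condition = "norm"),
    track("t3", 0:2, 0:2, rep(0, 3), 0.1, cell_id = "c2", condition = "noc")))
  g <- track_grouping(ts)
  expect_setequal(g$norm$c1, c("t1", "t2"))
  expect_equal(g$noc$c2, "t3")
})
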
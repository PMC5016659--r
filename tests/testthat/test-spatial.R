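grid20 <- gridSpec(c(0, 0), 1000, 20, 20)

test_that("axis-aligned road splits into exact cell-length segments", {
  net <- straightRoad(0, 500, 3000, 500)
  seg <- splitRoadsByGrid(net, grid20)
  expect_equal(nrow(seg$table), 3L)
  expect_equal(seg$table$length, rep(1000, 3), tolerance = 1e-9)
  expect_equal(seg$table$cell_id, 1:3)
  expect_equal(sum(seg$table$length), 3000, tolerance = 1e-9)
})

test_that("segmentation conserves length and matches the cell-clip oracle", {
  set.seed(31)
  for (rep in 1:10) {
    net <- randomNetwork(grid20, nRoads = 4L)
    seg <- splitRoadsByGrid(net, grid20)
    expect_equal(sum(seg$table$length), networkLength(net),
                 tolerance = 1e-6)
    expect_true(all(seg$table$length > 0))
  }
  # random diagonal road: per-cell clipped length equals the
  # Liang-Barsky rectangle-clipping oracle
  m <- rbind(c(150, 250), c(17850, 19650))
  seg <- splitRoadsByGrid(roadNetwork(list(m), "arterial"), grid20)
  oracle <- oracleCellLengths(m, grid20)
  got <- numeric(length(oracle))
  got[seg$table$cell_id] <- seg$table$length
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("segment midpoints lie on the geometry inside the owning cell", {
  set.seed(77)
  net <- randomNetwork(grid20, nRoads = 6L)
  seg <- splitRoadsByGrid(net, grid20)
  tab <- seg$table
  for (i in seq_len(nrow(tab))) {
    d <- pointsToPolylineDistance(tab$mid_x[i], tab$mid_y[i],
                                          seg$geometry[[i]])
    expect_lt(d, 1e-6)
    cellRow <- (tab$cell_id[i] - 1L) %/% 20L
    cellCol <- (tab$cell_id[i] - 1L) %% 20L
    expect_gte(tab$mid_x[i], cellCol * 1000 - 1e-9)
    expect_lte(tab$mid_x[i], (cellCol + 1) * 1000 + 1e-9)
    expect_gte(tab$mid_y[i], cellRow * 1000 - 1e-9)
    expect_lte(tab$mid_y[i], (cellRow + 1) * 1000 + 1e-9)
  }
  expect_error(splitRoadsByGrid(straightRoad(-10, 0, 500, 0), grid20),
               "outside grid extent")
})

test_that("accuracy filter keeps the boundary and preserves order", {
  recs <- data.frame(x = 1:3, y = 1:3, accuracy = c(100, 300, 301))
  kept <- filterRecordsByAccuracy(recs, 300)
  expect_equal(kept$accuracy, c(100, 300))
  expect_equal(nrow(filterRecordsByAccuracy(recs[0, ], 300)), 0L)
  expect_equal(nrow(filterRecordsByAccuracy(
    data.frame(x = 1, y = 1, accuracy = 500), 300)), 0L)
})

test_that("records map to nearest segments, deduplicated, per the all-pairs oracle", {
  set.seed(13)
  net <- randomNetwork(grid20, nRoads = 20L)
  seg <- splitRoadsByGrid(net, grid20)
  # subset to ~200 segments for the oracle comparison
  keep <- seq_len(min(200L, nrow(seg$table)))
  seg <- list(table = seg$table[keep, ], geometry = seg$geometry[keep])
  # a record lying exactly on a segment maps to it
  g <- seg$geometry[[17]]
  onSeg <- colMeans(g[1:2, , drop = FALSE])
  res <- assignRecordsToSegments(data.frame(x = onSeg[1], y = onSeg[2]), seg)
  expect_equal(res$assignment, seg$table$segment_id[17])
  # two records nearest the same segment produce one coded segment
  res2 <- assignRecordsToSegments(
    data.frame(x = rep(onSeg[1], 2), y = rep(onSeg[2], 2)), seg)
  expect_length(res2$collisionIds, 1L)
  # 500 random records vs the exhaustive distance scan
  recs <- data.frame(x = runif(500, 0, 20000), y = runif(500, 0, 20000))
  got <- assignRecordsToSegments(recs, seg)$assignment
  oracle <- vapply(seq_len(500), function(i) {
    d <- vapply(seg$geometry, function(m)
      pointsToPolylineDistance(recs$x[i], recs$y[i], m), 0)
    seg$table$segment_id[which.min(d)]
  }, 0L)
  expect_equal(got, oracle)
})

test_that("background segment draws are disjoint, sized, and seeded", {
  scene <- smallScene()
  seg <- sceneSegments(scene)
  coll <- sort(sample(seg$table$segment_id, 40))
  bg <- drawBackgroundSegments(seg, coll, ratio = 2, seed = 9L)
  expect_length(bg, 80L)
  expect_length(intersect(bg, coll), 0L)
  expect_identical(bg, drawBackgroundSegments(seg, coll, ratio = 2, seed = 9L))
  expect_length(drawBackgroundSegments(seg, coll, ratio = 0, seed = 9L), 0L)
  expect_error(drawBackgroundSegments(seg, coll, ratio = 1e6, seed = 9L),
               "short by")
})
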
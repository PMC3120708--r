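test_that("global peak search breaks ties by smallest i then j and honours masks", {
  L <- mkLandscape(matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3))
  p <- findGlobalPeak(L)
  expect_equal(p[c("i", "j")], list(i = 1L, j = 1L))
  expect_equal(p$height, 1L)

  expect_null(findGlobalPeak(mkLandscape(matrix(0, 3, 3))))

  mask <- matrix(FALSE, 3, 3); mask[1, 1] <- TRUE
  expect_equal(findGlobalPeak(L, mask)[c("i", "j")], list(i = 1L, j = 2L))

  M <- mkLandscape(matrix(c(0, 5, 0, 9, 0, 0, 0, 0, 0), 3, 3))
  mask <- matrix(FALSE, 3, 3); mask[1, 2] <- TRUE  # mask the max at (1,2)
  expect_equal(findGlobalPeak(M, mask)[c("i", "j", "height")],
               list(i = 2L, j = 1L, height = 5L))
})

test_that("spurious spikes are those with an in-bounds neighbour below threshold", {
  H <- matrix(10, 3, 3); H[2, 2] <- 20
  prm <- siteParams(percentPeak = 0.5)  # threshold 10
  L <- mkLandscape(H)
  expect_false(isSpuriousPeak(L, list(i = 2L, j = 2L, height = 20L), prm))
  H2 <- H; H2[1, 2] <- 9  # one neighbour just below 0.5 * 20
  expect_true(isSpuriousPeak(mkLandscape(H2), list(i = 2L, j = 2L), prm))
  # boundary peaks: out-of-bounds directions are treated as satisfied
  Hc <- matrix(0, 3, 3); Hc[1, 1] <- 20; Hc[1, 2] <- 12; Hc[2, 1] <- 12
  expect_false(isSpuriousPeak(mkLandscape(Hc), list(i = 1L, j = 1L), prm))
  # a strict peak is always spurious at percentPeak = 1
  expect_true(isSpuriousPeak(L, list(i = 2L, j = 2L),
                             siteParams(percentPeak = 1)))
})

test_that("the walk reproduces the hand-traced 5x5 rectangle", {
  H <- matrix(0, 5, 5)
  H[3, ] <- c(4, 12, 20, 15, 6)
  H[, 3] <- c(3, 11, 20, 18, 9)
  L <- mkLandscape(H)
  rect <- walkPeak(L, list(i = 3L, j = 3L), percentPeak = 0.5)  # t = 10
  expect_identical(rect, c(i0 = 2L, i1 = 4L, j0 = 2L, j1 = 4L))

  # corner peak with both neighbours above threshold
  Hc <- matrix(0, 3, 3); Hc[1, 1] <- 20; Hc[2, 1] <- 12; Hc[1, 2] <- 12
  rc <- walkPeak(mkLandscape(Hc), list(i = 1L, j = 1L), percentPeak = 0.5)
  expect_identical(rc, c(i0 = 1L, i1 = 2L, j0 = 1L, j1 = 2L))

  # calling the walk on a spurious spike is a contract violation
  Hs <- matrix(0, 3, 3); Hs[2, 2] <- 20
  expect_error(walkPeak(mkLandscape(Hs), list(i = 2L, j = 2L), 0.5),
               "spurious")
})

test_that("window rectangles convert to 1-based inclusive residue ranges", {
  expect_identical(rectToRanges(c(i0 = 2, i1 = 4, j0 = 2, j1 = 4), w = 3),
                   c(startA = 2L, endA = 6L, startB = 2L, endB = 6L))
  expect_identical(rectToRanges(c(i0 = 1, i1 = 1, j0 = 1, j1 = 1), w = 1),
                   c(startA = 1L, endA = 1L, startB = 1L, endB = 1L))
  expect_identical(rectToRanges(c(i0 = 5, i1 = 5, j0 = 7, j1 = 7), w = 20),
                   c(startA = 5L, endA = 24L, startB = 7L, endB = 26L))
})

# A broad pyramid-shaped hill centred at (ci, cj).
hill <- function(n, ci, cj, height) {
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- height - 4 * max(abs(i - ci), abs(j - cj))
    if (v > 0) H[i, j] <- v
  }
  H
}

test_that("site prediction gates low landscapes and masks claimed rectangles", {
  # tallest peak 9 < 10: no predictions at all
  H9 <- hill(7, 4, 4, 9)
  expect_equal(nrow(predictSites(mkLandscape(H9))), 0L)

  # one broad hill: exactly one prediction even with maxPeaks = 3
  H1 <- hill(7, 4, 4, 30)
  pred <- predictSites(mkLandscape(H1, w = 2))
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$peakHeight, 30L)
  # whole hill stays above 0.3 * 30 = 9, so the walk reaches the edges
  expect_equal(unname(unlist(pred[, c("i0", "i1", "j0", "j1")])),
               c(1L, 7L, 1L, 7L))
  expect_equal(c(pred$startA, pred$endA), c(1L, 8L))  # window union, w = 2

  # two disjoint hills rank by decreasing height
  H2 <- matrix(0, 15, 15)
  H2[1:7, 1:7] <- hill(7, 4, 4, 30)
  H2[9:15, 9:15] <- hill(7, 4, 4, 20)
  pred2 <- predictSites(mkLandscape(H2))
  expect_equal(pred2$rank, c(1L, 2L))
  expect_equal(pred2$peakHeight, c(30L, 20L))
  expect_true(pred2$i0[2] >= 9L)
})

test_that("predicted rectangles contain their peaks, are disjoint and deterministic", {
  set.seed(11)
  for (rep in 1:10) {
    H <- matrix(rpois(20 * 18, 4), 20, 18)
    H[5, 5] <- 25; H[4:6, 5] <- pmax(H[4:6, 5], 15); H[5, 4:6] <- pmax(H[5, 4:6], 15)
    L <- mkLandscape(H)
    pred <- predictSites(L, siteParams(percentPeak = 0.4, maxPeaks = 3))
    if (!nrow(pred)) next
    expect_true(all(pred$peakHeight == sort(pred$peakHeight,
                                            decreasing = TRUE)))
    cells <- lapply(seq_len(nrow(pred)), function(r)
      as.vector(outer(pred$i0[r]:pred$i1[r], (pred$j0[r]:pred$j1[r]) * 1000,
                      `+`)))
    expect_equal(anyDuplicated(unlist(cells)), 0L)
    for (r in seq_len(nrow(pred))) {
      pk <- H[pred$i0[r]:pred$i1[r], pred$j0[r]:pred$j1[r], drop = FALSE]
      expect_true(max(pk) >= pred$peakHeight[r])
    }
    expect_identical(pred, predictSites(L, siteParams(percentPeak = 0.4,
                                                      maxPeaks = 3)))
  }
})

test_that("planted motif sites are recovered on synthetic data (smoke)", {
  hits <- 0L
  for (seed in 1:10) {
    ds <- recoveryDataset(seed)
    tr <- ds$truth[[1]]
    L <- computeLandscape(tr$idA, tr$idB, ds$db, matchParams(w = 10))
    pred <- predictSites(L)
    if (!nrow(pred)) next
    cell <- expectedPeakCell(ds, tr$idA, tr$idB)
    if (pred$i0[1] <= cell["i"] && cell["i"] <= pred$i1[1] &&
        pred$j0[1] <= cell["j"] && cell["j"] <= pred$j1[1])
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
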
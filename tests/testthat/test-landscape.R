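test_that("window enumeration covers every start and handles short proteins", {
  w <- proteinWindows(c(P = "MKLV"), 2)
  expect_identical(w$start, 1:3)
  expect_identical(w$window, c("MK", "KL", "LV"))
  expect_identical(proteinWindows(c(P = "MKLV"), 4)$window, "MKLV")
  expect_equal(nrow(proteinWindows(c(P = "MK"), 3)), 0L)
})

test_that("exact window matching is substring occurrence", {
  p <- matchParams(w = 2)
  expect_true(windowMatch("KL", c(X = "QMKL"), p))
  expect_false(windowMatch("LV", c(X = "QMKL"), p))
  expect_identical(matchProfile(c(A = "MKLV"), c(X = "QMKL"), p), c(1L, 2L))
  expect_identical(matchProfile(c(A = "MKLV"), c(X = "WWWW"), p), integer())
  expect_identical(matchProfile(c(A = "MKLV"), c(X = "MKLV"), p), 1:3)
})

test_that("similarity matching scores windows against a substitution matrix", {
  # self-score of "MK" under BLOSUM62 is M/M + K/K = 5 + 5 = 10
  pEq <- matchParams(w = 2, mode = "similarity", scoreThreshold = 10)
  expect_true(windowMatch("MK", c(X = "MK"), pEq))
  pHigh <- matchParams(w = 2, mode = "similarity", scoreThreshold = 11)
  expect_false(windowMatch("MK", c(X = "MK"), pHigh))
  # conservative 'X': never matches any position in similarity mode
  pAny <- matchParams(w = 2, mode = "similarity", scoreThreshold = -100)
  expect_false(windowMatch("MX", c(X = "MX"), pAny))
})

test_that("the worked toy landscape matches the hand-derived matrix", {
  prot <- Biostrings::AAStringSet(c(A = "MKLV", B = "AAGW",
                                    X = "QMKL", Y = "GAAG"))
  db <- InteractionDB(data.frame(idA = "X", idB = "Y"), prot)
  L <- computeLandscape("A", "B", db, matchParams(w = 2))
  expect_identical(landscapeMatrix(L),
                   matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 3, 3))

  # empty database -> all-zero matrix
  db0 <- InteractionDB(data.frame(idA = character(), idB = character()), prot)
  expect_true(all(landscapeMatrix(
    computeLandscape("A", "B", db0, matchParams(w = 2))) == 0L))

  # self-interaction toy: every cell of the landscape is supported
  prot2 <- Biostrings::AAStringSet(c(S = "MKLVAG"))
  dbS <- InteractionDB(data.frame(idA = "S", idB = "S"), prot2)
  LS <- computeLandscape("S", "S", dbS, matchParams(w = 2),
                         excludeQueryPair = FALSE)
  expect_true(all(landscapeMatrix(LS) >= 1L))
})

test_that("a query shorter than the window yields a zero-extent landscape", {
  prot <- Biostrings::AAStringSet(c(A = "MK", B = "AAGW", X = "QMKL"))
  db <- InteractionDB(data.frame(idA = "X", idB = "B"), prot)
  L <- computeLandscape("A", "B", db, matchParams(w = 3))
  expect_identical(dim(landscapeMatrix(L)), c(0L, 2L))
})

test_that("computeLandscape equals the brute-force oracle on random toys", {
  set.seed(421)
  for (rep in 1:50) {
    inst <- randomToyInstance()
    prot <- Biostrings::AAStringSet(inst$seqs)
    db <- InteractionDB(inst$pairs, prot)
    L <- computeLandscape(inst$A, inst$B, db, matchParams(w = inst$w),
                          excludeQueryPair = FALSE)
    expect_identical(
      landscapeMatrix(L),
      bruteLandscape(inst$seqs[[inst$A]], inst$seqs[[inst$B]],
                     dbPairs(db)[, 1:2], inst$seqs, inst$w))
  }
})

test_that("the landscape is symmetric in the query roles", {
  set.seed(77)
  for (rep in 1:10) {
    inst <- randomToyInstance()
    prot <- Biostrings::AAStringSet(inst$seqs)
    db <- InteractionDB(inst$pairs, prot)
    p <- matchParams(w = inst$w)
    Lab <- computeLandscape(inst$A, inst$B, db, p, excludeQueryPair = FALSE)
    Lba <- computeLandscape(inst$B, inst$A, db, p, excludeQueryPair = FALSE)
    expect_identical(landscapeMatrix(Lab), t(landscapeMatrix(Lba)))
  }
})

test_that("adding a database pair never decreases any landscape cell", {
  set.seed(99)
  for (rep in 1:10) {
    inst <- randomToyInstance()
    prot <- Biostrings::AAStringSet(inst$seqs)
    base <- inst$pairs[-1L, , drop = FALSE]
    p <- matchParams(w = inst$w)
    H0 <- landscapeMatrix(computeLandscape(
      inst$A, inst$B, InteractionDB(rbind(base, inst$pairs[1L, ]), prot), p,
      excludeQueryPair = FALSE))
    if (nrow(base)) {
      H1 <- landscapeMatrix(computeLandscape(
        inst$A, inst$B, InteractionDB(base, prot), p,
        excludeQueryPair = FALSE))
      expect_true(all(H0 - H1 >= 0L))
    } else {
      expect_true(all(H0 >= 0L))
    }
  }
})

test_that("every count respects the oriented-pair bound and w=1 reduces to residue counting", {
  prot <- Biostrings::AAStringSet(c(A = "MKM", B = "KK", X = "MK", Y = "KM"))
  db <- InteractionDB(data.frame(idA = c("X", "Y"), idB = c("Y", "Y")), prot)
  L <- computeLandscape("A", "B", db, matchParams(w = 1),
                        excludeQueryPair = FALSE)
  H <- landscapeMatrix(L)
  expect_true(all(H <= 2L * nrow(dbPairs(db))))
  # closed form: count oriented pairs whose first member contains A[i] and
  # second contains B[j]; all of M,K occur in X and in Y, so every cell is
  # the full oriented-pair count: (X,Y),(Y,X),(Y,Y) -> 3
  expect_true(all(H == 3L))
})

test_that("excluding the query pair removes exactly its contribution", {
  set.seed(31)
  inst <- randomToyInstance()
  pairs <- rbind(inst$pairs, data.frame(idA = inst$A, idB = inst$B))
  prot <- Biostrings::AAStringSet(inst$seqs)
  db <- InteractionDB(pairs, prot)
  p <- matchParams(w = inst$w)
  Hexcl <- landscapeMatrix(computeLandscape(inst$A, inst$B, db, p,
                                            excludeQueryPair = TRUE))
  expect_identical(Hexcl,
                   bruteLandscape(inst$seqs[[inst$A]], inst$seqs[[inst$B]],
                                  dbPairs(db)[, 1:2], inst$seqs, inst$w,
                                  excludeIds = c(inst$A, inst$B)))
})
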
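gseaResultFixture <- function(ids, q, nes) {
  data.frame(set_id = ids, size = 20, es = sign(nes) * 0.5, nes = nes,
             fdr_q = q, direction = ifelse(nes > 0, "pos", "neg"),
             significant = q < 0.25, stringsAsFactors = FALSE)
}

test_that("significant terms are filtered strictly and ordered deterministically", {
  res <- gseaResultFixture(c("t1", "t2", "t3"), q = c(0.3, 0.1, 0.25),
                           nes = c(2, 1.5, 1.2))
  r <- rankSignificantTerms(res, fdrCutoff = 0.25)
  expect_identical(r$pos$term, "t2")  # 0.25 excluded by the strict cutoff
  expect_identical(nrow(r$neg), 0L)

  # q ties broken by |nes| descending, then set id
  res2 <- gseaResultFixture(c("b", "a", "c"), q = c(0, 0, 0),
                            nes = c(1.4, 2.2, 1.4))
  r2 <- rankSignificantTerms(res2)
  expect_identical(r2$pos$term, c("a", "b", "c"))

  lr <- data.frame(set_id = c("x", "y", "z"), size = 10, b0 = 0,
                   b1 = c(1, -1, 2), se = 1,
                   wald_p = c(0.002, 0.001, 0.003),
                   bh_q = c(0.01, 0.01, 0.5),
                   direction = c("pos", "neg", "pos"),
                   significant = c(TRUE, TRUE, FALSE))
  r3 <- rankSignificantTerms(lr)
  expect_identical(r3$term, c("y", "x"))
})

test_that("list matching truncates to the shorter list", {
  a <- paste0("t", 1:7)
  b <- paste0("t", 3:6)
  m <- matchLists(a, b)
  expect_identical(m$N, 4L)
  expect_length(m$a, 4L)
  expect_identical(matchLists(a, a)$N, 7L)
  expect_message(m0 <- matchLists(a, character(0)), "undefined")
  expect_identical(m0$N, 0L)
})

test_that("pos/neg combination truncates per direction then concatenates", {
  m <- combinePosNeg(paste0("p", 1:3), paste0("n", 1:4),
                     paste0("q", 1:5), paste0("m", 1:2))
  expect_identical(m$N, 5L)  # min(3,5) + min(4,2)
  expect_identical(m$a, c("p1", "p2", "p3", "n1", "n2"))

  same <- combinePosNeg(paste0("p", 1:3), paste0("n", 1:2),
                        paste0("p", 1:3), paste0("n", 1:2))
  expect_identical(same$a, same$b)
  expect_identical(same$N, 5L)

  # empty negatives on both sides reduces to a pos-only match
  ponly <- combinePosNeg(paste0("p", 1:4), character(0),
                         paste0("p", c(2, 1, 3)), character(0))
  expect_identical(ponly$N, 3L)
  expect_identical(ponly$a, paste0("p", 1:3))
})

test_that("overlap percentage equals the top-i set intersection", {
  a <- c("w", "x", "y", "z")
  b <- c("x", "w", "z", "v")
  expect_equal(overlapPercentage(a, b, 1), 0)
  expect_equal(overlapPercentage(a, b, 2), 100)
  expect_equal(overlapPercentage(a, b, 4), 75)
  expect_equal(overlapPercentage(a, a, 3), 100)
  expect_equal(overlapPercentage(a, c("q", "r", "s", "t"), 4), 0)
  expect_error(overlapPercentage(a, b, 5), "depth")
  expect_error(overlapPercentage(a, b, 0), "depth")
})

test_that("concordance curves match the worked example and the brute oracle", {
  cv <- concordanceCurve(c("w", "x", "y", "z"), c("x", "w", "z", "v"))
  expect_equal(cv$pog, c(0, 100, 200 / 3, 75))
  expect_equal(attr(cv, "terminal"), 75)

  flat <- concordanceCurve(paste0("t", 1:10), paste0("t", 1:10))
  expect_true(all(flat$pog == 100))

  empty <- suppressMessages(concordanceCurve(character(0), letters[1:3]))
  expect_identical(attr(empty, "N"), 0L)
  expect_true(is.na(attr(empty, "terminal")))
})

test_that("curve properties hold on random list pairs", {
  set.seed(71)
  for (i in 1:200) {
    u <- sprintf("u%03d", 1:60)
    n <- sample(3:30, 1)
    a <- sample(u, n)
    b <- sample(u, n)
    cv <- concordanceCurve(a, b)
    # counts never decrease, and each depth is checked against brute force
    expect_true(all(diff(cv$overlap) >= 0))
    for (i2 in sample(seq_len(n), min(4, n))) {
      expect_equal(cv$overlap[i2], bruteTopOverlap(a, b, i2))
    }
    # one-step change bound: advancing the depth adds one term to EACH
    # list, so the overlap count can rise by up to two
    if (n > 1) {
      expect_true(all(abs(diff(cv$pog)) <= 200 / (seq_len(n - 1) + 1) + 1e-9))
    }
    # permuting terms below depth i leaves POG_i unchanged
    iCut <- sample(seq_len(n), 1)
    if (iCut < n) {
      a2 <- c(a[seq_len(iCut)], sample(a[(iCut + 1):n]))
      b2 <- c(b[seq_len(iCut)], sample(b[(iCut + 1):n]))
      expect_equal(overlapPercentage(a2, b2, iCut),
                   cv$pog[iCut])
    }
  }
})

test_that("adjacent swaps move each depth's overlap by at most one term", {
  set.seed(72)
  u <- sprintf("u%02d", 1:40)
  a <- sample(u, 12)
  b <- sample(u, 12)
  base <- concordanceCurve(a, b)$pog
  for (j in 1:11) {
    a2 <- a
    a2[c(j, j + 1)] <- a2[c(j + 1, j)]
    swapped <- concordanceCurve(a2, b)$pog
    expect_true(all(abs(swapped - base) <= 100 / seq_len(12) + 1e-9))
  }
})

test_that("compareAll emits the planned comparison families", {
  mkTerms <- function(seed, engine) {
    set.seed(seed)
    u <- sprintf("S%03d", 1:40)
    if (engine == "gsea") {
      list(pos = sample(u, 8), neg = sample(u, 6))
    } else {
      list(all = sample(u, 10))
    }
  }
  grid <- expand.grid(engine = c("gsea", "lrpath"), platform = c("P1", "P2"),
                      site = c("1", "2", "3"), method = c("FC", "SAM", "TTEST"),
                      p_cutoff = 0.05, stringsAsFactors = FALSE)
  grid$terms <- lapply(seq_len(nrow(grid)),
                       function(i) mkTerms(i, grid$engine[i]))
  cc <- suppressMessages(compareAll(grid))

  # family (i): per engine, 2 platforms x 3 methods x C(3,2) site pairs
  expect_identical(sum(cc$family == "inter_site" & cc$engine == "gsea"),
                   2L * 3L * 3L)
  # family (ii): per engine, 2 platforms x 3 sites x C(3,2) method pairs
  expect_identical(sum(cc$family == "intra_site" & cc$engine == "lrpath"),
                   2L * 3L * 3L)
  # family (iii): per engine, 3 sites x 3 methods x C(2,2) platform pair
  expect_identical(sum(cc$family == "inter_platform" & cc$engine == "gsea"),
                   3L * 3L * 1L)
  expect_identical(nrow(attr(cc, "exclusions")), 0L)

  # symmetry: swapping every entry's role reproduces the same POG values
  rev <- grid[nrow(grid):1, ]
  ccR <- suppressMessages(compareAll(rev))
  key <- function(d) paste(d$family, d$engine,
                           pmin(d$site_a, d$site_b), pmax(d$site_a, d$site_b),
                           pmin(d$platform_a, d$platform_b),
                           pmax(d$platform_a, d$platform_b),
                           pmin(d$method_a, d$method_b),
                           pmax(d$method_a, d$method_b))
  expect_equal(cc$pog[order(key(cc))], ccR$pog[order(key(ccR))])

  # a missing combination lands in the exclusions report
  holey <- grid[-5, ]
  ccH <- suppressMessages(compareAll(holey))
  expect_identical(nrow(attr(ccH, "exclusions")), 1L)
})

test_that("random equal-size truncations match the hypergeometric overlap rate", {
  set.seed(73)
  U <- 200; N <- 20
  u <- sprintf("u%03d", seq_len(U))
  pogs <- vapply(1:500, function(i) {
    overlapPercentage(sample(u, N), sample(u, N), N)
  }, numeric(1))
  expect_equal(mean(pogs), 100 * N / U, tolerance = 0.15)
})
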
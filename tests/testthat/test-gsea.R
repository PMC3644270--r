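rankedFixture <- function(scores, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_along(scores))
  data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
}

test_that("ranked lists sort by signed metric with lexicographic tie-break", {
  st <- data.frame(gene = c("a", "b", "c"), t_p = c(0.5, 0.5, 0.5),
                   log2fc = c(2, -3, 1), sam_d = c(2, -3, 1),
                   snr = c(1, -1, 0.5), stringsAsFactors = FALSE)
  dl <- structure(data.frame(gene = c("a", "b", "c"), metric = abs(st$log2fc)),
                  criterion = degCriterion("FC"), class = c("DEGList", "data.frame"))
  rk <- buildRankedList(dl, st)
  expect_identical(rk$gene, c("a", "c", "b"))
  expect_equal(rk$score, c(2, 1, -3))

  # t-test metric: signed -log10 p
  st2 <- data.frame(gene = c("a", "b"), t_p = c(0.01, 0.01),
                    log2fc = c(-1, 2), stringsAsFactors = FALSE)
  rk2 <- buildRankedList(NULL, st2, method = "TTEST")
  expect_equal(rk2$score[rk2$gene == "a"], -2)
  expect_equal(rk2$score[rk2$gene == "b"], 2)

  # identical metrics: lexicographic order
  st3 <- data.frame(gene = c("z", "m", "a"), log2fc = c(1, 1, 1),
                    t_p = 0.01, stringsAsFactors = FALSE)
  expect_identical(buildRankedList(NULL, st3, method = "FC")$gene,
                   c("a", "m", "z"))

  # metric missing for a listed gene is an analysis error
  dlBad <- structure(data.frame(gene = "missing", metric = 1),
                     criterion = degCriterion("FC"),
                     class = c("DEGList", "data.frame"))
  expect_error(buildRankedList(dlBad, st), "missing")
})

test_that("enrichment score reproduces the worked micro-examples", {
  # unweighted, hits at positions 1 and 3 of 4
  r1 <- enrichmentScore(rankedFixture(c(4, 3, 2, 1)), c("g01", "g03"),
                        weightExponent = 0)
  expect_equal(r1$runningSum, c(0.5, 0, 0.5, 0))
  expect_equal(r1$es, 0.5)

  # weight 1, hits at the two ends
  r2 <- enrichmentScore(rankedFixture(c(4, 3, 2, 1)), c("g01", "g04"),
                        weightExponent = 1)
  expect_equal(r2$runningSum, c(0.8, 0.3, -0.2, 0))
  expect_equal(r2$es, 0.8)
  expect_identical(r2$position, 1L)

  # a single member at the very bottom: ES = -1
  r3 <- enrichmentScore(rankedFixture(10:1), "g10", weightExponent = 0)
  expect_equal(r3$es, -1)

  expect_error(enrichmentScore(rankedFixture(3:1), "absent"), "no members")
  expect_error(enrichmentScore(rankedFixture(3:1), c("g01", "g02", "g03")),
               "every ranked gene")
})

test_that("enrichment score equals a brute-force running-sum oracle", {
  set.seed(51)
  for (i in 1:200) {
    N <- sample(5:20, 1)
    scores <- sort(round(rnorm(N, 0, 2), 3), decreasing = TRUE)
    k <- sample(seq_len(N - 1), 1)
    hitPos <- sort(sample.int(N, k))
    w <- sample(c(0, 1), 1)
    rk <- rankedFixture(scores)
    ours <- enrichmentScore(rk, rk$gene[hitPos], weightExponent = w)
    oracle <- bruteRunningSum(scores, seq_len(N) %in% hitPos, w)
    expect_equal(ours$es, oracle$es, tolerance = 1e-12)
    expect_equal(ours$runningSum, oracle$runningSum, tolerance = 1e-12)
    expect_true(abs(ours$es) <= 1 + 1e-12)
    expect_lt(abs(ours$runningSum[N]), 1e-9)
  }
})

test_that("weight zero reduces to the classic two-sample KS statistic", {
  set.seed(52)
  for (i in 1:50) {
    N <- sample(8:20, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    k <- sample(2:(N - 2), 1)
    hitPos <- sort(sample.int(N, k))
    rk <- rankedFixture(scores)
    es <- enrichmentScore(rk, rk$gene[hitPos], weightExponent = 0)$es
    # KS-style: max signed difference between hit and miss ECDFs over ranks
    hitCdf <- cumsum(seq_len(N) %in% hitPos) / k
    missCdf <- cumsum(!seq_len(N) %in% hitPos) / (N - k)
    dev <- hitCdf - missCdf
    # same stable tie rule as the package's extremum selection
    ks <- if (max(dev) + min(dev) >= -1e-12) max(dev) else min(dev)
    expect_equal(es, ks, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's implementation", {
  set.seed(53)
  for (i in 1:25) {
    N <- sample(10:40, 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    k <- sample(2:(N - 2), 1)
    hitPos <- sort(sample.int(N, k))
    rk <- rankedFixture(scores)
    ours <- enrichmentScore(rk, rk$gene[hitPos], weightExponent = 1)$es
    ref <- fgsea::calcGseaStat(scores, hitPos, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("reordering tied-score genes moves ES at most one step", {
  set.seed(54)
  for (i in 1:20) {
    N <- 12
    scores <- c(3, 2, rep(1, 4), rep(-0.5, 4), -2, -3)
    genes <- sprintf("g%02d", seq_len(N))
    hit <- sample(genes, 4)
    rk1 <- data.frame(gene = genes, score = scores)
    # permute genes within each tied block
    genes2 <- genes
    genes2[3:6] <- sample(genes[3:6])
    genes2[7:10] <- sample(genes[7:10])
    rk2 <- data.frame(gene = genes2, score = scores)
    es1 <- enrichmentScore(rk1, hit, 1)$es
    es2 <- enrichmentScore(rk2, hit, 1)$es
    w <- abs(scores[genes %in% hit])
    bound <- max(max(w / sum(w)), 1 / (N - 4))
    # each extremum moves by at most one step; the *magnitude* obeys the
    # bound even when a near-tie lets the sign flip
    expect_lte(abs(abs(es1) - abs(es2)), bound + 1e-12)
  }
})

test_that("the permutation null is seeded and symmetric for symmetric scores", {
  rk <- rankedFixture(c(rep(2, 10), rep(-2, 10)))
  n1 <- geneSetPermutationNull(rk, setSize = 5, nPerm = 1000, seed = 9)
  n2 <- geneSetPermutationNull(rk, setSize = 5, nPerm = 1000, seed = 9)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1)), 3 * stats::sd(n1) / sqrt(length(n1)))

  expect_error(geneSetPermutationNull(rk, setSize = 20, nPerm = 100), "setSize")
  expect_error(geneSetPermutationNull(rk, setSize = 5, nPerm = 50), "nPerm")
})

test_that("NES and FDR follow their defining identities", {
  set.seed(55)
  nulls <- list(a = c(runif(200, 0, 1), -runif(200, 0, 1)))
  obs <- c(a = mean(nulls$a[nulls$a > 0]))
  r <- normalizeAndFdr(obs, nulls)
  expect_equal(r$nes, 1)

  # an observed score beyond every null: q = 0
  nulls2 <- list(a = nulls$a, b = nulls$a)
  obs2 <- c(a = 5, b = 0.2)
  r2 <- normalizeAndFdr(obs2, nulls2)
  expect_equal(r2["a", "fdr_q"], 0)

  # duplicated sets get identical results
  expect_equal(r2["a", ], normalizeAndFdr(c(a = 5, b = 5),
                                          nulls2)["b", ],
               ignore_attr = TRUE)
})

test_that("runGsea filters, scores and flags significance end to end", {
  set.seed(56)
  genes <- sprintf("G%03d", 1:120)
  scores <- sort(rnorm(120, 0, 1.5), decreasing = TRUE)
  st <- data.frame(gene = genes, log2fc = scores, t_p = 0.01,
                   stringsAsFactors = FALSE)
  sets <- GeneSetCollection(list(
    top = genes[1:12],            # coherent: top of the list
    spread = genes[seq(5, 115, 10)],
    tiny = genes[1:2],            # below minSize
    alien = paste0("X", 1:10)))   # absent from the list
  res <- suppressMessages(runGsea(NULL, st, sets, method = "FC",
                                  nPerm = 500, minSize = 5, seed = 3))
  expect_setequal(res$set_id, c("top", "spread"))
  expect_identical(res$direction[res$set_id == "top"], "pos")
  expect_true(res$significant[res$set_id == "top"])
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))

  # the fast scorer used internally must agree with the exported walker
  rk <- buildRankedList(NULL, st, method = "FC")
  for (sid in res$set_id) {
    expect_equal(res$es[res$set_id == sid],
                 enrichmentScore(rk, sets[[sid]], 1)$es, tolerance = 1e-12)
  }

  expect_error(suppressMessages(
    runGsea(NULL, st, GeneSetCollection(list(s = paste0("X", 1:8))),
            method = "FC", nPerm = 500)), "size filter")
})
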
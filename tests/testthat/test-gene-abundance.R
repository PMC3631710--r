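test_that("hit filtering applies both cutoffs and keeps order", {
  empty <- randomHitTable(10, seed = 1)[0, ]
  expect_equal(nrow(filterHits(empty)), 0)

  h <- data.frame(read_id = c("r1", "r2", "r3"), gene_id = "g",
                  family = "soxB",
                  evalue = c(1e-9, 1e-10, 1e-11),
                  pct_identity = c(80, 49.9, 50),
                  stringsAsFactors = FALSE)
  kept <- filterHits(h)
  # 1e-9 exceeds the cutoff; 49.9% identity falls below it; boundary values
  # (evalue exactly 1e-10, identity exactly 50) are retained
  expect_identical(kept$read_id, "r3")
  expect_identical(filterHits(h, maxEvalue = 1e-8,
                              minIdentity = 0)$read_id,
                   c("r1", "r2", "r3"))

  tab <- randomHitTable(1000, seed = 7)
  got <- filterHits(tab)
  oracle <- tab[tab$evalue <= 1e-10 & tab$pct_identity >= 50, ]
  expect_identical(got, oracle)
})

test_that("deduplication keeps one best hit per read and family", {
  h <- randomHitTable(50, seed = 3)
  hNoDup <- h[!duplicated(paste(h$read_id, h$family)), ]
  expect_identical(dedupHits(hNoDup), hNoDup)

  dup <- data.frame(read_id = "r1", gene_id = c("g1", "g1"),
                    family = "soxB", evalue = c(1e-20, 1e-25),
                    pct_identity = c(90, 70), stringsAsFactors = FALSE)
  expect_equal(dedupHits(dup)$evalue, 1e-25)

  # ties on e-value break by identity, then first occurrence
  tie <- data.frame(read_id = "r1", gene_id = c("a", "b", "c"),
                    family = "soxB", evalue = 1e-20,
                    pct_identity = c(80, 95, 95), stringsAsFactors = FALSE)
  expect_identical(dedupHits(tie)$gene_id, "b")

  # a read may still count once in each of several families
  multi <- data.frame(read_id = "r1", gene_id = c("g1", "g2"),
                      family = c("soxB", "dsrA"), evalue = 1e-20,
                      pct_identity = 90, stringsAsFactors = FALSE)
  expect_equal(nrow(dedupHits(multi)), 2)

  # randomized duplicated tables match the brute-force group-by oracle
  for (seed in 1:5) {
    tab <- randomHitTable(2000, nReads = 300, seed = seed)
    got <- dedupHits(filterHits(tab))
    counts <- table(got$family)
    oracle <- bruteforceFamilyCounts(tab)
    expect_equal(as.integer(counts[names(oracle)]), unname(oracle))
  }
})

test_that("NRA normalizes by gene length and copy number", {
  expect_equal(nra(0, 2000), 0)
  expect_equal(nra(100, 2000, 1), 50)
  expect_equal(nra(100, 2000, 2), 25)
  expect_error(nra(10, 0), "length")
  expect_error(nra(10, 1000, 0), "copy")
  # unit self-consistency: halving length doubles the per-kb abundance
  expect_equal(nra(100, 1000), 2 * nra(100, 2000))
})

test_that("binomial confidence intervals have the closed form and nominal coverage", {
  r <- nraCI(50, 100, lengthBp = 1000, copyNumber = 1)
  # SE(p = 0.5, n = 100) = 0.05; count CI = 100 * (0.5 +/- 2.58 * 0.05)
  expect_equal(r$ci_high - r$nra, 2.58 * 0.05 * 100, tolerance = 1e-12)
  expect_equal(r$nra - r$ci_low, 2.58 * 0.05 * 100, tolerance = 1e-12)

  r0 <- nraCI(0, 100, lengthBp = 1000)
  expect_equal(c(r0$ci_low, r0$nra, r0$ci_high), c(0, 0, 0))

  r1 <- nraCI(30, 40, lengthBp = 1500, copyNumber = 2)
  expect_true(r1$ci_low <= r1$nra && r1$nra <= r1$ci_high)
  expect_gte(r1$ci_low, 0)
  # NRA-scale bounds are the count-scale bounds over the same divisor
  p <- 30 / 40; se <- sqrt(p * (1 - p) / 40)
  expect_equal(r1$ci_high, 40 * (p + 2.58 * se) / 1.5 / 2, tolerance = 1e-12)

  expect_error(nraCI(1, 0, 1000), "positive")
  expect_error(nraCI(5, 4, 1000), "k must")

  # Monte-Carlo coverage of the 99% interval (Wald on counts)
  set.seed(20240601)
  n <- 1000; p <- 0.5; reps <- 2000
  k <- rbinom(reps, n, p)
  ph <- k / n
  se <- sqrt(ph * (1 - ph) / n)
  covered <- (n * (ph - 2.58 * se) <= n * p) & (n * p <= n * (ph + 2.58 * se))
  expect_gte(mean(covered), 0.98)
  expect_lte(mean(covered), 1.00)
})

test_that("the NRA table integrates filter, dedup, counting and CIs", {
  specs <- data.frame(family = c("soxB", "dsrA", "sqr", "aclB"),
                      length_bp = c(2000, 1500, 1300, 1200),
                      copy_number = c(1, 1, 2, 1),
                      stringsAsFactors = FALSE)
  tab <- randomHitTable(5000, nReads = 800, seed = 11)
  res <- nraTable(tab, specs)
  oracle <- bruteforceFamilyCounts(tab)
  expect_equal(res$k[match(names(oracle), res$family)], unname(oracle))
  expect_equal(unique(res$n_total), sum(oracle))
  i <- match("sqr", res$family)
  expect_equal(res$nra[i], res$k[i] / 1.3 / 2, tolerance = 1e-12)
  expect_true(all(res$ci_low <= res$nra & res$nra <= res$ci_high))

  # hits against a family absent from the spec table are an error
  expect_error(nraTable(tab, specs[1:2, ]), "missing")
  # an explicit denominator (e.g. all annotated proteins) is honored
  res2 <- nraTable(tab, specs, nTotal = 5e5)
  expect_equal(unique(res2$n_total), 5e5)
  expect_equal(res2$k, res$k)
})

test_that("significance calls are symmetric with touching intervals overlapping", {
  a <- data.frame(ci_low = 10, ci_high = 20)
  b <- data.frame(ci_low = 30, ci_high = 40)
  c_ <- data.frame(ci_low = 20, ci_high = 30)
  expect_identical(compareNRA(a, a), "not_significant")
  expect_identical(compareNRA(a, b), "significant")
  expect_identical(compareNRA(b, a), "significant")
  expect_identical(compareNRA(a, c_), "not_significant")
  expect_identical(compareNRA(c_, a), "not_significant")

  specs <- data.frame(family = c("soxB", "dsrA"),
                      length_bp = c(2000, 2000), copy_number = 1)
  tab <- randomHitTable(4000, nReads = 700, seed = 5)
  tab <- tab[tab$family %in% specs$family, ]
  m <- significanceMatrix(nraTable(tab, specs))
  expect_identical(m, t(m))
  expect_false(any(diag(m)))
})
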
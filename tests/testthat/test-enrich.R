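test_that("ORA matches the worked hypergeometric example", {
  uni <- sprintf("u%02d", 1:20)
  coll <- list(s1 = uni[1:5])
  query <- c(uni[1:4], uni[6:9])       # n = 8, k = 4, K = 5, N = 20
  res <- ora(query, coll, uni)
  expect_equal(res$foldEnrichment, 2.0)
  expect_equal(res$pValue, oracle_hyper_tail(4, 5, 20, 8),
               tolerance = 1e-12)
  # zero overlap: fold 0, p = 1
  res0 <- ora(uni[6:10], list(s1 = uni[1:5]), uni)
  expect_equal(res0$foldEnrichment, 0)
  expect_equal(res0$pValue, 1)
  # ids outside the universe dropped with a warning
  expect_warning(ora(c(uni[1:3], "zz"), coll, uni), "dropped")
  expect_error(suppressWarnings(ora("zz", coll, uni)), "empty query")
})

test_that("ORA equals brute-force enumeration on small universes", {
  for (N in c(5, 8, 12)) {
    uni <- sprintf("u%02d", seq_len(N))
    for (K in 1:N) {
      coll <- list(s = uni[seq_len(K)])
      for (n in 1:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          query <- c(uni[seq_len(k)],
                     if (n > k) uni[K + seq_len(n - k)])
          res <- suppressWarnings(ora(query, coll, uni))
          expect_equal(res$pValue, oracle_hyper_tail(k, K, N, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # larger universes, random instances
  set.seed(99)
  for (N in c(20, 30)) {
    uni <- sprintf("u%02d", seq_len(N))
    for (i in 1:20) {
      K <- sample(N, 1); n <- sample(N, 1)
      coll <- list(s = sample(uni, K))
      query <- sample(uni, n)
      k <- length(intersect(query, coll$s))
      res <- ora(query, coll, uni)
      expect_equal(res$pValue, oracle_hyper_tail(k, K, N, n),
                   tolerance = 1e-12)
      expect_equal(res$qValue, bh_adjust(res$pValue))
    }
  }
})

test_that("GSEA reproduces the brute-force running sum", {
  sc <- stats::setNames(c(3, 2, 1, 0.5, 0.1), paste0("g", 1:5))
  g <- gsea(sc, "g2", n_perm = 100, seed = 1)
  expect_equal(g$ES, 0.75)
  expect_equal(g$ES, oracle_gsea_es(sc, "g2"))
  expect_equal(g$leadingEdge, "g2")
  # set = all genes -> ES = 1
  expect_equal(gsea(sc, names(sc), n_perm = 50, seed = 1)$ES, 1.0)
  expect_error(gsea(sc, "absent", n_perm = 50), "intersect")
  expect_error(gsea(sc, "g2", n_perm = 5), "n_perm")
  # random instances vs the oracle
  set.seed(12)
  for (i in 1:10) {
    s <- stats::setNames(rnorm(60), sprintf("r%02d", 1:60))
    set <- sample(names(s), 8)
    expect_equal(gsea(s, set, n_perm = 20, seed = 2)$ES,
                 oracle_gsea_es(s, set), tolerance = 1e-12)
  }
})

test_that("GSEA ES is scale-invariant and antisymmetric under sign flip", {
  set.seed(5)
  s <- stats::setNames(rnorm(100), sprintf("g%03d", 1:100))
  set <- sample(names(s), 12)
  e1 <- gsea(s, set, n_perm = 20, seed = 3)$ES
  e2 <- gsea(s * 7.3, set, n_perm = 20, seed = 3)$ES
  expect_equal(e1, e2, tolerance = 1e-12)
  # flipping all score signs reverses the ranking and negates ES (up to
  # the tie-break at equal positive/negative deviation)
  e3 <- gsea(-s, set, n_perm = 20, seed = 3)$ES
  expect_equal(e3, -e1, tolerance = 1e-12)
})

test_that("GSEA matches the independent fgsea implementation", {
  set.seed(8)
  s <- sort(stats::setNames(rnorm(200), sprintf("g%03d", 1:200)),
            decreasing = TRUE)
  set <- sample(names(s), 15)
  mine <- gsea(s, set, n_perm = 50, seed = 1)$ES
  ref <- fgsea::calcGseaStat(s, selectedStats = match(set, names(s)),
                             gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("GSEA permutation p is healthy under the null", {
  healthy <- vapply(1:50, function(s) {
    set.seed(s + 700)
    scores <- stats::setNames(rnorm(200), sprintf("g%03d", 1:200))
    set <- sample(names(scores), 10)
    gsea(scores, set, n_perm = 200, seed = 7)$pValue > 0.05
  }, logical(1))
  expect_gte(sum(healthy), 45)
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  tss <- data.frame(chrom = "chr1", pos = c(50000, 58000, 400000),
                    strand = "+", geneId = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  dom <- regulatory_domains(tss, genome_size = 1e6)
  # neighbours clip the extension at the adjacent basal domain, but a
  # gene always keeps its own basal domain
  expect_equal(dom$end[dom$geneId == "a"], 55000)   # own basal end
  expect_equal(dom$start[dom$geneId == "b"], 53000) # own basal start
  # isolated gene gets the full extension
  expect_equal(dom$start[dom$geneId == "c"], 300000)
  expect_equal(dom$end[dom$geneId == "c"], 500000)
  # never below the basal domain
  expect_true(all(dom$start <= tss$pos - 5000 + 1e-9))
  expect_true(all(dom$end >= tss$pos + 5000 - 1e-9))
  expect_error(regulatory_domains(rbind(tss, tss[1, ]), 1e6), "unique")
})

test_that("binomial peak enrichment matches the closed-form tail", {
  mk_peaks <- function(mids) data.frame(
    chrom = "chr1", start = mids - 1, end = mids + 1,
    name = sprintf("p%03d", seq_along(mids)), stringsAsFactors = FALSE)
  # worked example: n = 10, p0 = 0.2, k = 5
  dom <- data.frame(chrom = "chr1", start = 0, end = 200,
                    geneId = "g1", stringsAsFactors = FALSE)
  pk <- mk_peaks(c(seq(10, 170, length.out = 5) %/% 1,
                   seq(300, 900, length.out = 5) %/% 1))
  res <- region_enrichment_binomial(pk, dom, "g1", genome_size = 1000)
  expect_equal(res$k, 5)
  expect_equal(res$coverage, 0.2)
  expect_equal(res$pValue, oracle_binom_tail(5, 10, 0.2),
               tolerance = 1e-12)
  expect_equal(round(res$pValue, 4), 0.0328)
  # k = 0 -> p = 1; full coverage -> k = n, p = 1
  res0 <- region_enrichment_binomial(mk_peaks(c(500, 700)), dom, "g1",
                                     1000)
  expect_equal(res0$pValue, 1)
  domf <- data.frame(chrom = "chr1", start = 0, end = 1000,
                     geneId = "g1", stringsAsFactors = FALSE)
  resf <- region_enrichment_binomial(mk_peaks(c(10, 500)), domf, "g1",
                                     1000)
  expect_equal(resf$k, resf$n)
  expect_equal(resf$pValue, 1)
})

test_that("binomial tail agrees with enumeration over an n <= 25 grid", {
  dom_for <- function(p0) data.frame(chrom = "chr1", start = 0,
                                     end = p0 * 1000, geneId = "g1",
                                     stringsAsFactors = FALSE)
  for (p0 in c(0.2, 0.5)) {
    dom <- dom_for(p0)
    for (n in c(1, 5, 12, 25)) {
      for (k in 0:n) {
        mids <- c(if (k > 0) seq(5, p0 * 1000 - 5, length.out = k),
                  if (n - k > 0) seq(p0 * 1000 + 5, 995,
                                     length.out = n - k))
        pk <- data.frame(chrom = "chr1", start = floor(mids) - 1,
                         end = floor(mids) + 1,
                         name = sprintf("p%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
        res <- region_enrichment_binomial(pk, dom, "g1", 1000)
        expect_equal(res$k, k)
        expect_equal(res$pValue, oracle_binom_tail(k, n, p0),
                     tolerance = 1e-9)
      }
    }
  }
})
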
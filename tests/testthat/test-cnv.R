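seg <- function(chrom, start, end, cn, minor = pmin(1, cn), lr = NULL) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  total_cn = cn, minor_cn = minor)
  if (!is.null(lr)) d$log_ratio <- lr
  d
}

test_that("category calls partition segments relative to rounded ploidy", {
  p <- seg("chr9", 0, 5e6, 0)
  expect_equal(as.character(call_cn_categories(p, 3)$category),
               "homozygous_deletion")
  expect_equal(as.character(call_cn_categories(seg("chr1", 0, 1e6, 2), 2)$category),
               "neutral")
  expect_equal(as.character(call_cn_categories(seg("chr1", 0, 1e6, 5), 2)$category),
               "amplification")
  expect_equal(as.character(call_cn_categories(seg("chr1", 0, 1e6, 4), 2)$category),
               "gain")
  expect_equal(as.character(call_cn_categories(seg("chr1", 0, 1e6, 2), 3.2)$category),
               "loss")
  # partition property: every segment gets exactly one category
  set.seed(8)
  prof <- seg(paste0("chr", 1:22), 0, 1e7, sample(0:8, 22, replace = TRUE))
  cats <- call_cn_categories(prof, 2.7)$category
  expect_false(any(is.na(cats)))
  expect_error(call_cn_categories(seg("chr1", 0, 1e6, -1), 2), "negative|minor")
})

test_that("profile correlation has Pearson structure and matches a direct oracle", {
  set.seed(21)
  lr1 <- round(rnorm(22, 0, 0.5), 3)
  lr2 <- lr1; lr2[1:3] <- rnorm(3)  # ~90% shared segments
  genome <- genome_definition()
  p1 <- seg(names(genome), 0, unname(genome), 2, 1, lr1)
  p2 <- seg(names(genome), 0, unname(genome), 2, 1, lr2)
  neg <- seg(names(genome), 0, unname(genome), 2, 1, -lr1)
  res <- cn_correlation_matrix(list(a = p1, b = p2, n = neg))
  expect_equal(unname(diag(res$r)), c(1, 1, 1))
  expect_equal(res$r, t(res$r))
  expect_true(all(res$r >= -1 - 1e-12 & res$r <= 1 + 1e-12))
  expect_equal(res$r["a", "n"], -1)
  # oracle: direct Pearson on length-weighted bin vectors
  w <- rep(ceiling(genome / 1e6), length(genome) * 0 + 1)
  oracle <- cor(rep(lr1, ceiling(genome / 1e6)), rep(lr2, ceiling(genome / 1e6)))
  expect_lt(abs(res$r["a", "b"] - oracle), 0.03)
  # invariant to adding a constant to all log ratios
  p2s <- p2; p2s$log_ratio <- p2s$log_ratio + 0.7
  res2 <- cn_correlation_matrix(list(a = p1, b = p2s))
  expect_equal(res2$r["a", "b"], res$r["a", "b"], tolerance = 1e-12)
  # strong concordance is highly significant
  expect_lt(res$p["a", "b"], 1e-4)
})

test_that("homozygous deletions intersect genes with half-open semantics", {
  genes <- data.frame(chrom = "chr9", start = c(21.9e6, 21.8e6, 30e6),
                      end = c(22.1e6, 21.95e6, 30.5e6),
                      gene = c("CDKN2A", "MTAP", "OTHER"))
  prof <- seg("chr9", c(21.85e6, 40e6), c(22.0e6, 41e6), c(0, 2))
  hits <- find_homozygous_deletions(prof, genes)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$genes, "CDKN2A,MTAP")
  # no CN-0 segments
  expect_equal(nrow(find_homozygous_deletions(seg("chr9", 0, 1e6, 2), genes)), 0)
  # abutment at the half-open boundary is not an overlap
  prof2 <- seg("chr9", 21.0e6, 21.8e6, 0)
  expect_equal(find_homozygous_deletions(prof2, genes)$genes, "")
})
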
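make_filter_fixture <- function() {
  # six observations constructed to hit each rule of the cascade once:
  # v1/A primary pass; v2 relaxed pass in A (2 alt reads, sibling B passes);
  # v3/A fails the VAF floor; v4/A fails read support with no sibling rescue;
  # v5/A removed by the panel of normals despite strong support
  data.frame(
    variant_id = c("v1", "v2", "v2", "v3", "v4", "v5"),
    patient = "pt1",
    population = c("A", "A", "B", "A", "A", "A"),
    alt = c(10, 2, 8, 10, 2, 30),
    depth = c(100, 40, 80, 2500, 40, 100))
}

test_that("filter cascade applies primary, relaxed, VAF and panel rules", {
  fx <- make_filter_fixture()
  res <- apply_filters(fx, filter_config(), pon_hits = c(v5 = 3L))
  expect_equal(sort(unique(res$retained$variant_id)), c("v1", "v2"))
  expect_equal(nrow(res$retained), 3)  # v1/A, v2/A, v2/B
  expect_equal(unname(res$tally["retained"]), 3L)
  expect_equal(unname(res$tally["panel_of_normals"]), 1L)
  expect_equal(unname(res$tally["vaf_below_min"]), 1L)
  expect_equal(unname(res$tally["insufficient_reads"]), 1L)
})

test_that("relaxed rule requires a sibling population passing the primary rule", {
  fx <- data.frame(variant_id = "v1", patient = "pt1",
                   population = c("A", "B"), alt = c(2, 2), depth = c(40, 40))
  res <- apply_filters(fx, filter_config())
  expect_equal(nrow(res$retained), 0)
  # and never rescues a record failing the VAF floor
  fx2 <- data.frame(variant_id = "v1", patient = "pt1",
                    population = c("A", "B"), alt = c(2, 50), depth = c(500, 100))
  res2 <- apply_filters(fx2, filter_config())
  expect_equal(res2$retained$population, "B")
})

test_that("filtering is idempotent and the tally conserves the input", {
  set.seed(31)
  for (trial in 1:15) {
    tab <- toy_variant_table(n_var = 60, pops = c("A", "B", "C"),
                             vaf = runif(1, 0.01, 0.3),
                             depth = sample(20:150, 1))
    pon <- setNames(sample(0:3, 10, replace = TRUE),
                    sample(unique(tab$variant_id), 10))
    res1 <- apply_filters(tab, filter_config(), pon_hits = pon)
    expect_equal(sum(res1$tally), nrow(tab))
    res2 <- apply_filters(res1$retained, filter_config(), pon_hits = pon)
    expect_identical(res2$retained, res1$retained)
    expect_equal(unname(res2$tally["retained"]), nrow(res1$retained))
  }
})

test_that("unknown populations in the patient map are rejected", {
  fx <- make_filter_fixture()
  expect_error(
    apply_filters(fx, filter_config(),
                  patient_populations = list(pt1 = c("A"))),
    "absent from patient map")
  expect_silent(
    apply_filters(fx, filter_config(),
                  patient_populations = list(pt1 = c("A", "B"))))
})

test_that("driver annotation flags non-synonymous hits on the list only", {
  rec <- data.frame(gene = c("NRAS", "NRAS", "TTN"),
                    effect = c("non_synonymous", "synonymous", "non_synonymous"))
  out <- annotate_drivers(rec, c("NRAS", "BRAF"))
  expect_equal(out$driver, c(TRUE, FALSE, FALSE))
  expect_false(any(annotate_drivers(rec, character(0))$driver))
})

test_that("driver clonality matrix counts mutations clonal in all their populations", {
  fx <- read.delim(system.file("extdata", "driver_clonality_fixture.tsv",
                               package = "clonesort"))
  drivers <- read_driver_genes(system.file("extdata", "melanoma_driver_genes.txt",
                                           package = "clonesort"))
  res <- driver_clonality_matrix(annotate_drivers(fx, drivers))
  expect_equal(res$n_driver, 14L)
  expect_equal(res$n_clonal, 10L)
  expect_equal(res$clonal_pct, 71.4)
  expect_equal(dim(res$matrix), c(14L, 8L))
})

test_that("TMB divides mutation count by callable megabases", {
  expect_equal(tmb(390, 30), 13.0)
  expect_equal(tmb(0, 30), 0.0)
  ret <- data.frame(variant_id = sprintf("v%d", 1:357))
  expect_equal(tmb(ret, 35.7), 10.0)
  expect_error(tmb(10, 0), "> 0")
})

test_that("shared/private summary reproduces the worked percentages", {
  # 995 of 1072 mutations shared by both populations
  shared_ids <- sprintf("s%04d", 1:995)
  priv_ids <- sprintf("p%04d", 1:77)
  rec <- rbind(
    expand.grid(variant_id = shared_ids, population = c("PST", "MT"),
                stringsAsFactors = FALSE),
    data.frame(variant_id = priv_ids, population = "MT"))
  s <- shared_private_summary(rec, c("PST", "MT"))
  expect_equal(s["shared_by_all", "count"], 995L)
  expect_equal(s["shared_by_all", "pct"], 92.8)
  # 813 of 1164 private
  rec2 <- rbind(
    expand.grid(variant_id = sprintf("s%04d", 1:351),
                population = c("PST", "MT"), stringsAsFactors = FALSE),
    data.frame(variant_id = sprintf("p%04d", 1:813), population = "MT"))
  s2 <- shared_private_summary(rec2, c("PST", "MT"))
  expect_equal(s2["private", "pct"], 69.8)
  expect_lt(abs(sum(s2$pct) - 100), 0.1)
  # degenerate: everything shared
  s3 <- shared_private_summary(
    expand.grid(variant_id = c("a", "b"), population = c("X", "Y"),
                stringsAsFactors = FALSE), c("X", "Y"))
  expect_equal(s3["shared_by_all", "pct"], 100)
  expect_equal(s3["private", "pct"], 0)
  expect_error(shared_private_summary(rec, "PST"), ">= 2 populations")
})
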
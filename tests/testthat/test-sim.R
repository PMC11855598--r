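test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_patient(patient1_config(seed = 9))
  s2 <- simulate_patient(patient1_config(seed = 9))
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$facs, s2$facs)
  s3 <- simulate_patient(patient1_config(seed = 10))
  expect_false(identical(s1$variants$alt, s3$variants$alt))
})

test_that("observed VAFs converge to the closed-form expectation", {
  # depth 200, CCF 0.5, purity 0.9, CN_t 2, m 1:
  # expected VAF = 0.5 * 0.9 / (0.9*2 + 0.1*2) = 0.225
  set.seed(23)
  n <- 1000; depth <- 200
  v_exp <- expected_vaf(0.5, 0.9, 2, 2, 1)
  expect_equal(v_exp, 0.225)
  alt <- rbinom(n, depth, v_exp)
  se <- sqrt(v_exp * (1 - v_exp) / (depth * n))
  expect_lt(abs(mean(alt / depth) - v_exp), 3 * se)

  # and in the full simulator: truncal mutations of a diploid pure
  # population are expected at VAF 0.5
  pops <- data.frame(id = c("X", "Y"), biopsy = "b", site = c("primary", "metastasis"),
                     ploidy = 2, purity = 0.5, purity_postsort = 1)
  cc <- function(...) setNames(c(...), pops$id)
  cfg <- sim_config(pops, list(list(ccf = cc(1, 1), n = 400, parent = NA)),
                    depth_mean = 150,
                    cn_profiles = list(
                      X = data.frame(chrom = names(genome_definition()), start = 0,
                                     end = unname(genome_definition()),
                                     total_cn = 2, minor_cn = 1),
                      Y = data.frame(chrom = names(genome_definition()), start = 0,
                                     end = unname(genome_definition()),
                                     total_cn = 2, minor_cn = 1)),
                    seed = 31)
  sim <- simulate_patient(cfg)
  expect_lt(abs(mean(sim$variants$vaf) - 0.5), 0.01)
})

test_that("configurations violating cluster containment are rejected", {
  pops <- data.frame(id = c("A", "B"), biopsy = "b", site = c("primary", "metastasis"),
                     ploidy = 2, purity = 0.5, purity_postsort = 0.9)
  cc <- function(...) setNames(c(...), pops$id)
  good <- list(list(ccf = cc(1, 1), n = 10, parent = NA),
               list(ccf = cc(0.5, 0), n = 10, parent = 1))
  expect_s3_class(sim_config(pops, good), "sim_config")
  bad <- list(list(ccf = cc(1, 1), n = 10, parent = NA),
              list(ccf = cc(0.5, 0), n = 10, parent = 1),
              list(ccf = cc(0.8, 0), n = 10, parent = 2))
  expect_error(sim_config(pops, bad), "containment")
  not_truncal <- list(list(ccf = cc(1, 0.9), n = 10, parent = NA))
  expect_error(sim_config(pops, not_truncal), "truncal")
})

test_that("the reference patient restricts its PST1/MT2 lineage correctly", {
  sim <- simulate_patient(patient1_config(seed = 12))
  v <- sim$variants
  c4 <- v[v$cluster == 4, ]
  # expected VAF is zero outside PST1 and MT2, so alt counts are all zero
  expect_true(all(c4$alt[c4$population %in% c("PST2", "MT1")] == 0))
  expect_gt(mean(c4$alt[c4$population == "MT2"] > 0), 0.95)
  # truth bookkeeping is consistent with the emitted tables
  expect_equal(unname(sim$truth$cluster[v$variant_id[v$cluster == 4]][1]), 4L)
  expect_equal(sim$truth$seeding, c(MT1 = "PST2", MT2 = "PST1"))
})

test_that("FACS event simulation shapes DAPI and marker as configured", {
  pops <- data.frame(id = "T", ploidy = 2.6, purity = 0.6, marker_rate = 1)
  ev <- simulate_facs_events(pops, n_events = 20000, facs_cv = 0.05,
                             seed = 3, g2m_fraction = 0.1)
  tum <- ev[ev$population == "T", ]
  expect_lt(abs(mean(tum$phase == "G2/M") - 0.1), 0.01)
  g01 <- tum$dapi[tum$phase == "G0/G1"]
  g2m <- tum$dapi[tum$phase == "G2/M"]
  expect_lt(abs(median(g2m) / median(g01) - 2), 0.05)
  expect_error(simulate_facs_events(pops, 20000, facs_cv = 0), "facs_cv")
  expect_error(simulate_facs_events(pops, 50), "n_events")
})

test_that("signature context simulation is multinomial over the mixture", {
  ref <- toy_signature_reference()
  x <- simulate_signature_contexts(1000, c(UV.like = 1), ref, seed = 2)
  expect_equal(sum(x), 1000)
  expect_true(all(x[ref[, "UV.like"] == 0] == 0))
  expect_equal(sum(simulate_signature_contexts(0, c(UV.like = 1), ref)), 0)
  expect_error(simulate_signature_contexts(10, c(UV.like = -0.2, Flat = 1.2), ref),
               "non-negative")
})
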
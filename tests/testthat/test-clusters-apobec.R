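test_that("cluster calling finds maximal runs within the distance cap", {
  mk <- function(pos, ref = "C", alt = "T") sample_catalog(
    "s", data.frame(contig = "chr1", pos = pos, ref = ref, alt = alt))
  cl <- call_clusters(mk(c(1000, 1500, 2200, 500000)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3)
  expect_equal(cl$members[[1]], c(1000, 1500, 2200))
  expect_equal(attr(cl, "membership"), c(1L, 1L, 1L, NA))

  # all gaps above the cap: no clusters
  expect_equal(nrow(call_clusters(mk(c(1, 20001, 40001)))), 0)

  # chained gaps of 9000 form one cluster despite an 18000 bp span
  cl3 <- call_clusters(mk(c(1000, 10000, 19000)))
  expect_equal(cl3$size, 3)
  expect_equal(cl3$span, 18000)

  # record order does not matter and calling is idempotent
  shuffled <- mk(c(2200, 500000, 1000, 1500))
  expect_equal(call_clusters(shuffled)$members,
               call_clusters(mk(c(1000, 1500, 2200, 500000)))$members)

  # every mutation is in exactly one cluster or scattered
  set.seed(3)
  pos <- sort(sample.int(3e5, 120))
  cl <- call_clusters(mk(pos))
  mem <- attr(cl, "membership")
  expect_equal(sum(cl$size) + sum(is.na(mem)), 120)
})

test_that("coordination labels reflect single-base runs", {
  expect_equal(classify_coordination(c("C", "C", "C")), "GC_coordinated")
  expect_equal(classify_coordination(c("G", "G")), "GC_coordinated")
  expect_equal(classify_coordination(c("C", "G")), "non_coordinated")
  expect_equal(classify_coordination(c("T", "T")), "AT_coordinated")
  expect_equal(classify_coordination(c("A", "T")), "non_coordinated")
  expect_error(classify_coordination("C"), "at least 2")

  # invariant under strand flip of the whole catalogue
  g <- make_genome(3e4, seed = 71)
  sim <- make_catalog(g, 30,
                      list(process_spec("tCw", "fixed_count", 30,
                                        clustered_fraction = 0.6)),
                      seed = 72, sample_id = "s")
  cat <- exclude_complex(sim$catalog)
  cl1 <- call_clusters(cat)
  cl2 <- call_clusters(exclude_complex(flip_catalog(sim$catalog, g)))
  expect_equal(sort(table(cl1$coordination)),
               sort(table(cl2$coordination)))
})

test_that("category enrichment partitions and matches the genome-wide run", {
  g <- make_genome(5e4, seed = 81)
  sim <- make_catalog(g, 100,
                      list(process_spec("tCw", "fixed_count", 60,
                                        clustered_fraction = 0.5)),
                      seed = 82, sample_id = "s")
  cat <- exclude_complex(sim$catalog)
  cl <- call_clusters(cat)
  reg <- builtin_registry()
  tcw <- get_motif(reg, "tCw")

  gw <- category_enrichment(cat, cl, tcw, g, "genome_wide")
  direct <- build_count_table(cat, tcw, g)
  expect_equal(gw$mut_in_motif, direct$mut_in_motif)
  expect_equal(gw$ctx_center, direct$ctx_center)

  strata <- lapply(c("gc_clusters_size_2", "gc_clusters_size_3",
                     "gc_clusters_size_4plus"), function(cc)
    category_enrichment(cat, cl, tcw, g, cc))
  all_gc <- category_enrichment(cat, cl, tcw, g, "gc_clusters_all")
  expect_equal(sum(vapply(strata, `[[`, 0, "mut_in_motif")),
               all_gc$mut_in_motif)
  expect_equal(sum(vapply(strata, `[[`, 0, "mut_in_class")),
               all_gc$mut_in_class)
})

test_that("Breslow-Day reproduces reference values and symmetries", {
  t1 <- matrix(c(50, 50, 50, 50), 2, byrow = TRUE)
  t2 <- matrix(c(80, 20, 20, 80), 2, byrow = TRUE)
  # identical strata are perfectly homogeneous
  bd0 <- breslow_day(list(t2, t2))
  expect_equal(bd0$statistic, 0, tolerance = 1e-10)
  expect_equal(bd0$p_value, 1)

  # odds ratios 1 vs 16 at n = 200/stratum
  # (reference values: statsmodels StratifiedTable.test_equal_odds)
  bd <- breslow_day(list(t1, t2))
  expect_equal(bd$statistic, 39.214172734088606, tolerance = 1e-8)
  expect_equal(bd$p_value, 3.79773434922015e-10, tolerance = 1e-6)
  expect_equal(bd$common_or, 3.0689655172413794, tolerance = 1e-10)
  expect_lt(bd$p_value, 0.05)

  t3 <- matrix(c(8, 2, 20, 80), 2, byrow = TRUE)
  t4 <- matrix(c(15, 35, 120, 230), 2, byrow = TRUE)
  bd2 <- breslow_day(list(t3, t4))
  expect_equal(bd2$statistic, 14.946800701327012, tolerance = 1e-8)
  expect_equal(bd2$p_value, 0.00011058541741215677, tolerance = 1e-6)
  bd2t <- breslow_day(list(t3, t4), tarone = TRUE)
  expect_equal(bd2t$statistic, 14.943878486352459, tolerance = 1e-8)

  t5 <- matrix(c(12, 30, 40, 200), 2, byrow = TRUE)
  t6 <- matrix(c(30, 60, 90, 400), 2, byrow = TRUE)
  t7 <- matrix(c(5, 9, 33, 70), 2, byrow = TRUE)
  bd3 <- breslow_day(list(t5, t6, t7))
  expect_equal(bd3$df, 2)
  expect_equal(bd3$statistic, 0.9736752135971566, tolerance = 1e-8)
  expect_equal(bd3$p_value, 0.614566826315942, tolerance = 1e-8)

  # swapping strata changes nothing
  expect_equal(breslow_day(list(t2, t1))$statistic, bd$statistic)

  # degenerate strata are dropped; fewer than two usable strata error
  expect_warning(bdd <- breslow_day(list(t1, t2,
    matrix(c(0, 0, 5, 5), 2, byrow = TRUE))), "degenerate")
  expect_equal(bdd$n_strata, 2)
  expect_error(suppressWarnings(
    breslow_day(list(t1, matrix(c(0, 0, 5, 5), 2, byrow = TRUE)))),
    "at least 2")
})

test_that("ytCa-restricted deamination is assigned to the A3A-like motif", {
  g <- make_genome(2e5, seed = 61)
  sim <- make_catalog(g, 150,
                      list(process_spec("ytCa", "fixed_count", 220,
                                        clustered_fraction = 0.4)),
                      seed = 62, sample_id = "apobec")
  cat <- exclude_complex(sim$catalog)
  res <- subtype_analysis(cat, g)
  gw <- res[res$category == "genome_wide", ]
  expect_gt(gw$ytca_enrichment, gw$rtca_enrichment)
  expect_lt(gw$ytca_p, 0.05)
  # where both motifs test significant the Breslow-Day row is emitted
  emitted <- res[!is.na(res$bd_p), ]
  if (nrow(emitted) > 0) {
    expect_true(all(emitted$preferred == "ytCa"))
  }
  # no-significance rows carry no comparison
  expect_true(all(is.na(res$bd_p[is.na(res$ytca_p) | res$ytca_p > 0.05])))
})
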
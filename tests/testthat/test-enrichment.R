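test_that("complex mutations (<=10 bp apart) are excluded, chains wholly", {
  mk <- function(pos) sample_catalog(
    "s", data.frame(contig = "c", pos = pos, ref = "A", alt = "G"))
  expect_equal(exclude_complex(mk(c(100, 105, 300)))$records$pos, 300)
  expect_equal(exclude_complex(mk(c(100, 111)))$records$pos, c(100, 111))
  # chain via 8-bp links: pairwise oracle removes all three
  expect_equal(nrow(exclude_complex(mk(c(100, 108, 116)))$records), 0)
  expect_equal(attr(exclude_complex(mk(c(100, 108, 116))), "n_complex"), 3L)
  # different contigs never pair
  two <- sample_catalog("s", data.frame(contig = c("c1", "c2"),
                                        pos = c(100, 105),
                                        ref = "A", alt = "G"))
  expect_equal(nrow(exclude_complex(two)$records), 2)

  set.seed(21)
  for (i in 1:15) {
    pos <- sort(sample.int(2000, 40))
    got <- exclude_complex(mk(pos))$records$pos
    d <- as.matrix(dist(pos))
    diag(d) <- Inf
    keep_oracle <- pos[apply(d, 1, min) > 10]
    expect_equal(got, keep_oracle)
  }
})

test_that("count tables match a hand scan for a single mutation", {
  g <- reference_genome(c(chr1 = "AATAA"))
  cat <- sample_catalog("s", data.frame(contig = "chr1", pos = 3,
                                        ref = "T", alt = "C"))
  tab <- build_count_table(cat, get_motif(builtin_registry(), "aTn"), g,
                           flank = 2)
  expect_equal(tab$mut_in_class, 1)
  expect_equal(tab$mut_in_motif, 1)
  # window AATAA: t on both strands = #T + #A = 5; atn = ATA fwd + ATT rev
  expect_equal(tab$ctx_center, 5)
  expect_equal(tab$ctx_motif, 2)

  empty <- sample_catalog("s", data.frame(contig = character(0),
                                          pos = integer(0),
                                          ref = character(0),
                                          alt = character(0)))
  tab0 <- build_count_table(empty, get_motif(builtin_registry(), "aTn"), g)
  expect_equal(unlist(unclass(tab0)), c(mut_in_motif = 0, mut_in_class = 0,
                                        ctx_motif = 0, ctx_center = 0))
})

test_that("enrichment follows the (mut x ctx) / (class x motif) formula", {
  expect_equal(enrichment_ratio(motif_count_table(20, 100, 200, 1000)), 1)
  expect_equal(enrichment_ratio(motif_count_table(40, 100, 200, 1000)), 2)
  expect_equal(enrichment_ratio(motif_count_table(0, 100, 200, 1000)), 0)
  expect_true(is.na(enrichment_ratio(motif_count_table(0, 0, 200, 1000))))
  expect_true(is.na(enrichment_ratio(motif_count_table(0, 100, 0, 0))))
})

test_that("one-sided Fisher p equals the hypergeometric enumeration", {
  expect_equal(fisher_one_sided(motif_count_table(8, 10, 20, 100)),
               enum_fisher_upper(8, 2, 20, 80), tolerance = 1e-12)
  # zero observed in-motif mutations can never be overrepresented
  expect_equal(fisher_one_sided(motif_count_table(0, 7, 13, 40)), 1)
  # degenerate margins
  expect_equal(fisher_one_sided(motif_count_table(0, 0, 10, 20)), 1)

  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    tab <- motif_count_table(a, a + b, c, c + d)
    expect_equal(fisher_one_sided(tab), enum_fisher_upper(a, b, c, d),
                 tolerance = 1e-9, info = paste(cells, collapse = ","))
  }

  # p decreases as the in-motif cell grows with fixed margins
  ps <- vapply(0:10, function(k)
    fisher_one_sided(motif_count_table(k, 10, 30 - k, 100)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(c(0.04, 0.01, 0.03)), c(0.04, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("MEML applies the minimum-load formula behind the gate", {
  tab <- motif_count_table(40, 100, 200, 1000)
  expect_equal(meml(tab, 2, 0.01), 20)
  expect_equal(meml(tab, 2, 0.2), 0)     # not significant
  expect_equal(meml(tab, 0.8, 0.01), 0)  # not enriched
  expect_equal(meml(tab, 1e9, 1e-9), 40 * (1e9 - 1) / 1e9) # -> mut_in_motif
  expect_equal(meml(tab, NA_real_, NA_real_), 0)
})

test_that("run_enrichment gates MEML and orders output deterministically", {
  g <- make_genome(3e4, seed = 91)
  sim <- make_catalog(g, 60, seed = 92, sample_id = "one")
  reg <- builtin_registry()

  res1 <- run_enrichment(sim$catalog, g, registry = reg["aTn"])
  expect_equal(nrow(res1), 1)
  expect_equal(res1$q_value, res1$p_value)  # single test: q = p

  res <- run_enrichment(sim$catalog, g)
  expect_equal(res$motif, names(reg))
  expect_true(all(res$meml >= 0 & res$meml <= res$mut_in_motif))
  gate_fail <- is.na(res$enrichment) | res$enrichment <= 1 |
    res$q_value > 0.05
  expect_true(all(res$meml[gate_fail] == 0))
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))

  # for enriched tables, doubling every count leaves enrichment
  # unchanged and strengthens the evidence (p never larger)
  enriched <- which(res$status == "ok" & res$enrichment > 1)
  for (i in utils::head(enriched, 5)) {
    tab <- motif_count_table(res$mut_in_motif[i], res$mut_in_class[i],
                             res$ctx_motif[i], res$ctx_center[i])
    tab2 <- motif_count_table(2 * res$mut_in_motif[i],
                              2 * res$mut_in_class[i],
                              2 * res$ctx_motif[i], 2 * res$ctx_center[i])
    expect_equal(enrichment_ratio(tab2), enrichment_ratio(tab))
    expect_lte(fisher_one_sided(tab2), fisher_one_sided(tab) + 1e-12)
  }
})

test_that("the pipeline is invariant under genome reverse complement", {
  g <- make_genome(3e4, seed = 55)
  sim <- make_catalog(g, 80, list(process_spec("nCg", "fixed_count", 30)),
                      seed = 56, sample_id = "s")
  res1 <- run_enrichment(sim$catalog, g)
  res2 <- run_enrichment(flip_catalog(sim$catalog, g), flip_genome(g))
  cols <- c("motif", "mut_in_motif", "mut_in_class", "ctx_motif",
            "ctx_center", "enrichment", "p_value", "q_value", "meml")
  expect_identical(res1[, cols], res2[, cols])
})

test_that("reference-mismatching records are skipped with a count", {
  g <- reference_genome(c(chr1 = strrep("ACGT", 2500)))
  rec <- data.frame(contig = "chr1", pos = c(2, 6, 11),
                    ref = c("C", "C", "A"), alt = c("T", "T", "G"))
  # pos 11 has reference G in the genome, not A
  cat <- sample_catalog("s", rec)
  res <- run_enrichment(cat, g, registry = builtin_registry()["nCg"],
                        drop_complex = FALSE)
  expect_equal(res$n_ref_mismatch, 1)
  expect_equal(res$mut_in_class, 2)
})
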
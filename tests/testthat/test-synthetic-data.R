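test_that("simulated genomes respect composition, CpG factor and seeds", {
  g <- make_genome(1e5, seed = 1)
  s <- unclass(g)[[1]]
  freq <- table(strsplit(s, "")[[1]]) / nchar(s)
  expect_true(all(abs(freq - 0.25) < 0.01))   # ~3 binomial SEs at 1e5

  # determinism: identical seeds give identical FASTA bytes
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(make_genome(2e4, seed = 9), f1)
  write_genome_fasta(make_genome(2e4, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(unclass(make_genome(2e4, seed = 10))[[1]],
                         unclass(make_genome(2e4, seed = 9))[[1]]))

  # cpg_factor = 0 eliminates CG dinucleotides entirely
  count_cg <- function(gg) {
    m <- gregexpr("CG", unclass(gg)[[1]], fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  expect_equal(count_cg(make_genome(2e4, cpg_factor = 0, seed = 2)), 0L)
  # cpg_factor > 1 inflates CpG frequency
  expect_gt(count_cg(make_genome(5e4, cpg_factor = 3, seed = 3)),
            1.5 * count_cg(make_genome(5e4, seed = 3)))

  expect_error(make_genome(5e3, seed = 1), ">= 1e4")
  expect_error(make_genome(2e4, base_composition = c(1, 1, 1, 1),
                           seed = 1), "summing to 1")
})

test_that("catalogue simulation honors process targets and truth", {
  g <- make_genome(5e4, seed = 31)
  reg <- builtin_registry()

  # pure process catalogue: every mutation matches the motif
  sim <- make_catalog(g, 0, list(process_spec("aTn", "fixed_count", 50)),
                      seed = 32, sample_id = "pure")
  expect_equal(nrow(sim$catalog$records), 50)
  atn <- get_motif(reg, "aTn")
  for (i in seq_len(50)) {
    r <- sim$catalog$records[i, ]
    w <- extract_window(g, r$contig, r$pos, flank = 2)
    expect_true(mutation_matches(atn, w, r$ref, r$alt))
  }

  # empty process list: catalogue is all background
  bg <- make_catalog(g, 77, seed = 33, sample_id = "bg")
  expect_equal(nrow(bg$catalog$records), 77)
  expect_equal(bg$truth$injected[bg$truth$process == "background"], 77)

  # truth conservation: catalogue size = background + injected
  mix <- make_catalog(g, 100,
                      list(process_spec("nCg", "fixed_count", 40),
                           process_spec("tCw", "fixed_count", 25)),
                      seed = 34, sample_id = "mix")
  expect_equal(nrow(mix$catalog$records), 100 + 40 + 25)
  expect_equal(sum(mix$truth$injected), 100 + 40 + 25)

  # positions are unique
  k <- with(mix$catalog$records, paste(contig, pos))
  expect_equal(anyDuplicated(k), 0)

  # site exhaustion fails loudly
  expect_error(make_catalog(g, 0,
                            list(process_spec("aTn", "fixed_count", 1e6)),
                            seed = 35),
               "site exhaustion")

  # determinism at the catalogue level
  a <- make_catalog(g, 50, list(process_spec("nCg", "fixed_count", 20)),
                    seed = 36)
  b <- make_catalog(g, 50, list(process_spec("nCg", "fixed_count", 20)),
                    seed = 36)
  expect_identical(a$catalog$records, b$catalog$records)
  expect_identical(a$truth, b$truth)
})

test_that("injected clustered runs are recovered with correct labels", {
  g <- make_genome(5e5, seed = 51)
  # few runs on a large genome so independent runs rarely fall within
  # one inter-mutation-distance cap of each other
  sim <- make_catalog(g, 0,
                      list(process_spec("tCw", "fixed_count", 12,
                                        clustered_fraction = 1,
                                        cluster_span = 4000)),
                      seed = 52, sample_id = "runs")
  cat <- exclude_complex(sim$catalog)
  expect_equal(attr(cat, "n_complex"), 0)  # runs are spaced > 10 bp
  cl <- call_clusters(cat)
  mem <- attr(cl, "membership")
  # every injected run is recovered inside a single called cluster;
  # runs of same-strand tCw sites are all-C or all-G, so a cluster is
  # GC-coordinated unless two independent opposite-strand runs merged
  rt <- sim$record_truth
  rec_key <- with(cat$records, paste(contig, pos))
  runs <- split(rt, rt$run_id)
  cluster_of_run <- integer(length(runs))
  for (i in seq_along(runs)) {
    ids <- mem[match(paste(runs[[i]]$contig, runs[[i]]$pos), rec_key)]
    expect_false(anyNA(ids))            # recalled as clustered
    expect_length(unique(ids), 1)       # not split across clusters
    cluster_of_run[i] <- ids[1]
  }
  # clusters holding exactly one injected run carry the correct label;
  # clusters where two opposite-strand runs merged may legitimately be
  # non-coordinated
  solo <- as.integer(names(which(table(cluster_of_run) == 1)))
  expect_true(all(cl$coordination[solo] == "GC_coordinated"))
})

test_that("cohorts derive per-sample seeds and scale rates with age", {
  g <- make_genome(1e5, seed = 61)
  design <- data.frame(donor_id = paste0("d", 1:6),
                       age = c(20, 20, 50, 50, 80, 80),
                       disease = rep(c("healthy", "copd"), 3))
  proc <- list(process_spec("nCg", "per_year_rate", 1,
                            disease_multiplier = 3))
  coh <- make_cohort(design, g, proc, n_background = 20, seed = 62)
  expect_length(coh$catalogs, 6)
  expect_equal(nrow(coh$metadata), 6)

  # reproducibility from the master seed
  coh2 <- make_cohort(design, g, proc, n_background = 20, seed = 62)
  expect_identical(lapply(coh$catalogs, `[[`, "records"),
                   lapply(coh2$catalogs, `[[`, "records"))

  # age-proportional expectation with disease multiplier: Poisson counts
  inj <- coh$truth[coh$truth$process == "nCg", ]
  expected <- design$age * ifelse(design$disease == "copd", 3, 1)
  expect_true(all(abs(inj$injected - expected) <
                    4 * sqrt(expected) + 4))

  # different samples get different seeds
  expect_gt(length(unique(inj$seed)), 1)
})
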
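## Seed-deterministic simulator: reference genomes and mutation
## catalogues with controlled background, motif-targeted, clock-like and
## strand-coordinated clustered mutational processes, plus the truth
## tables needed for recovery experiments.

## run code under a given seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("an explicit seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic per-entity seed from a master seed
#'
#' Hashes an entity identifier into `[0, 2^31 - 2]` and mixes it with the
#' master seed, so every donor/sample of a simulated cohort gets a
#' reproducible RNG stream of its own.
#'
#' @param master Master integer seed.
#' @param id Entity identifier string.
#' @return Integer seed.
#' @export
derive_seed <- function(master, id) {
  m <- 2147483587
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% m
  as.integer((as.numeric(master) %% m * 48271 + h) %% m)
}

#' Simulate a reference genome
#'
#' Draws a pseudo-random nucleotide sequence with the given base
#' composition.  `cpg_factor` rescales the probability of G following C
#' through a first-order Markov chain, inflating (`> 1`) or suppressing
#' (`< 1`; `0` removes entirely) CpG dinucleotides.
#'
#' @param length Sequence length in bp (>= 1e4).
#' @param base_composition Probabilities for A, C, G, T (sum to 1).
#'   Uniform by default.
#' @param cpg_factor CpG adjustment ratio (default 1 = independent
#'   bases).
#' @param seed Mandatory integer seed.
#' @param contig Contig name (default `"chr1"`).
#' @return A `reference_genome` with one contig.
#' @export
make_genome <- function(length, base_composition = rep(0.25, 4),
                        cpg_factor = 1, seed, contig = "chr1") {
  p <- as.numeric(base_composition)
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("base_composition must be 4 non-negative probabilities ",
         "summing to 1")
  }
  if (length < 1e4) stop("genome length must be >= 1e4")
  n <- as.integer(length)
  seq <- .with_seed(seed, {
    if (cpg_factor == 1) {
      paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
    } else {
      ## transition rows: all equal to the composition except after C,
      ## where P(G) is rescaled by cpg_factor and the row renormalized
      rowC <- p
      rowC[3] <- rowC[3] * cpg_factor
      rowC <- rowC / sum(rowC)
      cum_base <- cumsum(p)
      cum_C <- cumsum(rowC)
      u <- stats::runif(n)
      x <- integer(n)
      x[1] <- findInterval(u[1], cum_base, left.open = TRUE) + 1L
      for (i in 2:n) {
        cum <- if (x[i - 1L] == 2L) cum_C else cum_base
        x[i] <- findInterval(u[i], cum, left.open = TRUE) + 1L
      }
      paste(.BASES[x], collapse = "")
    }
  })
  reference_genome(stats::setNames(seq, contig))
}

#' Define a mutational process for the simulator
#'
#' @param motif Motif name from the built-in registry, or a
#'   `mutation_motif`.
#' @param mode `"fixed_count"` or `"per_year_rate"` (clock-like:
#'   expected count = intensity x age, Poisson-distributed).
#' @param intensity Mutations (fixed_count) or mutations/year.
#' @param disease_multiplier Rate multiplier applied when the simulated
#'   donor carries a disease label other than `"healthy"` (default 1).
#' @param clustered_fraction Fraction of the process's mutations placed
#'   as same-strand clustered runs (default 0).
#' @param cluster_size_distribution Named probabilities over run sizes
#'   (default sizes 2/3/4 with probabilities 0.5/0.3/0.2).
#' @param cluster_span Maximum run span in bp (default 5000).
#' @return A `process_spec`.
#' @export
process_spec <- function(motif, mode = c("fixed_count", "per_year_rate"),
                         intensity, disease_multiplier = 1,
                         clustered_fraction = 0,
                         cluster_size_distribution =
                           c("2" = 0.5, "3" = 0.3, "4" = 0.2),
                         cluster_span = 5000L) {
  mode <- match.arg(mode)
  if (is.character(motif)) motif <- get_motif(builtin_registry(), motif)
  stopifnot(inherits(motif, "mutation_motif"), intensity >= 0,
            disease_multiplier > 0,
            clustered_fraction >= 0, clustered_fraction <= 1)
  sizes <- as.integer(names(cluster_size_distribution))
  if (any(is.na(sizes)) || any(sizes < 2)) {
    stop("cluster sizes must be named integers >= 2")
  }
  structure(list(motif = motif, mode = mode, intensity = intensity,
                 disease_multiplier = disease_multiplier,
                 clustered_fraction = clustered_fraction,
                 cluster_size_distribution = cluster_size_distribution,
                 cluster_span = as.integer(cluster_span)),
            class = "process_spec")
}

#' Genomic positions matching a motif's reference pattern
#'
#' Scans both strands of the genome for full matches of the motif's
#' IUPAC reference pattern and reports the position of the mutated base.
#'
#' @param genome A `reference_genome`.
#' @param motif A `mutation_motif`.
#' @return Data frame with `contig`, `pos` (1-based position of the
#'   mutated base) and `strand` (`"+"` if the motif's pyrimidine is on
#'   the reference strand).
#' @export
motif_sites <- function(genome, motif) {
  pat <- motif$ref_pattern
  L <- nchar(pat)
  ci <- motif$center_index
  sets_f <- .iupac_sets(pat)
  sets_r <- .iupac_sets(reverse_complement(pat))
  rows <- lapply(names(genome), function(ct) {
    codes <- .base_codes(strsplit(.contig_seq(genome, ct), "",
                                  fixed = TRUE)[[1]])
    fw <- which(.match_starts(codes, sets_f))
    rv <- which(.match_starts(codes, sets_r))
    data.frame(
      contig = ct,
      pos = c(fw + ci - 1L, rv + (L - ci)),
      strand = rep(c("+", "-"), c(length(fw), length(rv))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## draw one clustered same-strand run of `size` sites from `sites`
## (available candidates of one strand, sorted), spaced > 10 bp and
## within `span`; returns row indices or NULL
.draw_run <- function(sites, size, span, tries = 100) {
  if (nrow(sites) < size) return(NULL)
  for (t in seq_len(tries)) {
    i <- sample.int(nrow(sites), 1)
    ct <- sites$contig[i]; p0 <- sites$pos[i]
    cand <- which(sites$contig == ct & sites$pos >= p0 &
                    sites$pos <= p0 + span)
    if (length(cand) < size) next
    picked <- cand[1]
    last <- sites$pos[cand[1]]
    for (j in cand[-1]) {
      if (sites$pos[j] - last > 10) {
        picked <- c(picked, j)
        last <- sites$pos[j]
        if (length(picked) == size) break
      }
    }
    if (length(picked) == size) return(picked)
  }
  NULL
}

#' Simulate a mutation catalogue for one sample
#'
#' Generates uniform background substitutions plus the mutations of each
#' mutational process.  A process injects its mutations at genomic sites
#' matching its motif's reference pattern on either strand, applying one
#' of the motif's substitutions on the matched strand; a configurable
#' fraction is placed as same-strand clustered runs.  All positions are
#' unique; background draws avoid positions already used by processes
#' (collisions are resampled and reported).
#'
#' @param genome A `reference_genome`.
#' @param n_background Number of uniform background SNVs.
#' @param processes List of `process_spec` (may be empty).
#' @param age Donor age in years (used by per-year-rate processes).
#' @param disease Disease label; `"healthy"` disables disease
#'   multipliers.
#' @param seed Mandatory integer seed.
#' @param sample_id,donor_id,tissue,assay,study_id Metadata.
#' @param site_cache Optional environment memoizing [motif_sites()]
#'   results by motif name across calls; only valid while reusing one
#'   genome.
#' @return List with `catalog` (a `sample_catalog`), `truth` (data
#'   frame: one row per process plus one for the background, with
#'   requested/injected/in-motif/clustered counts and collision count),
#'   and `record_truth` (per injected mutation: position, generating
#'   process, and clustered-run id or NA for scattered placement).
#' @export
make_catalog <- function(genome, n_background, processes = list(),
                         age = NA_real_, disease = "healthy", seed,
                         sample_id = "S1", donor_id = sample_id,
                         tissue = "simulated", assay = "WGS",
                         study_id = "SIM", site_cache = NULL) {
  if (inherits(processes, "process_spec")) processes <- list(processes)
  get_sites <- function(motif) {
    if (is.null(site_cache)) return(motif_sites(genome, motif))
    if (is.null(site_cache[[motif$name]])) {
      site_cache[[motif$name]] <- motif_sites(genome, motif)
    }
    site_cache[[motif$name]]
  }
  .with_seed(seed, {
    used_keys <- character(0)
    key <- function(ct, p) paste0(ct, ":", p)
    recs <- list()
    truth <- list()
    rec_truth <- list()   # per-mutation provenance (process, run id)

    for (ps in processes) {
      n <- switch(ps$mode,
        fixed_count = as.integer(round(ps$intensity)),
        per_year_rate = {
          if (is.na(age)) stop("per_year_rate process needs a donor age")
          mult <- if (disease != "healthy") ps$disease_multiplier else 1
          stats::rpois(1, ps$intensity * age * mult)
        })
      sites <- get_sites(ps$motif)
      avail <- !(key(sites$contig, sites$pos) %in% used_keys)
      sites <- sites[avail, , drop = FALSE]
      if (nrow(sites) < n) {
        stop("site exhaustion for motif ", ps$motif$name, ": need ", n,
             ", only ", nrow(sites), " unused sites")
      }
      n_clust_target <- round(ps$clustered_fraction * n)
      picked <- integer(0)
      run_ids <- character(0)
      run_no <- 0L
      n_clustered <- 0L
      ## clustered runs first
      while (n_clustered < n_clust_target) {
        sz <- as.integer(sample(names(ps$cluster_size_distribution), 1,
                                prob = ps$cluster_size_distribution))
        sz <- min(sz, n_clust_target - n_clustered + 1L, n - length(picked))
        if (sz < 2) break
        strand <- sample(c("+", "-"), 1)
        pool <- setdiff(which(sites$strand == strand), picked)
        run <- .draw_run(sites[pool, , drop = FALSE], sz, ps$cluster_span)
        if (is.null(run)) {
          stop("site exhaustion: cannot place a clustered run of size ",
               sz, " for motif ", ps$motif$name)
        }
        picked <- c(picked, pool[run])
        run_no <- run_no + 1L
        run_ids <- c(run_ids, rep(paste0(ps$motif$name, "_run", run_no),
                                  sz))
        n_clustered <- n_clustered + sz
      }
      ## scattered remainder
      n_scatter <- n - length(picked)
      if (n_scatter > 0) {
        pool <- setdiff(seq_len(nrow(sites)), picked)
        picked <- c(picked, sample(pool, n_scatter))
        run_ids <- c(run_ids, rep(NA_character_, n_scatter))
      }
      sel <- sites[picked, , drop = FALSE]
      if (nrow(sel) > 0) {
        pyr <- ps$motif$center_base
        alt_motif <- sample(ps$motif$mutant_bases, nrow(sel),
                            replace = TRUE)
        minus <- sel$strand == "-"
        comp <- function(b) chartr("ACGT", "TGCA", b)
        ref <- ifelse(minus, comp(pyr), pyr)
        alt <- ifelse(minus, comp(alt_motif), alt_motif)
        used_keys <- c(used_keys, key(sel$contig, sel$pos))
        recs[[length(recs) + 1L]] <- data.frame(
          contig = sel$contig, pos = sel$pos, ref = ref, alt = alt,
          vaf = NA_real_, stringsAsFactors = FALSE)
        rec_truth[[length(rec_truth) + 1L]] <- data.frame(
          contig = sel$contig, pos = sel$pos,
          process = ps$motif$name, run_id = run_ids,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sample_id, process = ps$motif$name, mode = ps$mode,
        requested = n, injected = nrow(sel), in_motif = nrow(sel),
        clustered = n_clustered, collisions = 0L,
        stringsAsFactors = FALSE)
    }

    ## uniform background, resampling collisions with used positions
    collisions <- 0L
    if (n_background > 0) {
      lens <- nchar(unclass(genome))
      ct_names <- names(genome)
      got <- 0L
      bg <- vector("list", 0)
      guard <- 0L
      while (got < n_background) {
        guard <- guard + 1L
        if (guard > 1000) stop("background sampling failed to converge")
        need <- n_background - got
        ct <- sample(ct_names, need, replace = TRUE, prob = lens)
        pos <- vapply(ct, function(c1) sample.int(lens[[c1]], 1), 1L)
        ref <- substr(unclass(genome)[ct], pos, pos)
        ok <- ref %in% .BASES &
          !(key(ct, pos) %in% used_keys) &
          !duplicated(key(ct, pos))
        collisions <- collisions + sum(!ok)
        if (any(ok)) {
          ct <- ct[ok]; pos <- pos[ok]; ref <- ref[ok]
          alt <- vapply(ref, function(r)
            sample(setdiff(.BASES, r), 1), "")
          used_keys <- c(used_keys, key(ct, pos))
          bg[[length(bg) + 1L]] <- data.frame(
            contig = ct, pos = pos, ref = unname(ref), alt = unname(alt),
            vaf = NA_real_, stringsAsFactors = FALSE)
          got <- got + sum(ok)
        }
      }
      recs[[length(recs) + 1L]] <- do.call(rbind, bg)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = sample_id, process = "background", mode = "fixed_count",
      requested = n_background, injected = n_background, in_motif = NA,
      clustered = 0L, collisions = collisions, stringsAsFactors = FALSE)

    records <- if (length(recs) > 0) do.call(rbind, recs) else
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 vaf = numeric(0))
    cat <- sample_catalog(sample_id, records, donor_id = donor_id,
                          tissue = tissue, disease = disease, age = age,
                          assay = assay, study_id = study_id)
    truth_df <- do.call(rbind, truth)
    truth_df$seed <- as.integer(seed)
    rownames(truth_df) <- NULL
    rec_truth_df <- if (length(rec_truth) > 0) {
      do.call(rbind, rec_truth)
    } else {
      data.frame(contig = character(0), pos = integer(0),
                 process = character(0), run_id = character(0))
    }
    rownames(rec_truth_df) <- NULL
    list(catalog = cat, truth = truth_df, record_truth = rec_truth_df)
  })
}

#' Simulate a donor/sample cohort
#'
#' Applies the given processes and background to every sample of every
#' donor of the design; per-sample seeds are derived deterministically
#' from the master seed.  Per-year-rate processes give age-proportional
#' expected counts; disease multipliers act only on donors whose disease
#' label differs from `"healthy"`.
#'
#' @param design Data frame with one row per donor: `donor_id`, `age`,
#'   and optionally `tissue`, `disease`, `n_samples`, `study_id`,
#'   `assay` (defaults: "simulated", "healthy", 1, "SIM", "WGS").
#' @param genome A `reference_genome`.
#' @param processes List of `process_spec` applied to every sample.
#' @param n_background Background SNVs per sample.
#' @param seed Mandatory master seed.
#' @return List with `catalogs` (named list of `sample_catalog`),
#'   `metadata` (data frame) and `truth` (row-bound truth tables).
#' @export
make_cohort <- function(design, genome, processes = list(),
                        n_background = 0, seed) {
  if (nrow(design) == 0) stop("empty cohort design")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (is.null(design$tissue)) design$tissue <- "simulated"
  if (is.null(design$disease)) design$disease <- "healthy"
  if (is.null(design$n_samples)) design$n_samples <- 1L
  if (is.null(design$study_id)) design$study_id <- "SIM"
  if (is.null(design$assay)) design$assay <- "WGS"
  catalogs <- list()
  truth <- list()
  meta <- list()
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    for (k in seq_len(d$n_samples)) {
      sid <- paste0(d$donor_id, "_s", k)
      sim <- make_catalog(genome, n_background, processes,
                          age = d$age, disease = d$disease,
                          seed = derive_seed(seed, sid),
                          sample_id = sid, donor_id = d$donor_id,
                          tissue = d$tissue, assay = d$assay,
                          study_id = d$study_id, site_cache = cache)
      catalogs[[sid]] <- sim$catalog
      truth[[sid]] <- sim$truth
      meta[[sid]] <- data.frame(
        sample_id = sid, donor_id = d$donor_id, tissue = d$tissue,
        disease = d$disease, age = d$age, assay = d$assay,
        study_id = d$study_id, stringsAsFactors = FALSE)
    }
  }
  list(catalogs = catalogs,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
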
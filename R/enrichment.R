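## Per-sample motif enrichment, one-sided Fisher testing, BH gating and
## the Minimal Estimate of Mutation Load (MEML).
##
## For a motif such as aTn->aCn the statistic is
##   enrichment = (Mutations[aTn->aCn] * Context[t]) /
##                (Mutations[T->C]     * Context[atn])
## where the Context terms count pattern occurrences (both strands) in
## the +/-20 bp windows around the sample's mutations, and the 2x2
##   [mut_in_motif, mut_in_class - mut_in_motif]
##   [ctx_motif,    ctx_center   - ctx_motif ]
## is tested one-sided for overrepresentation.

#' Exclude complex mutations from a catalogue
#'
#' Removes every mutation lying within `max_dist` bp of any other
#' mutation of the same sample on the same contig (default 10 bp).
#' Closely spaced calls may arise from single multi-nucleotide events and
#' would confound motif attribution; chains of close mutations are
#' removed wholly.
#'
#' @param catalog A `sample_catalog`.
#' @param max_dist Maximum distance (bp) defining a complex pair.
#' @return A new catalogue; the number of removed records is available as
#'   `attr(, "n_complex")`.
#' @export
exclude_complex <- function(catalog, max_dist = 10L) {
  rec <- catalog$records
  if (nrow(rec) < 2) {
    out <- .with_records(catalog, rec)
    attr(out, "n_complex") <- 0L
    return(out)
  }
  ## records are stored sorted by (contig, pos); a record is complex iff
  ## it is within max_dist of an adjacent record on its contig
  same_prev <- c(FALSE, rec$contig[-1] == rec$contig[-nrow(rec)] &
                          diff(rec$pos) <= max_dist)
  complex <- same_prev | c(same_prev[-1], FALSE)
  out <- .with_records(catalog, rec[!complex, , drop = FALSE])
  attr(out, "n_complex") <- sum(complex)
  out
}

## ---------------------------------------------------------------------
## internal vectorized per-sample engine

## windows for every record of a catalogue; drops (and counts) records
## whose reference base disagrees with the genome
.catalog_windows <- function(catalog, genome, flank = 20L) {
  rec <- catalog$records
  n <- nrow(rec)
  win <- character(n); center <- integer(n); keep <- logical(n)
  if (n > 0) {
    for (ct in unique(rec$contig)) {
      i <- which(rec$contig == ct)
      seq <- .contig_seq(genome, ct)
      L <- nchar(seq)
      if (any(rec$pos[i] > L)) {
        stop("position beyond contig ", ct, " length ", L)
      }
      start <- pmax(1L, rec$pos[i] - as.integer(flank))
      end <- pmin(L, rec$pos[i] + as.integer(flank))
      win[i] <- substr(rep(seq, length(i)), start, end)
      center[i] <- rec$pos[i] - start + 1L
      keep[i] <- substr(win[i], center[i], center[i]) == rec$ref[i]
    }
  }
  list(records = rec[keep, , drop = FALSE],
       windows = win[keep], centers = center[keep],
       n_ref_mismatch = sum(!keep))
}

## per-window both-strand occurrence counts for each pattern in `patterns`
## (list of lowercase strings); returns matrix [window x pattern]
.window_pattern_counts <- function(windows, patterns) {
  n <- length(windows)
  out <- matrix(0L, nrow = n, ncol = length(patterns),
                dimnames = list(NULL, patterns))
  if (n == 0 || length(patterns) == 0) return(out)
  lens <- nchar(windows)
  .concat <- function(ws) {
    big <- paste(ws, collapse = "-")
    codes <- .base_codes(strsplit(big, "", fixed = TRUE)[[1]])
    ids <- rep(seq_along(ws), times = lens + 1L)
    ids <- ids[seq_along(codes)]
    list(codes = codes, ids = ids)
  }
  fwd <- .concat(windows)
  rcw <- reverse_complement(windows)
  rev <- .concat(rcw)
  for (p in patterns) {
    sets <- .iupac_sets(p)
    k <- length(sets)
    cnt <- integer(n)
    for (side in list(fwd, rev)) {
      hit <- .match_starts(side$codes, sets)
      if (any(hit)) {
        ids <- side$ids[seq_along(hit)]
        cnt <- cnt + tabulate(ids[hit], nbins = n)
      }
    }
    out[, p] <- cnt
  }
  out
}

## full per-sample counting for every motif of a registry.
## context_scope: "all" sums context windows over all mutations of the
## sample; "class" restricts to windows of mutations in the motif's own
## substitution class.
.sample_motif_counts <- function(catalog, registry, genome, flank = 20L,
                                 context_scope = c("all", "class")) {
  context_scope <- match.arg(context_scope)
  cw <- .catalog_windows(catalog, genome, flank)
  rec <- cw$records
  win <- toupper(cw$windows)
  center <- cw$centers
  n <- nrow(rec)

  ctx_patterns <- unique(c("c", "t",
                           vapply(registry, `[[`, "", "context_pattern")))
  pc <- .window_pattern_counts(win, ctx_patterns)

  ## canonical (pyrimidine-strand) view of every mutation
  is_pyr <- rec$ref %in% c("C", "T")
  wc <- win
  off <- center
  if (any(!is_pyr)) {
    wc[!is_pyr] <- reverse_complement(win[!is_pyr])
    off[!is_pyr] <- nchar(win[!is_pyr]) - center[!is_pyr] + 1L
  }
  sub_canon <- if (n > 0) .canonical_pair(rec$ref, rec$alt) else character(0)

  ## local canonical contexts for each distinct (pattern length, center)
  shapes <- unique(t(vapply(registry, function(m)
    c(nchar(m$ref_pattern), m$center_index), integer(2))))
  loc <- list()
  for (i in seq_len(nrow(shapes))) {
    L <- shapes[i, 1]; ci <- shapes[i, 2]
    from <- off - ci + 1L
    to <- off + (L - ci)
    s <- substr(wc, from, to)
    s[from < 1L] <- NA_character_   # truncated at the contig edge
    loc[[paste(L, ci)]] <- s
  }

  rows <- lapply(registry, function(m) {
    in_class <- sub_canon %in% m$class_subs
    key <- paste(nchar(m$ref_pattern), m$center_index)
    in_motif <- in_class & .match_iupac_strings(loc[[key]], m$ref_pattern)
    ctx_rows <- if (context_scope == "all") rep(TRUE, n) else in_class
    data.frame(
      motif = m$name,
      mut_in_motif = sum(in_motif),
      mut_in_class = sum(in_class),
      ctx_motif = sum(pc[ctx_rows, m$context_pattern]),
      ctx_center = sum(pc[ctx_rows, tolower(m$center_base)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_ref_mismatch") <- cw$n_ref_mismatch
  out
}

## ---------------------------------------------------------------------
## public statistics

#' Build the motif count table for one sample and motif
#'
#' Counts mutations in the motif's substitution class, mutations matching
#' the full motif, and the both-strand occurrences of the motif context
#' and its central base in the +/-`flank` bp windows around the sample's
#' mutations.  The catalogue should already be complex-excluded.
#'
#' @param catalog A `sample_catalog`.
#' @param motif A `mutation_motif`.
#' @param genome A `reference_genome`.
#' @param flank Context half-width in bp (default 20).
#' @param context_scope `"all"` (default) accumulates context windows
#'   over all mutations of the sample; `"class"` restricts to mutations
#'   of the motif's own substitution class.
#' @return A `motif_count_table`: list with `mut_in_motif`,
#'   `mut_in_class`, `ctx_motif`, `ctx_center`.
#' @export
build_count_table <- function(catalog, motif, genome, flank = 20L,
                              context_scope = "all") {
  reg <- .motif_registry(list(motif))
  row <- .sample_motif_counts(catalog, reg, genome, flank, context_scope)
  motif_count_table(row$mut_in_motif, row$mut_in_class,
                    row$ctx_motif, row$ctx_center)
}

#' Construct a motif count table
#'
#' @param mut_in_motif,mut_in_class Mutation counts (in motif; in the
#'   motif's substitution class, which includes the former).
#' @param ctx_motif,ctx_center Context occurrence counts (full motif
#'   pattern; central base), both strands.
#' @return A `motif_count_table`.
#' @export
motif_count_table <- function(mut_in_motif, mut_in_class,
                              ctx_motif, ctx_center) {
  v <- c(mut_in_motif, mut_in_class, ctx_motif, ctx_center)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  if (mut_in_motif > mut_in_class || ctx_motif > ctx_center) {
    stop("nested counts violated: mut_in_motif <= mut_in_class and ",
         "ctx_motif <= ctx_center required")
  }
  structure(list(mut_in_motif = as.numeric(mut_in_motif),
                 mut_in_class = as.numeric(mut_in_class),
                 ctx_motif = as.numeric(ctx_motif),
                 ctx_center = as.numeric(ctx_center)),
            class = "motif_count_table")
}

#' Motif enrichment ratio
#'
#' `(mut_in_motif * ctx_center) / (mut_in_class * ctx_motif)`: the
#' incidence of the substitution inside the motif relative to the random
#' incidence expected from the motif's abundance in the local context.
#'
#' @param table A `motif_count_table`.
#' @return The enrichment ratio, or `NA` when the denominator is zero
#'   (undefined enrichment).
#' @export
enrichment_ratio <- function(table) {
  denom <- table$mut_in_class * table$ctx_motif
  if (denom == 0) return(NA_real_)
  (table$mut_in_motif * table$ctx_center) / denom
}

#' One-sided Fisher exact test for motif overrepresentation
#'
#' Tests the 2x2 table `[[mut_in_motif, mut_in_class - mut_in_motif],
#' [ctx_motif, ctx_center - ctx_motif]]` for overrepresentation of
#' in-motif mutations (upper hypergeometric tail with fixed margins).
#'
#' @param table A `motif_count_table`.
#' @return The one-sided p-value in (0, 1]; degenerate margins give 1.
#' @export
fisher_one_sided <- function(table) {
  a <- table$mut_in_motif
  b <- table$mut_in_class - a
  c <- table$ctx_motif
  d <- table$ctx_center - c
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(1)
  }
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving against the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Minimal Estimate of Mutation Load (MEML)
#'
#' For samples whose motif enrichment is statistically significant
#' (enrichment > 1 and q <= `alpha`), the number of in-motif mutations
#' attributable to the motif-preferring process is estimated as
#' `mut_in_motif * (enrichment - 1) / enrichment`.  MEML is zero for
#' samples without significant enrichment.
#'
#' @param table A `motif_count_table`.
#' @param enrichment Enrichment ratio computed from `table`.
#' @param q_value BH-adjusted p-value from the cohort-wide pass.
#' @param alpha Significance gate (default 0.05).
#' @return Non-negative MEML value (mutation-count scale).
#' @export
meml <- function(table, enrichment, q_value, alpha = 0.05) {
  if (is.na(enrichment) || is.na(q_value)) return(0)
  if (enrichment > 1 && q_value <= alpha) {
    table$mut_in_motif * (enrichment - 1) / enrichment
  } else {
    0
  }
}

#' Run the full motif-enrichment pipeline over a cohort
#'
#' For every sample x motif: collapses duplicate records, excludes
#' complex mutations, builds the count table, computes enrichment and the
#' one-sided Fisher p-value; then applies Benjamini-Hochberg correction
#' (by default within each motif across all samples of the run) and the
#' MEML significance gate.
#'
#' @param catalogs List of `sample_catalog` (or a single catalogue).
#' @param genome A `reference_genome` covering all catalogue contigs.
#' @param registry A `motif_registry` (default [builtin_registry()]).
#' @param flank Context half-width in bp (default 20).
#' @param alpha Significance gate for MEML (default 0.05).
#' @param bh_scope `"per_motif"` (default) corrects across samples within
#'   each motif; `"global"` corrects across all sample x motif tests.
#' @param context_scope Passed to the counting engine; see
#'   [build_count_table()].
#' @param drop_complex Apply complex-mutation exclusion first
#'   (default TRUE).
#' @return Data frame with one row per sample x motif: metadata, the four
#'   counts, `enrichment`, `p_value`, `q_value`, `meml` and `status`
#'   (`"ok"`, `"undefined_enrichment"` or `"no_mutations"`).
#' @export
run_enrichment <- function(catalogs, genome, registry = builtin_registry(),
                           flank = 20L, alpha = 0.05,
                           bh_scope = c("per_motif", "global"),
                           context_scope = "all", drop_complex = TRUE) {
  bh_scope <- match.arg(bh_scope)
  if (inherits(catalogs, "sample_catalog")) catalogs <- list(catalogs)
  per_sample <- lapply(catalogs, function(cat) {
    cat <- collapse_duplicates(cat)
    if (drop_complex) cat <- exclude_complex(cat)
    counts <- .sample_motif_counts(cat, registry, genome, flank,
                                   context_scope)
    meta <- data.frame(sample_id = cat$sample_id, donor_id = cat$donor_id,
                       tissue = cat$tissue, disease = cat$disease,
                       age = cat$age, assay = cat$assay,
                       study_id = cat$study_id, stringsAsFactors = FALSE)
    cbind(meta[rep(1, nrow(counts)), , drop = FALSE], counts,
          n_ref_mismatch = attr(counts, "n_ref_mismatch"))
  })
  res <- do.call(rbind, per_sample)
  rownames(res) <- NULL

  res$enrichment <- with(res, ifelse(
    mut_in_class * ctx_motif == 0, NA_real_,
    (mut_in_motif * ctx_center) / (mut_in_class * ctx_motif)))
  ## upper hypergeometric tail, vectorized over rows
  a <- res$mut_in_motif
  res$p_value <- stats::phyper(a - 1, a + res$ctx_motif,
                               (res$mut_in_class - a) +
                                 (res$ctx_center - res$ctx_motif),
                               res$mut_in_class, lower.tail = FALSE)
  degen <- res$mut_in_class == 0 | res$ctx_center == 0 |
    (a + res$ctx_motif) == 0 |
    ((res$mut_in_class - a) + (res$ctx_center - res$ctx_motif)) == 0
  res$p_value[degen] <- 1
  res$p_value[is.na(res$enrichment)] <- NA_real_

  res$q_value <- NA_real_
  if (bh_scope == "per_motif") {
    for (m in unique(res$motif)) {
      i <- which(res$motif == m & !is.na(res$p_value))
      res$q_value[i] <- bh_adjust(res$p_value[i])
    }
  } else {
    i <- which(!is.na(res$p_value))
    res$q_value[i] <- bh_adjust(res$p_value[i])
  }

  gate <- !is.na(res$enrichment) & !is.na(res$q_value) &
    res$enrichment > 1 & res$q_value <= alpha
  res$meml <- ifelse(gate,
                     res$mut_in_motif * (res$enrichment - 1) /
                       res$enrichment,
                     0)
  res$status <- ifelse(res$mut_in_class == 0 & res$mut_in_motif == 0 &
                         res$ctx_center == 0, "no_mutations",
                       ifelse(is.na(res$enrichment),
                              "undefined_enrichment", "ok"))
  res
}

#' Write enrichment results to TSV
#'
#' @param results Data frame from [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
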
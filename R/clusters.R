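## Mutation-cluster calling, strand-coordination classification,
## per-category enrichment and APOBEC3A/3B subtype dissection.

#' Call mutation clusters by inter-mutation distance
#'
#' Clusters are maximal runs of same-contig mutations in which every
#' consecutive inter-mutation distance is at most `max_imd` (single
#' linkage); runs of fewer than `min_size` mutations are not reported.
#' The lower distance bound of clustered mutagenesis is enforced by the
#' prior complex-mutation exclusion (<= 10 bp).
#'
#' @param catalog A `sample_catalog`, ideally complex-excluded.
#' @param max_imd Maximum consecutive inter-mutation distance in bp
#'   (default 1e4).
#' @param min_size Minimum cluster size (default 2).
#' @return Data frame with one row per cluster: `sample_id`, `contig`,
#'   `start`, `end`, `size`, `span`, `coordination`, and a list column
#'   `members` of member positions.  The attribute `membership` holds the
#'   cluster id (or NA) for every record of the catalogue, in record
#'   order.
#' @export
call_clusters <- function(catalog, max_imd = 10000L, min_size = 2L) {
  rec <- catalog$records
  membership <- rep(NA_integer_, nrow(rec))
  rows <- list()
  cid <- 0L
  for (ct in unique(rec$contig)) {
    i <- which(rec$contig == ct)          # records are sorted by pos
    pos <- rec$pos[i]
    run <- cumsum(c(1L, as.integer(diff(pos) > max_imd)))
    for (r in unique(run)) {
      j <- i[run == r]
      if (length(j) < min_size) next
      cid <- cid + 1L
      membership[j] <- cid
      rows[[cid]] <- data.frame(
        sample_id = catalog$sample_id, contig = ct,
        start = rec$pos[j[1]], end = rec$pos[j[length(j)]],
        size = length(j),
        span = rec$pos[j[length(j)]] - rec$pos[j[1]],
        coordination = classify_coordination(rec$ref[j]),
        stringsAsFactors = FALSE)
      rows[[cid]]$members <- I(list(rec$pos[j]))
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), size = integer(0),
               span = integer(0), coordination = character(0),
               members = I(list()))
  rownames(out) <- NULL
  attr(out, "membership") <- membership
  out
}

#' Strand-coordination label of a mutation cluster
#'
#' A cluster is `GC_coordinated` when all member reference bases are G or
#' all are C (the signature of deamination on one strand of a
#' single-stranded DNA stretch), `AT_coordinated` when all are A or all
#' are T, and `non_coordinated` otherwise.
#'
#' @param refs Character vector of member reference bases (length >= 2).
#' @return One of `"GC_coordinated"`, `"AT_coordinated"`,
#'   `"non_coordinated"`.
#' @export
classify_coordination <- function(refs) {
  if (length(refs) < 2) stop("a cluster has at least 2 members")
  u <- unique(toupper(refs))
  if (length(u) == 1 && u %in% c("G", "C")) "GC_coordinated"
  else if (length(u) == 1 && u %in% c("A", "T")) "AT_coordinated"
  else "non_coordinated"
}

## subset a catalogue to a mutation category defined by cluster calls
.category_records <- function(catalog, clusters, category) {
  membership <- attr(clusters, "membership")
  rec <- catalog$records
  gc_ids <- which(clusters$coordination == "GC_coordinated")
  keep <- switch(category,
    genome_wide = rep(TRUE, nrow(rec)),
    scattered = is.na(membership),
    gc_clusters_all = membership %in% gc_ids,
    gc_clusters_size_2 = membership %in%
      intersect(gc_ids, which(clusters$size == 2)),
    gc_clusters_size_3 = membership %in%
      intersect(gc_ids, which(clusters$size == 3)),
    gc_clusters_size_4plus = membership %in%
      intersect(gc_ids, which(clusters$size >= 4)),
    stop("unknown category: ", category)
  )
  rec[keep, , drop = FALSE]
}

#' Motif enrichment within a mutation category
#'
#' Applies the enrichment machinery to the subset of a sample's
#' mutations belonging to a category derived from cluster calls
#' (all GC-coordinated clusters, a cluster-size stratum, scattered
#' mutations, or the whole genome).  Context windows are drawn from the
#' category's own mutations.
#'
#' @param catalog A complex-excluded `sample_catalog`.
#' @param clusters Output of [call_clusters()] on `catalog`.
#' @param motif A `mutation_motif`.
#' @param genome A `reference_genome`.
#' @param category One of `"genome_wide"`, `"scattered"`,
#'   `"gc_clusters_all"`, `"gc_clusters_size_2"`, `"gc_clusters_size_3"`,
#'   `"gc_clusters_size_4plus"`.
#' @param flank Context half-width in bp (default 20).
#' @return One-row data frame with the category, counts, enrichment,
#'   p-value (one-sided Fisher), MEML gated at `p <= 0.05`, and status.
#' @export
category_enrichment <- function(catalog, clusters, motif, genome,
                                category = "genome_wide", flank = 20L) {
  rec <- .category_records(catalog, clusters, category)
  sub <- .with_records(catalog, rec)
  tab <- build_count_table(sub, motif, genome, flank)
  e <- enrichment_ratio(tab)
  p <- if (is.na(e)) NA_real_ else fisher_one_sided(tab)
  data.frame(
    sample_id = catalog$sample_id, category = category, motif = motif$name,
    mut_in_motif = tab$mut_in_motif, mut_in_class = tab$mut_in_class,
    ctx_motif = tab$ctx_motif, ctx_center = tab$ctx_center,
    enrichment = e, p_value = p,
    meml = meml(tab, e, p),
    status = if (is.na(e)) "undefined_enrichment" else "ok",
    stringsAsFactors = FALSE)
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Classic Breslow-Day chi-square test of whether the odds ratios of two
#' or more 2x2 tables are equal, computed against the Mantel-Haenszel
#' common odds ratio, with `df = K - 1` for `K` usable strata.  The
#' Tarone correction can be enabled.
#'
#' @param strata List of 2x2 matrices (rows: mutations in/out of motif;
#'   columns unchanged across strata) or `motif_count_table` objects.
#' @param tarone Apply the Tarone adjustment (default FALSE).
#' @return List with `statistic`, `p_value`, `df`, `common_or` and
#'   `n_strata`.
#' @export
breslow_day <- function(strata, tarone = FALSE) {
  as_cells <- function(s) {
    if (inherits(s, "motif_count_table")) {
      c(a = s$mut_in_motif, b = s$mut_in_class - s$mut_in_motif,
        c = s$ctx_motif, d = s$ctx_center - s$ctx_motif)
    } else {
      m <- as.matrix(s)
      if (!all(dim(m) == c(2, 2))) stop("each stratum must be 2x2")
      c(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2])
    }
  }
  cells <- t(vapply(strata, as_cells, numeric(4)))
  ok <- (cells[, "a"] + cells[, "b"]) > 0 &
    (cells[, "c"] + cells[, "d"]) > 0 &
    (cells[, "a"] + cells[, "c"]) > 0 &
    (cells[, "b"] + cells[, "d"]) > 0
  if (any(!ok)) {
    warning(sum(!ok), " degenerate stratum(a) dropped from Breslow-Day")
    cells <- cells[ok, , drop = FALSE]
  }
  K <- nrow(cells)
  if (K < 2) stop("Breslow-Day needs at least 2 usable strata")
  a <- cells[, "a"]; b <- cells[, "b"]
  cc <- cells[, "c"]; d <- cells[, "d"]
  n <- a + b + cc + d
  or_mh <- sum(a * d / n) / sum(b * cc / n)

  r1 <- a + b          # first-row margins
  c1 <- a + cc         # first-column margins
  ## expected a under the common odds ratio: root of
  ## (psi-1) E^2 - [psi (r1 + c1) + (n - r1 - c1)] E + psi r1 c1 = 0
  E <- numeric(K); V <- numeric(K)
  for (i in seq_len(K)) {
    psi <- or_mh
    if (abs(psi - 1) < 1e-12) {
      Ei <- r1[i] * c1[i] / n[i]
    } else {
      A <- psi - 1
      B <- -(psi * (r1[i] + c1[i]) + (n[i] - r1[i] - c1[i]))
      C <- psi * r1[i] * c1[i]
      disc <- sqrt(max(B^2 - 4 * A * C, 0))
      roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
      lo <- max(0, r1[i] + c1[i] - n[i])
      hi <- min(r1[i], c1[i])
      valid <- roots[roots > lo & roots < hi]
      Ei <- if (length(valid) > 0) valid[1] else r1[i] * c1[i] / n[i]
    }
    E[i] <- Ei
    V[i] <- 1 / (1 / Ei + 1 / (r1[i] - Ei) + 1 / (c1[i] - Ei) +
                   1 / (n[i] - r1[i] - c1[i] + Ei))
  }
  stat <- sum((a - E)^2 / V)
  if (tarone) stat <- stat - sum(a - E)^2 / sum(V)
  df <- K - 1
  list(statistic = stat, p_value = stats::pchisq(stat, df,
                                                 lower.tail = FALSE),
       df = df, common_or = or_mh, n_strata = K)
}

#' APOBEC3A-like vs APOBEC3B-like subtype dissection
#'
#' For each mutation category (GC-coordinated clusters overall and by
#' size stratum, scattered mutations, genome-wide), builds the 2x2
#' tables of the `ytCa` (APOBEC3A-preferred) and `rtCa`
#' (APOBEC3B-preferred) tetranucleotide motifs over combined C>T and C>G
#' substitutions, tests each with the one-sided Fisher exact test, and -
#' where both are significant - compares their odds ratios with the
#' Breslow-Day homogeneity test.
#'
#' @param catalog A complex-excluded `sample_catalog` (per sample or
#'   pooled over the APOBEC-candidate samples of a tissue).
#' @param genome A `reference_genome`.
#' @param clusters Optional precomputed [call_clusters()] output.
#' @param alpha Significance level for the Fisher precondition
#'   (default 0.05).
#' @param flank Context half-width in bp (default 20).
#' @return Data frame with one row per category: both enrichments and
#'   p-values, `bd_statistic`, `bd_p` (NA unless both Fisher tests were
#'   significant) and `preferred` (`"ytCa"`, `"rtCa"` or NA).
#' @export
subtype_analysis <- function(catalog, genome, clusters = NULL,
                             alpha = 0.05, flank = 20L) {
  if (is.null(clusters)) clusters <- call_clusters(catalog)
  reg <- builtin_registry()
  ytca <- get_motif(reg, "ytCa")
  rtca <- get_motif(reg, "rtCa")
  cats <- c("gc_clusters_all", "gc_clusters_size_2", "gc_clusters_size_3",
            "gc_clusters_size_4plus", "scattered", "genome_wide")
  rows <- lapply(cats, function(cat) {
    rec <- .category_records(catalog, clusters, cat)
    sub <- .with_records(catalog, rec)
    ty <- build_count_table(sub, ytca, genome, flank)
    tr <- build_count_table(sub, rtca, genome, flank)
    ey <- enrichment_ratio(ty); er <- enrichment_ratio(tr)
    py <- if (is.na(ey)) NA_real_ else fisher_one_sided(ty)
    pr <- if (is.na(er)) NA_real_ else fisher_one_sided(tr)
    both_sig <- !is.na(py) && !is.na(pr) && py <= alpha && pr <= alpha
    bd_stat <- NA_real_; bd_p <- NA_real_; preferred <- NA_character_
    if (both_sig) {
      bd <- breslow_day(list(ty, tr))
      bd_stat <- bd$statistic; bd_p <- bd$p_value
      preferred <- if (ey >= er) "ytCa" else "rtCa"
    }
    data.frame(sample_id = catalog$sample_id, category = cat,
               n_mutations = nrow(rec),
               ytca_enrichment = ey, ytca_p = py,
               rtca_enrichment = er, rtca_p = pr,
               bd_statistic = bd_stat, bd_p = bd_p,
               preferred = preferred, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write cluster calls to TSV
#'
#' @param clusters Output of [call_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- clusters
  df$members <- vapply(df$members, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
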
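## Donor-level aggregation and cohort statistics: 96-channel profiles,
## cosine similarity, age correlations, age-tercile disease comparisons,
## age+disease regression, and single-cell MEML proration.

.SUBS_96 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.channel_names_96 <- function() {
  unlist(lapply(.SUBS_96, function(s) {
    unlist(lapply(.BASES, function(f5)
      paste0(f5, "[", s, "]", .BASES)))
  }))
}

#' 96-channel trinucleotide mutation profile
#'
#' Counts every usable SNV into one of the 96 pyrimidine-canonical
#' trinucleotide substitution channels (6 substitutions x 16 flanking
#' base pairs), using COSMIC-style channel names like `"A[C>T]G"`.
#' Mutations at contig edges (no 5' or 3' base) are skipped and counted.
#'
#' @param catalogs A `sample_catalog` or list of them.
#' @param genome A `reference_genome`.
#' @return Named integer vector of length 96; skipped-record count in
#'   `attr(, "n_skipped")`.
#' @export
profile_96 <- function(catalogs, genome) {
  if (inherits(catalogs, "sample_catalog")) catalogs <- list(catalogs)
  out <- stats::setNames(integer(96), .channel_names_96())
  skipped <- 0L
  for (cat in catalogs) {
    rec <- cat$records
    if (nrow(rec) == 0) next
    for (ct in unique(rec$contig)) {
      i <- which(rec$contig == ct)
      seq <- .contig_seq(genome, ct)
      L <- nchar(seq)
      pos <- rec$pos[i]
      usable <- pos > 1L & pos < L
      skipped <- skipped + sum(!usable)
      i <- i[usable]; pos <- pos[usable]
      if (length(i) == 0) next
      f5 <- substr(rep(seq, length(i)), pos - 1L, pos - 1L)
      f3 <- substr(rep(seq, length(i)), pos + 1L, pos + 1L)
      ok <- f5 %in% .BASES & f3 %in% .BASES &
        substr(rep(seq, length(i)), pos, pos) == rec$ref[i]
      skipped <- skipped + sum(!ok)
      i <- i[ok]; f5 <- f5[ok]; f3 <- f3[ok]
      if (length(i) == 0) next
      canon <- canonical_substitution(rec$ref[i], rec$alt[i], f5, f3)
      ## "aTg>aCg" -> "A[T>C]G"
      ch <- paste0(toupper(substr(canon, 1, 1)), "[",
                   substr(canon, 2, 2), ">", substr(canon, 6, 6), "]",
                   toupper(substr(canon, 3, 3)))
      tab <- table(ch)
      out[names(tab)] <- out[names(tab)] + as.integer(tab)
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Cosine similarity between two mutation profiles
#'
#' @param u,v Numeric vectors of equal length.
#' @return `u.v / (|u||v|)`; NA with a warning if either vector is zero.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine similarity undefined for a zero vector")
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Aggregate sample-level MEML to donors
#'
#' Computes, per donor x motif, the mean MEML over all samples of the
#' donor both including zeros (the quantity used for age correlations)
#' and excluding zeros (NA when every sample has MEML 0).
#'
#' @param results Data frame from [run_enrichment()]; must carry
#'   `donor_id` (as produced when catalogues have donor metadata) or be
#'   joined with `metadata`.
#' @param metadata Optional data frame with `sample_id`, `donor_id`,
#'   `tissue`, `disease`, `age`, `assay`, `study_id` overriding the
#'   result columns.
#' @return Data frame with one row per donor x motif: metadata,
#'   `n_samples`, `mean_meml`, `mean_meml_nonzero`.
#' @export
donor_aggregate <- function(results, metadata = NULL) {
  if (!is.null(metadata)) {
    keep <- setdiff(names(results),
                    c("donor_id", "tissue", "disease", "age", "assay",
                      "study_id"))
    results <- merge(results[, keep, drop = FALSE], metadata,
                     by = "sample_id")
    if (nrow(results) == 0) stop("no samples matched the metadata")
  }
  if (any(is.na(results$donor_id))) {
    warning(sum(is.na(results$donor_id)),
            " result row(s) without donor_id dropped")
    results <- results[!is.na(results$donor_id), , drop = FALSE]
  }
  sp <- split(results, list(results$donor_id, results$motif), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(
      donor_id = g$donor_id[1], motif = g$motif[1],
      tissue = g$tissue[1], disease = g$disease[1], age = g$age[1],
      study_id = g$study_id[1], n_samples = nrow(g),
      mean_meml = mean(g$meml),
      mean_meml_nonzero = if (any(g$meml > 0)) mean(g$meml[g$meml > 0])
                          else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$donor_id, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value
#' uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Paired numeric vectors, length >= 4.
#' @return List with `rho`, `p_value` and `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Fixed age terciles
#'
#' Assigns ages to the fixed groups T1 = [0, 33.3], T2 = (33.3, 66.7],
#' T3 = (66.7, 100] years (half-open intervals; ages above 100 fall in
#' T3 with a warning).
#'
#' @param age Numeric vector of ages in years, `0 <= age`.
#' @return Character vector of `"T1"`, `"T2"`, `"T3"` (NA for NA input).
#' @export
tercile_of <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("negative age")
  if (any(age > 100, na.rm = TRUE)) {
    warning("age(s) above 100 assigned to T3")
  }
  ifelse(is.na(age), NA_character_,
         ifelse(age <= 33.3, "T1", ifelse(age <= 66.7, "T2", "T3")))
}

#' Compare diseased vs healthy donors within study and age tercile
#'
#' For every study x tissue x age-tercile x motif cell containing both
#' healthy donors and donors with a given disease, compares donor mean
#' MEML with a two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction), then applies Benjamini-Hochberg correction
#' across all emitted comparisons.
#'
#' @param summaries Donor summary table from [donor_aggregate()].
#' @param value Column to compare (default `"mean_meml"`).
#' @return Data frame with one row per comparison: grouping columns,
#'   group sizes, the rank-sum statistic `W`, `p_value`, `q_value`, and
#'   the median difference (diseased - healthy).
#' @export
compare_cohorts <- function(summaries, value = "mean_meml") {
  summaries$tercile <- tercile_of(summaries$age)
  summaries <- summaries[!is.na(summaries$tercile), , drop = FALSE]
  key <- with(summaries, paste(study_id, tissue, tercile, motif,
                               sep = "\r"))
  rows <- list()
  for (cell in unique(key)) {
    g <- summaries[key == cell, , drop = FALSE]
    healthy <- g[[value]][g$disease == "healthy"]
    if (length(healthy) == 0) next
    for (dis in setdiff(unique(g$disease), "healthy")) {
      sick <- g[[value]][g$disease == dis]
      if (length(sick) == 0) next
      wt <- suppressWarnings(
        stats::wilcox.test(sick, healthy, exact = FALSE, correct = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = g$study_id[1], tissue = g$tissue[1],
        tercile = g$tercile[1], motif = g$motif[1], disease = dis,
        n_diseased = length(sick), n_healthy = length(healthy),
        W = unname(wt$statistic), p_value = wt$p.value,
        median_diff = stats::median(sick) - stats::median(healthy),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(study_id = character(0), tissue = character(0),
                      tercile = character(0), motif = character(0),
                      disease = character(0), n_diseased = integer(0),
                      n_healthy = integer(0), W = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      median_diff = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[, c("study_id", "tissue", "tercile", "motif", "disease",
                 "n_diseased", "n_healthy", "W", "p_value", "q_value",
                 "median_diff")]
  rownames(out) <- NULL
  out
}

#' Regress donor MEML on age and disease status
#'
#' Ordinary least squares of donor mean MEML on numeric age plus disease
#' indicators (healthy as baseline), fitted separately per tissue x
#' motif.
#'
#' @param summaries Donor summary table from [donor_aggregate()].
#' @param value Response column (default `"mean_meml"`).
#' @return Data frame of coefficients: `tissue`, `motif`, `term`,
#'   `estimate`, `std_error`, `t_value`, `p_value`, `n_donors`.
#' @export
regress_age_disease <- function(summaries, value = "mean_meml") {
  summaries <- summaries[!is.na(summaries$age), , drop = FALSE]
  key <- with(summaries, paste(tissue, motif, sep = "\r"))
  rows <- list()
  for (cell in unique(key)) {
    g <- summaries[key == cell, , drop = FALSE]
    g$disease <- stats::relevel(factor(g$disease,
      levels = c("healthy", setdiff(unique(g$disease), "healthy"))),
      ref = "healthy")
    n_pred <- 1L + max(0L, nlevels(g$disease) - 1L)
    if (nrow(g) < n_pred + 3L) next
    fit <- if (nlevels(g$disease) > 1) {
      stats::lm(stats::reformulate(c("age", "disease"), response = value),
                data = g)
    } else {
      stats::lm(stats::reformulate("age", response = value), data = g)
    }
    co <- summary(fit)$coefficients
    aliased <- summary(fit)$aliased
    if (any(aliased)) {
      warning("rank-deficient fit in ", g$tissue[1], " / ", g$motif[1],
              ": ", paste(names(aliased)[aliased], collapse = ", "))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = g$tissue[1], motif = g$motif[1], term = rownames(co),
      estimate = co[, 1], std_error = co[, 2], t_value = co[, 3],
      p_value = co[, 4], n_donors = nrow(g),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tissue = character(0), motif = character(0),
               term = character(0), estimate = numeric(0),
               std_error = numeric(0), t_value = numeric(0),
               p_value = numeric(0), n_donors = integer(0))
  rownames(out) <- NULL
  out
}

#' Prorate a single-cell MEML estimate to the whole genome
#'
#' Single-cell catalogues report only the subset of mutations callable
#' by the study's pipeline; the MEML computed on that subset is scaled
#' by the sample-specific multiplier
#' `estimated_snvs / identified_mutations`.
#'
#' @param meml MEML value(s) computed on the called mutations.
#' @param estimated_snvs Study-estimated genome-wide SNV count.
#' @param identified_mutations Number of mutations actually called.
#' @return Prorated MEML.
#' @export
prorate_single_cell <- function(meml, estimated_snvs,
                                identified_mutations) {
  if (any(identified_mutations == 0)) {
    stop("identified_mutations must be positive")
  }
  meml * estimated_snvs / identified_mutations
}
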
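## Readers and writers for the standard formats the pipeline touches
## (FASTA, MAF, VCF, metadata TSV) and catalogue hygiene across samples.

.MAF_REQUIRED <- c("Chromosome", "Start_Position", "Reference_Allele",
                   "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")

#' Read somatic SNVs from a MAF file
#'
#' Only single-nucleotide substitutions (single-base reference and
#' alternate alleles in A/C/G/T) are retained; other rows are counted
#' and skipped.  Duplicate calls within a sample are recorded once.  An
#' optional `VAF` column is carried through.
#'
#' @param path Path to a tab-separated MAF file.
#' @return Named list of `sample_catalog` (one per
#'   `Tumor_Sample_Barcode`), with filter counters in
#'   `attr(, "n_skipped_non_snv")` and `attr(, "n_duplicates")`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  miss <- setdiff(.MAF_REQUIRED, names(df))
  if (length(miss) > 0) {
    stop("MAF is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  ref <- toupper(df$Reference_Allele)
  alt <- toupper(df$Tumor_Seq_Allele2)
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% .BASES &
    alt %in% .BASES & ref != alt
  n_skipped <- sum(!snv)
  if (n_skipped > 0) {
    message(n_skipped, " non-SNV MAF row(s) skipped (lines ",
            paste(utils::head(which(!snv), 5) + 1L, collapse = ", "),
            if (n_skipped > 5) ", ..." else "", ")")
  }
  df <- df[snv, , drop = FALSE]
  vaf <- if ("VAF" %in% names(df)) suppressWarnings(as.numeric(df$VAF))
         else NA_real_
  n_dup <- 0L
  out <- lapply(split(seq_len(nrow(df)), df$Tumor_Sample_Barcode),
                function(i) {
    cat <- sample_catalog(
      df$Tumor_Sample_Barcode[i[1]],
      data.frame(contig = as.character(df$Chromosome[i]),
                 pos = as.integer(df$Start_Position[i]),
                 ref = toupper(df$Reference_Allele[i]),
                 alt = toupper(df$Tumor_Seq_Allele2[i]),
                 vaf = if (length(vaf) > 1) vaf[i] else vaf,
                 stringsAsFactors = FALSE))
    cat <- collapse_duplicates(cat)
    n_dup <<- n_dup + attr(cat, "n_duplicates")
    cat
  })
  attr(out, "n_skipped_non_snv") <- n_skipped
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Write catalogues as a MAF file
#'
#' Emits the minimal MAF columns consumed by [read_maf()] plus `VAF`.
#' Output is byte-deterministic for identical input.
#'
#' @param catalogs A `sample_catalog` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(catalogs, path) {
  if (inherits(catalogs, "sample_catalog")) catalogs <- list(catalogs)
  rows <- lapply(catalogs, function(cat) {
    r <- cat$records
    data.frame(Chromosome = r$contig, Start_Position = r$pos,
               End_Position = r$pos, Reference_Allele = r$ref,
               Tumor_Seq_Allele2 = r$alt,
               Tumor_Sample_Barcode = cat$sample_id,
               VAF = r$vaf, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a somatic SNV catalogue from a VCF file
#'
#' Biallelic SNV records are used directly; multiallelic records are
#' split into one record per alternate allele.  Indels and other non-SNV
#' alleles are counted and skipped.  By default only records with FILTER
#' `PASS` or `.` are kept.
#'
#' @param path Path to a VCF 4.x file.
#' @param sample_id Sample identifier for the resulting catalogue.
#' @param pass_only Keep only FILTER PASS/`.` records (default TRUE).
#' @return A `sample_catalog`; skipped-allele count in
#'   `attr(, "n_skipped_non_snv")`.
#' @export
read_vcf <- function(path, sample_id, pass_only = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- sample_catalog(sample_id,
                          data.frame(contig = character(0),
                                     pos = integer(0), ref = character(0),
                                     alt = character(0)))
    attr(out, "n_skipped_non_snv") <- 0L
    return(out)
  }
  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  long <- data.frame(
    contig = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = toupper(rep(fix$REF, n_alt)),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE)
  snv <- nchar(long$ref) == 1 & nchar(long$alt) == 1 &
    long$ref %in% .BASES & long$alt %in% .BASES & long$ref != long$alt
  out <- collapse_duplicates(
    sample_catalog(sample_id, long[snv, , drop = FALSE]))
  attr(out, "n_skipped_non_snv") <- sum(!snv)
  out
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `donor_id`, `tissue`,
#'   `disease`, `age`, `assay`, `study_id` and optionally
#'   `estimated_snvs`, `identified_mutations`.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "tissue", "disease", "age")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Attach metadata to catalogues by sample id
#'
#' @param catalogs Named list of `sample_catalog`.
#' @param metadata Data frame as read by [read_metadata()].
#' @return The catalogues with donor/tissue/disease/age/assay/study
#'   fields filled in; samples absent from the metadata are left
#'   untouched with a warning.
#' @export
attach_metadata <- function(catalogs, metadata) {
  idx <- match(vapply(catalogs, `[[`, "", "sample_id"),
               metadata$sample_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " sample(s) not found in metadata")
  }
  for (i in seq_along(catalogs)) {
    if (is.na(idx[i])) next
    m <- metadata[idx[i], ]
    catalogs[[i]]$donor_id <- m$donor_id
    catalogs[[i]]$tissue <- m$tissue
    catalogs[[i]]$disease <- m$disease
    catalogs[[i]]$age <- as.numeric(m$age)
    if (!is.null(m$assay)) catalogs[[i]]$assay <- m$assay
    if (!is.null(m$study_id)) catalogs[[i]]$study_id <- m$study_id
  }
  catalogs
}

#' Remove cross-sample duplicate calls within a donor
#'
#' Variants shared by several samples of the same donor and tissue
#' (clones or single cells from one biospecimen) are kept once, in the
#' sample with the highest variant allele frequency; with missing or
#' tied VAF the first sample in the list order wins (with a warning when
#' no VAF was available at all).
#'
#' @param catalogs List of `sample_catalog` from one donor and tissue.
#' @return The catalogues with shared variants deduplicated.
#' @export
dedup_cross_sample <- function(catalogs) {
  donors <- unique(vapply(catalogs, `[[`, "", "donor_id"))
  if (length(donors) > 1) {
    warning("catalogs span several donors; deduplicating anyway")
  }
  all <- do.call(rbind, lapply(seq_along(catalogs), function(i) {
    r <- catalogs[[i]]$records
    if (nrow(r) == 0) return(NULL)
    data.frame(sample_idx = i, row = seq_len(nrow(r)),
               key = paste(r$contig, r$pos, r$ref, r$alt),
               vaf = r$vaf, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0) return(catalogs)
  drop <- logical(nrow(all))
  any_shared_no_vaf <- FALSE
  for (k in unique(all$key[duplicated(all$key)])) {
    i <- which(all$key == k)
    v <- all$vaf[i]
    if (all(is.na(v))) {
      winner <- i[which.min(all$sample_idx[i])]
      any_shared_no_vaf <- TRUE
    } else {
      v[is.na(v)] <- -Inf
      winner <- i[which.max(v)]
    }
    drop[setdiff(i, winner)] <- TRUE
  }
  if (any_shared_no_vaf) {
    warning("shared variant(s) without VAF assigned to the first sample")
  }
  for (i in seq_along(catalogs)) {
    bad <- all$row[all$sample_idx == i & drop]
    if (length(bad) > 0) {
      catalogs[[i]] <- .with_records(
        catalogs[[i]],
        catalogs[[i]]$records[-bad, , drop = FALSE])
    }
  }
  catalogs
}

#' Write a reference genome to FASTA
#'
#' @param genome A `reference_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write a metadata or truth table to TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
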
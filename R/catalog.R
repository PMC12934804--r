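## SampleCatalog: all somatic SNVs of one sample plus donor metadata.

#' Construct a sample catalogue of somatic SNVs
#'
#' @param sample_id Sample identifier.
#' @param records Data frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt` and optionally `vaf`.
#' @param donor_id,tissue,disease,age,assay,study_id Donor/sample
#'   metadata; `disease = "healthy"` marks healthy donors.
#' @return A `sample_catalog` object.
#' @export
sample_catalog <- function(sample_id, records,
                           donor_id = sample_id, tissue = NA_character_,
                           disease = "healthy", age = NA_real_,
                           assay = "WGS", study_id = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("contig", "pos", "ref", "alt")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (!"vaf" %in% names(records)) {
    records$vaf <- rep(NA_real_, nrow(records))
  }
  records$contig <- as.character(records$contig)
  records$pos <- as.integer(records$pos)
  records$ref <- toupper(as.character(records$ref))
  records$alt <- toupper(as.character(records$alt))
  if (nrow(records) > 0) {
    ok <- records$ref %in% .BASES & records$alt %in% .BASES &
      records$ref != records$alt & records$pos >= 1L
    if (!all(ok)) {
      stop(sum(!ok), " record(s) are not valid SNVs ",
           "(single differing A/C/G/T alleles, pos >= 1)")
    }
  }
  records <- records[order(records$contig, records$pos, records$alt), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(sample_id = sample_id, donor_id = donor_id,
                 tissue = tissue, disease = disease, age = age,
                 assay = assay, study_id = study_id,
                 records = records),
            class = "sample_catalog")
}

#' @export
print.sample_catalog <- function(x, ...) {
  cat(sprintf(
    "sample_catalog %s (donor %s, %s, %s): %d SNV(s)\n",
    x$sample_id, x$donor_id,
    ifelse(is.na(x$tissue), "tissue NA", x$tissue), x$disease,
    nrow(x$records)))
  invisible(x)
}

## replace the record table, keeping metadata
.with_records <- function(catalog, records) {
  catalog$records <- records
  rownames(catalog$records) <- NULL
  catalog
}

#' Collapse duplicate mutation records within a sample
#'
#' Records identical in (contig, pos, ref, alt) are kept once.
#'
#' @param catalog A `sample_catalog`.
#' @return The catalogue with duplicates removed; the number removed is
#'   available as `attr(, "n_duplicates")`.
#' @export
collapse_duplicates <- function(catalog) {
  key <- with(catalog$records, paste(contig, pos, ref, alt))
  keep <- !duplicated(key)
  out <- .with_records(catalog, catalog$records[keep, , drop = FALSE])
  attr(out, "n_duplicates") <- sum(!keep)
  out
}

#' Merge several catalogues into one pooled catalogue
#'
#' Used to analyse a tissue or cohort as a single mutation set (e.g. for
#' pooled APOBEC subtype analysis).  Metadata of the first catalogue is
#' kept; duplicates across samples are retained.
#'
#' @param catalogs List of `sample_catalog`.
#' @param sample_id Identifier for the pooled catalogue.
#' @return A `sample_catalog`.
#' @export
pool_catalogs <- function(catalogs, sample_id = "pooled") {
  recs <- do.call(rbind, lapply(catalogs, function(x) x$records))
  first <- catalogs[[1]]
  sample_catalog(sample_id, recs, donor_id = sample_id,
                 tissue = first$tissue, disease = first$disease,
                 assay = first$assay, study_id = first$study_id)
}
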
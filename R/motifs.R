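## Knowledge-based mutational motifs: representation, the built-in
## registry, and IUPAC matching of individual mutations against motifs.

#' Define a mutational motif
#'
#' A motif is an IUPAC pattern with exactly one uppercase letter marking
#' the mutated position, plus the set of alternate bases the associated
#' process produces there.  Motifs are stored pyrimidine-canonical: the
#' uppercase letter is C or T, and matching handles the opposite strand
#' internally.
#'
#' @param name Short motif label, e.g. `"aTn"`.
#' @param ref_pattern IUPAC pattern with one uppercase letter (C or T).
#' @param mutant_bases Character vector of allowed alternate bases at the
#'   mutated position (subset of A/C/G/T, excluding the reference base).
#' @return A `mutation_motif` object.
#' @examples
#' mutation_motif("aTn", "aTn", "C")
#' @export
mutation_motif <- function(name, ref_pattern, mutant_bases) {
  chars <- strsplit(ref_pattern, "", fixed = TRUE)[[1]]
  upper <- which(chars %in% LETTERS)
  if (length(upper) != 1) {
    stop("ref_pattern must contain exactly one uppercase letter: ",
         ref_pattern)
  }
  center_base <- chars[upper]
  if (!center_base %in% c("C", "T")) {
    stop("motifs are stored pyrimidine-canonical; the mutated base must ",
         "be C or T, got ", center_base, " in ", ref_pattern)
  }
  mutant_bases <- toupper(mutant_bases)
  if (length(mutant_bases) == 0 || !all(mutant_bases %in% .BASES)) {
    stop("mutant_bases must be a non-empty subset of A/C/G/T")
  }
  if (center_base %in% mutant_bases) {
    stop("mutant_bases must exclude the reference base ", center_base)
  }
  bad <- setdiff(toupper(chars), names(.IUPAC))
  if (length(bad) > 0) stop("unknown IUPAC code(s): ",
                            paste(bad, collapse = ", "))
  structure(list(
    name = name,
    ref_pattern = ref_pattern,
    mutant_bases = sort(unique(mutant_bases)),
    center_index = upper,                 # 1-based position in the pattern
    center_base = center_base,
    context_pattern = tolower(ref_pattern),
    class_subs = paste0(center_base, ">", sort(unique(mutant_bases)))
  ), class = "mutation_motif")
}

#' @export
print.mutation_motif <- function(x, ...) {
  cat(sprintf("motif %s: %s -> {%s} at position %d\n", x$name,
              x$ref_pattern, paste(x$mutant_bases, collapse = ","),
              x$center_index))
  invisible(x)
}

.motif_registry <- function(motifs) {
  names(motifs) <- vapply(motifs, `[[`, "", "name")
  if (anyDuplicated(names(motifs))) stop("duplicate motif names")
  structure(motifs, class = "motif_registry")
}

#' Built-in registry of knowledge-based mutational motifs
#'
#' Returns the default motif set: eleven curated tri-nucleotide motifs
#' associated with known mutagenic mechanisms, four disambiguating
#' sub-motifs, the two APOBEC3A/3B-discriminating tetranucleotides, and
#' the combined APOBEC motif.
#'
#' Mechanism annotations: `aTn->aCn` small epoxides / SN2 electrophiles;
#' `yCn->yTn` UV; `nCg->nTg` spontaneous meCpG deamination; `nTt->nCt`
#' minor UV; `tCw->tTw` and `tCw->tGw` APOBEC deamination; `tgC->tgA`
#' redox stress; `hTg->hGg` SN2 alkylation (MMS-like); `aCy->aTy` SN1
#' alkylation; `gCn->gAn` acetaldehyde; `cTg->cAg` aristolochic acid.
#' Sub-motifs `aTr`, `rCg`, `yCg`, `yCh` restrict their parent motifs to
#' contexts that exclude a confounding mechanism, and `ytCa` / `rtCa`
#' separate APOBEC3A-like from APOBEC3B-like deamination by the base two
#' positions 5' of the mutated cytosine.
#'
#' @return A `motif_registry` (named list of `mutation_motif`).
#' @export
builtin_registry <- function() {
  .motif_registry(list(
    mutation_motif("aTn", "aTn", "C"),
    mutation_motif("yCn", "yCn", "T"),
    mutation_motif("nCg", "nCg", "T"),
    mutation_motif("nTt", "nTt", "C"),
    mutation_motif("tCw_tTw", "tCw", "T"),
    mutation_motif("tCw_tGw", "tCw", "G"),
    mutation_motif("tgC", "tgC", "A"),
    mutation_motif("hTg", "hTg", "G"),
    mutation_motif("aCy", "aCy", "T"),
    mutation_motif("gCn", "gCn", "A"),
    mutation_motif("cTg", "cTg", "A"),
    mutation_motif("aTr", "aTr", "C"),
    mutation_motif("rCg", "rCg", "T"),
    mutation_motif("yCg", "yCg", "T"),
    mutation_motif("yCh", "yCh", "T"),
    mutation_motif("ytCa", "ytCa", c("T", "G")),
    mutation_motif("rtCa", "rtCa", c("T", "G")),
    mutation_motif("tCw", "tCw", c("T", "G"))
  ))
}

#' Look up a motif by name
#'
#' @param registry A `motif_registry`.
#' @param name Motif name.
#' @return The `mutation_motif`.
#' @export
get_motif <- function(registry, name) {
  if (!name %in% names(registry)) stop("motif not in registry: ", name)
  registry[[name]]
}

#' @export
print.motif_registry <- function(x, ...) {
  cat("motif_registry with", length(x), "motifs:\n")
  for (m in x) {
    cat(sprintf("  %-8s %s -> %s\n", m$name, m$ref_pattern,
                paste(m$mutant_bases, collapse = "/")))
  }
  invisible(x)
}

#' Read a motif registry from a TSV config file
#'
#' The file must have columns `name`, `ref_pattern` and `mutant_bases`
#' (alternate bases concatenated or comma-separated, e.g. `"TG"` or
#' `"T,G"`).
#'
#' @param path Path to the TSV file.
#' @return A `motif_registry`.
#' @export
read_motif_config <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("name", "ref_pattern", "mutant_bases")
  if (!all(req %in% names(df))) {
    stop("motif config must have columns: ", paste(req, collapse = ", "))
  }
  .motif_registry(lapply(seq_len(nrow(df)), function(i) {
    mb <- strsplit(gsub(",", "", df$mutant_bases[i]), "", fixed = TRUE)[[1]]
    mutation_motif(df$name[i], df$ref_pattern[i], mb)
  }))
}

#' Write a motif registry to a TSV config file
#'
#' @param registry A `motif_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_config <- function(registry, path) {
  df <- data.frame(
    name = vapply(registry, `[[`, "", "name"),
    ref_pattern = vapply(registry, `[[`, "", "ref_pattern"),
    mutant_bases = vapply(registry, function(m)
      paste(m$mutant_bases, collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## case-insensitive IUPAC match of fixed-length strings against a pattern;
## strings shorter/longer than the pattern never match
.match_iupac_strings <- function(strings, pattern) {
  k <- nchar(pattern)
  sets <- .iupac_sets(pattern)
  ok <- !is.na(strings) & nchar(strings) == k
  for (j in seq_len(k)) {
    ch <- .base_codes(substr(strings, j, j))
    ok <- ok & !is.na(ch) & ch %in% sets[[j]]
  }
  ok
}

#' Does a single mutation match a motif?
#'
#' The mutation is mapped onto the strand on which its reference base is
#' the motif's pyrimidine; the strand-adjusted alternate base must be one
#' of the motif's mutant bases and the strand-adjusted flanking bases
#' must satisfy the IUPAC pattern.  Windows too short to cover the full
#' pattern around the mutated base do not match.
#'
#' @param motif A `mutation_motif`.
#' @param window A `context_window` centered on the mutation (or a
#'   nucleotide string with the mutated base in the middle).
#' @param ref,alt Reference and alternate base on the reference strand.
#' @return Logical.
#' @export
mutation_matches <- function(motif, window, ref, alt) {
  seq <- toupper(.window_seq(window))
  center <- if (inherits(window, "context_window")) window$center
            else (nchar(seq) + 1L) %/% 2L
  ref <- toupper(ref); alt <- toupper(alt)
  if (substr(seq, center, center) != ref) {
    stop("window base at center (", substr(seq, center, center),
         ") does not equal ref (", ref, ")")
  }
  if (!substitution_in_class(motif, ref, alt)) return(FALSE)
  if (ref %in% c("A", "G")) {
    seq <- reverse_complement(seq)
    center <- nchar(seq) - center + 1L
  }
  from <- center - motif$center_index + 1L
  to <- center + (nchar(motif$ref_pattern) - motif$center_index)
  if (from < 1L || to > nchar(seq)) return(FALSE)
  unname(.match_iupac_strings(substr(seq, from, to), motif$ref_pattern))
}

#' Is a substitution in a motif's substitution class?
#'
#' True when the pyrimidine-canonical form of `ref>alt` equals one of the
#' motif's substitution pairs (e.g. for the combined APOBEC motif, C>T,
#' C>G, and their reverse complements G>A, G>C).
#'
#' @param motif A `mutation_motif`.
#' @param ref,alt Reference and alternate base (vectors allowed).
#' @return Logical vector.
#' @export
substitution_in_class <- function(motif, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ")
  .canonical_pair(ref, alt) %in% motif$class_subs
}
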
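## Reference-genome access, context-window extraction and double-stranded
## IUPAC pattern counting.  All public coordinates are 1-based, matching
## MAF/VCF conventions.

.BASES <- c("A", "C", "G", "T")

## IUPAC nucleotide codes mapped to the sets of bases they denote.
## N denotes {A,C,G,T}; a literal N in a sequence never satisfies any code.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
.IUPAC_TO   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

## integer base codes used by the matching engine (A=1 C=2 G=3 T=4, else NA)
.base_codes <- function(chars) match(chars, .BASES)

.iupac_sets <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad) > 0) {
    stop("unknown IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  }
  lapply(chars, function(ch) match(.IUPAC[[ch]], .BASES))
}

#' Reverse complement of nucleotide sequences
#'
#' Complements every IUPAC nucleotide code (e.g. `y` <-> `r`) and reverses
#' the sequence.  Case is preserved, so motif patterns with a designated
#' uppercase mutated position keep their annotation through strand flips.
#'
#' @param seq Character vector of nucleotide strings (IUPAC alphabet).
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("ATG")   # "CAT"
#' reverse_complement("ytn")   # "nar"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector")
  known <- strsplit(.IUPAC_FROM, "")[[1]]
  bad <- setdiff(unique(unlist(strsplit(seq, "", fixed = TRUE))), known)
  if (length(bad) > 0) {
    stop("unknown character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, seq)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "",
         USE.NAMES = FALSE)
}

## string reversal without complementing (internal)
.str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased and any character outside A/C/G/T/N is mapped
#' to N.  Contig names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A `reference_genome`: named character vector of contig
#'   sequences with one element per contig.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path)
  contigs <- toupper(as.character(set))
  names(contigs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]),
               collapse = ", "))
  }
  reference_genome(contigs)
}

#' Construct a reference genome from character sequences
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @return A `reference_genome` object.
#' @export
reference_genome <- function(contigs) {
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("all contigs must be named")
  }
  contigs <- toupper(contigs)
  contigs <- gsub("[^ACGTN]", "N", contigs)
  if (any(nchar(contigs) == 0)) stop("empty contig sequence")
  structure(contigs, class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome with", length(x), "contig(s):\n")
  for (nm in names(x)) cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

.contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  unclass(genome)[[contig]]
}

#' Extract the sequence context window around a mutated base
#'
#' Returns the +/-`flank` bases surrounding `pos`; windows at contig edges
#' are truncated rather than padded.
#'
#' @param genome A `reference_genome`.
#' @param contig Contig name.
#' @param pos 1-based position of the mutated base.
#' @param flank Number of bases on each side (default 20).
#' @return A `context_window`: list with `sequence` and `center` (1-based
#'   offset of the mutated base within `sequence`).
#' @export
extract_window <- function(genome, contig, pos, flank = 20L) {
  seq <- .contig_seq(genome, contig)
  L <- nchar(seq)
  if (flank < 1) stop("`flank` must be >= 1")
  if (pos < 1 || pos > L) {
    stop("position ", pos, " outside contig ", contig, " [1, ", L, "]")
  }
  start <- max(1L, pos - as.integer(flank))
  end <- min(L, pos + as.integer(flank))
  structure(list(sequence = substr(seq, start, end),
                 center = as.integer(pos - start + 1L)),
            class = "context_window")
}

.window_seq <- function(window) {
  if (inherits(window, "context_window")) window$sequence
  else if (is.character(window) && length(window) == 1) window
  else stop("`window` must be a context_window or a single string")
}

## logical vector of pattern-match start positions over an integer code
## vector; NA codes (N or separators) never match
.match_starts <- function(codes, sets) {
  n <- length(codes)
  k <- length(sets)
  if (n < k) return(logical(0))
  idx <- seq_len(n - k + 1L)
  hit <- codes[idx] %in% sets[[1]]
  if (k > 1) {
    for (j in 2:k) hit <- hit & (codes[idx + (j - 1L)] %in% sets[[j]])
  }
  hit
}

#' Count IUPAC pattern occurrences on both strands of a window
#'
#' Counts overlapping occurrences of `pattern` in the window sequence plus
#' occurrences in its reverse complement.  Positions containing N never
#' match.  This is the Context() term of the motif enrichment statistic.
#'
#' @param window A `context_window` or a single nucleotide string.
#' @param pattern IUPAC pattern (case-insensitive), length >= 1.
#' @return Integer count.
#' @examples
#' count_pattern("CATGA", "atn")  # 2: ATG forward, ATG on the other strand
#' count_pattern("TTTT", "t")     # 4
#' @export
count_pattern <- function(window, pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0) {
    stop("`pattern` must be a single non-empty string")
  }
  seq <- toupper(.window_seq(window))
  sets <- .iupac_sets(pattern)
  fwd <- .base_codes(strsplit(seq, "", fixed = TRUE)[[1]])
  rev <- .base_codes(strsplit(reverse_complement(seq), "", fixed = TRUE)[[1]])
  sum(.match_starts(fwd, sets)) + sum(.match_starts(rev, sets))
}

#' Pyrimidine-canonical trinucleotide substitution
#'
#' Reports a single-base substitution with its immediate 5'/3' context in
#' the conventional orientation where the mutated base is a pyrimidine
#' (C or T); purine-reference substitutions are reverse-complemented.
#' The mutated base is uppercase, the flanks lowercase.
#'
#' @param ref,alt Reference and alternate base (single A/C/G/T each);
#'   vectors are recycled together.
#' @param five_prime,three_prime Bases immediately 5' and 3' of the
#'   mutated base on the reference strand.
#' @return Character vector like `"aTg>aCg"`.
#' @export
canonical_substitution <- function(ref, alt, five_prime, three_prime) {
  ref <- toupper(ref); alt <- toupper(alt)
  five_prime <- toupper(five_prime); three_prime <- toupper(three_prime)
  ok <- ref %in% .BASES & alt %in% .BASES &
    five_prime %in% .BASES & three_prime %in% .BASES
  if (!all(ok)) stop("all bases must be single A/C/G/T characters")
  if (any(ref == alt)) stop("ref and alt must differ")
  pur <- ref %in% c("A", "G")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  f5 <- ifelse(pur, comp(three_prime), five_prime)
  f3 <- ifelse(pur, comp(five_prime), three_prime)
  r <- ifelse(pur, comp(ref), ref)
  a <- ifelse(pur, comp(alt), alt)
  paste0(tolower(f5), r, tolower(f3), ">", tolower(f5), a, tolower(f3))
}

## canonical substitution pair only ("T>C"), vectorized
.canonical_pair <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  paste0(ifelse(pur, comp(ref), ref), ">", ifelse(pur, comp(alt), alt))
}
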
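# Independent oracles and small fixture builders used across the suite.

# brute-force both-strand overlapping pattern count over a window string
brute_count_pattern <- function(window, pattern) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pat <- strsplit(toupper(pattern), "")[[1]]
  one_strand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch); k <- length(pat)
    if (n < k) return(0L)
    hits <- 0L
    for (i in seq_len(n - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!ch[i + j - 1] %in% iupac[[pat[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }
  one_strand(toupper(window)) + one_strand(rc(toupper(window)))
}

# exhaustive hypergeometric upper-tail p for the 2x2
# [[a, b], [c, d]] via lchoose enumeration over all tables with the
# observed margins
enum_fisher_upper <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  p <- exp(logp)
  p <- p / sum(p)
  sum(p[support >= a])
}

# independently coded BH step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# random ACGT(N) window string
random_window <- function(len, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  ch <- sample(alphabet, len, replace = TRUE)
  if (p_n > 0) {
    ch[runif(len) < p_n] <- "N"
  }
  paste(ch, collapse = "")
}

# catalogue with the genome reverse-complemented and every record
# flipped to the other strand (positions mirrored)
flip_catalog <- function(catalog, genome) {
  stopifnot(length(genome) == 1)
  L <- nchar(unclass(genome)[[1]])
  r <- catalog$records
  comp <- function(b) chartr("ACGT", "TGCA", b)
  sample_catalog(catalog$sample_id,
                 data.frame(contig = r$contig, pos = L + 1L - r$pos,
                            ref = comp(r$ref), alt = comp(r$alt),
                            stringsAsFactors = FALSE),
                 donor_id = catalog$donor_id, tissue = catalog$tissue,
                 disease = catalog$disease, age = catalog$age,
                 assay = catalog$assay, study_id = catalog$study_id)
}

flip_genome <- function(genome) {
  reference_genome(stats::setNames(
    reverse_complement(unclass(genome)[[1]]), names(genome)[1]))
}
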
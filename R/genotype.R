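#' Enumerate the full combinatorial genotype library
#'
#' Returns every combination of allowed alleles across the scheme's variable
#' positions, as strings of length \code{nrow(scheme$positions)} ordered
#' lexicographically (position order, alleles alphabetical). For the default
#' 13-position scheme this is the full 2^10 x 3^3 = 27,648-member library.
#'
#' @param scheme A \code{"variant_scheme"}.
#' @return Character vector of genotype strings, lexicographically sorted,
#'   no duplicates.
#' @export
enumerate_genotypes <- function(scheme) {
  stopifnot(inherits(scheme, "variant_scheme"))
  alle <- lapply(scheme$positions$alleles, sort)
  # expand.grid varies the first factor fastest; reverse so the *last*
  # position varies fastest, giving lexicographic order of the strings
  grid <- expand.grid(rev(alle), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

#' Reference (ancestral) genotype of a scheme
#'
#' @param scheme A \code{"variant_scheme"}.
#' @return Genotype string carrying the backbone allele at every position.
#' @export
ancestral_genotype <- function(scheme) {
  paste(scheme$positions$reference, collapse = "")
}

#' Hamming distance between genotypes
#'
#' Number of variable positions at which two genotypes differ. Vectorized
#' over \code{g1} and \code{g2} (recycled).
#'
#' @param g1,g2 Genotype strings from the same scheme.
#' @return Non-negative integer vector.
#' @export
hamming_distance <- function(g1, g2) {
  if (!all(nchar(g1) == nchar(g2)))
    stop("genotypes have different lengths; are they from the same scheme?")
  if (!length(g1) || !length(g2)) return(integer(0))
  n <- max(length(g1), length(g2))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
  m1 <- genotype_matrix(g1)
  m2 <- genotype_matrix(g2)
  as.integer(rowSums(m1 != m2))
}

#' Single-substitution neighbors of a genotype
#'
#' All genotypes at Hamming distance exactly one from \code{g}: every allowed
#' alternative allele at every variable position. Count equals
#' \code{sum(lengths(alleles) - 1)} (16 for the default scheme).
#'
#' @param scheme A \code{"variant_scheme"}.
#' @param g Genotype string.
#' @return Character vector of neighbor genotypes.
#' @export
neighbors <- function(scheme, g) {
  validate_genotype(scheme, g)
  ch <- seq_chars(g)
  out <- character(0)
  for (i in seq_len(n_positions(scheme))) {
    for (a in setdiff(scheme$positions$alleles[[i]], ch[i])) {
      h <- ch; h[i] <- a
      out <- c(out, paste(h, collapse = ""))
    }
  }
  out
}

#' Convert between genotypes and full-length sequences
#'
#' \code{genotype_to_sequence} writes a genotype's alleles into the backbone,
#' yielding the 67-nt ribozyme sequence. \code{sequence_to_genotype} is the
#' inverse: it requires the sequence to differ from the backbone only at
#' scheme positions and only by allowed alleles, and raises an error naming
#' the first offending backbone position otherwise. This is how sequences
#' outside the combinatorial library are detected.
#'
#' @param scheme A \code{"variant_scheme"}.
#' @param g Genotype string.
#' @return \code{genotype_to_sequence}: full-length sequence string;
#'   \code{sequence_to_genotype}: genotype string.
#' @export
genotype_to_sequence <- function(scheme, g) {
  validate_genotype(scheme, g)
  ch <- seq_chars(scheme$backbone)
  ch[scheme$positions$index] <- seq_chars(g)
  paste(ch, collapse = "")
}

#' @rdname genotype_to_sequence
#' @param seq Nucleotide string of backbone length (T accepted, normalized
#'   to U).
#' @export
sequence_to_genotype <- function(scheme, seq) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != nchar(scheme$backbone))
    stop("sequence length ", nchar(seq), " != backbone length ",
         nchar(scheme$backbone))
  ch <- seq_chars(seq)
  bb <- seq_chars(scheme$backbone)
  diffs <- which(ch != bb)
  off <- setdiff(diffs, scheme$positions$index)
  if (length(off))
    stop("off-scheme difference at backbone position ", off[1],
         " (", bb[off[1]], "->", ch[off[1]], ")")
  alle <- ch[scheme$positions$index]
  ok <- mapply(function(a, set) a %in% set, alle, scheme$positions$alleles)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop("allele ", alle[i], " not allowed at backbone position ",
         scheme$positions$index[i])
  }
  paste(alle, collapse = "")
}

#' Named mutations separating two genotypes
#'
#' One label per differing position, formatted as reference allele, backbone
#' index, observed allele (e.g. \code{"G1A"}, \code{"C9U"}), where the
#' reference allele is taken from \code{ref}.
#'
#' @param scheme A \code{"variant_scheme"}.
#' @param g Genotype to describe.
#' @param ref Reference genotype (default: the scheme's ancestral genotype).
#' @return Character vector of mutation labels; empty iff \code{g == ref}.
#' @export
mutations_from <- function(scheme, g, ref = ancestral_genotype(scheme)) {
  validate_genotype(scheme, g)
  validate_genotype(scheme, ref)
  gc <- seq_chars(g); rc <- seq_chars(ref)
  d <- which(gc != rc)
  paste0(rc[d], scheme$positions$index[d], gc[d])
}

## ---- internal -------------------------------------------------------------

validate_genotype <- function(scheme, g) {
  stopifnot(inherits(scheme, "variant_scheme"), is.character(g), length(g) == 1L)
  if (nchar(g) != n_positions(scheme))
    stop("genotype length ", nchar(g), " != number of scheme positions ",
         n_positions(scheme))
  ch <- seq_chars(g)
  ok <- mapply(function(a, set) a %in% set, ch, scheme$positions$alleles)
  if (!all(ok))
    stop("genotype allele ", ch[which(!ok)[1]], " not allowed at position ",
         which(!ok)[1])
  invisible(g)
}

# split a vector of equal-length genotype strings into a character matrix
genotype_matrix <- function(g) {
  n <- nchar(g[1])
  matrix(unlist(strsplit(g, "", fixed = TRUE), use.names = FALSE),
         ncol = n, byrow = TRUE)
}

# all single-substitution mutants of a genotype *vector*, per (position,
# allele) move; returns data.frame(from, to) with from < to deduplication
# left to callers
mutate_at <- function(scheme, genos, pos, allele) {
  cur <- substr(genos, pos, pos)
  keep <- cur != allele
  from <- genos[keep]
  to <- from
  substr(to, pos, pos) <- allele
  list(from = from, to = to)
}
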
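#' Construct a combinatorial variant scheme
#'
#' A variant scheme describes a doped combinatorial mutational library on a
#' 67-nt ribozyme backbone: which positions vary, which alleles each position
#' admits, the constant 9-nt 5' leader that marks uncleaved assay molecules,
#' and the constant 3' primer-binding region used to anchor sequencing reads.
#'
#' Coordinates are 1-based on the ribozyme sense strand; position 1 is the
#' first ribozyme nucleotide immediately 3' of the self-cleavage site (the
#' "G1" position). The leader sits upstream of position 1 and is indexed
#' separately. Sequences are held in the RNA alphabet (A, C, G, U); inputs
#' containing T are normalized to U.
#'
#' @param backbone Single string, the ribozyme reference (ancestral) sequence.
#'   Must contain only A, C, G, U after normalization.
#' @param positions A data.frame with columns \code{index} (1-based integer
#'   into the backbone), \code{alleles} (comma-joined nucleotides, e.g.
#'   \code{"G,A"}, or a list column of character vectors), and optionally
#'   \code{element} (structural element label, e.g. \code{"P1"}, \code{"L4"})
#'   and \code{name} (a label such as \code{"G1"}; defaults to reference
#'   allele + index). The reference allele of each position is taken from the
#'   backbone and must be a member of its allele set.
#' @param leader 9-nt upstream sequence whose presence marks an uncleaved
#'   read. Default \code{"GGACCAUUC"}.
#' @param primer_site Constant 3' primer-binding sequence appended to every
#'   transcript and used as the read anchor.
#'
#' @return An object of class \code{"variant_scheme"}: a list with elements
#'   \code{backbone}, \code{positions} (data.frame with list column
#'   \code{alleles} and derived columns \code{reference}, \code{element},
#'   \code{name}), \code{leader} and \code{primer_site}.
#' @seealso [default_scheme()], [enumerate_genotypes()], [read_scheme_tsv()]
#' @export
#' @examples
#' sc <- variant_scheme(
#'   backbone = "GAUC",
#'   positions = data.frame(index = c(1, 3), alleles = c("G,A", "U,C,A"))
#' )
#' enumerate_genotypes(sc)
variant_scheme <- function(backbone, positions,
                           leader = "GGACCAUUC",
                           primer_site = default_primer_site()) {
  backbone <- normalize_rna(backbone)
  leader <- normalize_rna(leader)
  primer_site <- normalize_rna(primer_site)
  stopifnot(is.data.frame(positions), all(c("index", "alleles") %in% names(positions)))
  bb <- seq_chars(backbone)

  idx <- as.integer(positions$index)
  if (anyNA(idx)) stop("position indices must be integers")
  if (any(idx < 1L) || any(idx > nchar(backbone)))
    stop("position indices must lie within [1, ", nchar(backbone), "]")
  if (anyDuplicated(idx)) stop("position indices must be unique")
  if (is.unsorted(idx, strictly = TRUE)) stop("position indices must be strictly increasing")

  alle <- positions$alleles
  if (!is.list(alle)) alle <- strsplit(as.character(alle), ",[[:space:]]*")
  alle <- lapply(alle, function(a) sort(normalize_rna(a)))
  ok <- vapply(alle, function(a) {
    length(a) %in% c(2L, 3L) && !anyDuplicated(a) && all(a %in% RNA_BASES)
  }, logical(1))
  if (!all(ok))
    stop("each allele set must contain 2 or 3 distinct bases from {A,C,G,U} (position index ",
         paste(idx[!ok], collapse = ", "), ")")

  ref <- bb[idx]
  bad <- !mapply(function(r, a) r %in% a, ref, alle)
  if (any(bad))
    stop("backbone allele not in allele set at position ", paste(idx[bad], collapse = ", "))

  element <- if ("element" %in% names(positions)) as.character(positions$element) else rep("other", length(idx))
  element[is.na(element) | element == ""] <- "other"
  name <- if ("name" %in% names(positions)) as.character(positions$name) else paste0(ref, idx)
  name[is.na(name) | name == ""] <- paste0(ref, idx)[is.na(name) | name == ""]

  pos <- data.frame(index = idx, reference = ref, element = element,
                    name = name, stringsAsFactors = FALSE)
  pos$alleles <- alle

  structure(list(backbone = backbone, positions = pos,
                 leader = leader, primer_site = primer_site),
            class = "variant_scheme")
}

#' @export
print.variant_scheme <- function(x, ...) {
  n_alle <- lengths(x$positions$alleles)
  cat("Variant scheme: ", nchar(x$backbone), "-nt backbone, ",
      nrow(x$positions), " variable positions (",
      sum(n_alle == 2L), " biallelic, ", sum(n_alle == 3L), " triallelic)\n",
      sep = "")
  cat("Library size:", prod(n_alle), "genotypes\n")
  cat("Leader:", x$leader, " Primer site:", x$primer_site, "\n")
  df <- x$positions
  df$alleles <- vapply(df$alleles, paste, "", collapse = "/")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Default phased-RT primer-binding site
#'
#' Constant 3' sequence appended to every simulated transcript; reads are
#' anchored on its rightmost occurrence during classification.
#' @return A 20-nt RNA string.
#' @export
default_primer_site <- function() "CUGGAAUUCGUCGGCAGCGU"

#' Packaged default 13-position scheme
#'
#' A 13-position combinatorial scheme on a 67-nt backbone with ten biallelic
#' and three triallelic positions (2^10 x 3^3 = 27,648 genotypes), emulating
#' the phylogenetically designed CPEB3 ribozyme library: it includes the G1
#' position (alleles G/A) that forms the first base pair next to the cleavage
#' site, the near-neutral C9U and G30A substitutions, the U36C change that
#' disrupts the G1:U36 wobble pair, and four positions in the peripheral L4
#' loop where mutations barely affect self-cleavage.
#'
#' The backbone sequence and the exact position identities are a synthetic
#' stand-in: they honor the structural constraints above but are not the
#' biological CPEB3 sequence. Supply your own scheme via [variant_scheme()]
#' or [read_scheme_tsv()] for real data.
#'
#' @return A \code{"variant_scheme"} object.
#' @export
#' @examples
#' sc <- default_scheme()
#' length(enumerate_genotypes(sc))  # 27648
default_scheme <- function() {
  backbone <- paste0(
    "GGCAAGGCCUAGCCGUCAGAGCUGAUGGCG", # 1-30
    "ACGUAUGGCAUCCCAUAGCGUGAUCCGUAC", # 31-60
    "GAUCGCA")                        # 61-67
  positions <- data.frame(
    index   = c(1L, 5L, 9L, 14L, 21L, 30L, 36L, 44L, 45L, 46L, 47L, 52L, 60L),
    alleles = c("G,A", "A,G", "C,U", "C,A", "G,A,U", "G,A", "U,C",
                "C,U", "A,G,U", "U,C", "A,G", "G,U", "C,A,G"),
    element = c("P1", "P1", "P1", "P2", "P3", "P2", "P1",
                "L4", "L4", "L4", "L4", "P4", "J4/2"),
    stringsAsFactors = FALSE
  )
  variant_scheme(backbone, positions)
}

#' Read / write a variant scheme as TSV
#'
#' The TSV has columns \code{index}, \code{reference}, \code{alleles}
#' (comma-joined), \code{element}, \code{name}; backbone, leader and primer
#' site are carried in \code{#key: value} header comments.
#'
#' @param path File path.
#' @return \code{read_scheme_tsv} returns a \code{"variant_scheme"};
#'   \code{write_scheme_tsv} returns \code{path} invisibly.
#' @export
read_scheme_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- function(key) {
    m <- grep(paste0("^#", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("scheme TSV missing '#", key, ":' header")
    trimws(sub(paste0("^#", key, ":"), "", m[1]))
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  variant_scheme(kv("backbone"), df, leader = kv("leader"),
                 primer_site = kv("primer_site"))
}

#' @rdname read_scheme_tsv
#' @param scheme A \code{"variant_scheme"}.
#' @export
write_scheme_tsv <- function(scheme, path) {
  stopifnot(inherits(scheme, "variant_scheme"))
  df <- scheme$positions
  df$alleles <- vapply(df$alleles, paste, "", collapse = ",")
  df <- df[, c("index", "reference", "alleles", "element", "name")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#backbone: ", scheme$backbone),
               paste0("#leader: ", scheme$leader),
               paste0("#primer_site: ", scheme$primer_site)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- internal helpers -----------------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")

# uppercase, DNA->RNA; validates the alphabet
normalize_rna <- function(x) {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) stop("sequence contains non-ACGU/T characters: ",
                     substr(x[bad][1], 1, 30))
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

n_positions <- function(scheme) nrow(scheme$positions)

# index of the scheme position sitting at backbone coordinate 1 (the G1
# position), or NA if coordinate 1 is not variable
g1_position <- function(scheme) match(1L, scheme$positions$index)

l4_indices <- function(scheme) scheme$positions$index[scheme$positions$element == "L4"]
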
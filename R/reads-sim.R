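#' Phasing pad oligos
#'
#' The four fixed pads of 9, 12, 15 and 18 nt prepended to reads during
#' phased template-switching reverse transcription (cluster-diversity
#' phasing). They share a common 9-nt 3' end chosen to be dissimilar from
#' the cleavage-site leader so that pad suffixes are never mistaken for it.
#'
#' @return Named character vector of length 4 (names "9", "12", "15", "18").
#' @export
phasing_pads <- function() {
  c("9"  = "UCAACGUCA",
    "12" = "AGCUCAACGUCA",
    "15" = "GGUAGCUCAACGUCA",
    "18" = "ACCGGUAGCUCAACGUCA")
}

#' Simulate self-cleavage assay reads
#'
#' Emulates the co-transcriptional self-cleavage sequencing assay: for each
#' molecule of genotype g, the cleavage state is Bernoulli with the
#' genotype's true cleavage probability; an uncleaved molecule retains the
#' 9-nt leader immediately 5' of the ribozyme while a cleaved one has lost
#' it; every read is
#' \code{pad + [leader if uncleaved] + ribozyme(g) + primer_site},
#' with the pad drawn uniformly from the four phasing pads, followed by
#' i.i.d. substitution errors at \code{error_rate}. Replicates use seeds
#' derived deterministically from \code{seed}, so the same seed yields
#' byte-identical output.
#'
#' @param landscape A \code{"truth_landscape"}, or any data.frame with
#'   columns \code{genotype} and \code{p}.
#' @param scheme The \code{"variant_scheme"} the genotypes belong to.
#' @param reads_per_genotype Molecules simulated per genotype per replicate
#'   (default 100).
#' @param n_replicates Number of replicate streams (default 3, as in the
#'   assay).
#' @param error_rate Per-base substitution error probability in [0, 0.25).
#' @param seed Integer master seed.
#' @param genotypes Optional subset of genotypes to simulate (default: all
#'   genotypes in the landscape). Genotypes absent from the landscape are an
#'   error.
#' @return A \code{"read_set"}: data.frame with columns \code{id},
#'   \code{sequence}, \code{replicate}, \code{true_state} ("cleaved" /
#'   "uncleaved") and \code{genotype} (truth metadata, not encoded in the
#'   sequence payload).
#' @seealso [count_reads()], [write_reads_fastq()]
#' @export
simulate_reads <- function(landscape, scheme, reads_per_genotype = 100L,
                           n_replicates = 3L, error_rate = 0.001,
                           seed = 1L, genotypes = NULL) {
  stopifnot(inherits(scheme, "variant_scheme"),
            reads_per_genotype >= 0, n_replicates >= 1,
            error_rate >= 0, error_rate < 0.25)
  lp <- stats::setNames(landscape$p, landscape$genotype)
  if (is.null(genotypes)) genotypes <- landscape$genotype
  missing <- setdiff(genotypes, names(lp))
  if (length(missing))
    stop("genotype(s) absent from landscape: ",
         paste(utils::head(missing, 3), collapse = ", "))
  p <- unname(lp[genotypes])
  ribo <- vapply(genotypes, function(g) genotype_to_sequence(scheme, g), "")

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  pads <- phasing_pads()
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    n <- reads_per_genotype * length(genotypes)
    g_idx <- rep(seq_along(genotypes), each = reads_per_genotype)
    cleaved <- stats::rbinom(n, 1L, p[g_idx]) == 1L
    pad <- pads[sample.int(4L, n, replace = TRUE)]
    seqs <- paste0(pad, ifelse(cleaved, "", scheme$leader),
                   ribo[g_idx], scheme$primer_site)
    if (error_rate > 0) seqs <- add_substitution_errors(seqs, error_rate)
    out[[r]] <- data.frame(
      id = sprintf("rep%d_read%06d", r, seq_len(n)),
      sequence = seqs,
      replicate = r,
      true_state = ifelse(cleaved, "cleaved", "uncleaved"),
      genotype = genotypes[g_idx],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("read_set", "data.frame")
  res
}

# i.i.d. substitution errors; each errored base is replaced by a uniform
# draw from the three other bases
add_substitution_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(stats::runif(total) < rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  read_of <- findInterval(hit, starts)
  offset <- hit - starts[read_of] + 1L
  for (k in seq_along(hit)) {
    i <- read_of[k]; j <- offset[k]
    cur <- substr(seqs[i], j, j)
    substr(seqs[i], j, j) <- sample(setdiff(RNA_BASES, cur), 1L)
  }
  seqs
}

#' Write / read simulated reads as FASTQ or FASTA
#'
#' FASTQ records carry constant quality "I". Headers hold only the read id;
#' truth metadata stays in the \code{"read_set"} data.frame.
#'
#' @param reads A \code{"read_set"} (or data.frame with \code{id},
#'   \code{sequence}, \code{replicate}).
#' @param path Output file.
#' @return \code{path} (writers) or a read data.frame (readers), invisibly
#'   for writers.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::BStringSet(reads$sequence)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::BStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_reads_fastq
#' @param format "fastq" or "fasta".
#' @param replicate Replicate id to assign to all reads in the file
#'   (default 1); assays with several replicate files are read one file at a
#'   time.
#' @export
read_reads_fastx <- function(path, format = c("fastq", "fasta"), replicate = 1L) {
  format <- match.arg(format)
  x <- Biostrings::readBStringSet(path, format = format)
  data.frame(id = names(x),
             sequence = normalize_rna(as.character(x)),
             replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}
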
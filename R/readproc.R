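#' Classify a single assay read
#'
#' Implements the anchor-based read analysis: locate the reverse-transcription
#' primer-binding site at the 3' end of the read (rightmost match with at
#' most \code{max_mismatch} substitutions), index the 67-nt ribozyme
#' immediately 5' of it, then decide the cleavage state from the 9 nt
#' immediately 5' of the ribozyme: if they match the leader (same mismatch
#' tolerance) the molecule is uncleaved; if there is no leader and the
#' ribozyme begins within the maximal phasing-pad window the molecule is
#' cleaved. Alleles are extracted at the scheme's variable offsets; a
#' genotype is returned only when every extracted allele is allowed
#' (mismatch-bearing variable positions are rejected, not corrected).
#'
#' @param read Nucleotide string (T accepted and normalized to U).
#' @param scheme A \code{"variant_scheme"}.
#' @param max_mismatch Mismatch tolerance for the primer-site and leader
#'   anchors (default 1).
#' @return List with \code{state} ("cleaved", "uncleaved" or "unassigned"),
#'   \code{genotype} (string or \code{NA}) and \code{reason} (\code{NA} or
#'   one of "no_primer", "no_ribozyme_window", "ambiguous_prefix",
#'   "offscheme_allele").
#' @export
#' @examples
#' sc <- default_scheme()
#' anc <- ancestral_genotype(sc)
#' rd <- paste0(phasing_pads()[["12"]], genotype_to_sequence(sc, anc),
#'              sc$primer_site)
#' classify_read(rd, sc)  # cleaved, ancestral
classify_read <- function(read, scheme, max_mismatch = 1L) {
  read <- normalize_rna(read)
  classify_read_int(utf8ToInt(read), scheme_codes(scheme), max_mismatch)
}

# precompute integer-coded anchors and offsets for the hot loop
scheme_codes <- function(scheme) {
  list(primer = utf8ToInt(scheme$primer_site),
       leader = utf8ToInt(scheme$leader),
       rlen = nchar(scheme$backbone),
       offsets = scheme$positions$index,
       alleles = scheme$positions$alleles,
       max_pad = max(nchar(phasing_pads())))
}

classify_read_int <- function(codes, sc, max_mismatch) {
  plen <- length(sc$primer)
  L <- length(codes)
  unassigned <- function(reason) list(state = "unassigned", genotype = NA_character_,
                                      reason = reason)
  if (L < plen + sc$rlen) return(unassigned("no_primer"))
  # rightmost primer-site match with <= max_mismatch substitutions
  p_start <- NA_integer_
  for (s in (L - plen + 1L):1L) {
    if (sum(codes[s:(s + plen - 1L)] != sc$primer) <= max_mismatch) {
      p_start <- s
      break
    }
  }
  if (is.na(p_start)) return(unassigned("no_primer"))
  r_start <- p_start - sc$rlen
  if (r_start < 1L) return(unassigned("no_ribozyme_window"))

  llen <- length(sc$leader)
  has_leader <- r_start > llen &&
    sum(codes[(r_start - llen):(r_start - 1L)] != sc$leader) <= max_mismatch
  if (has_leader) {
    state <- "uncleaved"
    prefix <- r_start - llen - 1L
  } else {
    state <- "cleaved"
    prefix <- r_start - 1L
  }
  # the remaining 5' prefix must fit inside one phasing pad
  if (prefix > sc$max_pad) return(unassigned("ambiguous_prefix"))

  obs <- codes[r_start - 1L + sc$offsets]
  g <- character(length(obs))
  for (i in seq_along(obs)) {
    a <- intToUtf8(obs[i])
    if (!a %in% sc$alleles[[i]])
      return(list(state = state, genotype = NA_character_,
                  reason = "offscheme_allele"))
    g[i] <- a
  }
  list(state = state, genotype = paste(g, collapse = ""), reason = NA_character_)
}

#' Count cleaved and uncleaved reads per genotype and replicate
#'
#' Applies [classify_read()] to every read and tabulates counts. Each read
#' contributes to exactly one cell: \code{n_cleaved} or \code{n_uncleaved}
#' of its genotype, \code{n_rejected} of its genotype when the state could
#' not be determined, or the per-replicate unassigned pool when no genotype
#' could be extracted. Order of input reads does not affect the result.
#'
#' @param reads A \code{"read_set"} or data.frame with columns
#'   \code{sequence} and \code{replicate}.
#' @param scheme A \code{"variant_scheme"}.
#' @param max_mismatch Anchor mismatch tolerance (see [classify_read()]).
#' @return A \code{"cleavage_counts"}: data.frame with columns
#'   \code{genotype}, \code{replicate}, \code{n_cleaved},
#'   \code{n_uncleaved}, \code{n_rejected}, sorted by genotype then
#'   replicate, plus attribute \code{unassigned} (named integer per
#'   replicate: reads with no extractable genotype).
#' @export
count_reads <- function(reads, scheme, max_mismatch = 1L) {
  stopifnot(is.data.frame(reads) || inherits(reads, "read_set"))
  sc <- scheme_codes(scheme)
  n <- nrow(reads)
  reps <- sort(unique(as.integer(reads$replicate)))
  if (n == 0L) {
    out <- data.frame(genotype = character(0), replicate = integer(0),
                      n_cleaved = integer(0), n_uncleaved = integer(0),
                      n_rejected = integer(0))
    attr(out, "unassigned") <- stats::setNames(integer(length(reps)),
                                               as.character(reps))
    class(out) <- c("cleavage_counts", "data.frame")
    return(out)
  }
  seqs <- normalize_rna(reads$sequence)
  states <- character(n); genos <- character(n)
  for (i in seq_len(n)) {
    cl <- classify_read_int(utf8ToInt(seqs[i]), sc, max_mismatch)
    states[i] <- cl$state
    genos[i] <- cl$genotype
  }
  rep_id <- as.integer(reads$replicate)
  assigned <- !is.na(genos)
  unassigned <- table(factor(rep_id[!assigned], levels = reps))
  key <- interaction(genos[assigned], rep_id[assigned], drop = TRUE, lex.order = TRUE)
  st <- factor(states[assigned], levels = c("cleaved", "uncleaved", "unassigned"))
  tab <- table(key, st)
  parts <- strsplit(rownames(tab), ".", fixed = TRUE)
  out <- data.frame(
    genotype = vapply(parts, `[`, "", 1L),
    replicate = as.integer(vapply(parts, `[`, "", 2L)),
    n_cleaved = as.integer(tab[, "cleaved"]),
    n_uncleaved = as.integer(tab[, "uncleaved"]),
    n_rejected = as.integer(tab[, "unassigned"]),
    stringsAsFactors = FALSE)
  out <- out[order(out$genotype, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- stats::setNames(as.integer(unassigned),
                                             as.character(reps))
  class(out) <- c("cleavage_counts", "data.frame")
  out
}

#' Fraction of reads in the cleaved state
#'
#' The activity estimator of the sequencing assay:
#' \code{n_cleaved / (n_cleaved + n_uncleaved)}. Vectorized. When both
#' counts are zero there is no data and the result is \code{NA}, never 0.
#'
#' @param n_cleaved,n_uncleaved Non-negative integer vectors.
#' @return Numeric vector in [0, 1] (or \code{NA} where no reads).
#' @export
fraction_cleaved <- function(n_cleaved, n_uncleaved) {
  if (any(n_cleaved < 0) || any(n_uncleaved < 0))
    stop("read counts must be non-negative")
  tot <- n_cleaved + n_uncleaved
  ifelse(tot > 0, n_cleaved / tot, NA_real_)
}

#' Aggregate replicate counts into an activity table
#'
#' Computes per-genotype, per-replicate fraction cleaved, flags
#' genotype-replicate cells with fewer than \code{min_reads} classified
#' reads, averages the fraction over qualifying replicates (or pools counts
#' first when \code{pooled = TRUE}), and reports pairwise Pearson
#' correlations between replicate fraction vectors restricted to genotypes
#' qualifying in both members of each pair.
#'
#' @param counts A \code{"cleavage_counts"} data.frame.
#' @param min_reads Minimum \code{n_cleaved + n_uncleaved} for a
#'   genotype-replicate cell to qualify (default 20).
#' @param pooled If \code{TRUE}, the headline activity is the ratio of
#'   pooled counts over qualifying replicates instead of the unweighted
#'   mean of per-replicate fractions.
#' @return An \code{"activity_table"}: data.frame with columns
#'   \code{genotype}, one \code{frac_rep<r>} per replicate,
#'   \code{mean_fraction}, \code{total_reads} and \code{qc_pass} (at least
#'   one qualifying replicate); attribute \code{replicate_cor} holds the
#'   pairwise correlation matrix, \code{min_reads} the threshold used.
#' @export
aggregate_replicates <- function(counts, min_reads = 20L, pooled = FALSE) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) {
    warning("no genotype qualifies: empty counts")
    out <- data.frame(genotype = character(0), mean_fraction = numeric(0),
                      total_reads = integer(0), qc_pass = logical(0))
    class(out) <- c("activity_table", "data.frame")
    return(out)
  }
  reps <- sort(unique(counts$replicate))
  genos <- sort(unique(counts$genotype))
  nrep <- length(reps)
  frac <- matrix(NA_real_, length(genos), nrep,
                 dimnames = list(genos, paste0("frac_rep", reps)))
  ncl <- nun <- matrix(0L, length(genos), nrep)
  gi <- match(counts$genotype, genos)
  ri <- match(counts$replicate, reps)
  ncl[cbind(gi, ri)] <- counts$n_cleaved
  nun[cbind(gi, ri)] <- counts$n_uncleaved
  tot <- ncl + nun
  qual <- tot >= min_reads
  frac[] <- fraction_cleaved(as.vector(ncl), as.vector(nun))
  fq <- frac; fq[!qual] <- NA_real_
  mean_fraction <- if (pooled) {
    nc <- rowSums(ncl * qual); nu <- rowSums(nun * qual)
    fraction_cleaved(nc, nu)
  } else {
    rowMeans(fq, na.rm = TRUE)
  }
  mean_fraction[rowSums(qual) == 0L] <- NA_real_

  out <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (j in seq_len(nrep)) out[[colnames(frac)[j]]] <- frac[, j]
  out$mean_fraction <- mean_fraction
  out$total_reads <- as.integer(rowSums(tot))
  out$qc_pass <- rowSums(qual) > 0L
  if (!any(out$qc_pass)) warning("no genotype passes the min_reads threshold")

  cors <- matrix(NA_real_, nrep, nrep, dimnames = list(reps, reps))
  diag(cors) <- 1
  if (nrep > 1) {
    for (a in 1:(nrep - 1)) for (b in (a + 1):nrep) {
      both <- qual[, a] & qual[, b]
      if (sum(both) >= 3)
        cors[a, b] <- cors[b, a] <- stats::cor(frac[both, a], frac[both, b])
    }
  }
  attr(out, "replicate_cor") <- cors
  attr(out, "min_reads") <- min_reads
  class(out) <- c("activity_table", "data.frame")
  out
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Activity table:", nrow(x), "genotypes;",
      sum(x$qc_pass), "pass QC\n")
  rc <- attr(x, "replicate_cor")
  if (!is.null(rc) && nrow(rc) > 1)
    cat("Replicate correlations (Pearson):",
        paste(sprintf("%.3f", rc[upper.tri(rc)]), collapse = ", "), "\n")
  NextMethod()
}

#' Read / write counts and activity tables as TSV
#' @param x A \code{"cleavage_counts"} or \code{"activity_table"}.
#' @param path File path.
#' @return Readers return data.frames; writers return \code{path} invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- utils::read.delim(path, colClasses = c(genotype = "character"))
  class(out) <- c("cleavage_counts", "data.frame")
  out
}

#' @rdname write_counts_tsv
#' @export
write_activity_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_activity_tsv <- function(path) {
  out <- utils::read.delim(path, colClasses = c(genotype = "character"))
  class(out) <- c("activity_table", "data.frame")
  out
}
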
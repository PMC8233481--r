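#' Enumerate mutation-pair squares around a reference genotype
#'
#' A square is a reference genotype g00, two single mutants g10 and g01
#' (one substitution each, at two distinct positions) and the double
#' mutant g11 carrying both substitutions. One square is produced per
#' unordered pair of distinct positions and per choice of one non-current
#' allele at each. For the default 13-position scheme any reference yields
#' C(10,2)·1 + 10·3·2 + C(3,2)·4 = 117 squares.
#'
#' @param scheme A \code{"variant_scheme"}.
#' @param reference Reference genotype (g00).
#' @return data.frame: \code{pos1}, \code{pos2} (backbone indices),
#'   \code{allele1}, \code{allele2}, \code{g00}, \code{g10}, \code{g01},
#'   \code{g11}.
#' @export
enumerate_squares <- function(scheme, reference) {
  validate_genotype(scheme, reference)
  np <- n_positions(scheme)
  alle <- scheme$positions$alleles
  idx <- scheme$positions$index
  ch <- seq_chars(reference)
  rows <- list()
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    for (a in setdiff(alle[[i]], ch[i])) for (b in setdiff(alle[[j]], ch[j])) {
      g10 <- g01 <- g11 <- reference
      substr(g10, i, i) <- a
      substr(g01, j, j) <- b
      substr(g11, i, i) <- a
      substr(g11, j, j) <- b
      rows[[length(rows) + 1L]] <- data.frame(
        pos1 = idx[i], pos2 = idx[j], allele1 = a, allele2 = b,
        g00 = reference, g10 = g10, g01 = g01, g11 = g11,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify pairwise epistasis in a square
#'
#' Vectorized classification of mutation-pair squares from their four
#' activities. The epistasis magnitude is
#' \code{e = w11 - w10 - w01 + w00}; squares with \code{|e| <= delta} are
#' \emph{none}. Otherwise each mutation's effect is evaluated on both
#' backgrounds (mutation 1: \code{w10 - w00} and \code{w11 - w01};
#' mutation 2: \code{w01 - w00} and \code{w11 - w10}); a mutation
#' \emph{flips} when its two background effects have strictly opposite
#' signs with both magnitudes above \code{delta} (effects within
#' \code{delta} of zero never flip). Both mutations flip:
#' \emph{reciprocal_sign}; exactly one: \emph{sign}; neither:
#' \emph{magnitude}. The classification is symmetric in the two mutations.
#'
#' @param w00,w10,w01,w11 Activity vectors in [0, 1] (reference, the two
#'   single mutants, the double mutant).
#' @param delta Noise tolerance (default 0: exact arithmetic).
#' @return data.frame: \code{class} (factor with levels none, magnitude,
#'   sign, reciprocal_sign) and \code{e}.
#' @export
classify_square <- function(w00, w10, w01, w11, delta = 0) {
  vals <- cbind(w00, w10, w01, w11)
  if (any(!is.finite(vals))) stop("activities must be finite")
  if (delta < 0) stop("delta must be >= 0")
  e <- w11 - w10 - w01 + w00
  d1 <- w10 - w00; d1p <- w11 - w01
  d2 <- w01 - w00; d2p <- w11 - w10
  # small guard so additive squares classify as "none" at delta = 0 despite
  # floating-point cancellation
  delta <- delta + 1e-9
  flips <- function(a, b) (a > delta & b < -delta) | (a < -delta & b > delta)
  f1 <- flips(d1, d1p)
  f2 <- flips(d2, d2p)
  cls <- ifelse(abs(e) <= delta, "none",
         ifelse(f1 & f2, "reciprocal_sign",
         ifelse(f1 | f2, "sign", "magnitude")))
  data.frame(class = factor(cls, levels = c("none", "magnitude", "sign",
                                            "reciprocal_sign")),
             e = e)
}

#' Epistasis class fractions around a reference
#'
#' Enumerates the squares around \code{reference}, looks their four
#' corners up in the activity table, classifies each evaluable square
#' (squares with any missing corner are skipped and counted), and reports
#' per-class counts and percentages.
#'
#' @param activity Activity carrier (see [build_network()]).
#' @param scheme A \code{"variant_scheme"}.
#' @param reference Reference genotype; must be present in the activity
#'   table.
#' @param delta Noise tolerance passed to [classify_square()].
#' @return An \code{"epistasis_summary"} list: \code{reference},
#'   \code{delta}, \code{n_squares}, \code{n_evaluable}, \code{n_missing},
#'   \code{counts} (named integer), \code{percent} (named numeric),
#'   \code{squares} (the classified square table).
#' @export
epistasis_summary <- function(activity, scheme, reference, delta = 0) {
  av <- activity_vector(activity)
  if (!reference %in% names(av) || is.na(av[reference]))
    stop("reference genotype absent from the activity table")
  sq <- enumerate_squares(scheme, reference)
  sq$w00 <- unname(av[sq$g00])
  sq$w10 <- unname(av[sq$g10])
  sq$w01 <- unname(av[sq$g01])
  sq$w11 <- unname(av[sq$g11])
  ok <- stats::complete.cases(sq[, c("w00", "w10", "w01", "w11")])
  ev <- sq[ok, , drop = FALSE]
  cl <- classify_square(ev$w00, ev$w10, ev$w01, ev$w11, delta)
  ev$class <- cl$class
  ev$e <- cl$e
  counts <- table(cl$class)
  structure(list(reference = reference, delta = delta,
                 n_squares = nrow(sq), n_evaluable = nrow(ev),
                 n_missing = nrow(sq) - nrow(ev),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 percent = stats::setNames(
                   100 * as.numeric(counts) / max(nrow(ev), 1L),
                   names(counts)),
                 squares = ev),
            class = "epistasis_summary")
}

#' @export
print.epistasis_summary <- function(x, ...) {
  cat("Epistasis around", x$reference, "(delta =", x$delta, ")\n")
  cat(sprintf("  %d squares, %d evaluable, %d with missing corners\n",
              x$n_squares, x$n_evaluable, x$n_missing))
  for (k in names(x$counts))
    cat(sprintf("  %-16s %6d  (%5.1f%%)\n", k, x$counts[k], x$percent[k]))
  invisible(x)
}

#' Dataset-wide epistasis class fractions
#'
#' Classifies the reference-rooted squares of every genotype in
#' \code{references} (default: all genotypes with an activity) and pools
#' the class counts — the dataset-wide average prevalence of each
#' epistasis class. Vectorized over square templates, so the full default
#' library (27,648 references x 117 squares) is feasible.
#'
#' @inheritParams epistasis_summary
#' @param references Genotypes to use as square roots (default: all with
#'   non-missing activity).
#' @return List like [epistasis_summary()] without the per-square table,
#'   plus \code{n_references}.
#' @export
epistasis_dataset_summary <- function(activity, scheme, delta = 0,
                                      references = NULL) {
  av <- activity_vector(activity)
  av <- av[!is.na(av)]
  if (is.null(references)) references <- names(av)
  np <- n_positions(scheme)
  alle <- scheme$positions$alleles
  counts <- stats::setNames(integer(4), c("none", "magnitude", "sign",
                                          "reciprocal_sign"))
  n_squares <- 0L
  n_evaluable <- 0L
  w00 <- unname(av[references])
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    ci <- substr(references, i, i)
    cj <- substr(references, j, j)
    for (a in alle[[i]]) for (b in alle[[j]]) {
      keep <- ci != a & cj != b
      if (!any(keep)) next
      n_squares <- n_squares + sum(keep)
      g10 <- g01 <- g11 <- references[keep]
      substr(g10, i, i) <- a
      substr(g01, j, j) <- b
      substr(g11, i, i) <- a
      substr(g11, j, j) <- b
      w10 <- unname(av[g10]); w01 <- unname(av[g01]); w11 <- unname(av[g11])
      ok <- !is.na(w00[keep]) & !is.na(w10) & !is.na(w01) & !is.na(w11)
      if (!any(ok)) next
      n_evaluable <- n_evaluable + sum(ok)
      cl <- classify_square(w00[keep][ok], w10[ok], w01[ok], w11[ok], delta)
      counts <- counts + table(cl$class)[names(counts)]
    }
  }
  list(delta = delta, n_references = length(references),
       n_squares = n_squares, n_evaluable = n_evaluable,
       n_missing = n_squares - n_evaluable,
       counts = stats::setNames(as.integer(counts), names(counts)),
       percent = stats::setNames(100 * as.numeric(counts) /
                                   max(n_evaluable, 1L), names(counts)))
}

#' Write an epistasis summary as JSON or TSV
#' @param x An \code{"epistasis_summary"} (or the list from
#'   [epistasis_dataset_summary()]).
#' @param path Output file; extension \code{.json} selects JSON, anything
#'   else a two-column TSV of the class percentages.
#' @return \code{path}, invisibly.
#' @export
write_epistasis_summary <- function(x, path) {
  x <- unclass(x)
  x$squares <- NULL
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(class = names(x$counts), count = unname(x$counts),
                     percent = unname(x$percent))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
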
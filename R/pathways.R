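#' Closed-form count of ordered distinct-position pathways
#'
#' The number of ordered mutational pathways of exactly \code{L} steps from
#' any genotype, where each step substitutes a distinct variable position
#' to any allowed alternative allele, for a scheme with \code{b} biallelic
#' and \code{t} triallelic positions:
#' \deqn{P(L) = L! \sum_k \binom{t}{k} \binom{b}{L-k} 2^k.}
#' For the default library (b = 10, t = 3, L = 4) this is 37,200.
#'
#' @param b,t Numbers of biallelic and triallelic positions.
#' @param L Pathway length (number of steps).
#' @return Integer count.
#' @export
pathway_count_closed_form <- function(b, t, L) {
  k <- 0:min(t, L)
  factorial(L) * sum(choose(t, k) * choose(b, L - k) * 2^k)
}

#' Enumerate and filter mutational pathways
#'
#' Enumerates every ordered pathway of \code{max_steps} single-position
#' substitutions from \code{start}, with the steps at pairwise-distinct
#' positions (no reversions) and each substitution to any allowed
#' non-current allele. A pathway is \emph{viable} when the genotype after
#' every step has activity strictly greater than \code{threshold}
#' (the start's own activity is not filtered); pathways are truncated at
#' the first non-viable genotype, which is what makes realized pathways
#' "up to" \code{max_steps} long. Genotypes with missing (\code{NA})
#' activity are treated as below threshold.
#'
#' @param activity Activity carrier (see [build_network()]).
#' @param scheme A \code{"variant_scheme"}.
#' @param start Start genotype.
#' @param max_steps Pathway length (default 4; must not exceed the number
#'   of variable positions).
#' @param threshold Viability threshold (default 0.5; use \code{-Inf} for
#'   the unfiltered enumeration).
#' @param keep_paths If \code{TRUE}, also return each viable pathway as a
#'   string of comma-joined mutation labels.
#' @return A \code{"pathway_report"} list: \code{start},
#'   \code{max_steps}, \code{threshold}, \code{total_enumerated},
#'   \code{viable_count}, and (optionally) \code{paths}.
#' @export
count_viable_pathways <- function(activity, scheme, start, max_steps = 4L,
                                  threshold = 0.5, keep_paths = FALSE) {
  validate_genotype(scheme, start)
  np <- n_positions(scheme)
  if (max_steps > np)
    stop("max_steps exceeds the number of variable positions")
  act <- new.env(hash = TRUE, parent = emptyenv())
  if (threshold > -Inf) {
    av <- activity_vector(activity)
    for (i in seq_along(av)) assign(names(av)[i], av[[i]], envir = act)
  }
  alleles <- scheme$positions$alleles
  idx <- scheme$positions$index
  total <- 0L
  viable <- 0L
  paths <- if (keep_paths) character(0) else NULL

  recurse <- function(g, used, depth, is_viable, labels) {
    if (depth == max_steps) {
      total <<- total + 1L
      if (is_viable) {
        viable <<- viable + 1L
        if (keep_paths) paths <<- c(paths, paste(labels, collapse = ","))
      }
      return(invisible())
    }
    for (i in seq_len(np)) {
      if (used[i]) next
      cur <- substr(g, i, i)
      for (a in alleles[[i]]) {
        if (a == cur) next
        h <- g
        substr(h, i, i) <- a
        v <- is_viable
        if (v && threshold > -Inf) {
          ha <- get0(h, envir = act, ifnotfound = NA_real_)
          v <- !is.na(ha) && ha > threshold
        }
        used[i] <- TRUE
        recurse(h, used, depth + 1L,
                v, if (keep_paths) c(labels, paste0(cur, idx[i], a)) else NULL)
        used[i] <- FALSE
      }
    }
  }
  recurse(start, rep(FALSE, np), 0L, TRUE, character(0))
  out <- list(start = start, max_steps = max_steps, threshold = threshold,
              total_enumerated = total, viable_count = viable)
  if (keep_paths) out$paths <- paths
  class(out) <- "pathway_report"
  out
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("Pathway report from", x$start, "\n")
  cat(sprintf("  %d steps, activity threshold %s\n", x$max_steps,
              format(x$threshold)))
  cat(sprintf("  %d enumerated, %d viable (%.1f%%)\n", x$total_enumerated,
              x$viable_count, 100 * x$viable_count / max(x$total_enumerated, 1)))
  invisible(x)
}

#' Write a pathway report as JSON
#' @param report A \code{"pathway_report"}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_pathway_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Accessible mutational neighborhood rings
#'
#' For each distance d = 0..\code{max_dist}, the set of genotypes at
#' Hamming distance d from \code{start} that are reachable by a viable
#' pathway whose distance from the start increases by one at every step
#' and whose every intermediate (and endpoint) has activity strictly above
#' \code{threshold}. Ring 0 is the start itself.
#'
#' @inheritParams count_viable_pathways
#' @param max_dist Outermost ring (default 4).
#' @return Named list \code{ring0 ... ring<max_dist>} of genotype vectors.
#' @export
neighborhood_rings <- function(activity, scheme, start, max_dist = 4L,
                               threshold = 0.5) {
  validate_genotype(scheme, start)
  av <- activity_vector(activity)
  av <- av[!is.na(av)]
  active <- names(av)[av > threshold]
  rings <- vector("list", max_dist + 1L)
  names(rings) <- paste0("ring", 0:max_dist)
  rings[[1]] <- start
  for (d in seq_len(max_dist)) {
    prev <- rings[[d]]
    if (!length(prev)) { rings[[d + 1L]] <- character(0); next }
    cand <- unique(unlist(lapply(prev, function(g) neighbors(scheme, g))))
    cand <- cand[cand %in% active]
    cand <- cand[hamming_distance(cand, start) == d]
    rings[[d + 1L]] <- sort(cand)
  }
  rings
}

#' Distance-activity profile of the library
#'
#' Bins every genotype in the activity table by Hamming distance from a
#' reference genotype (typically the ancestral sequence) and reports the
#' count and mean activity per distance — the summary behind the
#' "activity versus mutations from ancestral" decay curve.
#'
#' @param activity Activity carrier (see [build_network()]).
#' @param scheme A \code{"variant_scheme"}.
#' @param reference Reference genotype (default: ancestral).
#' @return A \code{"distance_profile"} data.frame: \code{distance},
#'   \code{n}, \code{mean_activity}; attribute \code{activities} holds the
#'   per-distance activity lists.
#' @export
distance_activity_profile <- function(activity, scheme,
                                      reference = ancestral_genotype(scheme)) {
  validate_genotype(scheme, reference)
  av <- activity_vector(activity)
  d <- hamming_distance(names(av), reference)
  dists <- 0:max(d)
  n <- as.integer(table(factor(d, levels = dists)))
  mean_activity <- vapply(dists, function(k) mean(av[d == k], na.rm = TRUE),
                          numeric(1))
  out <- data.frame(distance = dists, n = n, mean_activity = mean_activity)
  attr(out, "activities") <- split(unname(av), d)
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Count genotypes below an activity cutoff
#'
#' Strict-inequality count of genotypes with activity < \code{cutoff}
#' (\code{NA} activities are not counted).
#'
#' @param activity Activity carrier (see [build_network()]).
#' @param cutoff Cutoff (default 0.2, the "essentially inactive" bound).
#' @return Integer count.
#' @export
count_below <- function(activity, cutoff = 0.2) {
  av <- activity_vector(activity)
  sum(av < cutoff, na.rm = TRUE)
}

#' Per-group activity summaries
#'
#' Summarizes node activity assignments by user-supplied group labels
#' (e.g. taxonomic clades): per group, the number of nodes with an
#' activity, the mean and the median.
#'
#' @param assignments A \code{"node_activity"} data.frame (from
#'   [assign_node_activity()]).
#' @param grouping Named character vector mapping node id to group label.
#'   Every name must be a node of \code{assignments}; unknown node keys are
#'   an error.
#' @return data.frame: \code{group}, \code{n}, \code{mean_activity},
#'   \code{median_activity}.
#' @export
group_summary <- function(assignments, grouping) {
  stopifnot(is.data.frame(assignments), !is.null(names(grouping)))
  unknown <- setdiff(names(grouping), assignments$node)
  if (length(unknown))
    stop("unknown node key(s) in grouping: ", paste(unknown, collapse = ", "))
  act <- stats::setNames(assignments$activity, assignments$node)[names(grouping)]
  groups <- sort(unique(unname(grouping)))
  do.call(rbind, lapply(groups, function(g) {
    a <- act[grouping == g]
    a <- a[!is.na(a)]
    data.frame(group = g, n = length(a),
               mean_activity = if (length(a)) mean(a) else NA_real_,
               median_activity = if (length(a)) stats::median(a) else NA_real_)
  }))
}

#' Write a distance profile as TSV
#' @param profile A \code{"distance_profile"}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
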
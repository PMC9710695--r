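## Evaluation metrics: alignment pair scores, Rand index for orthology
## partitions, and prediction precision/recall against a reference CDS set.

#' Aligned nucleotide pairs of a multiple alignment
#'
#' Extracts the set of aligned position pairs ((id1, pos1), (id2, pos2)) from
#' every column where both rows are non-gap, with id1 < id2.
#'
#' @param msa A \code{\link{multiple_alignment}}.
#' @return Character vector of canonical pair keys.
#' @export
msa_pair_set <- function(msa) {
  ids <- names(msa)
  chars <- lapply(as.character(msa), function(r) strsplit(r, "")[[1]])
  pos <- lapply(chars, function(ch) cumsum(ch != "-"))
  out <- character(0)
  n <- length(ids)
  if (n < 2L || length(chars[[1]]) == 0L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- chars[[i]] != "-" & chars[[j]] != "-"
    if (!any(both)) next
    a <- ids[i]; b <- ids[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp
      pa <- pos[[j]][both]; pb <- pos[[i]][both]
    } else { pa <- pos[[i]][both]; pb <- pos[[j]][both] }
    out <- c(out, sprintf("%s:%d|%s:%d", a, pa, b, pb))
  }
  out
}

#' Precision, recall and F-score of an estimated alignment
#'
#' Precision is the fraction of aligned nucleotide pairs of the estimated
#' alignment also present in the true alignment; recall the converse; the
#' F-score their harmonic mean. Conventions: an estimate with no pairs has
#' precision 1; F is 0 when precision and recall are both 0.
#'
#' @param estimated,truth \code{\link{multiple_alignment}}s over the same
#'   sequences (rows must ungap identically).
#' @return Named numeric vector \code{c(precision, recall, fscore)}.
#' @export
msa_scores <- function(estimated, truth) {
  if (!setequal(names(estimated), names(truth)))
    stop("alignments cover different sequence sets")
  for (nm in names(estimated))
    if (!identical(ungap(estimated[[nm]]), ungap(truth[[nm]])))
      stop("row ", nm, " ungaps differently in the two alignments")
  E <- msa_pair_set(estimated)
  T_ <- msa_pair_set(truth)
  inter <- length(intersect(E, T_))
  precision <- if (length(E) == 0L) 1 else inter / length(E)
  recall <- if (length(T_) == 0L) 1 else inter / length(T_)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, fscore = f)
}

#' Rand index of two partitions
#'
#' The fraction of element pairs on which two partitions agree (placed
#' together in both, or apart in both). Partitions with fewer than two
#' elements score 1.
#'
#' @param estimated,truth Partitions of the same element set, each a list of
#'   character vectors.
#' @return Numeric scalar in \code{[0,1]}.
#' @export
rand_index <- function(estimated, truth) {
  els <- sort(unlist(estimated))
  if (!identical(els, sort(unlist(truth))))
    stop("partitions cover different element sets")
  if (anyDuplicated(els)) stop("partitions must be disjoint")
  n <- length(els)
  if (n < 2L) return(1)
  lab <- function(p) {
    l <- rep(seq_along(p), lengths(p))
    names(l) <- unlist(p)
    l[els]
  }
  a <- lab(estimated); b <- lab(truth)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  agree_same <- sum(ch2(tab))
  total <- ch2(n)
  suma <- sum(ch2(rowSums(tab))); sumb <- sum(ch2(colSums(tab)))
  (total + 2 * agree_same - suma - sumb) / total
}

#' Precision, recall and F-score of predicted CDS sets
#'
#' Compares a predicted CDS sequence set P against a reference set T under
#' one of two matching rules: \code{strict100} (exact sequence identity) or
#' \code{rbh90} (global-alignment PID above 0.9 and reciprocal best hits,
#' PID ties broken by lexicographic id). Precision is the fraction of P with
#' a match, recall the fraction of T with a match.
#'
#' @param predicted,truth Named character vectors of CDS sequences.
#' @param mode \code{"strict100"} or \code{"rbh90"}.
#' @return Named numeric vector \code{c(precision, recall, fscore)}.
#' @export
prediction_scores <- function(predicted, truth, mode = c("strict100", "rbh90")) {
  mode <- match.arg(mode)
  if (length(predicted) == 0L || length(truth) == 0L) {
    precision <- if (length(predicted) == 0L) 1 else 0
    recall <- if (length(truth) == 0L) 1 else 0
  } else if (mode == "strict100") {
    precision <- mean(predicted %in% truth)
    recall <- mean(truth %in% predicted)
  } else {
    if (is.null(names(predicted))) names(predicted) <- paste0("p", seq_along(predicted))
    if (is.null(names(truth))) names(truth) <- paste0("t", seq_along(truth))
    pidm <- outer(seq_along(predicted), seq_along(truth),
                  Vectorize(function(i, j) global_pid(predicted[[i]], truth[[j]])))
    best_t <- apply(pidm, 1, function(r) order(-r, names(truth))[1])
    best_p <- apply(pidm, 2, function(cl) order(-cl, names(predicted))[1])
    matched_p <- vapply(seq_along(predicted), function(i) {
      j <- best_t[i]
      best_p[j] == i && pidm[i, j] > 0.9
    }, TRUE)
    matched_t <- vapply(seq_along(truth), function(j) {
      i <- best_p[j]
      best_t[i] == j && pidm[i, j] > 0.9
    }, TRUE)
    precision <- mean(matched_p)
    recall <- mean(matched_t)
  }
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, fscore = f)
}
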
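# Center-offset evaluation: the quality of a prediction is the Euclidean
# distance between a predicted pocket center and the actual site center (the
# ligand's geometric mean).  Top-N evaluation keeps the N highest-scoring
# pockets and reports the one closest to the actual site; the looser hit
# criterion accepts a pocket center within 4 A of any ligand atom.

#' Center-to-center offset
#'
#' @param predicted,actual length-3 coordinate vectors, Angstrom.
#' @return Euclidean distance, Angstrom.
#' @export
offset <- function(predicted, actual) {
  sqrt(sum((as.numeric(predicted) - as.numeric(actual))^2))
}

#' Best offset among the top-n pockets
#'
#' @param pockets ranked `pocket_predictions` data.frame.
#' @param actual actual site center.
#' @param n number of top pockets considered.
#' @return minimum offset over the first `n` pockets; `Inf` when there are
#'   no pockets (no prediction).
#' @export
topN_offset <- function(pockets, actual, n) {
  sel <- top_n(pockets, n)
  if (nrow(sel) == 0) return(Inf)
  min(vapply(seq_len(nrow(sel)),
             function(i) offset(c(sel$x[i], sel$y[i], sel$z[i]), actual),
             numeric(1)))
}

#' Hit criterion: pocket center within a radius of any ligand atom
#'
#' @param pockets evaluated pockets (pre-select with [top_n()] as desired).
#' @param ligand a `ligand_structure`.
#' @param radius hit radius in Angstrom (default 4).
#' @return TRUE if any pocket center lies within `radius` of any ligand
#'   atom.
#' @export
hit_within <- function(pockets, ligand, radius = 4) {
  if (is.null(ligand$atoms) || nrow(ligand$atoms) == 0)
    stop("empty ligand", call. = FALSE)
  if (nrow(pockets) == 0) return(FALSE)
  lx <- as.matrix(ligand$atoms[c("x", "y", "z")])
  for (i in seq_len(nrow(pockets))) {
    d2 <- (lx[, 1] - pockets$x[i])^2 + (lx[, 2] - pockets$y[i])^2 +
      (lx[, 3] - pockets$z[i])^2
    if (any(d2 <= radius^2)) return(TRUE)
  }
  FALSE
}

#' Evaluate one protein's predictions
#'
#' @param id protein identifier.
#' @param pockets ranked `pocket_predictions`.
#' @param actual_center actual site center.
#' @param ligand optional `ligand_structure` for the 4 A hit criterion
#'   (evaluated over the top-3 pockets).
#' @return list of class `evaluation_record` with `offset_top1/3/5` and
#'   `hit_4A`.
#' @export
evaluate_protein <- function(id, pockets, actual_center, ligand = NULL) {
  rec <- list(id = id, actual_center = as.numeric(actual_center),
              pockets = pockets,
              n_pockets = nrow(pockets),
              offset_top1 = topN_offset(pockets, actual_center, 1),
              offset_top3 = topN_offset(pockets, actual_center, 3),
              offset_top5 = topN_offset(pockets, actual_center, 5),
              hit_4A = if (is.null(ligand)) NA else
                hit_within(top_n(pockets, 3), ligand))
  structure(rec, class = "evaluation_record")
}

#' Summarize evaluation records
#'
#' Reports the distribution of offsets over the given bins, the error sum
#' (sum of offsets), the mean offset and the mean pocket count.  Proteins
#' with no prediction (infinite offset) are counted separately and excluded
#' from the offset statistics.
#'
#' @param records list of `evaluation_record`s.
#' @param bin_edges increasing bin edges in Angstrom for the offset
#'   histogram.
#' @param which which Top-N offset to summarize ("offset_top3" by default).
#' @return list with `proportions` (named by bin), `error_sum`,
#'   `mean_offset`, `mean_n_pockets`, `n`, `n_no_prediction`, `hit_rate`.
#' @export
summarize_records <- function(records, bin_edges = c(0, 2, 4, 6, 8, 10, Inf),
                              which = "offset_top3") {
  if (length(records) == 0) stop("no records", call. = FALSE)
  offs <- vapply(records, function(r) r[[which]], numeric(1))
  npk <- vapply(records, function(r) r$n_pockets, numeric(1))
  hits <- vapply(records, function(r) as.logical(r$hit_4A), logical(1))
  none <- !is.finite(offs)
  offs_f <- offs[!none]
  bins <- cut(offs_f, bin_edges, right = FALSE)
  prop <- if (length(offs_f)) as.numeric(table(bins)) / length(offs_f) else
    rep(NA_real_, length(bin_edges) - 1)
  list(proportions = setNames(prop, levels(bins)),
       error_sum = sum(offs_f),
       mean_offset = if (length(offs_f)) mean(offs_f) else NA_real_,
       mean_n_pockets = mean(npk),
       n = length(records),
       n_no_prediction = sum(none),
       hit_rate = if (all(is.na(hits))) NA_real_ else mean(hits, na.rm = TRUE))
}
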
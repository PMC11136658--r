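# Substrate scoring: product of per-position selectivities, percentile
# ranking against a reference phosphoproteome, promiscuity annotation.

# Round to 4 decimal places, half away from zero (spreadsheet-style).
round_half_away <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Map flank characters to specificity-matrix row names.  Uppercase
# letters index their own row (Tyr uses the Tyr row, which equals Phe by
# construction); lowercase "t" and "y" index the phospho rows; lowercase
# "s" is scored with the pThr row by default (kinases that select pThr
# select pSer similarly); "_" padding maps to NA and contributes a
# neutral factor.
.flank_rows <- function(flank, phospho_ser_as_pthr = TRUE) {
  ch <- strsplit(flank, "")[[1]][-6L]   # drop central phosphoacceptor
  rows <- ch
  rows[ch == "t"] <- "t"
  rows[ch == "y"] <- "y"
  rows[ch == "s"] <- if (phospho_ser_as_pthr) "t" else "S"
  rows[ch == "_"] <- NA_character_
  bad <- !is.na(rows) & !rows %in% AA_FIXED
  if (any(bad)) {
    stop("unknown flank character '", ch[bad][1L], "'")
  }
  rows
}

# Per-kinase rounded selectivity matrix used by the product score.
.rounded_selectivity <- function(pssm) {
  round_half_away(selectivity(pssm), 4L)
}

#' Raw substrate score of a phosphosite for one kinase
#'
#' Each non-central, non-padding flank residue contributes its selectivity
#' (PSSM value scaled by the background size, so the mean randomized
#' residue scores 1) at that position.  Selectivities are rounded to the
#' nearest 1/10,000th and multiplied to give the raw score.
#'
#' @param pssm A [pssm()] object.
#' @param flank 11-character flanking sequence, central "Y"/"y".
#' @param phospho_ser_as_pthr Score lowercase "s" with the pThr row
#'   (default) rather than the plain Ser row.
#' @return Positive raw score (product over positions).
#' @export
score_site <- function(pssm, flank, phospho_ser_as_pthr = TRUE) {
  err <- validate_flank(flank)
  if (!is.null(err)) stop(err)
  rows <- .flank_rows(flank, phospho_ser_as_pthr)
  sel <- .rounded_selectivity(pssm)
  keep <- !is.na(rows)
  if (!any(keep)) return(1)
  prod(sel[cbind(rows[keep], .position_labels()[keep])])
}

#' Additive log2 substrate score
#'
#' Sum over flank positions of log2 selectivity (unrounded); a substrate
#' preferred over the random background scores positive, one selected
#' against scores negative.
#'
#' @inheritParams score_site
#' @return Log2 score (real).
#' @export
log2_score <- function(pssm, flank, phospho_ser_as_pthr = TRUE) {
  err <- validate_flank(flank)
  if (!is.null(err)) stop(err)
  rows <- .flank_rows(flank, phospho_ser_as_pthr)
  sel <- selectivity(pssm)
  keep <- !is.na(rows)
  if (!any(keep)) return(0)
  sum(log2(sel[cbind(rows[keep], .position_labels()[keep])]))
}

#' Score many sites against many kinases
#'
#' @param pssms Named list of [pssm()] objects.
#' @param flanks Character vector of 11-mer flanks.
#' @param type "raw" (rounded product score) or "log2" (unrounded sum).
#' @param phospho_ser_as_pthr See [score_site()].
#' @return Numeric matrix, sites (rows) by kinases (columns).
#' @export
score_matrix <- function(pssms, flanks, type = c("raw", "log2"),
                         phospho_ser_as_pthr = TRUE) {
  type <- match.arg(type)
  for (f in flanks) {
    err <- validate_flank(f)
    if (!is.null(err)) stop(err)
  }
  labs <- .position_labels()
  row_idx <- t(vapply(flanks, function(f)
    match(.flank_rows(f, phospho_ser_as_pthr), AA_FIXED),
    integer(10L)))
  out <- matrix(NA_real_, nrow = length(flanks), ncol = length(pssms),
                dimnames = list(names(flanks), names(pssms)))
  for (k in seq_along(pssms)) {
    m <- if (type == "raw") .rounded_selectivity(pssms[[k]])
         else log2(selectivity(pssms[[k]]))
    m <- m[, labs, drop = FALSE]
    # gather per-position factors; padding (NA row index) is neutral
    acc <- if (type == "raw") rep(1, length(flanks)) else rep(0, length(flanks))
    for (p in seq_len(10L)) {
      idx <- row_idx[, p]
      ok <- !is.na(idx)
      v <- m[idx[ok], p]
      if (type == "raw") acc[ok] <- acc[ok] * v else acc[ok] <- acc[ok] + v
    }
    out[, k] <- acc
  }
  out
}

#' Reference score distribution for a kinase
#'
#' Scores a reference Tyr phosphoproteome with the kinase PSSM and stores
#' the sorted raw scores; percentile scores of new substrates are read off
#' this distribution.
#'
#' @param pssm A [pssm()] object.
#' @param flanks Character vector of reference flanks (non-empty).
#' @param phospho_ser_as_pthr See [score_site()].
#' @return Object of class `score_reference` with fields `kinase_id`,
#'   `sorted_scores`.
#' @export
build_reference <- function(pssm, flanks, phospho_ser_as_pthr = TRUE) {
  if (!length(flanks)) stop("reference site list is empty")
  s <- score_matrix(list(k = pssm), flanks,
                    phospho_ser_as_pthr = phospho_ser_as_pthr)[, 1L]
  structure(list(kinase_id = pssm$kinase_id,
                 sorted_scores = sort(unname(s))),
            class = "score_reference")
}

#' Percentile of a raw score within a reference distribution
#'
#' Defined as `100 * #(reference scores <= score) / N`; monotone
#' non-decreasing in the score, 100 at or above the reference maximum, 0
#' strictly below the minimum.
#'
#' @param ref A [build_reference()] object (or sorted numeric vector).
#' @param score Numeric vector of raw scores.
#' @return Percentiles in \[0, 100\].
#' @export
percentile_score <- function(ref, score) {
  scores <- if (inherits(ref, "score_reference")) ref$sorted_scores else
    sort(as.numeric(ref))
  if (!length(scores)) stop("empty reference distribution")
  100 * findInterval(score, scores) / length(scores)
}

#' Rank kinases for one substrate
#'
#' Orders kinases by descending percentile, breaking ties by descending
#' raw score and then lexicographic kinase id so output is deterministic.
#'
#' @param percentiles Named numeric vector (one per kinase).
#' @param raw_scores Named numeric vector aligned with `percentiles`.
#' @return Character vector of kinase ids, best first.
#' @export
rank_kinases <- function(percentiles, raw_scores = NULL) {
  ids <- names(percentiles)
  if (is.null(ids)) stop("percentiles must be named by kinase")
  if (is.null(raw_scores)) raw_scores <- stats::setNames(rep(0, length(ids)), ids)
  ord <- order(-percentiles, -raw_scores[ids], ids)
  ids[ord]
}

#' Full score report for a site set against a kinase set
#'
#' @param pssms Named list of [pssm()] objects.
#' @param refs Named list of [build_reference()] objects aligned with
#'   `pssms` (same kinase ids).
#' @param sites Site table (`site_id`, `flank`).
#' @param phospho_ser_as_pthr See [score_site()].
#' @return List with `long` (data frame: site_id, kinase_id, raw_score,
#'   log2_score, percentile, rank) and `percentiles` / `raw` matrices
#'   (sites x kinases).
#' @export
score_report <- function(pssms, refs, sites, phospho_ser_as_pthr = TRUE) {
  ids <- names(pssms)
  if (!setequal(ids, names(refs))) {
    stop("pssms and refs must cover the same kinase ids")
  }
  refs <- refs[ids]
  raw <- score_matrix(pssms, sites$flank,
                      phospho_ser_as_pthr = phospho_ser_as_pthr)
  lg <- score_matrix(pssms, sites$flank, type = "log2",
                     phospho_ser_as_pthr = phospho_ser_as_pthr)
  perc <- raw
  for (k in ids) perc[, k] <- percentile_score(refs[[k]], raw[, k])
  rank_m <- raw
  for (i in seq_len(nrow(raw))) {
    ord <- rank_kinases(stats::setNames(perc[i, ], ids),
                        stats::setNames(raw[i, ], ids))
    rank_m[i, ] <- match(ids, ord)
  }
  rownames(raw) <- rownames(lg) <- rownames(perc) <- rownames(rank_m) <-
    sites$site_id
  long <- data.frame(
    site_id = rep(sites$site_id, times = length(ids)),
    kinase_id = rep(ids, each = nrow(sites)),
    raw_score = as.vector(raw),
    log2_score = as.vector(lg),
    percentile = as.vector(perc),
    rank = as.integer(as.vector(rank_m)),
    stringsAsFactors = FALSE)
  long <- long[order(long$kinase_id, long$site_id), ]
  rownames(long) <- NULL
  list(long = long, raw = raw, log2 = lg, percentiles = perc, rank = rank_m)
}

#' Promiscuity index and substrate category per site
#'
#' The promiscuity index of a site is the number of kinases scoring it in
#' their 90th percentile or better.  Sites split into three classes:
#' "broad" (favourable to six or more kinases), "exclusive" (one to
#' five), and "suboptimal" (none).
#'
#' @param percentiles Sites x kinases percentile matrix (e.g. from
#'   [score_report()]).
#' @param threshold Percentile cut-off (default 90).
#' @param broad_min Minimum index for the broad class (default 6).
#' @return Data frame: `site_id`, `promiscuity_index`, `category`.
#' @export
categorize_sites <- function(percentiles, threshold = 90, broad_min = 6L) {
  idx <- rowSums(percentiles >= threshold)
  category <- ifelse(idx >= broad_min, "broad",
                     ifelse(idx >= 1L, "exclusive", "suboptimal"))
  data.frame(site_id = rownames(percentiles) %||% seq_along(idx),
             promiscuity_index = as.integer(idx),
             category = factor(category,
                               levels = c("broad", "exclusive", "suboptimal")),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
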
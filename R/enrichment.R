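# Kinase-activity inference from differential phosphoproteomics: partition
# sites by fold change, mark the top-k biochemically favoured kinases per
# site, and test favoured-site over-representation with a one-sided
# hypergeometric (Fisher) test per kinase and direction.

#' Partition a differential site table by log2 fold change
#'
#' @param sites Site table with `site_id`, `flank`, `log2fc` columns.
#' @param fc_threshold Positive threshold on |log2 fold change|
#'   (default 1): sites at or above it are upregulated, at or below its
#'   negative downregulated, the rest unchanged.
#' @param strict_single_phospho Drop multiply phosphorylated flanks.
#' @return The deduplicated table with an added `regulation` factor
#'   (levels up/down/unchanged).
#' @export
partition_by_fc <- function(sites, fc_threshold = 1,
                            strict_single_phospho = FALSE) {
  stopifnot(fc_threshold > 0)
  if (!"log2fc" %in% names(sites)) stop("sites must have a log2fc column")
  sites <- as_site_table(sites, strict_single_phospho = strict_single_phospho)
  reg <- ifelse(sites$log2fc >= fc_threshold, "up",
                ifelse(sites$log2fc <= -fc_threshold, "down", "unchanged"))
  sites$regulation <- factor(reg, levels = c("up", "down", "unchanged"))
  sites
}

#' Biochemically favoured kinases per site
#'
#' A kinase is favoured for a site when it ranks within the top `k`
#' kinases for that site (percentile rank with deterministic tie-break).
#'
#' @param pssms,refs Named lists of PSSMs and matching reference
#'   distributions.
#' @param flanks Character vector of site flanks.
#' @param k Number of top-ranked kinases considered favoured (default 8).
#' @return Logical matrix sites x kinases; TRUE marks a favoured kinase.
#' @export
favoured_kinases <- function(pssms, refs, flanks, k = 8L) {
  ids <- names(pssms)
  if (k > length(ids)) stop("k exceeds the number of kinases")
  raw <- score_matrix(pssms, flanks)
  perc <- raw
  for (kk in ids) perc[, kk] <- percentile_score(refs[[kk]], raw[, kk])
  fav <- matrix(FALSE, nrow = length(flanks), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (i in seq_len(length(flanks))) {
    top <- rank_kinases(stats::setNames(perc[i, ], ids),
                        stats::setNames(raw[i, ], ids))[seq_len(k)]
    fav[i, top] <- TRUE
  }
  fav
}

# One-sided p for over-representation of favoured sites among regulated
# sites, for fixed margins (Fisher's exact test, alternative "greater").
# a = favoured & regulated, table rows favoured/not, columns
# regulated/unchanged.
fisher_p_greater <- function(a, n_reg, n_fav, n_total) {
  stats::phyper(a - 1L, n_fav, n_total - n_fav, n_reg, lower.tail = FALSE)
}

# Frequency factor: favoured fraction among regulated over favoured
# fraction among unchanged.  When any cell of the 2x2 table is zero the
# Haldane correction adds 0.5 to the favoured counts and their margins,
# so each fraction becomes (a + 0.5) / (n + 0.5); without zeros the
# plain fractions are used.
frequency_factor <- function(a, b, c, d) {
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    ff <- ((a + 0.5) / (a + b + 0.5)) / ((c + 0.5) / (c + d + 0.5))
  } else {
    ff <- (a / (a + b)) / (c / (c + d))
  }
  list(ff = ff, haldane = haldane)
}

#' Kinase enrichment analysis of a differential phosphoproteomics dataset
#'
#' For each kinase and each direction (up, down), builds the 2x2 table of
#' favoured-vs-not against regulated-vs-unchanged sites and computes a
#' one-sided Fisher's exact p-value for over-representation of favoured
#' sites among the regulated set.  Frequency factors are reported from the
#' Haldane-corrected table when any cell is zero (the exact test itself is
#' computed on the integer counts).  Kinases significant in both
#' directions are flagged `excluded_dual` and dropped from the volcano
#' table; otherwise each kinase is reported in its more significant
#' direction.
#'
#' @param sites Output of [partition_by_fc()] (or a table with a
#'   `regulation` column).
#' @param pssms,refs Named lists of PSSMs and reference distributions.
#' @param k Top-k favoured-kinase cut-off (default 8).
#' @param alpha Significance level for the dual-direction exclusion
#'   (default 0.05).
#' @param favoured Optional precomputed sites x kinases logical matrix
#'   from [favoured_kinases()]; the favoured set depends only on the
#'   flanks, so it can be reused across fold-change permutations.
#' @return Data frame, one row per kinase: counts, frequency factor,
#'   p-values per direction, selected `direction`, `p_value`,
#'   `log2_ff`, `excluded_dual`, `haldane_applied`.
#' @export
kinase_enrichment <- function(sites, pssms, refs, k = 8L, alpha = 0.05,
                              favoured = NULL) {
  if (!"regulation" %in% names(sites)) {
    stop("sites must carry a 'regulation' column; see partition_by_fc()")
  }
  n_unch <- sum(sites$regulation == "unchanged")
  if (n_unch == 0L) stop("no unchanged sites: enrichment has no background")
  n_up <- sum(sites$regulation == "up")
  n_dn <- sum(sites$regulation == "down")
  if (n_up + n_dn == 0L) {
    warning("no regulated sites; returning empty result")
    return(data.frame())
  }
  fav <- if (is.null(favoured)) {
    favoured_kinases(pssms, refs, sites$flank, k = k)
  } else {
    stopifnot(nrow(favoured) == nrow(sites))
    favoured
  }
  ids <- colnames(fav)
  res <- lapply(ids, function(kid) {
    f <- fav[, kid]
    fav_unch <- sum(f & sites$regulation == "unchanged")
    one_dir <- function(dir) {
      in_reg <- sites$regulation == dir
      a <- sum(f & in_reg)            # favoured, regulated
      b <- sum(in_reg) - a            # not favoured, regulated
      c <- fav_unch                   # favoured, unchanged
      d <- n_unch - fav_unch
      p <- fisher_p_greater(a, a + b, a + c, a + b + c + d)
      ffh <- frequency_factor(a, b, c, d)
      list(a = a, b = b, c = c, d = d, p = p,
           ff = ffh$ff, haldane = ffh$haldane)
    }
    up <- one_dir("up")
    dn <- one_dir("down")
    excl <- (up$p <= alpha) && (dn$p <= alpha)
    pick <- if (up$p <= dn$p) "up" else "down"
    sel <- if (pick == "up") up else dn
    data.frame(kinase_id = kid,
               fav_up = up$a, notfav_up = up$b,
               fav_down = dn$a, notfav_down = dn$b,
               fav_unchanged = fav_unch,
               notfav_unchanged = n_unch - fav_unch,
               p_up = up$p, p_down = dn$p,
               ff_up = up$ff, ff_down = dn$ff,
               direction = pick,
               p_value = sel$p,
               frequency_factor = sel$ff,
               log2_ff = log2(sel$ff),
               haldane_applied = sel$haldane,
               excluded_dual = excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$kinase_id), ]
  rownames(out) <- NULL
  out
}

#' Volcano-plot table from enrichment results
#'
#' One row per non-excluded kinase with signed x (log2 frequency factor,
#' negative for downregulated motifs) and y (-log10 p).
#'
#' @param results Output of [kinase_enrichment()] (or
#'   [sh2_enrichment()]; an `p_adj` column is carried through and used
#'   for y when present).
#' @return Data frame: `id`, `x`, `y`, `direction`.
#' @export
volcano_table <- function(results) {
  if (!nrow(results)) return(data.frame())
  res <- results[!results$excluded_dual, , drop = FALSE]
  id_col <- intersect(c("kinase_id", "sh2_id"), names(res))[1L]
  p <- if ("p_adj" %in% names(res)) res$p_adj else res$p_value
  dir_sign <- ifelse(res$direction %in% c("up", "favoured"), 1, -1)
  out <- data.frame(id = res[[id_col]],
                    x = dir_sign * res$log2_ff,
                    y = -log10(p),
                    direction = res$direction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  out
}
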
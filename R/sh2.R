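# SH2-domain binding specificity: matrix processing and enrichment of SH2
# motifs within kinase-motif-defined slices of the phosphoproteome.

#' Normalize a raw SH2-domain binding matrix
#'
#' SH2 binding arrays randomize 19 natural amino acids (no Cys) at each
#' position and read out mostly C-terminal to the central pTyr.  Zero
#' values are replaced with the minimal value at that position, columns
#' are normalized by the sum over the 19 non-Cys residues, and a neutral
#' Cys row fixed at 1/19 is added (Cys is absent from the raw data).
#'
#' @param sh2_id Domain identifier (e.g. "GRB2" or "PIK3R1_N").
#' @param intensities Non-negative matrix: rows are natural amino acids
#'   (Cys optional and ignored), columns position labels such as
#'   "-2".."5" (any contiguous window; 0 excluded).
#' @return Object of class `sh2_pssm` with `values` (20 rows including
#'   the neutral Cys row) and `background_size = 19`.
#' @export
normalize_sh2 <- function(sh2_id, intensities) {
  m <- as.matrix(intensities)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("SH2 matrix must have residue row names")
  colnames(m) <- sub("^\\+", "", colnames(m))
  res19 <- setdiff(AA_NATURAL, "C")
  missing <- setdiff(res19, rownames(m))
  if (length(missing)) {
    stop("SH2 matrix is missing residue rows: ",
         paste(missing, collapse = ", "))
  }
  m <- m[res19, , drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("SH2 intensities must be finite and non-negative")
  }
  if (any(colSums(m) <= 0)) {
    bad <- colnames(m)[colSums(m) <= 0][1L]
    stop("all-zero SH2 column at position ", bad)
  }
  for (j in seq_len(ncol(m))) {
    zero <- m[, j] == 0
    if (any(zero)) m[zero, j] <- min(m[!zero, j])
  }
  m <- sweep(m, 2L, colSums(m), "/")
  full <- rbind(m, C = rep(1 / 19, ncol(m)))
  full <- full[intersect(AA_NATURAL, rownames(full)), , drop = FALSE]
  structure(list(sh2_id = as.character(sh2_id), values = full,
                 background_size = 19L),
            class = "sh2_pssm")
}

#' @export
print.sh2_pssm <- function(x, ...) {
  cat("SH2 binding PSSM for", x$sh2_id, "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Read an SH2 binding matrix from a delimited file
#'
#' Same dialect as [read_pssm()] but with natural-residue rows only and an
#' arbitrary (typically C-terminal-biased) position window.
#'
#' @param path File path.
#' @param sh2_id Identifier; defaults to file base name.
#' @param raw If TRUE, run [normalize_sh2()] on the values; if FALSE the
#'   file already holds normalized values (the Cys row is still forced to
#'   1/19 if absent).
#' @return `sh2_pssm` object.
#' @export
read_sh2 <- function(path, sh2_id = NULL, raw = TRUE) {
  if (is.null(sh2_id)) sh2_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = 1L,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (raw) return(normalize_sh2(sh2_id, m))
  if (!"C" %in% rownames(m)) m <- rbind(m, C = rep(1 / 19, ncol(m)))
  colnames(m) <- sub("^\\+", "", colnames(m))
  structure(list(sh2_id = sh2_id,
                 values = m[intersect(AA_NATURAL, rownames(m)), , drop = FALSE],
                 background_size = 19L),
            class = "sh2_pssm")
}

# Product score of flanks against one SH2 PSSM: same rounded-selectivity
# kernel as kinase scoring, restricted to the positions present in the
# matrix; absent positions and padding contribute factor 1.  Phospho
# characters in the flank are scored as their unmodified residues (SH2
# arrays carry no phospho rows besides the central pTyr).
sh2_score_matrix <- function(sh2s, flanks) {
  for (f in flanks) {
    err <- validate_flank(f)
    if (!is.null(err)) stop(err)
  }
  chars <- t(vapply(flanks, function(f) strsplit(f, "")[[1]][-6L],
                    character(10L)))
  chars[chars == "s"] <- "S"; chars[chars == "t"] <- "T"
  chars[chars == "y"] <- "Y"
  out <- matrix(NA_real_, nrow = length(flanks), ncol = length(sh2s),
                dimnames = list(NULL, names(sh2s)))
  all_labs <- .position_labels()
  for (k in seq_along(sh2s)) {
    sel <- round_half_away(sh2s[[k]]$values * sh2s[[k]]$background_size, 4L)
    acc <- rep(1, length(flanks))
    for (p in which(all_labs %in% colnames(sel))) {
      idx <- match(chars[, p], rownames(sel))
      ok <- !is.na(idx) & chars[, p] != "_"
      acc[ok] <- acc[ok] * sel[idx[ok], all_labs[p]]
    }
    out[, k] <- acc
  }
  out
}

#' Split a scored phosphoproteome into favoured/neutral/disfavoured slices
#'
#' Sites are ordered by their raw score for one kinase (ties broken by
#' site id); the top 20% are favoured, the bottom 20% disfavoured, and the
#' middle 60% neutral.
#'
#' @param scores Numeric vector of raw kinase scores.
#' @param site_ids Character vector aligned with `scores`.
#' @param lower,upper Tertile fractions (defaults 0.2 / 0.2).
#' @return Factor (levels favoured/neutral/disfavoured) aligned with input.
#' @export
score_tertiles <- function(scores, site_ids, lower = 0.2, upper = 0.2) {
  n <- length(scores)
  if (n < 5L) stop("too few sites to form tertiles")
  if (max(scores) == min(scores)) {
    stop("degenerate tertiles: all sites have identical scores")
  }
  ord <- order(-scores, site_ids)
  n_fav <- floor(upper * n)
  n_dis <- floor(lower * n)
  if (n_fav == 0L || n_dis == 0L) stop("empty tertile")
  lab <- rep("neutral", n)
  lab[ord[seq_len(n_fav)]] <- "favoured"
  lab[ord[seq.int(n - n_dis + 1L, n)]] <- "disfavoured"
  factor(lab, levels = c("favoured", "neutral", "disfavoured"))
}

#' SH2-motif enrichment within kinase-defined slices of the phosphoproteome
#'
#' Scores the phosphoproteome with a kinase PSSM, splits it into favoured
#' (top 20%), neutral (middle 60%) and disfavoured (bottom 20%) slices,
#' marks the top-`k` SH2 domains per site as biochemically favoured
#' binders (percentile-ranked within the scored proteome itself), and
#' tests favoured-binder over-representation in the favoured and
#' disfavoured slices against the neutral background with one-sided
#' Fisher's exact tests.  P-values are Benjamini-Hochberg adjusted across
#' SH2 domains within each direction and each domain is reported in its
#' more significant direction.
#'
#' @param kinase A [pssm()] object conditioning the analysis.
#' @param sh2s Named list of `sh2_pssm` objects (length >= `k`).
#' @param sites Site table of the phosphoproteome.
#' @param k Top-k favoured SH2 cut-off (default 8).
#' @param sh2_alias Named character vector mapping absent domains to the
#'   matrix of another (e.g. `c(PIK3R3_C = "PIK3R2_C")`).
#' @return Data frame, one row per SH2 domain, mirroring
#'   [kinase_enrichment()] with an extra `p_adj` column.
#' @export
sh2_enrichment <- function(kinase, sh2s, sites, k = 8L, sh2_alias = NULL) {
  if (length(sh2_alias)) {
    for (nm in names(sh2_alias)) {
      src <- sh2_alias[[nm]]
      if (!src %in% names(sh2s)) stop("alias source ", src, " not present")
      cloned <- sh2s[[src]]
      cloned$sh2_id <- nm
      sh2s[[nm]] <- cloned
    }
    sh2s <- sh2s[order(names(sh2s))]
  }
  if (length(sh2s) < k) stop("need at least k SH2 matrices")
  kin_scores <- score_matrix(list(k = kinase), sites$flank)[, 1L]
  slice <- score_tertiles(kin_scores, sites$site_id)
  n_neut <- sum(slice == "neutral")

  sh2_raw <- sh2_score_matrix(sh2s, sites$flank)
  sh2_perc <- sh2_raw
  for (d in colnames(sh2_raw)) {
    sh2_perc[, d] <- percentile_score(sort(sh2_raw[, d]), sh2_raw[, d])
  }
  ids <- colnames(sh2_raw)
  fav <- matrix(FALSE, nrow = nrow(sites), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (i in seq_len(nrow(sites))) {
    top <- rank_kinases(stats::setNames(sh2_perc[i, ], ids),
                        stats::setNames(sh2_raw[i, ], ids))[seq_len(k)]
    fav[i, top] <- TRUE
  }

  res <- lapply(ids, function(did) {
    f <- fav[, did]
    c_n <- sum(f & slice == "neutral")
    one_dir <- function(lab) {
      in_s <- slice == lab
      a <- sum(f & in_s); b <- sum(in_s) - a
      d <- n_neut - c_n
      p <- fisher_p_greater(a, a + b, a + c_n, a + b + c_n + d)
      ffh <- frequency_factor(a, b, c_n, d)
      list(a = a, b = b, p = p, ff = ffh$ff, haldane = ffh$haldane)
    }
    up <- one_dir("favoured")
    dn <- one_dir("disfavoured")
    data.frame(sh2_id = did,
               fav_favoured = up$a, fav_disfavoured = dn$a,
               fav_neutral = c_n, n_neutral = n_neut,
               p_fav = up$p, p_dis = dn$p,
               ff_fav = up$ff, ff_dis = dn$ff,
               haldane_fav = up$haldane, haldane_dis = dn$haldane,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj_fav <- stats::p.adjust(out$p_fav, method = "BH")
  out$p_adj_dis <- stats::p.adjust(out$p_dis, method = "BH")
  pick_fav <- out$p_adj_fav <= out$p_adj_dis
  out$direction <- ifelse(pick_fav, "favoured", "disfavoured")
  out$p_value <- ifelse(pick_fav, out$p_fav, out$p_dis)
  out$p_adj <- ifelse(pick_fav, out$p_adj_fav, out$p_adj_dis)
  out$frequency_factor <- ifelse(pick_fav, out$ff_fav, out$ff_dis)
  out$log2_ff <- log2(out$frequency_factor)
  out$haldane_applied <- ifelse(pick_fav, out$haldane_fav, out$haldane_dis)
  out$excluded_dual <- FALSE
  out <- out[order(out$sh2_id), ]
  rownames(out) <- NULL
  out
}
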
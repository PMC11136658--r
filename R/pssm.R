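#' Construct a raw PSPA intensity matrix
#'
#' Wraps quantified spot intensities from a positional scanning peptide
#' array for a single kinase: 22 fixed residues (20 natural amino acids
#' plus pThr "t" and pTyr "y") by 10 flanking positions (-5..-1, 1..5).
#'
#' @param kinase_id Kinase identifier.
#' @param intensities Numeric 22 x 10 matrix, rows named by `AA_FIXED`,
#'   columns by `PSPA_POSITIONS` labels. Rows/columns are reordered to the
#'   canonical order if named.
#' @param background_size 18 or 16 depending on the peptide library used.
#' @param dual_specificity Logical; TRUE for Ser/Thr kinases with
#'   convergent Tyr activity, which triggers the S/T median rule during
#'   normalization.
#' @return Object of class `raw_pspa`.
#' @export
raw_pspa <- function(kinase_id, intensities, background_size = 18L,
                     dual_specificity = FALSE) {
  intensities <- .canonical_matrix(intensities, AA_FIXED)
  if (any(!is.finite(intensities))) {
    stop("raw PSPA intensities must be finite")
  }
  if (any(intensities < 0)) {
    stop("raw PSPA intensities must be non-negative; found negative value for ",
         kinase_id)
  }
  if (any(colSums(intensities) <= 0)) {
    bad <- colnames(intensities)[colSums(intensities) <= 0][1L]
    stop("all-zero intensity column at position ", bad, " for ", kinase_id)
  }
  background_residues(background_size)  # validates background_size
  structure(
    list(kinase_id = as.character(kinase_id),
         intensities = intensities,
         background_size = as.integer(background_size),
         dual_specificity = isTRUE(dual_specificity)),
    class = "raw_pspa")
}

# Coerce a matrix to canonical row/column order and check its shape.
.canonical_matrix <- function(m, rows, pos = PSPA_POSITIONS) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  labs <- .position_labels(pos)
  if (!is.null(rownames(m))) {
    missing_rows <- setdiff(rows, rownames(m))
    if (length(missing_rows)) {
      stop("matrix is missing residue rows: ",
           paste(missing_rows, collapse = ", "))
    }
    m <- m[rows, , drop = FALSE]
  } else if (nrow(m) == length(rows)) {
    rownames(m) <- rows
  } else {
    stop("matrix must have ", length(rows), " residue rows")
  }
  if (!is.null(colnames(m))) {
    # accept "+1" style labels on read
    colnames(m) <- sub("^\\+", "", colnames(m))
    missing_cols <- setdiff(labs, colnames(m))
    if (length(missing_cols)) {
      stop("matrix is missing position columns: ",
           paste(missing_cols, collapse = ", "))
    }
    m <- m[, labs, drop = FALSE]
  } else if (ncol(m) == length(labs)) {
    colnames(m) <- labs
  } else {
    stop("matrix must have ", length(labs), " position columns")
  }
  m
}

#' Construct a normalized position-specific scoring matrix
#'
#' Usually produced by [normalize_pspa()]; the constructor only validates
#' shape and positivity so that externally normalized matrices (for
#' example published specificity compendia) can be loaded directly.
#'
#' @param kinase_id Kinase identifier.
#' @param values Positive 22 x 10 numeric matrix of normalized values.
#' @param background_size 18 or 16.
#' @return Object of class `pssm`.
#' @export
pssm <- function(kinase_id, values, background_size = 18L) {
  values <- .canonical_matrix(values, AA_FIXED)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("PSSM values must be finite and strictly positive")
  }
  background_residues(background_size)
  structure(
    list(kinase_id = as.character(kinase_id),
         values = values,
         background_size = as.integer(background_size)),
    class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for", x$kinase_id,
      sprintf("(background %d residues)\n", x$background_size))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
print.raw_pspa <- function(x, ...) {
  cat("Raw PSPA intensities for", x$kinase_id,
      sprintf("(background %d%s)\n", x$background_size,
              if (x$dual_specificity) ", dual specificity" else ""))
  print(signif(x$intensities, 4))
  invisible(x)
}

#' Normalize a raw PSPA matrix into a PSSM
#'
#' Applies the standard processing chain, in order:
#' \enumerate{
#'   \item column-normalize each position by the sum over the randomized
#'     background residues (18, or 16 for the extended library), so that
#'     the background residues of every column sum to 1;
#'   \item rescale the whole Cys row by a single scalar so that its median
#'     across the 10 positions equals `1/background_size` (Cys is absent
#'     from the randomized background, so its raw scale is arbitrary);
#'   \item set the Tyr row equal to the Phe row at every position (fixed
#'     Tyr spots report phosphorylation of the fixed residue itself, not
#'     flanking preference);
#'   \item for dual-specificity kinases, set the Ser and Thr values at each
#'     position to the median of that position (median over the 20 natural
#'     residues, computed after steps 1-3).
#' }
#'
#' The background-sum property holds exactly after step 1; the Cys rescale
#' and Tyr overwrite perturb column totals and the matrix is deliberately
#' not re-normalized afterwards.
#'
#' @param raw A [raw_pspa()] object.
#' @return A [pssm()] object.
#' @export
normalize_pspa <- function(raw) {
  stopifnot(inherits(raw, "raw_pspa"))
  bg <- background_residues(raw$background_size)
  vals <- raw$intensities
  bg_sums <- colSums(vals[bg, , drop = FALSE])
  if (any(bg_sums <= 0)) {
    bad <- colnames(vals)[bg_sums <= 0][1L]
    stop("degenerate column: background residues sum to zero at position ",
         bad, " for ", raw$kinase_id)
  }
  vals <- sweep(vals, 2L, bg_sums, "/")

  cys_med <- stats::median(vals["C", ])
  if (cys_med <= 0) {
    stop("degenerate Cys row (median zero) for ", raw$kinase_id,
         "; cannot rescale")
  }
  vals["C", ] <- vals["C", ] * (1 / raw$background_size) / cys_med

  vals["Y", ] <- vals["F", ]

  if (raw$dual_specificity) {
    med <- apply(vals[AA_NATURAL, , drop = FALSE], 2L, stats::median)
    vals["S", ] <- med
    vals["T", ] <- med
  }

  if (any(vals <= 0)) {
    # strictly positive values are required downstream (log2 scores);
    # zero spot intensities are floored at the smallest positive value in
    # their column, mirroring the zero-replacement used for binding arrays
    for (j in seq_len(ncol(vals))) {
      zero <- vals[, j] <= 0
      if (any(zero)) {
        pos_min <- min(vals[!zero, j])
        vals[zero, j] <- pos_min
      }
    }
  }

  pssm(raw$kinase_id, vals, raw$background_size)
}

#' Selectivity matrix of a PSSM
#'
#' PSSM values rescaled by the background size so the mean randomized
#' residue has selectivity 1; values above 1 mark residues preferred over
#' random.
#'
#' @param x A [pssm()] object.
#' @return Numeric matrix of selectivities, same shape as `x$values`.
#' @export
selectivity <- function(x) {
  stopifnot(inherits(x, "pssm"))
  x$values * x$background_size
}

#' Letter-height matrix for a sequence logo
#'
#' The height of each letter at a flanking position is the ratio of its
#' PSSM value to the median value of the 20 natural residues at that
#' position.  The central position (0) contains only the phosphoacceptor
#' Tyr, whose height is set to the maximal height found in the peripheral
#' positions.
#'
#' @param x A [pssm()] object.
#' @return 22 x 11 numeric matrix (positions -5..5 including 0).
#' @export
logo_matrix <- function(x) {
  stopifnot(inherits(x, "pssm"))
  med <- apply(x$values[AA_NATURAL, , drop = FALSE], 2L, stats::median)
  if (any(med <= 0)) {
    bad <- colnames(x$values)[med <= 0][1L]
    stop("degenerate column: zero median at position ", bad)
  }
  heights <- sweep(x$values, 2L, med, "/")
  out <- matrix(0, nrow = length(AA_FIXED), ncol = 11L,
                dimnames = list(AA_FIXED, as.character(-5:5)))
  out[, colnames(heights)] <- heights
  out["Y", "0"] <- max(heights)
  out
}

#' Pearson correlation between two specificity matrices
#'
#' Correlates the log2 selectivities (PSSM value times background size)
#' entry-by-entry over the (residue, position) pairs shared by both
#' matrices.  Used to compare array-derived matrices with literature
#' specificity quantifications, which typically lack the phospho-residue
#' rows; non-shared rows or positions are dropped.
#'
#' @param a,b [pssm()] objects, or bare named matrices of normalized
#'   values accompanied by `background_size_a`/`background_size_b`.
#' @param background_size_a,background_size_b Background sizes used when
#'   `a`/`b` are bare matrices.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
pssm_correlation <- function(a, b, background_size_a = 18L,
                             background_size_b = 18L) {
  ma <- if (inherits(a, "pssm")) selectivity(a) else
    as.matrix(a) * background_size_a
  mb <- if (inherits(b, "pssm")) selectivity(b) else
    as.matrix(b) * background_size_b
  rows <- intersect(rownames(ma), rownames(mb))
  cols <- intersect(colnames(ma), colnames(mb))
  if (length(rows) * length(cols) < 3L) {
    stop("insufficient overlap: fewer than 3 shared (residue, position) entries")
  }
  va <- log2(as.vector(ma[rows, cols]))
  vb <- log2(as.vector(mb[rows, cols]))
  stats::cor(va, vb, method = "pearson")
}
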
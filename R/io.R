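#' Read a specificity matrix from a delimited file
#'
#' The matrix dialect is residues as rows in fixed order (the 20 natural
#' amino acids `ARNDCQEGHILKMFPSTWYV`, then "t" and "y" when present),
#' positions as columns labeled "-5".."-1","1".."5", tab-delimited with a
#' header row and a leading residue column.  Comma-delimited files are
#' accepted on read.
#'
#' @param path File path.
#' @param kinase_id Identifier to attach; defaults to the file base name.
#' @param background_size 18 or 16.
#' @param what "raw" returns a [raw_pspa()], "pssm" (default) a [pssm()].
#' @param dual_specificity Passed through for `what = "raw"`.
#' @return A `raw_pspa` or `pssm` object.
#' @export
read_pssm <- function(path, kinase_id = NULL, background_size = 18L,
                      what = c("pssm", "raw"), dual_specificity = FALSE) {
  what <- match.arg(what)
  if (is.null(kinase_id)) {
    kinase_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = 1L,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (what == "raw") {
    raw_pspa(kinase_id, m, background_size, dual_specificity)
  } else {
    pssm(kinase_id, m, background_size)
  }
}

#' Write a specificity matrix in the tab-delimited dialect
#'
#' @param x A `pssm`, `raw_pspa`, or bare residue-by-position matrix.
#' @param path Output file path.
#' @param digits Significant digits written (round-trips are value-exact
#'   to this precision).
#' @export
write_pssm <- function(x, path, digits = 7L) {
  m <- if (inherits(x, "pssm")) x$values else
    if (inherits(x, "raw_pspa")) x$intensities else as.matrix(x)
  df <- data.frame(residue = rownames(m), signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read every specificity matrix in a directory
#'
#' @param dir Directory containing `.tsv`/`.csv` matrix files; the file
#'   base name is used as the kinase identifier.
#' @param background_size Scalar or named vector (by kinase id) of 18/16.
#' @return Named list of [pssm()] objects, sorted by kinase id.
#' @export
read_pssm_dir <- function(dir, background_size = 18L) {
  files <- sort(list.files(dir, pattern = "\\.(tsv|csv)$", full.names = TRUE))
  if (!length(files)) stop("no matrix files found in ", dir)
  out <- lapply(files, function(f) {
    id <- sub("\\.[^.]*$", "", basename(f))
    bs <- if (length(background_size) > 1L) {
      if (is.na(background_size[id])) 18L else background_size[[id]]
    } else background_size
    read_pssm(f, kinase_id = id, background_size = bs)
  })
  names(out) <- vapply(out, `[[`, "", "kinase_id")
  out[order(names(out))]
}

#' Read a phosphosite table
#'
#' Expects a delimited table with columns `site_id` and `flank` (the
#' 11-mer flanking sequence, positions -5..+5 with the central
#' phosphoacceptor written "y" or "Y"), plus optional `log2fc` and
#' `p_adj` columns for differential datasets.
#'
#' @param path File path (TSV; CSV accepted).
#' @param strict_single_phospho Drop sites whose flank carries more than
#'   one lowercase phospho-character (multiply phosphorylated peptides).
#' @return Data frame with validated `site_id`, `flank` and any optional
#'   columns, deduplicated by `site_id`.
#' @export
read_sites <- function(path, strict_single_phospho = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (!all(c("site_id", "flank") %in% names(df))) {
    stop("site table must have columns 'site_id' and 'flank'")
  }
  df$site_id <- as.character(df$site_id)
  df$flank <- as.character(df$flank)
  as_site_table(df, strict_single_phospho = strict_single_phospho)
}

#' Validate and canonicalize an in-memory phosphosite table
#'
#' @param df Data frame with `site_id` and `flank` columns.
#' @inheritParams read_sites
#' @return The validated data frame (duplicated `site_id` rows removed,
#'   first occurrence kept).
#' @export
as_site_table <- function(df, strict_single_phospho = FALSE) {
  ok <- vapply(df$flank, function(f) is.null(validate_flank(f)), TRUE)
  if (!all(ok)) {
    msgs <- vapply(df$flank[!ok][1L], validate_flank, "")
    stop("invalid flank for site ", df$site_id[!ok][1L], ": ", msgs)
  }
  if (strict_single_phospho) {
    n_phos <- vapply(strsplit(df$flank, ""), function(ch)
      sum(ch %in% c("s", "t", "y")), 0L)
    df <- df[n_phos <= 1L, , drop = FALSE]
  }
  df <- df[!duplicated(df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check one 11-mer flank; NULL if valid, else a diagnostic string
#'
#' A valid flank has length 11; central character "Y" or "y"; characters
#' drawn from the 20 uppercase amino acids, lowercase "s"/"t"/"y" for
#' phospho-residues, or "_" padding; padding only contiguous at either
#' terminus.
#'
#' @param flank Character scalar.
#' @return NULL, or a single string describing the first violation.
#' @export
validate_flank <- function(flank) {
  if (!is.character(flank) || length(flank) != 1L || is.na(flank)) {
    return("flank must be a single string")
  }
  if (nchar(flank) != 11L) {
    return(sprintf("flank has length %d, expected 11", nchar(flank)))
  }
  ch <- strsplit(flank, "")[[1]]
  if (!ch[6] %in% c("Y", "y")) {
    return(sprintf("central residue '%s' is not a Tyr phosphoacceptor", ch[6]))
  }
  allowed <- c(AA_NATURAL, "s", "t", "y", "_")
  bad <- which(!ch %in% allowed)
  if (length(bad)) {
    return(sprintf("illegal character '%s' at flank position %d",
                   ch[bad[1]], bad[1]))
  }
  pads <- which(ch == "_")
  if (length(pads)) {
    left <- pads[pads < 6L]
    right <- pads[pads > 6L]
    if (length(left) && !identical(left, seq_len(length(left)))) {
      return("N-terminal padding must be contiguous from the start")
    }
    if (length(right) && !identical(right, seq.int(12L - length(right), 11L))) {
      return("C-terminal padding must be contiguous to the end")
    }
  }
  NULL
}

#' Read 11-mer flanks from a FASTA file
#'
#' Each record id becomes the site id and the sequence the flank; flanks
#' may contain lowercase phospho-characters and "_" padding.
#'
#' @param path FASTA file path.
#' @return Site table as from [read_sites()].
#' @export
read_sites_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  df <- data.frame(site_id = names(seqs), flank = as.character(seqs),
                   stringsAsFactors = FALSE)
  as_site_table(df)
}

#' Write a phosphosite table
#'
#' @param df Site table.
#' @param path Output TSV path.
#' @export
write_sites <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a set of input files
#'
#' Runs format checks over specificity matrices and phosphosite tables and
#' returns per-file diagnostics instead of stopping on the first error.
#'
#' @param paths Character vector of file paths; files ending in
#'   `.fasta`/`.fa` are parsed as FASTA flanks, other files are sniffed as
#'   a matrix (first header cell "residue") or a site table.
#' @return Data frame with columns `path`, `kind`, `ok`, `message`.
#' @export
validate_inputs <- function(paths) {
  one <- function(p) {
    if (!file.exists(p)) {
      return(data.frame(path = p, kind = "missing", ok = FALSE,
                        message = "file not found"))
    }
    kind <- if (grepl("\\.(fasta|fa)$", p)) "fasta" else {
      first <- readLines(p, n = 1L)
      if (grepl("^residue[\t,]", first)) "matrix" else "sites"
    }
    msg <- tryCatch({
      switch(kind,
             fasta = read_sites_fasta(p),
             matrix = read_pssm(p, what = "raw"),
             sites = {
               df <- utils::read.table(
                 p, sep = if (grepl("\t", readLines(p, n = 1L))) "\t" else ",",
                 header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
               if (!all(c("site_id", "flank") %in% names(df)))
                 stop("missing site_id/flank columns")
               for (i in seq_len(nrow(df))) {
                 v <- validate_flank(as.character(df$flank[i]))
                 if (!is.null(v)) stop(sprintf("line %d (%s): %s", i + 1L,
                                               df$site_id[i], v))
               }
               df
             })
      ""
    }, error = function(e) conditionMessage(e))
    data.frame(path = p, kind = kind, ok = identical(msg, ""),
               message = msg, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(paths, one))
}
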
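# Synthetic data generators: raw peptide-array matrices with planted
# position-specific preferences, phosphoproteomes drawn from motif
# mixtures, and differential datasets with a planted regulated kinase.
# All generators are deterministic given their seed, and their sampling
# models are simple enough that expectations are checkable in closed
# form (see the methods vignette).

.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Specify a planted kinase motif
#'
#' A motif is a set of per-position selectivity multipliers over the fixed
#' residues: intensity for residue r at position p is
#' `baseline * multiplier(r, p) * lognormal noise`, so a residue with
#' multiplier m is preferred about m-fold over an unweighted background
#' residue.
#'
#' @param kinase_id Identifier.
#' @param preferences Named list: names are position labels ("-5".."-1",
#'   "1".."5"), values named numeric vectors of multipliers, e.g.
#'   `list("-1" = c(I = 5), "3" = c(P = 4, I = 2))`.  Unlisted residues
#'   have multiplier 1.
#' @param background_size 18 or 16.
#' @param dual_specificity Logical.
#' @param noise_sd Standard deviation of multiplicative lognormal noise
#'   on the log scale (default 0.1, typical densitometric spot
#'   variability).
#' @param baseline Baseline spot intensity (default 1000).
#' @param ptm_multiplier Baseline multiplier applied to the pThr/pTyr
#'   rows (default 1; raise to plant phosphopriming selectivity).
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(kinase_id, preferences = list(),
                       background_size = 18L, dual_specificity = FALSE,
                       noise_sd = 0.1, baseline = 1000,
                       ptm_multiplier = 1) {
  labs <- .position_labels()
  bad <- setdiff(names(preferences), labs)
  if (length(bad)) stop("unknown position label: ", bad[1L])
  for (p in names(preferences)) {
    v <- preferences[[p]]
    if (any(v <= 0)) stop("multipliers must be positive")
    if (!all(names(v) %in% AA_FIXED)) {
      stop("unknown residue in preferences at position ", p)
    }
  }
  stopifnot(noise_sd >= 0, baseline > 0, ptm_multiplier > 0)
  structure(list(kinase_id = as.character(kinase_id),
                 preferences = preferences,
                 background_size = as.integer(background_size),
                 dual_specificity = isTRUE(dual_specificity),
                 noise_sd = noise_sd, baseline = baseline,
                 ptm_multiplier = ptm_multiplier),
            class = "motif_spec")
}

# Deterministic multiplier matrix of a motif spec (22 x 10, no noise).
.spec_multipliers <- function(spec) {
  labs <- .position_labels()
  mult <- matrix(1, nrow = length(AA_FIXED), ncol = length(labs),
                 dimnames = list(AA_FIXED, labs))
  mult[AA_PTM, ] <- spec$ptm_multiplier
  for (p in names(spec$preferences)) {
    v <- spec$preferences[[p]]
    mult[names(v), p] <- v
  }
  mult
}

#' Generate a raw PSPA intensity matrix from a motif specification
#'
#' Intensity(r, p) = baseline x multiplier(r, p) x exp(N(0, noise_sd^2)).
#' With zero noise and no planted preferences, normalization returns the
#' uniform PSSM (every background value 1/background_size).
#'
#' @param spec A [motif_spec()].
#' @param seed Integer seed; the output is byte-identical per seed.
#' @return A [raw_pspa()] object.
#' @export
gen_raw_pspa <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  mult <- .spec_multipliers(spec)
  inten <- .with_seed(seed, {
    noise <- matrix(stats::rlnorm(length(mult), 0, spec$noise_sd),
                    nrow = nrow(mult))
    spec$baseline * mult * noise
  })
  dimnames(inten) <- dimnames(mult)
  raw_pspa(spec$kinase_id, inten, spec$background_size,
           spec$dual_specificity)
}

#' Generate a batch of random kinase motif specifications
#'
#' Emulates a kinome of distinct specificities: each kinase receives
#' planted preferences at 2-4 of the positions -2..+3 (where real Tyr
#' kinases concentrate their selectivity), with fold-preferences drawn
#' between `fold_range[1]` and `fold_range[2]`.  A fraction of kinases
#' receives a phosphopriming preference (a pThr or pTyr multiplier).
#'
#' @param n Number of kinases.
#' @param seed Integer seed.
#' @param fold_range Range of planted fold-preferences (default 3-8).
#' @param priming_fraction Fraction of kinases given a planted
#'   phospho-residue preference (default 0.5).
#' @param noise_sd Per-spec lognormal noise sd.
#' @return Named list of [motif_spec()] objects ("KIN001", ...).
#' @export
gen_kinome_specs <- function(n, seed = 1L, fold_range = c(3, 8),
                             priming_fraction = 0.5, noise_sd = 0.1) {
  core_pos <- c("-2", "-1", "1", "2", "3")
  pickable <- setdiff(background_residues(18L), character(0))
  .with_seed(seed, {
    specs <- lapply(seq_len(n), function(i) {
      npos <- sample(2:4, 1L)
      pos <- sample(core_pos, npos)
      prefs <- lapply(pos, function(p) {
        r <- sample(pickable, 1L)
        stats::setNames(stats::runif(1L, fold_range[1], fold_range[2]), r)
      })
      names(prefs) <- pos
      if (stats::runif(1L) < priming_fraction) {
        pp <- sample(c("-1", "1", "2"), 1L)
        ptm <- sample(AA_PTM, 1L)
        add <- stats::setNames(stats::runif(1L, fold_range[1], fold_range[2]),
                               ptm)
        prefs[[pp]] <- c(prefs[[pp]], add)
      }
      motif_spec(sprintf("KIN%03d", i), prefs, noise_sd = noise_sd)
    })
    names(specs) <- vapply(specs, `[[`, "", "kinase_id")
    specs
  })
}

#' Generate a synthetic Tyr phosphoproteome
#'
#' Draws `n` 11-mer flanks centred on Tyr.  A weighted fraction of sites
#' is drawn from each kinase's motif (flanking residues sampled with
#' probability proportional to the planted multipliers over the
#' randomized-background alphabet); the remainder is uniform over that
#' alphabet.  Cys never appears at flanking positions by default,
#' mirroring the composition of the randomized peptide library.  Small
#' fractions of sites carry terminal padding or phospho-characters so
#' readers and scorers see every legal symbol.
#'
#' @param n Number of sites.
#' @param specs Named list of [motif_spec()] (may be empty for a fully
#'   uniform proteome).
#' @param weights Mixture weights per spec; the remainder to 1 is
#'   uniform background.  Default: all background.
#' @param seed Integer seed.
#' @param pad_fraction Fraction of sites with terminal "_" padding
#'   (default 0.05).
#' @param phospho_fraction Fraction of sites carrying one lowercase
#'   phospho-character at a flank position (default 0.05).
#' @param allow_cys Allow Cys at flanking positions (default FALSE).
#' @return Site table: `site_id`, `flank`, `source` (spec id or
#'   "background").
#' @export
gen_phosphoproteome <- function(n, specs = list(), weights = NULL,
                                seed = 1L, pad_fraction = 0.05,
                                phospho_fraction = 0.05,
                                allow_cys = FALSE) {
  if (n == 0L) {
    return(data.frame(site_id = character(), flank = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  if (is.null(weights)) weights <- rep(0, length(specs))
  stopifnot(length(weights) == length(specs), sum(weights) <= 1 + 1e-12)
  alphabet <- background_residues(18L)
  if (allow_cys) alphabet <- c(alphabet, "C")
  labs <- .position_labels()
  # per-spec sampling probabilities per position, over the flank alphabet
  prob_tabs <- lapply(specs, function(sp) {
    mult <- .spec_multipliers(sp)[alphabet, , drop = FALSE]
    sweep(mult, 2L, colSums(mult), "/")
  })
  .with_seed(seed, {
    src <- if (length(specs)) {
      sample(c(names(specs), "background"), n, replace = TRUE,
             prob = c(weights, 1 - sum(weights)))
    } else rep("background", n)
    flanks <- vapply(seq_len(n), function(i) {
      ch <- if (src[i] == "background") {
        sample(alphabet, 10L, replace = TRUE)
      } else {
        pt <- prob_tabs[[src[i]]]
        vapply(seq_len(10L), function(p)
          sample(alphabet, 1L, prob = pt[, p]), "")
      }
      paste0(paste(ch[1:5], collapse = ""), "Y",
             paste(ch[6:10], collapse = ""))
    }, "")
    # terminal padding
    n_pad <- round(pad_fraction * n)
    if (n_pad > 0L) {
      which_pad <- sample.int(n, n_pad)
      for (i in which_pad) {
        w <- sample(1:4, 1L)
        flanks[i] <- if (stats::runif(1L) < 0.5) {
          paste0(strrep("_", w), substr(flanks[i], w + 1L, 11L))
        } else {
          paste0(substr(flanks[i], 1L, 11L - w), strrep("_", w))
        }
      }
    }
    # lowercase phospho-characters at non-central positions
    n_ph <- round(phospho_fraction * n)
    if (n_ph > 0L) {
      which_ph <- sample.int(n, n_ph)
      for (i in which_ph) {
        pos <- sample(setdiff(1:11, 6L), 1L)
        if (substr(flanks[i], pos, pos) != "_") {
          substr(flanks[i], pos, pos) <- sample(c("s", "t", "y"), 1L)
        }
      }
    }
    data.frame(site_id = sprintf("SYN%05d", seq_len(n)), flank = flanks,
               source = src, stringsAsFactors = FALSE)
  })
}

#' Generate a differential phosphoproteomics dataset with a planted kinase
#'
#' Sites biochemically favoured by the planted kinase (top-`k` rank for
#' that site) receive `log2fc ~ Normal(effect_mean, sd)` with probability
#' `effect`; all other draws come from `Normal(0, sd)`.  With
#' `effect = 0` the dataset carries no signal and calibrates the null.
#'
#' @param sites Site table (e.g. from [gen_phosphoproteome()]).
#' @param planted Kinase id to upregulate.
#' @param pssms,refs Named lists of PSSMs and reference distributions
#'   used to determine which sites the planted kinase favours.
#' @param effect Probability that a favoured site receives the shifted
#'   fold change (0 = null).
#' @param effect_mean Mean log2 fold change of shifted sites (default 2).
#' @param sd Fold-change noise sd (default 0.5).
#' @param k Top-k favoured cut-off (default 8).
#' @param seed Integer seed.
#' @return `sites` with an added `log2fc` column.
#' @export
gen_regulated_dataset <- function(sites, planted, pssms, refs, effect,
                                  effect_mean = 2, sd = 0.5, k = 8L,
                                  seed = 1L) {
  stopifnot(effect >= 0, effect <= 1)
  fav <- if (effect > 0) {
    if (!planted %in% names(pssms)) stop("planted kinase not in pssms")
    favoured_kinases(pssms, refs, sites$flank, k = k)[, planted]
  } else rep(FALSE, nrow(sites))
  .with_seed(seed, {
    fc <- stats::rnorm(nrow(sites), 0, sd)
    hit <- fav & stats::runif(nrow(sites)) < effect
    fc[hit] <- stats::rnorm(sum(hit), effect_mean, sd)
    sites$log2fc <- fc
    sites
  })
}

#' Generate a raw SH2-domain binding matrix
#'
#' Same planted-multiplier model as [gen_raw_pspa()] but over the 19
#' non-Cys natural residues and a C-terminal-biased position window, and
#' with an optional fraction of exact zero intensities to exercise the
#' zero-replacement rule.
#'
#' @param sh2_id Identifier.
#' @param preferences As in [motif_spec()], restricted to `positions`.
#' @param positions Position labels of the window (default "-2".."4",
#'   excluding 0).
#' @param noise_sd,baseline As in [motif_spec()].
#' @param zero_fraction Fraction of entries zeroed (default 0).
#' @param seed Integer seed.
#' @return Numeric 19 x length(positions) intensity matrix.
#' @export
gen_raw_sh2 <- function(sh2_id, preferences = list(),
                        positions = c("-2", "-1", "1", "2", "3", "4"),
                        noise_sd = 0.1, baseline = 1000,
                        zero_fraction = 0, seed = 1L) {
  res19 <- setdiff(AA_NATURAL, "C")
  mult <- matrix(1, nrow = length(res19), ncol = length(positions),
                 dimnames = list(res19, positions))
  for (p in names(preferences)) {
    if (!p %in% positions) stop("preference outside the SH2 window: ", p)
    v <- preferences[[p]]
    mult[names(v), p] <- v
  }
  .with_seed(seed, {
    m <- baseline * mult *
      matrix(stats::rlnorm(length(mult), 0, noise_sd), nrow = nrow(mult))
    if (zero_fraction > 0) {
      nz <- round(zero_fraction * length(m))
      if (nz > 0L) {
        # never zero out a full column
        idx <- sample(seq_along(m), nz)
        m[idx] <- 0
        for (j in seq_len(ncol(m))) {
          if (all(m[, j] == 0)) m[1L, j] <- baseline
        }
      }
    }
    dimnames(m) <- dimnames(mult)
    m
  })
}
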
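# Shared fixture builders.  Everything is generated in code; no files.

# Uniform raw array: every spot has the same intensity.
make_uniform_raw <- function(kinase_id = "UNI", intensity = 5,
                             background_size = 18L,
                             dual_specificity = FALSE) {
  m <- matrix(intensity, nrow = 22, ncol = 10,
              dimnames = list(AA_FIXED, as.character(c(-5:-1, 1:5))))
  raw_pspa(kinase_id, m, background_size, dual_specificity)
}

# PSSM with chosen selectivities; everything not listed has selectivity 1.
# sel is a named list: names are position labels, values named vectors,
# e.g. list("-1" = c(I = 2), "3" = c(P = 0.5)).
make_sel_pssm <- function(kinase_id = "TOY", sel = list(),
                          background_size = 18L) {
  m <- matrix(1 / background_size, nrow = 22, ncol = 10,
              dimnames = list(AA_FIXED, as.character(c(-5:-1, 1:5))))
  for (p in names(sel)) {
    v <- sel[[p]]
    m[names(v), p] <- v / background_size
  }
  m["Y", ] <- m["F", ]
  pssm(kinase_id, m, background_size)
}

# Seeded random flank over the 18-residue background alphabet, optionally
# with padding or phospho-characters.
random_flank <- function(pad = FALSE, phospho = FALSE) {
  alpha <- setdiff(AA_NATURAL, c("Y", "C"))
  ch <- sample(alpha, 10, replace = TRUE)
  if (phospho) ch[sample(10, 1)] <- sample(c("s", "t", "y"), 1)
  f <- paste0(paste(ch[1:5], collapse = ""), "Y",
              paste(ch[6:10], collapse = ""))
  if (pad) {
    w <- sample(1:4, 1)
    f <- if (runif(1) < 0.5) {
      paste0(strrep("_", w), substr(f, w + 1, 11))
    } else {
      paste0(substr(f, 1, 11 - w), strrep("_", w))
    }
  }
  f
}

# Independent brute-force product score: explicit per-position loop,
# rounding each selectivity to 4 decimals (half away from zero) before
# multiplying.  Kept deliberately simple and separate from score_matrix.
brute_force_score <- function(pssm, flank, phospho_ser_as_pthr = TRUE) {
  ch <- strsplit(flank, "")[[1]]
  labs <- as.character(c(-5:-1, 1:5))
  score <- 1
  for (i in seq_along(labs)) {
    c_i <- ch[if (i <= 5) i else i + 1]
    if (c_i == "_") next
    row <- if (c_i %in% c("t", "y")) c_i
           else if (c_i == "s") (if (phospho_ser_as_pthr) "t" else "S")
           else c_i
    s <- pssm$values[row, labs[i]] * pssm$background_size
    s4 <- sign(s) * floor(abs(s) * 1e4 + 0.5) / 1e4
    score <- score * s4
  }
  score
}

# Hypergeometric tail sum P(X >= a) for a 2x2 table with margins
# (row1 = n_reg, col1 = n_fav, total N), via explicit log-binomial
# coefficients.  This is the enumeration oracle for the one-sided
# Fisher test.
hyper_tail_oracle <- function(a, n_reg, n_fav, N) {
  lo <- max(0L, n_reg + n_fav - N)
  hi <- min(n_reg, n_fav)
  if (a > hi) return(0)
  ks <- max(a, lo):hi
  terms <- lchoose(n_fav, ks) + lchoose(N - n_fav, n_reg - ks) -
    lchoose(N, n_reg)
  sum(exp(terms))
}

# Unordered bipartitions (as sorted leaf-set strings) induced by the
# internal edges of a phylo tree; used for Robinson-Foulds comparison.
tree_bipartitions <- function(phy) {
  n_tip <- length(phy$tip.label)
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(n_tip))
  desc_tips <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, function(k)
      if (k <= n_tip) phy$tip.label[k] else desc_tips(k)))
  }
  parts <- vapply(internal, function(nd)
    paste(sort(desc_tips(nd)), collapse = "|"), "")
  # drop the trivial partition containing all tips
  setdiff(parts, paste(sort(phy$tip.label), collapse = "|"))
}

rf_distance <- function(t1, t2) {
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Small kinome + reference bundle reused by scoring/enrichment tests.
make_test_kinome <- function(n_kin = 20, n_ref = 400, seed = 101) {
  specs <- gen_kinome_specs(n_kin, seed = seed)
  pssms <- lapply(names(specs), function(id)
    normalize_pspa(gen_raw_pspa(specs[[id]], seed = seed + match(id, names(specs)))))
  names(pssms) <- names(specs)
  ref_sites <- gen_phosphoproteome(n_ref, specs,
                                   weights = rep(0.4 / n_kin, n_kin),
                                   seed = seed + 1000)
  refs <- lapply(pssms, build_reference, flanks = ref_sites$flank)
  list(specs = specs, pssms = pssms, refs = refs, ref_sites = ref_sites)
}
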
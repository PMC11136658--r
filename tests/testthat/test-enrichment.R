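# Kinase-activity inference: fold-change partition, favoured-kinase sets,
# one-sided Fisher tests with Haldane-corrected frequency factors.

test_that("fold-change partition is disjoint, exhaustive and deduplicated", {
  sites <- data.frame(
    site_id = c("a", "b", "c", "d", "d", "e"),
    flank = c("AAAAAYAAAAA", "AAAAIYAAAAA", "AAAALYAAAAA",
              "AAAADYAAAAA", "AAAADYAAAAA", "AAAAEYAAAAA"),
    log2fc = c(1.5, 1.0, -1.0, 0.99, 0.99, -0.2),
    stringsAsFactors = FALSE)
  part <- partition_by_fc(sites, fc_threshold = 1)
  expect_equal(nrow(part), 5)                       # duplicate d dropped
  expect_equal(as.vector(table(part$regulation)),
               c(2L, 1L, 2L))                       # up, down, unchanged
  expect_equal(sum(table(part$regulation)), nrow(part))
  # threshold is inclusive on both sides
  expect_equal(as.character(part$regulation[part$site_id == "b"]), "up")
  expect_equal(as.character(part$regulation[part$site_id == "c"]), "down")
})

test_that("multiply phosphorylated flanks are dropped in strict mode", {
  sites <- data.frame(
    site_id = c("a", "b"),
    flank = c("AAsAAYAtAAA", "AAAAAYAAAAA"),
    log2fc = c(2, 2), stringsAsFactors = FALSE)
  part <- partition_by_fc(sites, strict_single_phospho = TRUE)
  expect_equal(part$site_id, "b")
})

test_that("favoured kinases are the deterministic top-k per site", {
  kin <- make_test_kinome(n_kin = 12, n_ref = 200, seed = 81)
  flanks <- gen_phosphoproteome(15, kin$specs, weights = rep(0.05, 12),
                                seed = 82)$flank
  fav <- favoured_kinases(kin$pssms, kin$refs, flanks, k = 8)
  expect_equal(unname(rowSums(fav)), rep(8L, 15))
  expect_true(all(rowSums(favoured_kinases(kin$pssms, kin$refs, flanks,
                                           k = 1)) == 1))
  # k = n: every kinase favoured
  fav_all <- favoured_kinases(kin$pssms, kin$refs, flanks, k = 12)
  expect_true(all(fav_all))
  expect_error(favoured_kinases(kin$pssms, kin$refs, flanks, k = 13),
               "exceeds")
})

test_that("a site built from a kinase's optimal residues favours it", {
  kin <- make_test_kinome(n_kin = 12, n_ref = 300, seed = 91)
  planted <- "KIN003"
  sel <- selectivity(kin$pssms[[planted]])
  labs <- as.character(c(-5:-1, 1:5))
  ch <- vapply(labs, function(p)
    names(which.max(sel[setdiff(AA_NATURAL, c("Y", "C")), p])), "")
  f <- paste0(paste(ch[1:5], collapse = ""), "Y", paste(ch[6:10], collapse = ""))
  fav <- favoured_kinases(kin$pssms, kin$refs, f, k = 8)
  expect_true(fav[1, planted])
})

test_that("one-sided Fisher p equals the hypergeometric tail oracle", {
  # fixed example: 8 favoured of 20 regulated vs 40 favoured of 400 unchanged
  p_ex <- tyrmotif:::fisher_p_greater(8, 20, 48, 420)
  expect_equal(p_ex, hyper_tail_oracle(8, 20, 48, 420), tolerance = 1e-12)
  # randomized margins up to N = 200, all compared to the enumeration
  set.seed(13)
  for (rep in 1:300) {
    N <- sample(2:200, 1)
    n_reg <- sample(0:N, 1)
    n_fav <- sample(0:N, 1)
    lo <- max(0, n_reg + n_fav - N); hi <- min(n_reg, n_fav)
    a <- if (hi >= lo) sample(lo:hi, 1) else 0
    expect_equal(tyrmotif:::fisher_p_greater(a, n_reg, n_fav, N),
                 hyper_tail_oracle(a, n_reg, n_fav, N), tolerance = 1e-10)
  }
  # and to R's own Fisher implementation on a subsample
  for (rep in 1:40) {
    N <- sample(4:150, 1); n_reg <- sample(1:(N - 1), 1)
    n_fav <- sample(1:(N - 1), 1)
    lo <- max(0, n_reg + n_fav - N); hi <- min(n_reg, n_fav)
    a <- sample(lo:hi, 1)
    tab <- matrix(c(a, n_fav - a, n_reg - a, N - n_fav - n_reg + a), 2)
    expect_equal(tyrmotif:::fisher_p_greater(a, n_reg, n_fav, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("frequency factors use the Haldane-corrected table on zero cells", {
  # 0 favoured of 10 regulated vs 5 favoured of 100 unchanged
  ffh <- tyrmotif:::frequency_factor(0, 10, 5, 95)
  expect_true(ffh$haldane)
  expect_equal(ffh$ff, (0.5 / 10.5) / (5.5 / 100.5), tolerance = 1e-12)
  # no zero cell: plain ratio of favoured fractions
  ffh2 <- tyrmotif:::frequency_factor(8, 12, 40, 360)
  expect_false(ffh2$haldane)
  expect_equal(ffh2$ff, (8 / 20) / (40 / 400), tolerance = 1e-12)
})

test_that("a planted upregulated kinase is the top enrichment hit", {
  kin <- make_test_kinome(n_kin = 20, n_ref = 300, seed = 111)
  sites <- gen_phosphoproteome(400, kin$specs, weights = rep(0.03, 20),
                               seed = 112, pad_fraction = 0,
                               phospho_fraction = 0)
  reg <- gen_regulated_dataset(sites, "KIN005", kin$pssms, kin$refs,
                               effect = 1, seed = 113)
  part <- partition_by_fc(reg)
  expect_gt(sum(part$regulation == "unchanged"), 0)
  res <- kinase_enrichment(part, kin$pssms, kin$refs)
  best <- res$kinase_id[which.min(res$p_value)]
  expect_equal(best, "KIN005")
  expect_equal(res$direction[res$kinase_id == "KIN005"], "up")
  expect_lte(res$p_value[res$kinase_id == "KIN005"], 0.05)
})

test_that("contingency counts are consistent with the partition sizes", {
  kin <- make_test_kinome(n_kin = 10, n_ref = 150, seed = 121)
  sites <- gen_phosphoproteome(200, kin$specs, weights = rep(0.04, 10),
                               seed = 122)
  reg <- gen_regulated_dataset(sites, "KIN002", kin$pssms, kin$refs,
                               effect = 0.7, seed = 123)
  part <- partition_by_fc(reg)
  res <- kinase_enrichment(part, kin$pssms, kin$refs)
  n_up <- sum(part$regulation == "up")
  n_dn <- sum(part$regulation == "down")
  n_un <- sum(part$regulation == "unchanged")
  expect_true(all(res$fav_up + res$notfav_up == n_up))
  expect_true(all(res$fav_down + res$notfav_down == n_dn))
  expect_true(all(res$fav_unchanged + res$notfav_unchanged == n_un))
})

test_that("enrichment with no background or no regulated sites is handled", {
  kin <- make_test_kinome(n_kin = 10, n_ref = 100, seed = 131)
  sites <- gen_phosphoproteome(30, seed = 132)
  sites$log2fc <- 3                      # everything regulated
  part <- partition_by_fc(sites)
  expect_error(kinase_enrichment(part, kin$pssms, kin$refs), "background")
  sites$log2fc <- 0                      # nothing regulated
  part <- partition_by_fc(sites)
  expect_warning(res <- kinase_enrichment(part, kin$pssms, kin$refs),
                 "no regulated")
  expect_equal(nrow(res), 0)
})

test_that("volcano coordinates follow the log arithmetic and drop dual hits", {
  res <- data.frame(
    kinase_id = c("A", "B", "C", "D"),
    direction = c("up", "up", "down", "up"),
    p_value = c(1e-3, 1, 1e-4, 1e-6),
    frequency_factor = c(4, 1, 4, 8),
    log2_ff = log2(c(4, 1, 4, 8)),
    excluded_dual = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  v <- volcano_table(res)
  expect_equal(nrow(v), 3)                       # dual-significant D dropped
  expect_equal(v$x[v$id == "A"], 2)              # FF 4, up -> +2
  expect_equal(v$y[v$id == "A"], 3)              # p 1e-3 -> 3
  expect_equal(v$x[v$id == "B"], 0)              # FF 1 -> 0
  expect_equal(v$y[v$id == "B"], 0)              # p 1 -> 0
  expect_equal(v$x[v$id == "C"], -2)             # down direction negated
})

test_that("null datasets keep per-direction significance near alpha", {
  # moderate replicate count here; the full calibration runs in the
  # acceptance suite
  kin <- make_test_kinome(n_kin = 15, n_ref = 200, seed = 141)
  sites <- gen_phosphoproteome(240, kin$specs, weights = rep(0.02, 15),
                               seed = 142)
  fav <- favoured_kinases(kin$pssms, kin$refs, sites$flank, k = 8)
  n_sig <- 0; n_tot <- 0
  for (r in 1:60) {
    reg <- gen_regulated_dataset(sites, "KIN001", kin$pssms, kin$refs,
                                 effect = 0, sd = 0.8, seed = 5000 + r)
    part <- partition_by_fc(reg)
    res <- kinase_enrichment(part, kin$pssms, kin$refs, favoured = fav)
    n_sig <- n_sig + sum(res$p_up <= 0.05)
    n_tot <- n_tot + nrow(res)
  }
  rate <- n_sig / n_tot
  se <- sqrt(0.05 * 0.95 / n_tot)
  expect_lte(rate, 0.05 + 3 * se)
})
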
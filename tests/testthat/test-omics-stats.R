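# Collagen composition and differential abundance statistics.

single_sample_table <- function() {
  list(
    abundance = tibble::tibble(protein = c("colI", "colIII", "colIV"),
                               s1 = c(500, 300, 200)),
    annotation = tibble::tibble(protein = c("colI", "colIII", "colIV"),
                                collagen_type = c("I", "III", "IV")),
    groups = tibble::tibble(sample = "s1", group = "control"))
}

test_that("composition percentages are abundance shares of total collagen", {
  d <- single_sample_table()
  # two-group machinery needs both groups; duplicate the sample
  ab <- d$abundance; ab$s2 <- ab$s1
  gr <- tibble::tibble(sample = c("s1", "s2"), group = c("control", "case"))
  cc <- collagen_composition(ab, d$annotation, gr)
  p1 <- cc$per_sample[cc$per_sample$sample == "s1", ]
  expect_equal(sort(p1$percent, decreasing = TRUE), c(50, 30, 20))
  expect_equal(sum(p1$percent), 100, tolerance = 1e-9)
})

test_that("identical groups yield no significant composition differences", {
  exp1 <- generate_abundance_table(n_control = 4, n_case = 4,
                                   use_case_profile = FALSE, seed = 5)
  cc <- collagen_composition(exp1$abundance, exp1$annotation, exp1$groups)
  expect_true(all(cc$per_type$p_adjusted >= cc$per_type$p_value,
                  na.rm = TRUE))
  # per-sample percentages always sum to 100
  sums <- tapply(cc$per_sample$percent, cc$per_sample$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("composition is invariant to rescaling a single sample", {
  exp1 <- generate_abundance_table(seed = 6)
  ab2 <- exp1$abundance
  ab2$ctrl_1 <- ab2$ctrl_1 * 17.3
  cc1 <- collagen_composition(exp1$abundance, exp1$annotation, exp1$groups)
  cc2 <- collagen_composition(ab2, exp1$annotation, exp1$groups)
  expect_equal(cc1$per_sample$percent, cc2$per_sample$percent,
               tolerance = 1e-12)
})

test_that("zero-total-collagen samples are excluded with a warning", {
  exp1 <- generate_abundance_table(n_control = 3, n_case = 3, seed = 7)
  ab <- exp1$abundance
  ab$ctrl_1 <- 0
  expect_warning(
    cc <- collagen_composition(ab, exp1$annotation, exp1$groups),
    "zero total collagen")
  expect_false("ctrl_1" %in% cc$per_sample$sample)
})

test_that("BH adjustment matches the hand-applied step-up procedure", {
  # 4 proteins with raw p .01/.02/.03/.04 all adjust to .04
  ab <- tibble::tibble(protein = paste0("p", 1:4))
  # construct via p.adjust directly on the known vector as the oracle...
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # and check the pipeline's BH sits between raw p and Bonferroni
  exp1 <- generate_abundance_table(n_other = 40, seed = 8,
                                   other_log2_effects = c(rep(2, 5),
                                                          rep(0, 35)))
  de <- differential_expression(exp1$abundance, exp1$groups)
  ok <- de$tested
  bonf <- pmin(1, de$p_value[ok] * sum(ok))
  expect_true(all(de$fdr[ok] >= de$p_value[ok] - 1e-12))
  expect_true(all(de$fdr[ok] <= bonf + 1e-12))
  # BH is monotone in raw p
  ord <- order(de$p_value[ok])
  expect_true(all(diff(de$fdr[ok][ord]) >= -1e-12))
})

test_that("true differential proteins are detected and nulls controlled", {
  exp1 <- generate_abundance_table(
    n_control = 6, n_case = 6, n_other = 60,
    other_log2_effects = c(rep(3, 6), rep(0, 54)), seed = 9)
  de <- differential_expression(exp1$abundance, exp1$groups)
  hits <- de$protein[de$significant]
  expect_true(all(exp1$truth$protein %in% hits))
})

test_that("identical groups give no FDR-significant proteins", {
  ab <- tibble::tibble(protein = paste0("p", 1:20))
  vals <- matrix(rlnorm(20 * 6, 10, 1), 20)
  for (j in 1:3) ab[[paste0("a", j)]] <- vals[, j]
  for (j in 1:3) ab[[paste0("b", j)]] <- vals[, j]  # mirrored values
  gr <- tibble::tibble(sample = c(paste0("a", 1:3), paste0("b", 1:3)),
                       group = rep(c("control", "case"), each = 3))
  de <- differential_expression(ab, gr)
  expect_false(any(de$significant))
})

test_that("proteins missing in a whole group are flagged, not tested", {
  exp1 <- generate_abundance_table(n_control = 3, n_case = 3, n_other = 2,
                                   seed = 10)
  ab <- exp1$abundance
  ab[ab$protein == "PROT_001", paste0("ctrl_", 1:3)] <- 0
  de <- differential_expression(ab, exp1$groups)
  expect_false(de$tested[de$protein == "PROT_001"])
  expect_true(is.na(de$fdr[de$protein == "PROT_001"]))
})

test_that("under the null the FDR-significant fraction stays near nominal", {
  set.seed(12)
  fracs <- replicate(40, {
    exp1 <- generate_abundance_table(n_control = 5, n_case = 5,
                                     use_case_profile = FALSE,
                                     n_other = 100)
    de <- differential_expression(exp1$abundance, exp1$groups)
    mean(de$significant[de$tested])
  })
  # mean discovery fraction under the null must not exceed alpha + MC slack
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) / sqrt(length(fracs)) + 0.01)
})
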
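# Summary-statistic I/O, harmonization, GRS construction and diagnostics.

test_that("summary statistics round-trip through TSV and validate records", {
  ss <- make_sumstats(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path)
  expect_equal(as.data.frame(back), as.data.frame(ss), ignore_attr = TRUE)
  expect_equal(nrow(exclusions(back)), 0)

  # invalid rows are excluded with reasons, not dropped silently
  bad <- ss
  bad$se[2] <- 0
  bad$effect_allele[3] <- "G" # equals other allele
  write_summary_stats(bad, path)
  got <- read_summary_stats(path)
  expect_equal(nrow(got), 1)
  log <- exclusions(got)
  expect_setequal(log$reason, c("nonpositive SE", "identical alleles"))

  # missing required column is a hard error naming the column
  readr::write_tsv(ss[setdiff(names(ss), "se")], path)
  expect_error(read_summary_stats(path), "se")

  # column aliases map foreign dialects
  aliased <- ss
  names(aliased)[names(aliased) == "variant_id"] <- "SNP"
  readr::write_tsv(aliased, path)
  expect_equal(
    read_summary_stats(path, aliases = list(variant_id = "SNP"))$variant_id,
    ss$variant_id
  )
})

test_that("harmonization aligns, flips, and excludes per policy", {
  exp <- make_sumstats(4, beta = 0.1, eaf = 0.3)
  out <- make_sumstats(4, beta = 0.1, eaf = 0.3)
  # SNP2: swapped effect/other alleles -> sign flip, eaf reflected
  out$effect_allele[2] <- "G"; out$other_allele[2] <- "A"
  # SNP3: palindromic on both sides
  exp$effect_allele[3] <- "A"; exp$other_allele[3] <- "T"
  out$effect_allele[3] <- "A"; out$other_allele[3] <- "T"
  exp$eaf[3] <- 0.5; out$eaf[3] <- 0.5
  # SNP4: irreconcilable pair
  out$effect_allele[4] <- "A"; out$other_allele[4] <- "C"

  h <- harmonize(exp, out)
  expect_equal(h$variant_id, c("snp_0001", "snp_0002"))
  expect_equal(h$beta_out, c(0.1, -0.1))
  expect_equal(h$eaf_out, c(0.3, 0.7))
  log <- exclusions(h)
  expect_equal(log$reason[log$variant_id == "snp_0003"],
               "palindromic SNP (strict-exclude)")
  expect_equal(log$reason[log$variant_id == "snp_0004"], "allele mismatch")

  # conservation: every input SNP appears exactly once across set and log
  expect_setequal(c(h$variant_id, log$variant_id), exp$variant_id)
  expect_equal(length(c(h$variant_id, log$variant_id)), 4)

  # eaf inference keeps a palindromic SNP when frequencies are informative
  exp$eaf[3] <- 0.2; out$eaf[3] <- 0.22
  h2 <- harmonize(exp, out, palindrome_policy = "infer-eaf")
  expect_true("snp_0003" %in% h2$variant_id)
})

test_that("harmonization is involution-safe", {
  exp <- make_sumstats(5, beta = 0.1)
  out <- make_sumstats(5, beta = 0.05)
  out$effect_allele[2] <- "G"; out$other_allele[2] <- "A"
  h1 <- harmonize(exp, out)
  # feed the harmonized set back through as two aligned tables
  exp2 <- exp
  out2 <- tibble::tibble(
    variant_id = h1$variant_id,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out,
    pvalue = 0.01, n = 1000L
  )
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
})

test_that("GRS equals the brute-force weighted allele sum", {
  set.seed(21)
  G <- matrix(sample(0:2, 20, replace = TRUE), nrow = 5)
  w <- rnorm(4)
  # double-loop oracle
  oracle <- sapply(1:5, function(i) sum(sapply(1:4, function(j) w[j] * G[i, j])))
  expect_equal(build_grs(G, w), oracle)
  expect_equal(build_grs(G, rep(0, 4)), rep(0, 5))
  expect_equal(build_grs(G[, 1, drop = FALSE], 1), G[, 1])
  expect_error(build_grs(G, w[1:3]), "length")
  G[1, 1] <- NA
  expect_error(build_grs(G, w), "missing")
  # explicit imputation fills by 2 * eaf
  imp <- impute_genotypes(G, eaf = c(0.25, 0.3, 0.3, 0.3))
  expect_equal(imp[1, 1], 0.5)
})

test_that("instrument strength follows the F/R^2 identity and edge cases", {
  set.seed(4)
  s <- rnorm(300)
  x <- 0.4 * s + rnorm(300)
  d <- instrument_strength(s, x, k = 1)
  expect_equal(d$f_statistic,
               ((d$n - d$k - 1) / d$k) * d$r_squared / (1 - d$r_squared))
  # F increases with R^2 at fixed n, k: stronger signal, bigger F
  d2 <- instrument_strength(s, 2 * s + 0.1 * rnorm(300), k = 1)
  expect_gt(d2$r_squared, d$r_squared)
  expect_gt(d2$f_statistic, d$f_statistic)
  # perfect fit reports the +Inf sentinel
  expect_equal(instrument_strength(s, s)$f_statistic, Inf)
  expect_error(instrument_strength(rep(1, 300), x), "degenerate")
})

test_that("confounder screen reports effects per SD of score", {
  set.seed(6)
  s <- rnorm(500)         # unit-SD score: slope on itself is ~1 per SD
  covs <- tibble::tibble(
    self = s,
    linked = 0.1 * s + rnorm(500, sd = 0.05),
    noise = rnorm(500),
    constant = rep(1, 500)
  )
  scr <- confounder_screen(s, covs)
  expect_equal(attr(scr, "skipped"), "constant")
  self_row <- scr[scr$covariate == "self", ]
  expect_equal(self_row$beta, sd(s), tolerance = 1e-6)
  expect_lt(self_row$pvalue, 1e-10)
  linked <- scr[scr$covariate == "linked", ]
  expect_lt(abs(linked$beta - 0.1 * sd(s)), 3 * linked$se)
  expect_true(linked$flagged)
})

test_that("independent covariates are flagged at roughly the nominal 5% rate", {
  set.seed(12)
  flags <- replicate(200, {
    s <- rnorm(150)
    confounder_screen(s, tibble::tibble(z = rnorm(150)))$flagged
  })
  rate <- mean(flags)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
})
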
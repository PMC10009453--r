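test_that("reading parses well-formed tables and enforces row invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\ta\tg\t0.30\t0.10\t0.02\t1e-10\t50000",
               "rs2\tC\tT\t0.10\t-0.05\t0.01\t1e-6\t50000",
               "rs3\tG\tA\t0.45\t0.02\t0.02\t0.4\t50000"), path)
  ss <- read_sumstats(path, trait_type = "binary_disease")
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss), 3)
  expect_equal(ss$effect_allele, c("A", "C", "G"))  # upper-cased
  expect_equal(attr(ss, "n_dropped"), 0)

  # se = 0 row is dropped and tallied, not fatal
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\tA\tG\t0.3\t0.1\t0\t1e-10\t50000",
               "rs2\tA\tG\t0.3\t0.1\t0.02\t1e-10\t50000"), path)
  expect_message(ss <- read_sumstats(path, trait_type = "continuous"),
                 "1 invalid row")
  expect_equal(nrow(ss), 1)
  expect_equal(attr(ss, "n_dropped"), 1)
})

test_that("reading honours column maps and fails cleanly on bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MarkerName,A1,A2,freq,b,stderr,P,N",
               "rs1,A,G,0.3,0.1,0.02,1e-10,1000"), path)
  ss <- read_sumstats(path,
                      column_map = c(rsid = "MarkerName",
                                     effect_allele = "A1",
                                     other_allele = "A2", eaf = "freq",
                                     beta = "b", se = "stderr",
                                     pval = "P", n = "N"),
                      trait_type = "binary_disease")
  expect_equal(ss$rsid, "rs1")

  expect_error(read_sumstats(path, trait_type = "binary_disease"),
               "format error")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\tA\tG\t0.3\t0.1\t0\t1e-10\t1000"), path)
  expect_error(suppressMessages(
    read_sumstats(path, trait_type = "binary_disease")),
    "empty-input")
})

test_that("write/read round-trip preserves every field to 10 significant digits", {
  set.seed(42)
  J <- 50
  ss <- make_ss(beta = rnorm(J, 0.1, 0.05), se = runif(J, 0.005, 0.05),
                eaf = runif(J, 0.05, 0.95))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path, trait_type = "binary_disease",
                        trait_name = attr(ss, "trait_name"))
  expect_identical(back$rsid, ss$rsid)
  expect_identical(back$effect_allele, ss$effect_allele)
  expect_identical(back$other_allele, ss$other_allele)
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    expect_equal(signif(back[[col]], 10), signif(ss[[col]], 10))
  }
})

test_that("instrument selection is strictly below threshold and idempotent", {
  ss <- make_ss(beta = c(0.1, 0.1, 0.1), se = 0.02,
                pval = c(4e-8, 5e-8, 6e-8))
  sel <- select_instruments(ss, 5e-8)
  expect_equal(sel$pval, 4e-8)  # 5e-8 itself excluded: strict inequality

  expect_equal(nrow(select_instruments(ss, 1)), 3)
  ss2 <- make_ss(beta = rep(0.01, 4), se = 0.02, pval = rep(0.5, 4))
  expect_equal(nrow(select_instruments(ss2, 5e-8)), 0)

  twice <- select_instruments(select_instruments(ss, 5e-8), 5e-8)
  expect_equal(as.data.frame(twice), as.data.frame(sel))
})

test_that("LD pruning keeps the smallest p-value per correlated set", {
  ss <- make_ss(beta = c(0.2, 0.18), se = 0.02, pval = c(1e-10, 1e-9),
                rsid = c("rsA", "rsB"))
  ld <- matrix(c(1, 0.002, 0.002, 1), 2,
               dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  pruned <- ld_prune(ss, ld, 0.001)
  expect_equal(pruned$rsid, "rsA")  # r2 = 0.002 > 0.001 discards rsB

  # independent variants are all retained
  ld0 <- diag(2); dimnames(ld0) <- dimnames(ld)
  expect_equal(nrow(ld_prune(ss, ld0, 0.001)), 2)

  expect_error(ld_prune(ss, ld0[1, 1, drop = FALSE], 0.001), "missing-LD")
})

test_that("block pruning matches brute-force per-block minima and the pairwise bound", {
  set.seed(7)
  J <- 12
  blocks <- rep(1:3, each = 4)
  rsid <- sprintf("rs%02d", 1:J)
  ld <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0))
  diag(ld) <- 1
  dimnames(ld) <- list(rsid, rsid)
  pv <- runif(J, 1e-12, 1e-8)
  ss <- make_ss(beta = rep(0.1, J), se = 0.02, pval = pv, rsid = rsid)

  pruned <- ld_prune(ss, ld, 0.001)
  # brute force: within each block exactly the p-minimum survives
  expected <- vapply(1:3, function(b) rsid[blocks == b][which.min(pv[blocks == b])], "")
  expect_setequal(pruned$rsid, expected)

  # invariant: no retained pair exceeds the threshold (random instances)
  for (rep in 1:10) {
    m <- matrix(runif(J * J, 0, 0.01), J)
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(rsid, rsid)
    pr <- ld_prune(ss, m, 0.005)
    sub <- m[pr$rsid, pr$rsid, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] <= 0.005))
  }
})

test_that("mean F-statistic is the mean squared z and order-invariant", {
  expect_equal(mean_f_statistic(make_ss(beta = 0.1, se = 0.02)), 25)
  expect_equal(mean_f_statistic(make_ss(beta = c(0.08, 0.12),
                                        se = c(0.02, 0.02))),
               mean(c(16, 36)))

  set.seed(1)
  ss <- make_ss(beta = rnorm(100, 0.1, 0.03), se = runif(100, 0.01, 0.03))
  loop <- 0
  for (i in 1:100) loop <- loop + (ss$beta[i] / ss$se[i])^2 / 100
  expect_equal(mean_f_statistic(ss), loop)

  shuffled <- sumstats(as.data.frame(ss)[sample(100), ])
  expect_equal(mean_f_statistic(shuffled), mean_f_statistic(ss))

  expect_error(mean_f_statistic(select_instruments(ss, 1e-300)),
               "empty-input")
})

test_that("variant exclusion removes listed rows and tolerates absent ids", {
  ss <- make_ss(beta = c(0.1, 0.2, 0.3), se = 0.02,
                rsid = c("rs7903146", "rs2", "rs3"))
  out <- exclude_snps(ss, "rs7903146")
  expect_equal(out$rsid, c("rs2", "rs3"))

  expect_equal(as.data.frame(exclude_snps(ss, character(0))),
               as.data.frame(ss))
  expect_equal(nrow(exclude_snps(ss, ss$rsid)), 0)
  expect_message(exclude_snps(ss, "rs_absent"), "not present")
})
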
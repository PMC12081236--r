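make_table <- function(classification, outcomes = NULL) {
  n <- length(classification)
  if (is.null(outcomes)) outcomes <- replicate(n, NA_character_, simplify = FALSE)
  structure(data.frame(chrom = "c", pos = seq_len(n), ref = "A", alt = "T",
                       classification = classification),
            class = c("labeled_variant_table", "data.frame")) -> tab
  tab$outcomes <- outcomes
  tab
}

test_that("Wald interval matches the hand computation and clamps", {
  w <- wald_ci(5, 20)
  expect_equal(w$p, 25)
  # p +/- 1.96 sqrt(p(1-p)/n), computed independently
  half <- 1.96 * sqrt(0.25 * 0.75 / 20)
  expect_equal(w$ci, c(100 * (0.25 - half), 100 * (0.25 + half)),
               tolerance = 1e-12)
  expect_equal(round(w$ci, 0), c(6, 44))
  w0 <- wald_ci(0, 10)
  expect_equal(w0$p, 0)
  expect_equal(w0$ci[1], 0)
  w1 <- wald_ci(12, 12)
  expect_equal(w1$ci[2], 100)
})

test_that("spliceogenicity estimates equal a brute-force rescan", {
  set.seed(21)
  keys <- sample(c("DD2 standard", "DA9 context", "DD7 auxiliary"), 200,
                 replace = TRUE)
  cls <- ifelse(runif(200) < 0.6, "splice-altering", "normal")
  tab <- make_table(cls)
  est <- estimate_spliceogenicity(tab, keys)
  expect_equal(est$p[est$subgroup == "DD7 auxiliary"],
               100 * sum(cls == "splice-altering" & keys == "DD7 auxiliary") /
                 sum(keys == "DD7 auxiliary"))
  # permutation invariance of per-subgroup counts
  perm <- sample(200)
  est2 <- estimate_spliceogenicity(tab[perm, , drop = FALSE], keys[perm])
  expect_equal(est, est2, ignore_attr = TRUE)
  # k=3 n=12 reproduces the 25.0% worked value
  tab3 <- make_table(rep(c("splice-altering", "normal"), c(3, 9)))
  est3 <- estimate_spliceogenicity(tab3, rep("DD7 auxiliary", 12))
  expect_equal(est3$p, 25)
  expect_equal(est3$n, 12)
})

test_that("subgroup validation flags n and separation rules", {
  est <- data.frame(
    subgroup = c("DX1 standard", "DX1 context", "DX2 standard", "DX2 context",
                 "DX3 standard"),
    k = c(93, 80, 25, 3, 5), n = c(100, 100, 100, 100, 9),
    p = c(93, 80, 25.4, 3.3, 55), ci_low = 0, ci_high = 100,
    source = "user_estimate")
  rep <- validate_subgroups(est)
  expect_equal(rep$insufficient_n, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # 13-point separation flagged; DA9-like 22-point separation passes
  expect_equal(rep$low_separation, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("outcome aggregation is multi-label with the >20 reporting gate", {
  # 10 SAVs: 6 skipping only, 3 skipping+retention, 1 reported 'none'
  oc <- c(replicate(6, "exon_skipping", simplify = FALSE),
          replicate(3, c("exon_skipping", "intron_retention"), simplify = FALSE),
          list(character(0)))
  tab <- make_table(rep("splice-altering", 10), oc)
  prof <- aggregate_outcomes(tab, rep("donor_site", 10))$donor_site
  expect_equal(prof$n_reported, 10)
  expect_false(prof$reportable)
  expect_equal(unname(prof$percentages["exon_skipping"]), 90)
  expect_equal(unname(prof$percentages["intron_retention"]), 30)
  expect_equal(prof$multi_outcome_rate, 0.3)

  # every SAV with two outcomes: percentages sum to 200
  oc2 <- replicate(30, c("exon_skipping", "exon_extension"), simplify = FALSE)
  tab2 <- make_table(rep("splice-altering", 30), oc2)
  prof2 <- aggregate_outcomes(tab2, rep("ppt", 30))$ppt
  expect_true(prof2$reportable)
  expect_equal(sum(prof2$percentages), 200)

  # rows without outcome info do not enter the denominator
  oc3 <- c(replicate(5, "exon_skipping", simplify = FALSE),
           replicate(5, NA_character_, simplify = FALSE))
  tab3 <- make_table(rep("splice-altering", 10), oc3)
  expect_equal(aggregate_outcomes(tab3, rep("ppt", 10))$ppt$n_reported, 5)
})

test_that("evidence TSV loading filters labels and parses outcomes", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ev.tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tgenome_build\tclassification\toutcomes\tmethod",
    "chr1\t100\tA\tG\tsynthetic\tsplice-altering\texon_skipping,intron_retention\tassay",
    "chr1\t200\tC\tT\tsynthetic\tnormal\t\tassay",
    "chr1\t300\tG\tA\tsynthetic\tlow-frequency\t\tassay",
    "chr1\t400\tG\tA\tsynthetic\tsplice-altering\tnone\tassay"), f)
  expect_message(tab <- load_evidence_table(f), "non-binary")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$outcomes[[1]], c("exon_skipping", "intron_retention"))
  expect_equal(tab$outcomes[[3]], character(0))
  expect_error(load_evidence_table(f, strict = TRUE), "unknown classification")
})

test_that("splice regions map as in the outcome windows", {
  expect_equal(splice_region("+5", "donor"), "donor_site")
  expect_equal(splice_region("E+1", "acceptor"), "acceptor_motif")
  expect_equal(splice_region("-3", "acceptor"), "acceptor_motif")
  expect_equal(splice_region("-15", "acceptor"), "ppt")
  expect_equal(splice_region("-30", "acceptor"), "branchpoint_region")
})

test_that("simulated outcome tables recover the configured proportions", {
  # oracle: the generator's outcome scheme is calibrated so realized
  # marginals match the configured map; at n = 2000 each marginal must land
  # within +/-3 percentage points of its target
  cfg <- generator_config(seed = 77)
  fake_panel <- list(
    variants = list(variant_record("c", 1, "A", "T")),
    subgroups = "DD2 standard")  # p = 99.9: nearly all rows are SAVs
  tab <- generate_labeled_table(fake_panel, cfg, n_replicates = 2000)
  sav <- tab[tab$classification == "splice-altering", ]
  n <- nrow(sav)
  for (nm in names(cfg$outcome_map)) {
    got <- 100 * sum(grepl(nm, sav$outcomes, fixed = TRUE)) / n
    expect_lt(abs(got - 100 * cfg$outcome_map[[nm]]), 3)
  }
  multi <- mean(grepl(",", sav$outcomes, fixed = TRUE))
  expect_lt(abs(multi - cfg$multi_outcome_rate), 0.03)
})
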
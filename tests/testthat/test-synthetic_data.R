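test_that("identical seeds produce byte-identical output", {
  s1 <- generate_compliant_transcript(generator_config(seed = 123, n_exons = 4))
  s2 <- generate_compliant_transcript(generator_config(seed = 123, n_exons = 4))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$tm$exons, s2$tm$exons)
  s3 <- generate_compliant_transcript(generator_config(seed = 124, n_exons = 4))
  expect_false(identical(s1$genome, s3$genome))
  # written FASTA bytes are identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_dataset(d1, s1)
  write_simulated_dataset(d2, s2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
})

test_that("infeasible and degenerate configurations behave as designed", {
  expect_error(generate_compliant_transcript(
    generator_config(intron_length = c(50L, 60L))), "infeasible")
  # intron length forced to 70: exons fail the intron_length item
  sim70 <- generate_compliant_transcript(
    generator_config(seed = 9, n_exons = 4, intron_length = c(70L, 70L)))
  res <- evaluate_checklist(sim70$tm, 2, sim70$genome)
  expect_equal(res$items$intron_length_upstream$verdict, "fail")
  # degenerate sampling produces checklist failures
  deg <- generate_compliant_transcript(
    generator_config(seed = 9, n_exons = 6, degenerate = TRUE))
  verdicts <- vapply(2:5, function(i)
    evaluate_checklist(deg$tm, i, deg$genome)$overall, character(1))
  expect_true(any(verdicts != "pass"))
})

test_that("planted ground truth matches what the checklist finds", {
  sim <- generate_compliant_transcript(generator_config(seed = 55, n_exons = 6))
  for (j in seq_along(sim$truth)) {
    ctx <- extract_splice_context(sim$tm, j, sim$genome)
    bp <- find_branchpoints(ctx$acceptor_intronic)
    expect_true(sim$truth[[j]]$bp_distance %in% bp$distance)
    expect_equal(substr(ctx$donor_intronic, 1, 2), "GT")
  }
})

test_that("the full recipe panel classifies to its requested subgroups", {
  sim <- generate_compliant_transcript(generator_config(seed = 8, n_exons = 25))
  panel <- generate_variant_panel(sim$tm, sim$genome)
  expect_length(panel$skipped, 0)
  recipes <- names(heurosplice:::panel_recipes())
  expect_equal(panel$subgroups, recipes)
  # requesting more subgroups than introns fails loudly
  small <- generate_compliant_transcript(generator_config(seed = 8, n_exons = 3))
  expect_error(generate_variant_panel(small$tm, small$genome), "introns")
})

test_that("labeled tables follow the configured Bernoulli truths", {
  fake <- list(variants = list(variant_record("c", 1, "A", "T"),
                               variant_record("c", 2, "C", "G")),
               subgroups = c("DD1 standard", "DA9 context"))
  cfg <- generator_config(seed = 4)
  tab <- generate_labeled_table(fake, cfg, n_replicates = 400)
  # p = 100 subgroup: every row splice-altering
  dd1 <- tab[tab$subgroup == "DD1 standard", ]
  expect_true(all(dd1$classification == "splice-altering"))
  # p = 3.3 subgroup: few positives
  da9 <- tab[tab$subgroup == "DA9 context", ]
  expect_lt(mean(da9$classification == "splice-altering"), 0.1)

  # p = 0.5 at n = 10,000 concentrates near 0.5
  cfg2 <- generator_config(seed = 6,
                           spliceogenicity_map = c("X standard" = 50))
  fake2 <- list(variants = list(variant_record("c", 1, "A", "T")),
                subgroups = "X standard")
  tab2 <- generate_labeled_table(fake2, cfg2, n_replicates = 10000)
  expect_gt(mean(tab2$classification == "splice-altering"), 0.49)
  expect_lt(mean(tab2$classification == "splice-altering"), 0.51)

  # outcome map collapsed on one outcome: every SAV lists it
  cfg3 <- generator_config(seed = 6, outcome_map = c(exon_skipping = 1),
                           multi_outcome_rate = 0)
  tab3 <- generate_labeled_table(fake, cfg3, n_replicates = 50)
  sav3 <- tab3[tab3$classification == "splice-altering", ]
  expect_true(all(sav3$outcomes == "exon_skipping"))
})

test_that("classify -> estimate closes the loop on simulated truth", {
  sim <- generate_compliant_transcript(generator_config(seed = 14, n_exons = 25))
  keys <- c("DD6 standard", "DA1 context", "DA9 standard", "DD8 auxiliary")
  panel <- generate_variant_panel(sim$tm, sim$genome, keys)
  cfg <- generator_config(seed = 14)
  tab <- generate_labeled_table(panel, cfg, n_replicates = 150)
  # re-classify every row from scratch and re-estimate
  assigned <- vapply(seq_len(nrow(tab)), function(i) {
    v <- variant_record(tab$chrom[i], tab$pos[i], tab$ref[i], tab$alt[i])
    a <- classify_snv(v, sim$tm, panel$genome)
    paste(a$rule_id, a$subgroup)
  }, character(1))
  expect_equal(unique(assigned[tab$subgroup == keys[1]]), keys[1])
  est <- estimate_spliceogenicity(tab, assigned)
  for (k in keys) {
    truth <- cfg$spliceogenicity_map[[k]]
    row <- est[est$subgroup == k, ]
    expect_lt(abs(row$p - truth), 12)   # binomial noise at n = 150
  }
})
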
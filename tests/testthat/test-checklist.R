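test_that("theoretical intron minima follow from the spacing constraints", {
  tmin <- theoretical_intron_minimum()
  expect_equal(tmin$absolute_min_nt, 62L)
  expect_equal(tmin$low_risk_min_nt, 77L)
  # additivity: raising the branchpoint window lower bound shifts both
  cfg <- checklist_config(bp_window_nt = c(20L, 50L))
  expect_equal(theoretical_intron_minimum(cfg)$absolute_min_nt, 65L)
})

test_that("count_ppt enforces the nine-pyrimidine minimum at its boundary", {
  # window of 24 nt ending at -1; -24..-5 are the first 20 positions
  mk <- function(n_py) {
    paste0(paste(rep(c("T", "A"), c(n_py, 20 - n_py)), collapse = ""), "ACAG")
  }
  expect_true(count_ppt(mk(9))$passes_minimum)
  expect_false(count_ppt(mk(8))$passes_minimum)
  expect_equal(count_ppt(mk(9))$pyrimidines_in_window, 9L)
})

test_that("strong-PPT definition: 12 consecutive or 17 total in -24..-4", {
  # 12 consecutive Ts then purines; strength window -24..-4
  w1 <- paste0(strrep("T", 12), strrep("A", 9), "CAG")  # 24 nt
  r1 <- count_ppt(w1)
  expect_equal(r1$max_consecutive, 12L)
  expect_true(r1$is_strong)
  # 11 consecutive only, 11 total -> not strong
  w2 <- paste0(strrep("T", 11), strrep("A", 10), "CAG")
  expect_false(count_ppt(w2)$is_strong)
  # 17 scattered pyrimidines with max run 4
  w3 <- paste0(strrep("TTTTA", 4), "C", "CAG")   # -24..-4: TTTTA x4 + C
  r3 <- count_ppt(w3)
  expect_equal(r3$total_in_strength_window, 17L)
  expect_equal(r3$max_consecutive, 4L)
  expect_true(r3$is_strong)
  # N in the window -> indeterminate
  expect_true(is.na(count_ppt(paste0("N", strrep("T", 23)))$is_strong))
})

test_that("branchpoint search respects the motif and the 17-50 nt window", {
  # build a -50..-1 region: all C, then plant motifs
  base <- strrep("C", 50)
  plant <- function(region, d, triplet) {
    # place triplet so its A sits at distance d
    n <- nchar(region)
    substr(region, n - d - 1L, n - d + 1L) <- triplet
    region
  }
  r <- plant(base, 25, "TGA")
  bp <- find_branchpoints(r)
  expect_equal(bp$position, -25)
  expect_equal(bp$distance, 25)
  # A at -10: below the 17 nt minimum, rejected
  expect_equal(nrow(find_branchpoints(plant(base, 10, "TTA"))), 0)
  # A at -50 accepted, at -51 rejected
  base55 <- strrep("C", 55)
  expect_equal(nrow(find_branchpoints(plant(base55, 50, "TCA"))), 1)
  expect_equal(nrow(find_branchpoints(plant(base55, 51, "TCA"))), 0)
  # YNA motif accepts C at the -2 context position, TNA does not
  r2 <- plant(base, 30, "CCA")
  expect_equal(nrow(find_branchpoints(r2)), 0)
  expect_equal(nrow(find_branchpoints(r2, motif = "YNA")), 1)
})

test_that("AG-exclusion zone flags -13..-6 but tolerates -5", {
  # AGYAG|G layout: AG with A at -5
  w1 <- paste0(strrep("C", 45), "AGCAG")
  r1 <- check_agez(w1)
  expect_true(r1$pass)
  expect_length(r1$violating_AG_positions, 0)
  # AG with A at -8
  w2 <- paste0(strrep("C", 42), "AG", "CCC", "CAG")
  r2 <- check_agez(w2)
  expect_false(r2$pass)
  expect_equal(r2$violating_AG_positions, -8L)
  # no AG at all
  expect_true(check_agez(strrep("C", 50))$pass)
})

test_that("checklist passes a compliant exon and fails designed violations", {
  toy <- toy_transcript()
  res <- evaluate_checklist(toy$tm, 2, toy$genome)
  expect_equal(res$overall, "pass")
  expect_equal(res$items$intron_length_upstream$verdict, "pass")
  expect_equal(res$items$donor_motif$verdict, "pass")
  expect_equal(res$items$branchpoint$verdict, "pass")

  # shorten the upstream intron to 79 nt: intron_length fails
  tm79 <- toy$tm
  tm79$exons$start[2] <- tm79$exons$start[2] - 21L  # intron1 100 -> 79
  res79 <- evaluate_checklist(tm79, 2, toy$genome)
  expect_equal(res79$items$intron_length_upstream$verdict, "fail")
  expect_equal(res79$overall, "fail")

  # last exon of 118 nt fails, 119 passes
  tm118 <- toy$tm
  tm118$exons$end[3] <- tm118$exons$start[3] + 118L
  expect_equal(evaluate_checklist(tm118, 3, toy$genome)$items$exon_length$verdict,
               "fail")
  tm119 <- toy$tm
  tm119$exons$end[3] <- tm119$exons$start[3] + 119L
  expect_equal(evaluate_checklist(tm119, 3, toy$genome)$items$exon_length$verdict,
               "pass")
})

test_that("tightening any single threshold never turns a fail into a pass", {
  toy <- toy_transcript()
  base_cfg <- checklist_config()
  base <- evaluate_checklist(toy$tm, 2, toy$genome, base_cfg)
  tighter <- list(
    checklist_config(min_intron_nt = 120L),
    checklist_config(ppt_min_pyrimidines = 19L),
    checklist_config(min_exon_nt = list(first = 30L, internal = 60L, last = 119L)),
    checklist_config(bp_window_nt = c(24L, 50L))
  )
  rank <- c(pass = 3, indeterminate = 2, fail = 1)
  for (cfg in tighter) {
    res <- evaluate_checklist(toy$tm, 2, toy$genome, cfg)
    for (nm in names(base$items)) {
      expect_lte(rank[res$items[[nm]]$verdict], rank[base$items[[nm]]$verdict])
    }
  }
})

test_that("manual and in-silico modes agree on motif extremes", {
  toy <- toy_transcript()
  suppressMessages({
    man <- evaluate_checklist(toy$tm, 2, toy$genome, mode = "manual")
    sil <- evaluate_checklist(toy$tm, 2, toy$genome, mode = "in_silico")
  })
  # motif-perfect toy donor passes both modes
  expect_equal(man$items$donor_motif$verdict, "pass")
  expect_equal(sil$items$donor_motif$verdict, "pass")
  # destroy the donor GT entirely: both modes fail the donor item
  g2 <- toy$genome
  dpos <- heurosplice:::rel_to_genomic(toy$tm, 2, "donor", "+1")
  substr(g2[["chrT"]], dpos, dpos + 1L) <- "AA"
  suppressMessages({
    man2 <- evaluate_checklist(toy$tm, 2, g2, mode = "manual")
    sil2 <- evaluate_checklist(toy$tm, 2, g2, mode = "in_silico")
  })
  expect_equal(man2$items$donor_motif$verdict, "fail")
  expect_equal(sil2$items$donor_motif$verdict, "fail")
})
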
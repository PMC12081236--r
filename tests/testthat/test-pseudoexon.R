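# Fixtures with very long introns so deep-intronic positions exist; strong
# planted sites use the scoring model's consensus sequences.

deep_fixture <- function(seed = 11) {
  generate_compliant_transcript(generator_config(
    seed = seed, n_exons = 3, intron_length = c(2000L, 2000L)))
}

# Plant a consensus acceptor ending (boundary after AG) at 1-based genomic
# position `apos` (plus strand); 23-mer window with strong PPT.
plant_acceptor <- function(genome, chrom, apos) {
  acc <- paste0(strrep("T", 17), "CAG", "GAA")  # -20..E+3 consensus-ish
  substr(genome[[chrom]], apos - 19L, apos + 3L) <- acc
  genome
}

test_that("mechanism attribution: canonical dinucleotide creation", {
  fx <- deep_fixture()
  tm <- fx$tm; g <- fx$genome
  pos <- introns(tm)$start[1] + 1000L
  # force the local ref so the variant completes a GT
  substr(g[[tm$chrom]], pos, pos + 1L) <- "AT"
  v <- variant_record(tm$chrom, pos, "A", "G")
  m <- attribute_mechanism(v, tm, g)
  expect_equal(m$category, "created_donor_GT")
  expect_equal(m$site_pos, pos)
  # an AG-completing variant
  substr(g[[tm$chrom]], pos, pos + 1L) <- "CG"
  m2 <- attribute_mechanism(variant_record(tm$chrom, pos, "C", "A"), tm, g)
  expect_equal(m2$category, "created_acceptor_AG")
})

test_that("mechanism attribution: strengthening vs unresolved", {
  fx <- deep_fixture(13)
  tm <- fx$tm; g <- fx$genome
  apos <- introns(tm)$start[1] + 1200L
  g <- plant_acceptor(g, tm$chrom, apos)
  # weaken one PPT base, then the variant restores it (alt > ref, both pass)
  wpos <- apos - 10L
  substr(g[[tm$chrom]], wpos, wpos) <- "A"
  v <- variant_record(tm$chrom, wpos, "A", "T")
  m <- attribute_mechanism(v, tm, g)
  expect_equal(m$category, "strengthened_existing_site")
  expect_gt(m$alt_score, m$ref_score)
  expect_true("PPT strengthened" %in% m$notes)

  # a variant with no candidate site anywhere: unresolved
  fx2 <- deep_fixture(17)
  pos2 <- introns(fx2$tm)$start[1] + 900L
  g2 <- fx2$genome
  substr(g2[[fx2$tm$chrom]], pos2 - 1L, pos2 + 1L) <- "CCC"
  m3 <- attribute_mechanism(variant_record(fx2$tm$chrom, pos2, "C", "A"),
                            fx2$tm, g2)
  expect_true(m3$category %in% c("unresolved", "new_candidate_other"))
})

test_that("variants inside heuristic windows are redirected", {
  fx <- deep_fixture()
  tm <- fx$tm
  pos <- heurosplice:::rel_to_genomic(tm, 1, "donor", "+3")
  ref <- substr(fx$genome[[tm$chrom]], pos, pos)
  v <- variant_record(tm$chrom, pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  res <- predict_pseudoexon(v, tm, fx$genome)
  expect_true(res$redirect)
  expect_error(attribute_mechanism(v, tm, fx$genome), "DD/DA pathway")
})

test_that("partner search respects the 31-750 nt window and relaxation", {
  models <- list(donor = score_model("donor_9mer"),
                 acceptor = score_model("acceptor_23mer"))
  cfg <- pseudoexon_config()
  # created acceptor at index 100 of a synthetic region; plant partner GTs
  set.seed(99)
  region <- paste(sample(c("A", "C"), 2000, replace = TRUE), collapse = "")
  p <- 1000L
  substr(region, p, p + 1L) <- "AG"
  plant_donor <- function(region, q) {
    substr(region, q - 3L, q + 5L) <- "CAGGTAAGT"
    region
  }
  # exon would be 25 nt (q = p + 2 + 25): too short
  q_short <- p + 27L
  # exon 100 nt: retained via relaxation if score >= 3
  q_mid <- p + 101L + 1L
  # exon 800 nt: too long
  q_long <- p + 801L + 1L
  region <- plant_donor(plant_donor(plant_donor(region, q_short), q_mid), q_long)
  cands <- find_partner_sites(list(site_index = p, site_type = "acceptor"),
                              region, models, cfg)
  expect_true(all(cands$exon_length >= 31 & cands$exon_length <= 750))
  expect_false(q_short %in% (cands$donor_index + 1L))
  expect_false(q_long %in% (cands$donor_index + 1L))
  mid <- cands[cands$donor_index == q_mid - 1L, ]
  expect_equal(nrow(mid), 1)
  expect_gte(mid$partner_score, 3)
  expect_true(mid$retained)
})

test_that("monotonicity: raising the strength threshold never adds candidates", {
  fx <- deep_fixture(23)
  tm <- fx$tm; g <- fx$genome
  pos <- introns(tm)$start[1] + 1000L
  substr(g[[tm$chrom]], pos, pos + 1L) <- "AT"
  g <- plant_acceptor(g, tm$chrom, pos - 120L)
  v <- variant_record(tm$chrom, pos, "A", "G")
  res_lo <- predict_pseudoexon(v, tm, g, config = pseudoexon_config())
  res_hi <- predict_pseudoexon(v, tm, g,
                               config = pseudoexon_config(strength_fraction = 0.9,
                                                          relax_min_score = 6))
  kept_lo <- res_lo$candidates[res_lo$candidates$retained, c("acceptor_index", "donor_index")]
  kept_hi <- res_hi$candidates[res_hi$candidates$retained, c("acceptor_index", "donor_index")]
  expect_true(nrow(kept_hi) <= nrow(kept_lo))
  if (nrow(kept_hi) > 0) {
    expect_true(all(paste(kept_hi[[1]], kept_hi[[2]]) %in%
                      paste(kept_lo[[1]], kept_lo[[2]])))
  }
})

test_that("a planted pseudoexon design is recovered end to end", {
  fx <- deep_fixture(29)
  tm <- fx$tm; g <- fx$genome
  # design: acceptor boundary at apos, created donor GT 120 nt downstream
  dpos <- introns(tm)$start[1] + 1000L
  apos <- dpos - 121L     # AG ends at apos; first exonic base is apos + 1
  g <- plant_acceptor(g, tm$chrom, apos)
  substr(g[[tm$chrom]], dpos, dpos + 1L) <- "AT"
  substr(g[[tm$chrom]], dpos - 3L, dpos - 1L) <- "CAG"  # donor exonic consensus
  substr(g[[tm$chrom]], dpos + 2L, dpos + 5L) <- "AAGT"
  v <- variant_record(tm$chrom, dpos, "A", "G")
  res <- predict_pseudoexon(v, tm, g)
  expect_equal(res$mechanism$category, "created_donor_GT")
  expect_false(is.null(res$top))
  expect_equal(res$top$acceptor_pos, apos + 1L)
  expect_equal(res$top$donor_pos, dpos - 1L)
  expect_equal(res$top$exon_length, 120L)
})
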
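# Narrated worked examples are regression-locked: each fixture variant must
# reproduce the printed subgroup and spliceogenicity exactly.

narrated_cases <- list(
  list(key = "DD2 standard", p = 99.9),
  list(key = "DD1 standard", p = 100.0),
  list(key = "DD1 context", p = 81.2),
  list(key = "DD4 standard", p = 99.7),
  list(key = "DD5 standard", p = 95.4),
  list(key = "DD6 standard", p = 95.1),
  list(key = "DD6 auxiliary", p = 28.6),
  list(key = "DD7 standard", p = 94.0),
  list(key = "DD7 auxiliary", p = 25.0),
  list(key = "DD8 standard", p = 93.6),
  list(key = "DD8 auxiliary", p = 25.0),
  list(key = "DA1 standard", p = 97.7),
  list(key = "DA1 context", p = 78.0),
  list(key = "DA1 auxiliary", p = 28.0),
  list(key = "DA2 standard", p = 99.7),
  list(key = "DA3 standard", p = 99.2),
  list(key = "DA6 standard", p = 66.7),
  list(key = "DA9 standard", p = 25.4),
  list(key = "DA9 context", p = 3.3),
  list(key = "DA9 auxiliary", p = 4.6)
)

test_that("every narrated subgroup is reproduced with its printed value", {
  sim <- generate_compliant_transcript(generator_config(seed = 2026,
                                                        n_exons = 25))
  keys <- vapply(narrated_cases, `[[`, character(1), "key")
  panel <- generate_variant_panel(sim$tm, sim$genome, keys)
  expect_length(panel$skipped, 0)
  expect_equal(panel$subgroups, keys)
  tab <- load_rule_table()
  for (i in seq_along(panel$variants)) {
    a <- classify_snv(panel$variants[[i]], sim$tm, panel$genome, tab)
    want <- narrated_cases[[i]]
    expect_equal(paste(a$rule_id, a$subgroup), want$key)
    expect_equal(a$annotation$p, want$p)
    expect_gt(length(a$trace), 0)
  }
})

test_that("routing follows the position-to-heuristic map", {
  tab <- load_rule_table()
  expect_setequal(route("+5", "donor", tab), c("DD4", "DD6"))
  expect_setequal(route("+1", "donor", tab), c("DD1", "DD2"))
  expect_true(all(c("DA1", "DA9") %in% route("-15", "acceptor", tab)))
  r <- route("E+50", "donor", tab)
  expect_length(r, 0)
  expect_equal(attr(r, "signal"), "not_covered")
})

test_that("base cascades compare as specified, including ties", {
  expect_equal(cascade_compare("A", "T", "E-1"), "less_preferred")
  expect_equal(cascade_compare("C", "T", "+3"), "equal")
  expect_equal(cascade_compare("A", "C", "E+1"), "equal")
  expect_equal(cascade_compare("C", "A", "+3"), "more_preferred")
  expect_true(is.na(cascade_compare("N", "A", "E-1")))
})

test_that("creates_dinucleotide reports created positions only", {
  # -10 C>A with G at -9 creates AG indexed at the first base
  expect_equal(creates_dinucleotide("TCGT", "TAGT", "AG"), 2L)
  # +3 A>G with T at +4 creates GT
  expect_equal(creates_dinucleotide("GTAT", "GTGT", "GT",
                                    labels = c("+1", "+2", "+3", "+4")), "+3")
  # destroying without creating yields nothing
  expect_length(creates_dinucleotide("TAGT", "TCGT", "AG"), 0)
})

test_that("classification is deterministic and strand-equivalent", {
  sim <- generate_compliant_transcript(generator_config(seed = 31, n_exons = 8))
  keys <- c("DD4 standard", "DA1 standard", "DA9 context", "DD7 standard")
  panel <- generate_variant_panel(sim$tm, sim$genome, keys)
  mir <- mirror_transcript(sim$tm, panel$genome)
  L <- nchar(panel$genome[[sim$tm$chrom]])
  for (i in seq_along(panel$variants)) {
    v <- panel$variants[[i]]
    a1 <- classify_snv(v, sim$tm, panel$genome)
    a2 <- classify_snv(v, sim$tm, panel$genome)
    expect_identical(a1$trace, a2$trace)
    expect_identical(a1$rule_id, a2$rule_id)
    # mirrored transcript: same variant in mirrored coordinates
    vm <- variant_record(v$chrom, L - v$pos + 1L, revcomp(v$ref), revcomp(v$alt))
    am <- classify_snv(vm, mir$tm, mir$genome)
    expect_equal(paste(am$rule_id, am$subgroup), keys[i])
    expect_equal(format_relpos(parse_relpos(am$label)), a1$label)
  }
})

test_that("every SNV in the heuristic windows gets an assignment or flag", {
  sim <- generate_compliant_transcript(generator_config(seed = 5, n_exons = 4))
  tm <- sim$tm; genome <- sim$genome
  tab <- load_rule_table()
  labels <- list(donor = c("E-3", "E-2", "E-1", paste0("+", 1:6)),
                 acceptor = c(paste0("-", 1:50), "E+1"))
  n_checked <- 0L
  for (sc in names(labels)) {
    for (lab in labels[[sc]]) {
      pos <- heurosplice:::rel_to_genomic(tm, 2, sc, lab)
      ref <- substr(genome[[tm$chrom]], pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        a <- classify_snv(variant_record(tm$chrom, pos, ref, alt), tm, genome,
                          tab, site_class = sc)
        ok <- (!is.na(a$rule_id) && !is.null(a$annotation)) || length(a$flags) > 0
        expect_true(ok, info = paste(sc, lab, ref, ">", alt))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, 3L * (9L + 51L))
})

test_that("U12 introns are flagged unsupported, not classified", {
  sim <- generate_compliant_transcript(generator_config(seed = 5, n_exons = 4))
  tm <- sim$tm
  tm$intron_classes[1] <- "U12"
  pos <- heurosplice:::rel_to_genomic(tm, 1, "donor", "+1")
  v <- variant_record(tm$chrom, pos, substr(sim$genome[[tm$chrom]], pos, pos), "A")
  a <- classify_snv(v, tm, sim$genome)
  expect_true("U12_unsupported" %in% a$flags)
  expect_true(is.na(a$rule_id))
})

test_that("indeterminate N context is flagged, never passed", {
  sim <- generate_compliant_transcript(generator_config(seed = 5, n_exons = 4))
  g <- sim$genome
  # N at E-1 makes the +5 path indeterminate at the context predicate
  e1 <- heurosplice:::rel_to_genomic(sim$tm, 1, "donor", "E-1")
  substr(g[[sim$tm$chrom]], e1, e1) <- "N"
  p5 <- heurosplice:::rel_to_genomic(sim$tm, 1, "donor", "+5")
  g2 <- g
  substr(g2[[sim$tm$chrom]], p5, p5) <- "G"
  a <- classify_snv(variant_record(sim$tm$chrom, p5, "G", "A"), sim$tm, g2)
  expect_true("indeterminate" %in% a$flags)
})

test_that("rule-table validation enforces the schema and inclusion rules", {
  tab <- load_rule_table()
  expect_equal(sort(unique(tab$annotations$rule_id[grepl("^DD", tab$annotations$rule_id)])),
               sort(paste0("DD", 1:12)))
  expect_true(all(tab$annotations$n >= 10))

  mangle <- function(f) {
    raw <- jsonlite::fromJSON(system.file("extdata", "heuristic_rules.json",
                                          package = "heurosplice"),
                              simplifyVector = FALSE)
    raw <- f(raw)
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
    path
  }
  # n = 9 violates the 10-variant inclusion rule
  p1 <- mangle(function(r) { r$annotations[[1]]$n <- 9L; r })
  expect_error(load_rule_table(p1), "10-variant inclusion rule")
  # unknown predicate rejected
  p2 <- mangle(function(r) {
    r$paths$donor[[1]]$branches[[1]]$when[[1]]$pred <- "phase_of_moon"; r
  })
  expect_error(load_rule_table(p2), "unknown predicate")
  # assignment without annotation rejected
  p3 <- mangle(function(r) {
    r$paths$donor[[1]]$branches[[1]]$assign <- list("DD99", "standard"); r
  })
  expect_error(load_rule_table(p3), "without annotation")
})

test_that("indels decompose into per-position matches with a max summary", {
  sim <- generate_compliant_transcript(generator_config(seed = 17, n_exons = 4))
  tm <- sim$tm; g <- sim$genome
  # deletion of the donor GT of intron 1: DD2 standard among matches
  dpos <- heurosplice:::rel_to_genomic(tm, 1, "donor", "+1")
  ref3 <- substr(g[[tm$chrom]], dpos, dpos + 1L)
  expect_equal(ref3, "GT")
  res <- classify_indel(variant_record(tm$chrom, dpos, "GT", ""), tm, g)
  keys <- vapply(res$assignments, function(a)
    paste(a$rule_id, a$subgroup), character(1))
  expect_true("DD2 standard" %in% keys)
  expect_equal(res$summary$annotation$p, 99.9)

  # insertion creating AG at -8 of intron 2: DA1 standard among matches
  apos <- heurosplice:::rel_to_genomic(tm, 2, "acceptor", "-9")
  anchor <- substr(g[[tm$chrom]], apos, apos)
  g2 <- g
  # make sure -8 region has no AG already, then insert 'AG' after -9
  ins <- variant_record(tm$chrom, apos, anchor, paste0(anchor, "AG"))
  res2 <- classify_indel(ins, tm, g2)
  keys2 <- vapply(res2$assignments, function(a)
    paste(a$rule_id, a$subgroup), character(1))
  expect_true("DA1 standard" %in% keys2)

  # deletion swallowing a whole exon is not covered
  s2 <- tm$exons$start[2]; e2 <- tm$exons$end[2]
  big <- variant_record(tm$chrom, s2 - 5L,
                        substr(g[[tm$chrom]], s2 - 5L, e2 + 5L), "")
  res3 <- classify_indel(big, tm, g)
  expect_true("not_covered" %in% res3$summary$flags)
})
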
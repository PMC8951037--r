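split_vcf <- system.file("extdata", "melt_split_synthetic.vcf", package = "sinephylo")
del_vcf <- system.file("extdata", "melt_deletion_synthetic.vcf", package = "sinephylo")

test_that("MELT VCF parsing assigns mode-aware genotype polarity", {
  cs <- read_melt_vcf(split_vcf, "split")
  cd <- read_melt_vcf(del_vcf, "deletion")
  # split mode: ALT is the insertion
  first <- cs[cs$locus_id == "chr1:1000:VES", ]
  expect_equal(first$genotype[first$species == "sppA"], "het")
  expect_equal(first$genotype[first$species == "sppB"], "hom_present")
  expect_equal(first$genotype[first$species == "sppC"], "hom_absent")
  expect_equal(first$assess[1], 5L)
  # deletion mode: ALT deletes a reference insertion, so 1/1 = absent
  dfirst <- cd[cd$locus_id == "chr1:1500:VES", ]
  expect_equal(dfirst$genotype[dfirst$species == "sppA"], "hom_present")
  expect_equal(dfirst$genotype[dfirst$species == "sppC"], "hom_absent")
  expect_true(all(is.na(cd$assess)))
  expect_equal(cs$genotype[cs$species == "sppD" & cs$locus_id == "chr2:1200:VES"],
               "missing")
})

test_that("call filtering keeps PASS and (split-mode) ASSESS >= 2", {
  calls <- data.frame(
    species = "X", locus_id = sprintf("l%d", 1:5),
    mode = c("split", "split", "split", "deletion", "deletion"),
    genotype = "hom_present",
    filter_status = c("PASS", "PASS", "lc", "PASS", "lc"),
    assess = c(3L, 1L, 5L, NA, NA))
  f <- filter_melt_calls(calls)
  expect_equal(f$locus_id, c("l1", "l4"))
  expect_equal(unname(attr(f, "dropped")["low_assess"]), 1L)
  expect_equal(unname(attr(f, "dropped")["non_pass"]), 2L)
  # boundary: assess == 1 is dropped, == 2 kept
  calls$filter_status <- "PASS"
  calls$assess <- c(1L, 2L, 3L, NA, NA)
  expect_equal(filter_melt_calls(calls)$locus_id, c("l2", "l3", "l4", "l5"))
})

test_that("malformed records abort by default and can be skipped", {
  calls <- data.frame(species = c("X", NA), locus_id = c("l1", "l2"),
                      mode = "split", genotype = "het",
                      filter_status = "PASS", assess = 5L)
  expect_error(filter_melt_calls(calls), "malformed")
  expect_warning(f <- filter_melt_calls(calls, on_error = "skip"), "skipped")
  expect_equal(nrow(f), 1)
})

test_that("build_matrix maps genotypes to states with het as presence", {
  calls <- data.frame(
    species = c("X", "Y", "Z", "X", "Y"),
    locus_id = c("l1", "l1", "l1", "l2", "l2"),
    mode = "split",
    genotype = c("het", "hom_absent", "hom_present", "hom_absent", "missing"),
    filter_status = "PASS", assess = 5L)
  m <- build_matrix(calls, taxa = c("X", "Y", "Z"))
  expect_equal(unname(m["X", "l1"]), 1L)   # het counts as presence
  expect_equal(unname(m["Y", "l1"]), 0L)
  expect_equal(unname(m["Z", "l1"]), 1L)
  expect_true(is.na(m["Y", "l2"]))         # explicit missing genotype
  expect_true(is.na(m["Z", "l2"]))         # no record at all
  expect_error(build_matrix(calls, taxa = c("X", "Y")), "not in")
})

test_that("conflicting duplicates resolve by mode or error within mode", {
  base <- data.frame(species = "X", locus_id = "l1", genotype = "hom_present",
                     filter_status = "PASS", assess = NA_integer_)
  two <- rbind(base, base)
  two$mode <- c("split", "deletion")
  two$genotype <- c("hom_present", "hom_absent")
  expect_warning(m <- build_matrix(two, taxa = "X"), "Deletion-mode")
  expect_equal(unname(m["X", "l1"]), 0L)
  two$mode <- c("split", "split")
  expect_error(build_matrix(two, taxa = "X"), "l1")
})

test_that("complete and informative filters behave and are idempotent", {
  m <- pa_matrix(rbind(a = c(1L, 1L, NA, 1L, 1L), b = c(0L, 1L, 1L, 1L, 0L),
                       c = c(0L, 0L, 0L, 1L, 1L), d = c(1L, 0L, 1L, 1L, 0L)))
  mc <- filter_complete(m)
  expect_equal(ncol(mc), 4)
  expect_identical(pa_states(filter_complete(mc)), pa_states(mc))
  mi <- filter_informative(mc)
  # all-present column and singleton-ish columns go
  expect_true(all(colSums(mi) >= 2 & colSums(mi) <= nrow(mi) - 2))
  expect_identical(pa_states(filter_informative(mi)), pa_states(mi))
  # relaxed Dollo-informative rule keeps (n-1)-presence columns
  expect_gte(ncol(filter_informative(mc, min_absent = 1)), ncol(mi))
  expect_error(filter_informative(mc, min_present = 3, min_absent = 3), "exceeds")
  # missing data must be cleared first
  expect_error(filter_informative(m), "missing")
})

test_that("heterozygosity is the het fraction of genotyped calls", {
  calls <- data.frame(
    species = rep(c("X", "Y", "Z"), c(1000, 3, 1)),
    locus_id = paste0("l", 1:1004), mode = "split",
    genotype = c(rep("hom_present", 996), rep("het", 4),
                 rep("het", 3), "missing"),
    filter_status = "PASS", assess = 5L)
  h <- suppressWarnings(heterozygosity(calls))
  expect_equal(unname(h["X"]), 0.004)
  expect_equal(unname(h["Y"]), 1.0)
  expect_warning(hz <- heterozygosity(calls, "Z"), "undefined")
  expect_true(is.na(hz))
})

test_that("matrix round-trips losslessly across all three dialects", {
  set.seed(71)
  for (rep in 1:3) {
    m <- random_pa(11, 100)
    # sprinkle missing data; tsv and nexus must preserve it
    idx <- sample(length(m), 30)
    mm <- unclass(m); mm[idx] <- NA
    m <- pa_matrix(mm)
    for (dialect in c("nexus01", "phylip01", "tsv")) {
      p <- tempfile()
      write_pa_matrix(m, p, dialect)
      m2 <- read_pa_matrix(p, dialect)
      expect_equal(rownames(m2), rownames(m))
      expect_identical(unname(pa_states(m2)), unname(pa_states(m)))
      if (dialect != "phylip01") expect_equal(colnames(m2), colnames(m))
      unlink(p)
    }
  }
})

test_that("matrix parsing rejects malformed input with position info", {
  p <- tempfile(fileext = ".phy")
  writeLines(c("2 4", "A 0101", "B 010"), p)
  expect_error(read_pa_matrix(p), "declares 4")
  writeLines(c("3 4", "A 0101", "B 0100"), p)
  expect_error(read_pa_matrix(p), "3 taxa")
  writeLines(c("2 4", "A 01X1", "B 0100"), p)
  expect_error(read_pa_matrix(p), "invalid state symbol 'X'")
  unlink(p)
})

test_that("end-to-end VCF merge reproduces known matrix states", {
  calls <- rbind(read_melt_vcf(split_vcf, "split"),
                 read_melt_vcf(del_vcf, "deletion"))
  f <- filter_melt_calls(calls)
  m <- suppressWarnings(build_matrix(f))
  expect_setequal(rownames(m), c("sppA", "sppB", "sppC", "sppD"))
  expect_equal(unname(m["sppA", "chr1:1000:VES"]), 1L)
  expect_equal(unname(m["sppC", "chr1:1500:VES"]), 0L)   # deletion-mode 1/1
  expect_false("chr1:4000:VES" %in% colnames(m))          # ASSESS=1 dropped
  expect_false("chr1:6000:VES" %in% colnames(m))          # lc filter dropped
  mi <- filter_informative(filter_complete(m))
  expect_true(all(colSums(is.na(mi)) == 0))
})
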
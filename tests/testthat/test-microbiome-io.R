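# MetaPhlAn-style table reading, cross-study merging, filtering,
# binarization and stratification. All fixtures are built in code.

test_that("the reader keeps species rows, drops other ranks, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "clade_name\tsampleA\tsampleB",
    "k__Bacteria\t90\t80",
    "k__Bacteria|g__Gemella\t50\t40",
    "k__Bacteria|g__Gemella|s__Gemella_morbillorum\t12.5\t0",
    "k__Bacteria|g__Gemella|s__Gemella_morbillorum|t__SGB0001\t12.5\t0",
    "k__Bacteria|g__Parvimonas|s__Parvimonas_micra\t7.25\t30",
    "UNKNOWN\t10\t20"
  ), path)
  tab <- read_profiles(path, study = "toy")
  expect_s3_class(tab, "abundance_table")
  expect_setequal(rownames(tab$values),
                  c("k__Bacteria|g__Gemella|s__Gemella_morbillorum",
                    "k__Bacteria|g__Parvimonas|s__Parvimonas_micra",
                    "unclassified"))
  expect_equal(tab$values["k__Bacteria|g__Parvimonas|s__Parvimonas_micra", ],
               c(sampleA = 7.25, sampleB = 30))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(tab, out)
  back <- read_profiles(out, study = "toy")
  expect_identical(back$values, tab$values)
})

test_that("malformed abundance cells fail with row/column context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_name\ts1",
               "k__B|s__X\t1.5",
               "k__B|s__Y\toops"), path)
  expect_error(read_profiles(path), "non-numeric.*s1")
})

test_that("cross-study merging keeps universal species and conserves totals", {
  tables <- toy_three_studies()
  before <- do.call(c, lapply(tables, function(tb) colSums(tb$values)))
  merged <- merge_profiles(tables)
  expect_setequal(setdiff(rownames(merged$values), "unclassified"),
                  c(sp("shared_a"), sp("shared_b")))
  # dropped abundances moved into unclassified, per sample
  expect_equal(merged$values["unclassified", "s1"], 40 + 2 + 1)
  expect_equal(merged$values["unclassified", "s5"], 35)
  after <- colSums(merged$values)
  expect_equal(after, before[names(after)], tolerance = 1e-9)
  # identical single-study input is unchanged
  solo <- merge_profiles(tables[1])
  expect_equal(solo$values[rownames(tables[[1]]$values), ],
               tables[[1]]$values)
  dup <- tables[c(1, 1)]
  expect_error(merge_profiles(dup), "duplicate sample ids")
})

test_that("abundance and prevalence filters remove rule-violating species only", {
  samples <- sprintf("s%02d", 1:25)
  vals <- rbind(
    common = c(rep(8, 25)),              # kept
    low_ra = c(rep(0.5, 25)),            # peak RA 0.5% < 1% -> removed
    rare = c(2, rep(0, 24)),             # 1/25 = 4% of samples < 5% -> removed
    never = rep(0, 25),                  # detected nowhere -> removed
    unclassified = rep(50, 25))
  rownames(vals) <- c(sp("common"), sp("low_ra"), sp("rare"), sp("never"),
                      "unclassified")
  colnames(vals) <- samples
  tab <- abundance_table(vals)
  before <- colSums(tab$values)
  filtered <- filter_species(tab)
  expect_setequal(setdiff(rownames(filtered$values), "unclassified"),
                  sp("common"))
  expect_equal(colSums(filtered$values), before, tolerance = 1e-9)
  expect_equal(filtered$values["unclassified", "s01"], 50 + 0.5 + 2)
  # zero thresholds: only the never-detected species can go (prev 0 < 0 is
  # false, so nothing is removed at all)
  untouched <- filter_species(tab, ra_threshold = 0, prevalence_threshold = 0)
  expect_identical(untouched$values, tab$values)
})

test_that("binarization is a strict >0 indicator, idempotent, without unclassified", {
  vals <- rbind(a = c(0, 0.003, 12), b = c(1, 0, 0), unclassified = c(50, 60, 70))
  rownames(vals) <- c(sp("a"), sp("b"), "unclassified")
  colnames(vals) <- c("s1", "s2", "s3")
  tab <- abundance_table(vals)
  bin <- binarize(tab)
  expect_equal(unname(bin), rbind(c(0, 1, 1), c(1, 0, 0)))
  expect_false("unclassified" %in% rownames(bin))
  expect_identical(binarize(bin), bin)
})

test_that("stratification splits by sex and the 65-year age boundary", {
  vals <- matrix(c(5, 6, 7, 8), nrow = 1,
                 dimnames = list(sp("x"), c("s1", "s2", "s3", "s4")))
  tab <- abundance_table(vals)
  metadata <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    class = "CRC",
    sex = c("female", "male", "male", NA),
    age = c(65, 66, 40, 80))
  by_age <- stratify_samples(tab, metadata, by = "age")
  expect_setequal(colnames(by_age$adult$values), c("s1", "s3"))  # 65 is adult
  expect_setequal(colnames(by_age$senior$values), c("s2", "s4")) # 66 is senior
  expect_warning(by_sex <- stratify_samples(tab, metadata, by = "sex"),
                 "excluded")
  expect_setequal(colnames(by_sex$male$values), c("s2", "s3"))
  expect_equal(colnames(by_sex$female$values), "s1")
  # union of strata covers every sample with a usable key
  expect_setequal(c(colnames(by_age$adult$values),
                    colnames(by_age$senior$values)),
                  metadata$sample_id)
  expect_error(stratify_samples(tab, metadata[, 1:2], by = "sex"), "no 'sex'")
})

test_that("metadata reading drops adenoma samples with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass\tsex\tage\tstudy",
               "s1\tCRC\tmale\t60\tst1",
               "s2\tadenoma\tfemale\t55\tst1",
               "s3\tcontrol\tfemale\t70\tst1"), path)
  expect_warning(md <- read_metadata(path), "adenoma")
  expect_setequal(md$sample_id, c("s1", "s3"))
})

test_that("classifier-ready conversion transposes, binarizes and labels", {
  vals <- rbind(c(0, 5), c(3, 0), c(10, 20))
  rownames(vals) <- c(sp("a"), sp("b"), "unclassified")
  colnames(vals) <- c("s1", "s2")
  tab <- abundance_table(vals)
  metadata <- data.frame(sample_id = c("s1", "s2"),
                         class = c("CRC", "control"))
  ds <- as_labeled_dataset(tab, metadata)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(dim(ds$values), c(2, 2))
  expect_equal(unname(ds$values), rbind(c(0, 1), c(1, 0)))
  expect_equal(ds$labels, c("CRC", "control"))
})
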
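# Invariant-T-cell subtype rules, database lookups and the TIL analyses.

test_that("canonical V/J pairs map to their invariant subtypes exactly", {
  expect_equal(annotate_subtype("TRAV10", "TRAJ18")$subtype, "iNKT")
  expect_equal(annotate_subtype("TRAV1-2", "TRAJ33")$subtype, "MAIT")
  expect_equal(annotate_subtype("TRBV5-1", "TRBJ2-7")$subtype, "NONE")
  # prefix- and allele-insensitive matching
  expect_equal(annotate_subtype("V10", "J18")$subtype, "iNKT")
  expect_equal(annotate_subtype("TRAV10*01", "TRAJ18*01")$subtype, "iNKT")
  expect_equal(annotate_subtype("trav1-2", "traj33")$subtype, "MAIT")
  # a TRB-locus V10 is not an iNKT alpha chain
  expect_equal(annotate_subtype("TRBV10", "TRAJ18")$subtype, "NONE")
  expect_warning(bad <- annotate_subtype("garbled", "TRAJ18"), "unparseable")
  expect_equal(bad$subtype, "NONE")
})

test_that("subtype rules are total over a gene-name grid", {
  vs <- c(tcrstrat:::TRAV_GENES, tcrstrat:::TRBV_GENES)
  js <- c(tcrstrat:::TRAJ_GENES, tcrstrat:::TRBJ_GENES)
  grid <- expand.grid(v = vs, j = js, stringsAsFactors = FALSE)
  calls <- annotate_subtype(grid$v, grid$j)
  expect_true(all(calls$subtype %in% c("iNKT", "MAIT", "NONE")))
  expect_equal(sum(calls$subtype == "iNKT"),
               sum(grid$v == "TRAV10" & grid$j == "TRAJ18"))
  expect_equal(sum(calls$subtype == "MAIT"),
               sum(grid$v == "TRAV1-2" & grid$j == "TRAJ33"))
})

test_that("database entry counts equal a linear scan of the raw records", {
  raw <- data.frame(cdr3_aa = c("CAF", "CAF", "CSF", "CTW", "CSF", "CSF"),
                    prevalence = c(2, 14, 1, 1, 1, 1))
  db <- public_db(raw)
  counts <- db_entry_counts(c("CAF", "CSF", "CMISSINGF"), db)
  oracle <- vapply(c("CAF", "CSF", "CMISSINGF"), function(k) {
    sum(raw$prevalence[raw$cdr3_aa == k])
  }, numeric(1))
  expect_equal(counts, oracle)
  expect_equal(unname(counts["CMISSINGF"]), 0)
})

test_that("occurrence counting matches a brute-force double loop", {
  db <- til_db(list(s1 = c("CXF", "CYF"), s2 = "CYF", s3 = "CZF"),
               c(s1 = "OV", s2 = "OV", s3 = "BRCA"))
  expect_equal(count_samples_with_any(c("CXF", "CZF"), db), 2L)
  expect_equal(count_samples_with_any("CQQF", db), 0L)
  expect_error(count_samples_with_any(character(0), db), "empty query")

  set.seed(13)
  keys <- paste0("C", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][1:15], "F")
  samples <- lapply(1:20, function(i) sample(keys, sample(2:8, 1)))
  names(samples) <- paste0("t", 1:20)
  db2 <- til_db(samples, setNames(sample(c("OV", "LUAD"), 20, TRUE),
                                  names(samples)))
  for (i in 1:5) {
    q <- sample(keys, 3)
    oracle <- sum(vapply(samples, function(s) any(q %in% s), logical(1)))
    expect_equal(count_samples_with_any(q, db2), oracle)
  }
  # monotonicity: growing the query never lowers the count
  q <- sample(keys, 2)
  expect_gte(count_samples_with_any(c(q, sample(keys, 1)), db2),
             count_samples_with_any(q, db2))
})

test_that("the bootstrap null applies the plus-one rule", {
  db <- til_db(list(s1 = "CAAF", s2 = "CBBF"), c(s1 = "OV", s2 = "OV"))
  universe <- paste0("C", LETTERS[10:20], "F")   # none occur in the database
  nd <- bootstrap_occurrence_null(3, universe, db, observed = 0, B = 200,
                                  seed = 1)
  expect_true(all(nd$draws == 0))
  expect_equal(nd$p_value, 1)                    # ties count against the query
  nd2 <- bootstrap_occurrence_null(3, universe, db, observed = 1, B = 1000,
                                   seed = 1)
  expect_equal(nd2$p_value, 1 / 1001)            # exceeds every draw
  expect_lt(nd2$p_value, 1e-3)
  # p falls weakly as the observed count grows, draws fixed
  ps <- vapply(0:3, function(obs) {
    bootstrap_occurrence_null(3, universe, db, obs, B = 100, seed = 5)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # reproducible given seed; k larger than the universe errors
  expect_identical(bootstrap_occurrence_null(3, universe, db, 0, 50, 7)$draws,
                   bootstrap_occurrence_null(3, universe, db, 0, 50, 7)$draws)
  expect_error(bootstrap_occurrence_null(99, universe, db, 0, 10, 1),
               "exceeds universe")
})

test_that("per-cancer fractions partition the overall occurrence count", {
  db <- til_db(list(s1 = c("CXF"), s2 = c("CYF"), s3 = c("CZF"), s4 = "CXF"),
               c(s1 = "OV", s2 = "OV", s3 = "BRCA", s4 = "LUAD"))
  br <- per_cancer_breakdown(c("CXF", "CYF"), db)
  expect_equal(br$fraction[br$cancer_type == "LUAD"], 1)
  expect_equal(br$fraction[br$cancer_type == "BRCA"], 0)
  expect_equal(br$fraction[br$cancer_type == "OV"], 1)
  expect_equal(sum(br$n_positive), count_samples_with_any(c("CXF", "CYF"), db))

  spec <- small_spec()
  db2 <- generate_til_db(spec, n_tumors = 60, clones_per_tumor = c(5, 20))
  q <- db2$samples[[1]][1:2]
  br2 <- per_cancer_breakdown(q, db2)
  expect_equal(sum(br2$n_samples), 60L)
  expect_equal(sum(br2$n_positive), count_samples_with_any(q, db2))
  expect_true(all(br2$fraction >= 0 & br2$fraction <= 1))
})
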
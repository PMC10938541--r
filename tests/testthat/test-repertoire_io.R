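# Clonotype-table parsing, CDR3 aggregation and the cohort matrix.

write_airr <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("AIRR tables parse with computed frequencies and QC filtering", {
  p <- write_airr(data.frame(junction_aa = c("CASSF", "CAIRW", "CASSLKETQYF"),
                             v_call = c("TRBV2*01", "TRAV10", "TRBV5-1"),
                             j_call = c("TRBJ1-1", "TRAJ18", "TRBJ2-5"),
                             duplicate_count = c(5, 3, 2)))
  rep <- read_clonotypes(p, "AIRR", "S1")
  expect_equal(rep$total_umis, 10)
  expect_equal(sort(rep$clonotypes$frequency, decreasing = TRUE),
               c(0.5, 0.3, 0.2))
  expect_equal(rep$clonotypes$v_gene[rep$clonotypes$cdr3_aa == "CASSF"],
               "TRBV2")  # allele stripped

  # nonproductive CDR3s are dropped and the total recomputed
  p2 <- write_airr(data.frame(junction_aa = c("CASSF", "CASS*YF", "CAS_F"),
                              v_call = "TRBV2", j_call = "TRBJ1-1",
                              duplicate_count = c(4, 6, 2)))
  rep2 <- read_clonotypes(p2, "AIRR", "S2")
  expect_equal(nrow(rep2$clonotypes), 1L)
  expect_equal(rep2$total_umis, 4)
  expect_equal(rep2$clonotypes$frequency, 1)
})

test_that("format errors name the missing column; fully unusable files error", {
  p <- write_airr(data.frame(junction_aa = "CASSF", v_call = "TRBV2",
                             duplicate_count = 1))
  expect_error(read_clonotypes(p, "AIRR", "S1"), "j_call")
  p2 <- write_airr(data.frame(junction_aa = "CASS*F", v_call = "TRBV2",
                              j_call = "TRBJ1-1", duplicate_count = 1))
  expect_error(read_clonotypes(p2, "AIRR", "S1"), "no usable")
  expect_error(read_clonotypes(tempfile(), "AIRR", "S1"), "no such file")
})

test_that("MiXCR-dialect round trip is the identity on clone fields", {
  spec <- small_spec(n_case = 1, n_control = 1)
  rep <- generate_cohort(spec)[[1]]
  expect_gt(nrow(rep$clonotypes), 50)
  p <- tempfile(fileext = ".tsv")
  write_clonotypes(rep, p, "MIXCR")
  back <- read_clonotypes(p, "MIXCR", rep$sample_id, rep$group)
  key <- function(r) {
    cl <- r$clonotypes[order(r$clonotypes$cdr3_aa), ]
    cl[, c("cdr3_aa", "v_gene", "j_gene", "count")]
  }
  expect_equal(key(back), key(rep), ignore_attr = TRUE)

  p2 <- tempfile(fileext = ".tsv")
  write_clonotypes(rep, p2, "AIRR")
  back2 <- read_clonotypes(p2, "AIRR", rep$sample_id)
  expect_equal(key(back2), key(rep), ignore_attr = TRUE)
})

test_that("aggregation merges CDR3 duplicates, keeps totals, picks max-count V/J", {
  rep <- repertoire("S1", data.frame(
    cdr3_aa = c("CASSLKETQYF", "CASSLKETQYF", "CAIRW"),
    v_gene = c("TRBV2", "TRBV9", "TRAV10"),
    j_gene = c("TRBJ1-1", "TRBJ2-2", "TRAJ18"),
    chain = c("TRB", "TRB", "TRA"),
    count = c(4, 6, 5)))
  agg <- aggregate_by_cdr3(rep)
  expect_equal(nrow(agg$clonotypes), 2L)
  merged <- agg$clonotypes[agg$clonotypes$cdr3_aa == "CASSLKETQYF", ]
  expect_equal(merged$count, 10)
  expect_equal(merged$v_gene, "TRBV9")   # highest-count constituent
  expect_equal(agg$total_umis, rep$total_umis)

  # already-unique repertoires pass through unchanged
  expect_identical(aggregate_by_cdr3(agg), agg)
})

test_that("aggregation conserves UMIs and never adds records (random fixtures)", {
  set.seed(42)
  for (i in 1:10) {
    keys <- sample(c("CAF", "CSF", "CTW", "CGGF", "CLLW"), 12, replace = TRUE)
    rep <- repertoire("S", data.frame(
      cdr3_aa = keys, v_gene = "TRBV2", j_gene = "TRBJ1-1", chain = "TRB",
      count = sample(1:20, 12, replace = TRUE)))
    agg <- aggregate_by_cdr3(rep)
    expect_equal(agg$total_umis, rep$total_umis)
    expect_lte(nrow(agg$clonotypes), nrow(rep$clonotypes))
    expect_false(anyDuplicated(agg$clonotypes$cdr3_aa) > 0)
    expect_equal(sum(agg$clonotypes$frequency), 1, tolerance = 1e-12)
  }
})

test_that("cohort matrix holds per-sample frequencies with zeros for absences", {
  a <- make_rep(c(CANF = 1), "A")
  b <- make_rep(c(CAYF = 1), "B")
  m <- build_cohort_matrix(list(a, b))
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(sum(m$values == 0), 2L)
  expect_equal(unname(colSums(m$values)), c(1, 1))

  # brute-force completeness on random small cohorts
  set.seed(7)
  keys <- replicate(40, paste0("C", paste(sample(LETTERS[LETTERS %in%
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]], 6, replace = TRUE),
    collapse = ""), "F"))
  reps <- lapply(1:5, function(i) {
    k <- sample(keys, sample(5:20, 1))
    make_rep(setNames(sample(1:30, length(k), replace = TRUE), k),
             paste0("S", i))
  })
  m2 <- build_cohort_matrix(reps)
  for (i in seq_along(reps)) {
    cl <- reps[[i]]$clonotypes
    for (r in rownames(m2$values)) {
      expected <- if (r %in% cl$cdr3_aa) cl$frequency[cl$cdr3_aa == r] else 0
      expect_equal(m2$values[r, reps[[i]]$sample_id], expected)
    }
  }
  expect_true(all(abs(colSums(m2$values) - 1) < 1e-9))

  expect_error(build_cohort_matrix(list(a, a)), "duplicate sample_id")
})

test_that("matrix row order is deterministic: sharing, then mass, then key", {
  a <- make_rep(c(CAAF = 2, CEEF = 6, CCCF = 2), "A")
  b <- make_rep(c(CAAF = 5, CDDF = 5), "B")
  m <- build_cohort_matrix(list(a, b))
  expect_equal(rownames(m$values)[1], "CAAF")        # shared by both
  expect_equal(rownames(m$values)[2], "CEEF")        # largest mass among rest
  expect_equal(rownames(m$values), c("CAAF", "CEEF", "CDDF", "CCCF"))
})

test_that("public databases load grouped, deduplicated and ordered", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(cdr3_aa = c("CAVF", "CAVF", "CAW"),
                         prevalence = c(2, 3, ""),
                         metadata = "x"),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  db <- load_public_db(p, "VDJDB_LIKE")
  expect_equal(nrow(db), 2L)
  expect_equal(db$prevalence[db$cdr3_aa == "CAVF"], 5)   # grouped and summed
  expect_equal(db$prevalence[db$cdr3_aa == "CAW"], 1)    # empty prevalence -> 1
  expect_equal(attr(db, "source"), "VDJDB_LIKE")

  # 100 records with 10 duplicated keys collapse to 90
  set.seed(3)
  keys <- replicate(120, paste0("C", paste(sample(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 5), collapse = ""), "F"))
  keys <- unique(keys)[1:90]
  recs <- data.frame(cdr3_aa = c(keys, keys[1:10]), prevalence = 1)
  db2 <- public_db(recs)
  expect_equal(nrow(db2), 90L)
  expect_true(all(diff(db2$prevalence) <= 0))

  # malformed rows are skipped with a warning; all-malformed errors
  expect_warning(db3 <- public_db(data.frame(cdr3_aa = c("CAVF", "cx1", ""),
                                             prevalence = c(1, 1, 1))),
                 "malformed")
  expect_equal(nrow(db3), 1L)
  expect_error(suppressWarnings(
    public_db(data.frame(cdr3_aa = "x", prevalence = 1))), "all database rows")
})
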
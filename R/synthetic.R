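# Synthetic cohort / database generator.
#
# Emulates the statistical structure of a bulk TCR-seq case-control study:
#   * a shared background clone pool with Zipf (power-law) abundance weights,
#     so repertoires are heavy-tailed and naturally share their common clones;
#   * per-sample UMI depths spanning orders of magnitude (log-uniform), with a
#     configurable number of deliberately undersized repertoires emulating the
#     samples an exclusion filter should drop;
#   * implanted group-discriminative clones with group-conditional presence
#     probabilities and frequency scales.
# Every generator is a pure function of (spec, seed); components draw from
# documented substreams of the single spec seed so each stage can be
# regenerated in isolation.

TRAV_GENES <- paste0("TRAV", c("1-1", "1-2", "2", "3", "4", "5", "6", "8-1",
                               "9-2", "10", "12-1", "13-1", "17", "19", "21",
                               "26-1", "29", "35", "38-1", "41"))
TRAJ_GENES <- paste0("TRAJ", c(4, 6, 9, 12, 15, 18, 20, 23, 28, 31, 33, 37,
                               40, 43, 45, 48, 49, 52, 54, 57))
TRBV_GENES <- paste0("TRBV", c("2", "4-1", "5-1", "6-1", "7-2", "7-9", "9",
                               "10-3", "11-2", "12-3", "13", "15", "18",
                               "19", "20-1", "24-1", "25-1", "27", "28",
                               "30"))
TRBJ_GENES <- paste0("TRBJ", c("1-1", "1-2", "1-3", "1-4", "1-5", "1-6",
                               "2-1", "2-2", "2-3", "2-4", "2-5", "2-6",
                               "2-7"))

#' Published signature clones used as default implants
#'
#' The discriminative CDR3s reported for the two selection routes, shipped as
#' fixture constants with canonical invariant-T-cell V/J annotations where the
#' subtype is known (iNKT: TRAV10/TRAJ18; MAIT: TRAV1-2/TRAJ33) and plausible
#' synthetic TRB annotations otherwise. These are documentation/fixture
#' constants; the package does not claim to re-derive them from data.
#'
#' @param p_case,p_control presence probability per group.
#' @param freq_case,freq_control mean within-sample frequency when present.
#' @return data.frame of implanted-clone definitions.
#' @export
topdown_signature_clones <- function(p_case = 1, p_control = 0,
                                     freq_case = 1e-3, freq_control = 1e-3) {
  implanted_clones(
    cdr3_aa = c("CVVSDRGSTLGRLYF", "CASSLKETQYF", "CASSLAYEQYF"),
    v_gene = c("TRAV10", "TRBV5-1", "TRBV7-9"),
    j_gene = c("TRAJ18", "TRBJ2-5", "TRBJ2-7"),
    p_case = p_case, p_control = p_control,
    freq_case = freq_case, freq_control = freq_control)
}

#' @rdname topdown_signature_clones
#' @export
topclones_signature_clones <- function(p_case = 0.95, p_control = 0.05,
                                       freq_case = 1e-3, freq_control = 1e-3) {
  implanted_clones(
    cdr3_aa = c("CAVRDSNYQLIW", "CVVSDRGSTLGRLYF", "CAVLDSNYQLIW",
                "CASSLGETQYF"),
    v_gene = c("TRAV1-2", "TRAV10", "TRAV1-2", "TRBV7-2"),
    j_gene = c("TRAJ33", "TRAJ18", "TRAJ33", "TRBJ2-5"),
    p_case = p_case, p_control = p_control,
    freq_case = freq_case, freq_control = freq_control)
}

#' Define implanted discriminative clones
#'
#' @param cdr3_aa,v_gene,j_gene clone identities and annotations.
#' @param p_case,p_control per-group presence probabilities in [0,1].
#' @param freq_case,freq_control mean relative abundance when present, in (0,1).
#' @export
implanted_clones <- function(cdr3_aa, v_gene, j_gene,
                             p_case = 1, p_control = 0,
                             freq_case = 1e-3, freq_control = 1e-3) {
  stopifnot(all(p_case >= 0 & p_case <= 1), all(p_control >= 0 & p_control <= 1),
            all(freq_case > 0 & freq_case < 1),
            all(freq_control > 0 & freq_control < 1))
  data.frame(cdr3_aa = cdr3_aa, v_gene = v_gene, j_gene = j_gene,
             p_present_case = rep_len(p_case, length(cdr3_aa)),
             p_present_control = rep_len(p_control, length(cdr3_aa)),
             freq_scale_case = rep_len(freq_case, length(cdr3_aa)),
             freq_scale_control = rep_len(freq_control, length(cdr3_aa)),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study design the pipeline targets: 34 case and 51
#' control repertoires, two of the controls generated with extremely small
#' repertoires (so an exclusion filter retains 83), per-sample UMI depths
#' log-uniform between 1e4 and 1e6, Zipf exponent 2 over a shared background
#' pool of 5e4 clones, and three implanted case-only clones at frequency 1e-3.
#'
#' @param n_case,n_control group sizes.
#' @param umis_range integer range of per-sample UMI depths (log-uniform).
#' @param clone_size_exponent Zipf/power-law exponent (> 1).
#' @param background_pool_size size of the shared background clone pool.
#' @param cdr3_length_range CDR3 amino-acid length range.
#' @param implanted data.frame from [implanted_clones()] (may have 0 rows).
#' @param n_undersized number of control repertoires generated below any
#'   reasonable exclusion threshold.
#' @param undersized_umis depth of the undersized repertoires.
#' @param seed base seed; all generators derive substreams from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_case = 34, n_control = 51,
                           umis_range = c(1e4, 1e6),
                           clone_size_exponent = 2,
                           background_pool_size = 5e4,
                           cdr3_length_range = c(10, 18),
                           implanted = topdown_signature_clones(),
                           n_undersized = 2, undersized_umis = 500,
                           seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, clone_size_exponent > 1,
            length(umis_range) == 2, umis_range[1] <= umis_range[2],
            length(cdr3_length_range) == 2,
            cdr3_length_range[1] >= 5, cdr3_length_range[2] <= 40,
            n_undersized >= 0, n_undersized <= n_control)
  if (nrow(implanted) > 0 &&
      (sum(implanted$freq_scale_case) > 1 || sum(implanted$freq_scale_control) > 1)) {
    stop("implanted frequency scales sum above 1")
  }
  structure(list(n_case = n_case, n_control = n_control,
                 umis_range = umis_range,
                 clone_size_exponent = clone_size_exponent,
                 background_pool_size = background_pool_size,
                 cdr3_length_range = cdr3_length_range,
                 implanted = implanted,
                 n_undersized = n_undersized,
                 undersized_umis = undersized_umis,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Random canonical CDR3 amino-acid strings: 'C' + random core + 'F'/'W'
#' @noRd
random_cdr3 <- function(n, length_range) {
  len <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  core_len <- len - 2L
  chars <- sample(AA_ALPHABET, sum(core_len), replace = TRUE)
  core <- vapply(split(chars, rep(seq_len(n), core_len)),
                 paste0, character(1), collapse = "")
  paste0("C", core, sample(c("F", "W"), n, replace = TRUE, prob = c(0.8, 0.2)))
}

#' The shared background clone pool (substream 1 of the spec seed)
#' @noRd
background_pool <- function(spec) {
  with_seed(substream(spec$seed, 1L), {
    n <- spec$background_pool_size
    seqs <- character(0)
    while (length(seqs) < n) {
      seqs <- unique(c(seqs, random_cdr3(n - length(seqs) + 100L,
                                         spec$cdr3_length_range)))
    }
    seqs <- seqs[seq_len(n)]
    seqs <- setdiff(seqs, spec$implanted$cdr3_aa)  # implants are never background
    n <- length(seqs)
    chain <- sample(c("TRA", "TRB"), n, replace = TRUE)
    v <- ifelse(chain == "TRA", sample(TRAV_GENES, n, replace = TRUE),
                sample(TRBV_GENES, n, replace = TRUE))
    j <- ifelse(chain == "TRA", sample(TRAJ_GENES, n, replace = TRUE),
                sample(TRBJ_GENES, n, replace = TRUE))
    w <- seq_len(n)^(-spec$clone_size_exponent)
    data.frame(cdr3_aa = seqs, v_gene = v, j_gene = j, chain = chain,
               weight = w / sum(w), stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort of repertoires
#'
#' @param spec a [synthetic_spec()].
#' @return list of aggregated `tcr_repertoire` objects (cases first, labelled
#'   "OC"; controls labelled "HD"; the last `n_undersized` controls are the
#'   undersized ones).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pool <- background_pool(spec)
  n <- spec$n_case + spec$n_control
  groups <- c(rep("OC", spec$n_case), rep("HD", spec$n_control))
  ids <- c(sprintf("OC_%02d", seq_len(spec$n_case)),
           sprintf("HD_%02d", seq_len(spec$n_control)))
  depths <- with_seed(substream(spec$seed, 2L), {
    d <- round(exp(stats::runif(n, log(spec$umis_range[1]),
                                log(spec$umis_range[2]))))
    if (spec$n_undersized > 0) {
      d[seq(n - spec$n_undersized + 1L, n)] <- spec$undersized_umis
    }
    d
  })
  lapply(seq_len(n), function(i) {
    with_seed(substream(spec$seed, 100L + i), {
      depth <- depths[i]
      imp <- spec$implanted
      imp_rows <- NULL
      if (nrow(imp) > 0) {
        p <- if (groups[i] == "OC") imp$p_present_case else imp$p_present_control
        f <- if (groups[i] == "OC") imp$freq_scale_case else imp$freq_scale_control
        present <- stats::runif(nrow(imp)) < p
        if (any(present)) {
          f_i <- f[present] * exp(stats::rnorm(sum(present), 0, 0.25))
          cnt <- pmax(1L, stats::rpois(sum(present), f_i * depth))
          imp_rows <- data.frame(cdr3_aa = imp$cdr3_aa[present],
                                 v_gene = imp$v_gene[present],
                                 j_gene = imp$j_gene[present],
                                 chain = ifelse(grepl("^TRB", imp$v_gene[present]),
                                                "TRB", "TRA"),
                                 count = cnt, stringsAsFactors = FALSE)
        }
      }
      n_bg <- depth - sum(if (is.null(imp_rows)) 0 else imp_rows$count)
      if (n_bg < 1) stop("implanted clones exceed sample depth")
      draws <- sample.int(nrow(pool), n_bg, replace = TRUE, prob = pool$weight)
      cnt <- tabulate(draws, nbins = nrow(pool))
      hit <- cnt > 0
      bg <- data.frame(cdr3_aa = pool$cdr3_aa[hit], v_gene = pool$v_gene[hit],
                       j_gene = pool$j_gene[hit], chain = pool$chain[hit],
                       count = cnt[hit], stringsAsFactors = FALSE)
      repertoire(ids[i], rbind(imp_rows, bg), groups[i])
    })
  })
}

#' Generate three public-database fixtures with overlapping top lists
#'
#' Builds VDJdb-, McPAS- and TCGA-TIL-like prevalence tables whose top-10
#' lists share `overlap` sequences. For `overlap < 10` each shared sequence
#' appears in exactly two of the three lists, so the union of the three
#' top-10 lists has `30 - overlap` members; `overlap = 10` is the degenerate
#' identical-lists case (union 10). Implanted clones are placed among the
#' shared top entries so the top-clones route can recover them, and the union
#' is constructed so that `n_in_cohort` of its members occur in cohorts
#' generated from the same spec (the rest are novel sequences absent from the
#' background pool).
#'
#' @param spec a [synthetic_spec()].
#' @param overlap number of sequences shared between top-10 lists (0..10).
#' @param n_top length of each database's top list.
#' @param n_in_cohort members of the union that occur in the cohort.
#' @return named list of three `public_db` objects (vdjdb, mcpas, tcga).
#' @export
generate_public_dbs <- function(spec, overlap = 5, n_top = 10,
                                n_in_cohort = 16) {
  stopifnot(inherits(spec, "synthetic_spec"), overlap >= 0, overlap <= n_top)
  pool <- background_pool(spec)
  union_size <- if (overlap == n_top) n_top else 3L * n_top - overlap
  n_in_cohort <- min(n_in_cohort, union_size)
  with_seed(substream(spec$seed, 3L), {
    imp <- spec$implanted$cdr3_aa
    # cohort-present sequences: implants first, then high-rank pool clones
    # (top Zipf ranks occur in essentially every generated sample)
    present_pool <- pool$cdr3_aa[seq_len(min(200L, nrow(pool)))]
    present_pool <- setdiff(present_pool, imp)
    present_seq <- c(imp, present_pool)[seq_len(n_in_cohort)]
    novel <- character(0)
    while (length(novel) < union_size - n_in_cohort) {
      cand <- random_cdr3(union_size, spec$cdr3_length_range)
      novel <- unique(c(novel, setdiff(cand, c(pool$cdr3_aa, present_seq))))
    }
    novel <- novel[seq_len(union_size - n_in_cohort)]
    members <- c(present_seq, novel)   # length union_size; present first

    lists <- vector("list", 3L)
    if (overlap == n_top) {
      top <- members[seq_len(n_top)]
      lists <- list(top, top, top)
    } else {
      shared <- if (overlap > 0) members[seq_len(overlap)] else character(0)
      rest <- if (overlap > 0) members[-seq_len(overlap)] else members
      # each shared sequence sits in exactly two lists, cycling over db pairs
      pair <- list(c(1, 2), c(2, 3), c(1, 3))
      shared_in <- lapply(1:3, function(d) character(0))
      for (s in seq_along(shared)) {
        p <- pair[[((s - 1L) %% 3L) + 1L]]
        for (d in p) shared_in[[d]] <- c(shared_in[[d]], shared[s])
      }
      unique_need <- n_top - lengths(shared_in)
      stopifnot(sum(unique_need) == length(rest))
      splits <- rep(1:3, unique_need)
      for (d in 1:3) {
        lists[[d]] <- c(shared_in[[d]], rest[splits == d])
      }
    }
    sources <- c("VDJDB_LIKE", "MCPAS_LIKE", "TCGA_TIL_LIKE")
    dbs <- lapply(1:3, function(d) {
      top <- lists[[d]]
      n_fill <- 150L
      fill <- sample(pool$cdr3_aa[seq(50L, min(5000L, nrow(pool)))], n_fill)
      fill <- setdiff(fill, top)
      records <- data.frame(
        cdr3_aa = c(top, fill),
        prevalence = c(round(seq(500, 60, length.out = length(top))),
                       sample.int(20, length(fill), replace = TRUE)),
        metadata = c(rep("top", length(top)), rep("background", length(fill))),
        stringsAsFactors = FALSE)
      public_db(records, sources[d])
    })
    names(dbs) <- c("vdjdb", "mcpas", "tcga")
    dbs
  })
}

#' Generate a synthetic tumor-infiltrating-lymphocyte (TIL) database
#'
#' Emulates a TIL compendium mined from bulk tumor RNA-seq: each tumor
#' sample's CDR3 set is dominated by private clones (novel sequences seen in
#' that tumor only), plus public clones from the spec's background pool.
#' Public sharing follows a rank-decaying per-tumor inclusion probability
#' `max_share * rank^(-share_decay)`, so even the most public clone appears
#' in at most about `max_share` of tumors — the sharing structure real
#' tumor-TCR compendia show, where no CDR3 is pan-tumor. Each clone in
#' `enriched` is independently added to each tumor with probability
#' `p_enriched`.
#'
#' @param spec a [synthetic_spec()].
#' @param n_tumors number of tumor samples.
#' @param clones_per_tumor integer range of private clones per tumor.
#' @param enriched character vector of clones to enrich (may be empty).
#' @param p_enriched per-tumor inclusion probability for enriched clones.
#' @param max_share per-tumor inclusion probability of the most public clone.
#' @param share_decay rank-decay exponent of public-clone sharing.
#' @param cancer_types labels to assign (recycled sampling).
#' @return object of class `til_db`.
#' @export
generate_til_db <- function(spec, n_tumors = 400,
                            clones_per_tumor = c(30, 100),
                            enriched = character(0), p_enriched = 0,
                            max_share = 0.1, share_decay = 0.7,
                            cancer_types = c("OV", "BRCA", "LUAD", "STAD",
                                             "COAD", "PRAD", "KIRC", "LIHC",
                                             "SKCM", "UCEC")) {
  stopifnot(inherits(spec, "synthetic_spec"),
            p_enriched >= 0, p_enriched <= 1, n_tumors >= 1,
            max_share > 0, max_share <= 1, share_decay >= 0)
  pool <- background_pool(spec)
  q_public <- max_share * seq_len(nrow(pool))^(-share_decay)
  with_seed(substream(spec$seed, 4L), {
    sizes <- sample(seq(clones_per_tumor[1], clones_per_tumor[2]),
                    n_tumors, replace = TRUE)
    types <- sample(cancer_types, n_tumors, replace = TRUE)
    ids <- sprintf("TUMOR_%04d", seq_len(n_tumors))
    # public clones: only ranks with non-negligible sharing can ever appear
    active <- which(q_public * n_tumors > 1e-3)
    samples <- lapply(seq_len(n_tumors), function(i) {
      pub <- pool$cdr3_aa[active[stats::runif(length(active)) < q_public[active]]]
      priv <- random_cdr3(sizes[i], spec$cdr3_length_range)
      cl <- unique(c(pub, priv))
      if (length(enriched)) {
        add <- enriched[stats::runif(length(enriched)) < p_enriched]
        cl <- unique(c(cl, add))
      }
      cl
    })
    names(samples) <- ids
    names(types) <- ids
    til_db(samples, types)
  })
}

#' Construct a TIL database
#'
#' @param samples named list: tumor sample id -> character vector of CDR3s.
#' @param cancer_type named character vector of cancer-type labels per sample.
#' @export
til_db <- function(samples, cancer_type) {
  stopifnot(!is.null(names(samples)), !anyDuplicated(names(samples)),
            all(names(samples) %in% names(cancer_type)),
            all(lengths(samples) > 0))
  n_per <- lengths(samples)
  index <- split(rep(seq_along(samples), n_per),
                 unlist(samples, use.names = FALSE))
  structure(list(samples = samples,
                 cancer_type = cancer_type[names(samples)],
                 index = index),
            class = "til_db")
}

#' @export
print.til_db <- function(x, ...) {
  cat(sprintf("TIL database: %d tumor samples, %d cancer types\n",
              length(x$samples), length(unique(x$cancer_type))))
  invisible(x)
}

#' Write / read a TIL database as a long-format delimited table
#'
#' Columns: `tumor_sample_id`, `cancer_type`, `cdr3_aa` (one clone per row).
#' @export
write_til_db <- function(db, path) {
  df <- data.frame(
    tumor_sample_id = rep(names(db$samples), lengths(db$samples)),
    cancer_type = rep(unname(db$cancer_type), lengths(db$samples)),
    cdr3_aa = unlist(db$samples, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_til_db
#' @export
read_til_db <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  samples <- split(df$cdr3_aa, df$tumor_sample_id)
  types <- tapply(df$cancer_type, df$tumor_sample_id, `[`, 1)
  til_db(samples, types[names(samples)])
}

#' Materialize a complete demo dataset on disk
#'
#' Writes per-sample clonotype tables (MiXCR dialect), a metadata CSV, the
#' three public-database fixtures and a TIL database under `dir`.
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  for (r in cohort) {
    write_clonotypes(r, file.path(dir, paste0(r$sample_id, ".tsv")), "MIXCR")
  }
  md <- data.frame(sample_id = vapply(cohort, `[[`, "", "sample_id"),
                   group = vapply(cohort, `[[`, "", "group"))
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  dbs <- generate_public_dbs(spec)
  for (nm in names(dbs)) {
    write_public_db(dbs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  write_til_db(generate_til_db(spec), file.path(dir, "til_db.tsv"))
  invisible(dir)
}
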
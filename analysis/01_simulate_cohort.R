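#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort and reference databases.
#
# Builds the synthetic analogue of the study design: 85 peripheral-blood TCR
# repertoires (34 ovarian-cancer cases, 51 healthy donors, two of them with
# extremely small repertoires), three public-database fixtures whose top-10
# prevalence lists overlap in 5 sequences, and a 400-tumor TIL database.
# Repertoires regenerate deterministically from the seed, so only the small
# artifacts (metadata, databases, summary) are written to disk.

suppressMessages(library(tcrstrat))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[1] else 1)
dir.create("results/fixtures", showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = seed)
cohort <- generate_cohort(spec)
depths <- vapply(cohort, `[[`, numeric(1), "total_umis")
groups <- vapply(cohort, `[[`, "", "group")
cat(sprintf("cohort: %d repertoires (%d OC / %d HD), depths %s-%s UMIs\n",
            length(cohort), sum(groups == "OC"), sum(groups == "HD"),
            format(min(depths), big.mark = ","),
            format(max(depths), big.mark = ",")))
cat(sprintf("undersized repertoires: %s\n",
            paste(sprintf("%s (%d)", vapply(cohort[depths < 1000], `[[`, "",
                                            "sample_id"),
                          depths[depths < 1000]), collapse = ", ")))

md <- data.frame(sample_id = vapply(cohort, `[[`, "", "sample_id"),
                 group = groups, total_umis = depths)
write.csv(md, "results/fixtures/metadata.csv", row.names = FALSE)

# database fixtures carry the top-clones signature in their top-10 lists
# (the route they seed); the top-down TRB clones stay rare in them
db_spec <- synthetic_spec(implanted = topclones_signature_clones(),
                          seed = seed)
dbs <- generate_public_dbs(db_spec, overlap = 5, n_in_cohort = 16)
for (nm in names(dbs)) {
  write_public_db(dbs[[nm]], file.path("results/fixtures",
                                       paste0(nm, ".tsv")))
}
cat(sprintf("public databases: top-10 union of %d sequences\n",
            length(top_db_clones(dbs))))

tumor_assoc <- unique(c(topdown_signature_clones()$cdr3_aa,
                        topclones_signature_clones()$cdr3_aa))
til <- generate_til_db(spec, n_tumors = 400, enriched = tumor_assoc,
                       p_enriched = 0.3)
write_til_db(til, "results/fixtures/til_db.tsv")
cat(sprintf("TIL database: %d tumors, %d cancer types\n",
            length(til$samples), length(unique(til$cancer_type))))
cat("fixtures written under results/fixtures/\n")
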
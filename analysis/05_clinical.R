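#!/usr/bin/env Rscript
# Stage 5 — clinical anthropometrics and matrilineal penetrance.
#
# Recomputes BMI for every subject, classifies obesity against the demo
# percentile cutoffs (adults against the Chinese adult convention), and
# summarises affection across the demo pedigree's matriline (3 of 7).

suppressMessages(library(mitoscreen))

subj <- read_subjects(subject_table_path())
cuts <- read.delim(demo_bmi_cutoffs_path(), comment.char = "#")
subj$bmi_recomputed <- bmi(subj$weight_kg, subj$height_cm)
subj$class <- vapply(seq_len(nrow(subj)), function(i) {
  classify_obesity(subj$bmi_recomputed[i], subj$age[i], subj$sex[i], cuts)
}, "")
print(subj[, c("id", "age", "sex", "bmi", "bmi_recomputed", "class")])

dir.create("results", showWarnings = FALSE)
write.table(subj, "results/clinical_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

paths <- demo_pedigree_paths()
ped <- read_pedigree(paths["links"], paths["affected"])
s <- matrilineal_summary(ped, "III-1")
cat(sprintf("matrilineal members (proband III-1): %s\n",
            paste(sort(s$matrilineal), collapse = ", ")))
cat(sprintf("affected among them: %d of %d (penetrance %.2f)\n",
            s$n_affected, s$n_matrilineal, s$penetrance))
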
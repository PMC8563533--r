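#!/usr/bin/env Rscript
# Profile interpretation: class-specific mean scores, cutoff bands, automatic
# labels, and paired self/parent tests per profile. Uses the illustrative
# cutoff file shipped with the package; substantive analyses must supply
# their own normed cutoffs.

library(sdqmix)

out <- "results/analysis"
data <- read_dataset(file.path(out, "subjects.csv"), file.path(out, "records.csv"))
model <- load_model(file.path(out, "model.json"))
post <- read.csv(file.path(out, "posteriors.csv"))

cutoffs <- read_cutoffs(system.file("extdata", "example_cutoffs.yaml",
                                    package = "sdqmix"))
means <- profile_bands(class_means(model), cutoffs)
labels <- label_profiles(means, scales = model$meta$scales)

write.csv(means, file.path(out, "profile_means.csv"), row.names = FALSE)
write.csv(data.frame(class = seq_along(labels), label = labels,
                     prevalence = model$pi),
          file.path(out, "profile_labels.csv"), row.names = FALSE)

cat("Profiles (ordered by expected total difficulties):\n")
for (c in seq_along(labels)) {
  cat(sprintf("  %d. %-45s pi = %.3f\n", c, shQuote(labels[c]), model$pi[c]))
}

assignments <- post$modal
tests <- informant_tests(data, assignments)
write.csv(tests, file.path(out, "informant_tests.csv"), row.names = FALSE)
sig <- tests[which(tests$significant), ]
cat(sprintf("\n%d of %d informant comparisons significant after Bonferroni (alpha = 0.01)\n",
            nrow(sig), sum(!tests$skipped)))

p <- plot_profiles(structure(list(means = means, labels = labels,
                                  prevalence = model$pi),
                             class = "sdqmix_profiles"))
ggplot2::ggsave(file.path(out, "profiles.pdf"), p, width = 8, height = 5)
cat(sprintf("Wrote profile plot to %s\n", file.path(out, "profiles.pdf")))
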
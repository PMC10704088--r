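#!/usr/bin/env Rscript
# Descriptive tables and group comparisons over the fitted cohort
# parameters: wavelength-resolved median (IQR) optical-property table,
# sex/age/BMI group tests (Mann-Whitney, Kruskal-Wallis with Dunn's
# Bonferroni post hocs), and the age trend of the scattering amplitude.

library(skindrs)

tab <- compile_hemoglobin_table()
truth <- read.table("results/cohort_truth.tsv", header = TRUE, sep = "\t")
fits <- read.table("results/cohort_fits.tsv", header = TRUE, sep = "\t")
keep <- !fits$excluded
cat(sprintf("using %d of %d fitted subjects\n", sum(keep), nrow(fits)))
f <- fits[keep, ]
cov <- truth[keep, c("sex", "age", "bmi_group")]

## Wavelength-resolved optical-property summary ---------------------------
wavelengths <- seq(475, 850, by = 25)
rows <- lapply(wavelengths, function(wl) {
  per <- t(vapply(seq_len(nrow(f)), function(i) {
    p <- skin_params_from_vector(unlist(f[i, cohort_quartiles()$param]))
    mua <- layer_absorptions(p, wl, tab)[1, ]
    c(mua1 = unname(mua[2]), mua2 = unname(mua[3]),
      mel_absorbance = unname(mua[1]) * p$epidermis$t_epi,
      musp = reduced_scattering(wl, p$scattering))
  }, numeric(4)))
  sm <- cohort_summary(per)
  data.frame(wavelength = wl, quantity = rownames(sm), sm, row.names = NULL)
})
summary_tab <- do.call(rbind, rows)
write.table(summary_tab, "results/optical_property_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
print(subset(summary_tab, wavelength %in% c(475, 600, 850)))

## Group comparisons at 570 nm --------------------------------------------
mua570 <- vapply(seq_len(nrow(f)), function(i) {
  p <- skin_params_from_vector(unlist(f[i, cohort_quartiles()$param]))
  layer_absorptions(p, 570, tab)[1, 2]
}, numeric(1))

sex_test <- group_tests(mua570, cov$sex)
cat(sprintf("upper-dermis mu_a(570) by sex: U = %.0f, p = %.3f\n",
            sex_test$statistic, sex_test$p_value))

age_group <- cut(cov$age, c(50, 55, 60, 65.4), right = FALSE,
                 labels = c("50-54.9", "55-59.9", "60-65"))
alpha_by_age <- group_tests(f$alpha, age_group)
cat(sprintf("alpha by age group: H = %.2f, p = %.3f\n",
            alpha_by_age$statistic, alpha_by_age$p_value))
print(alpha_by_age$posthoc)

bmi_group <- factor(cov$bmi_group)
if (nlevels(bmi_group) >= 2 && all(table(bmi_group) >= 2)) {
  bmi_test <- group_tests(mua570, bmi_group)
  cat(sprintf("mu_a(570) by BMI group: H = %.2f, p = %.3f\n",
              bmi_test$statistic, bmi_test$p_value))
}

## Age trend of the scattering amplitude ----------------------------------
tr <- trend_regression(cov$age, f$alpha)
cat(sprintf("alpha ~ age: slope %.4f mm^-1/yr (SE %.4f), p = %.3f\n",
            tr$slope, tr$se, tr$p_value))
trend <- data.frame(slope = tr$slope, se = tr$se, p_value = tr$p_value)
write.table(trend, "results/age_trend.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
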